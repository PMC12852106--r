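#' Read a directed network from an edge-list file
#'
#' Parses the plain-text edge lists produced by GRN inference tools: one
#' interaction per line, `source<sep>target[<sep>weight]`, tab- or
#' comma-separated (detected automatically). Lines starting with `#` are
#' skipped. A header row is detected by the non-numeric-third-field
#' heuristic: if the first data line has three fields and the third does not
#' parse as a number, the line is treated as a header. Any weight column is
#' parsed and then ignored: the controllability analysis is purely
#' topological.
#'
#' @param path edge-list file.
#' @param tf_list optional path to a transcription-factor list (one symbol
#'   per line, e.g. an AnimalTFDB export); `tf_nodes` becomes its
#'   intersection with the network's nodes. When absent, all source nodes
#'   are flagged as TFs.
#' @param nodes optional path to a node sidecar (one symbol per line)
#'   declaring the full node set, including isolated nodes.
#' @param name,phase passed to [grn_network()]; `name` defaults to the file
#'   name without extension.
#' @return A sanitized [grn_network()].
#' @export
read_edge_list <- function(path, tf_list = NULL, nodes = NULL,
                           name = NULL, phase = NA_integer_) {
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    stop("empty edge-list file: ", path, call. = FALSE)
  }

  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad)) {
    stop("malformed edge list at line ", lineno[bad[1]], " of ", path,
         ": expected 2-3 fields, got ", nf[bad[1]], call. = FALSE)
  }

  start <- 1L
  if (nf[1] == 3 &&
      is.na(suppressWarnings(as.numeric(trimws(fields[[1]][3]))))) {
    start <- 2L  # header row
    if (length(lines) == 1) {
      stop("edge-list file contains only a header: ", path, call. = FALSE)
    }
  }
  fields <- fields[start:length(fields)]
  src <- trimws(vapply(fields, `[[`, "", 1))
  tgt <- trimws(vapply(fields, `[[`, "", 2))
  # third column, when present, must be a numeric weight; parsed and dropped
  has3 <- vapply(fields, length, 0L) == 3
  if (any(has3)) {
    w <- suppressWarnings(as.numeric(vapply(fields[has3], `[[`, "", 3)))
    if (anyNA(w)) {
      at <- lineno[start:length(lineno)][has3][which(is.na(w))[1]]
      stop("non-numeric weight at line ", at, " of ", path, call. = FALSE)
    }
  }

  sidecar <- if (!is.null(nodes)) read_symbol_list(nodes) else NULL
  tfs <- if (!is.null(tf_list)) read_symbol_list(tf_list) else NULL
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  grn_network(tibble::tibble(source = src, target = tgt),
              nodes = sidecar, tf_nodes = tfs, name = name, phase = phase)
}

read_symbol_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  x[nzchar(x) & !grepl("^#", x)]
}

#' Write a network to an edge-list file
#'
#' Writes a tab-separated `source target` file that [read_edge_list()] reads
#' back losslessly. Optional sidecar files preserve the full node set
#' (including isolated nodes) and the TF flags, so the round trip reproduces
#' the node set, edge set and TF membership exactly.
#'
#' @param net a [grn_network()].
#' @param path output edge-list file.
#' @param nodes_path optional path for a node sidecar (one symbol per line).
#' @param tf_path optional path for a TF-list sidecar.
#' @return `net`, invisibly.
#' @export
write_edge_list <- function(net, path, nodes_path = NULL, tf_path = NULL) {
  assert_network(net)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(net$edges$source, net$edges$target, sep = "\t"),
             con, useBytes = TRUE)
  if (!is.null(nodes_path)) {
    writeLines(net$nodes, nodes_path, useBytes = TRUE)
  }
  if (!is.null(tf_path)) {
    writeLines(net$tf_nodes, tf_path, useBytes = TRUE)
  }
  invisible(net)
}

#' Export a network as GraphML
#'
#' Convenience export for graph viewers; node attribute `tf` marks
#' transcription factors.
#'
#' @param net a [grn_network()].
#' @param path output file.
#' @return `net`, invisibly.
#' @export
write_graphml <- function(net, path) {
  assert_network(net)
  g <- as_igraph(net)
  igraph::V(g)$tf <- as.integer(igraph::V(g)$name %in% net$tf_nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(net)
}
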