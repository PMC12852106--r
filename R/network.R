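#' Directed gene regulatory network
#'
#' `grn_network()` builds the directed-network object consumed by every
#' analysis stage from an edge table. Edges run from a regulator
#' (transcription factor) to a target gene. Construction sanitizes the input:
#' self-loops are dropped with a warning and duplicate edges are collapsed,
#' so the edge set is a simple directed graph -- the setting in which the
#' matching-based controllability quantities are defined.
#'
#' @param edges data frame with character columns `source` and `target`
#'   (extra columns are ignored). May have zero rows.
#' @param nodes optional character vector of node symbols. Endpoints of
#'   `edges` are always included; listing extra symbols declares isolated
#'   (degree-zero) nodes, which count towards `N` in density and
#'   driver-fraction calculations.
#' @param tf_nodes optional character vector flagging which nodes are
#'   transcription factors. Matching is exact-string (gene symbols are
#'   case-significant). Defaults to the set of source nodes.
#' @param name free-text label for the network.
#' @param phase optional integer group label (e.g. developmental phase 1-4).
#'
#' @return An object of class `grn_network`: a list with elements
#'   `edges` (tibble, sorted by source then target), `nodes` (sorted
#'   character), `tf_nodes`, `name`, `phase`.
#' @examples
#' net <- grn_network(data.frame(source = c("a", "b"), target = c("b", "c")))
#' network_size(net)
#' @export
grn_network <- function(edges, nodes = NULL, tf_nodes = NULL,
                        name = "network", phase = NA_integer_) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("source", "target") %in% names(edges))) {
    stop("`edges` must have columns `source` and `target`", call. = FALSE)
  }
  src <- as.character(if (nrow(edges)) edges$source else character())
  tgt <- as.character(if (nrow(edges)) edges$target else character())
  if (anyNA(src) || anyNA(tgt) || any(src == "") || any(tgt == "")) {
    stop("edge endpoints must be non-missing, non-empty symbols", call. = FALSE)
  }

  loop <- src == tgt
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) removed during sanitization",
            call. = FALSE)
    src <- src[!loop]
    tgt <- tgt[!loop]
  }
  key <- paste(src, tgt, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed during sanitization",
            call. = FALSE)
    src <- src[!dup]
    tgt <- tgt[!dup]
  }

  all_nodes <- unique(c(src, tgt, as.character(nodes %||% character())))
  all_nodes <- sort_c(all_nodes)
  tf <- if (is.null(tf_nodes)) unique(src) else as.character(tf_nodes)
  tf <- sort_c(intersect(tf, all_nodes))

  ord <- order(src, tgt, method = "radix")
  out <- structure(
    list(
      edges = tibble::tibble(source = src[ord], target = tgt[ord]),
      nodes = all_nodes,
      tf_nodes = tf,
      name = as.character(name),
      phase = as.integer(phase)
    ),
    class = "grn_network"
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic, locale-independent ordering of gene symbols
sort_c <- function(x) x[order(x, method = "radix")]

#' @export
print.grn_network <- function(x, ...) {
  cat("<grn_network> ", x$name,
      if (!is.na(x$phase)) paste0(" (phase ", x$phase, ")") else "", "\n",
      sep = "")
  cat("  nodes: ", length(x$nodes),
      "  edges: ", nrow(x$edges),
      "  TFs: ", length(x$tf_nodes), "\n", sep = "")
  invisible(x)
}

#' Node and edge counts of a network
#'
#' @param net a [grn_network()].
#' @return One-row tibble with columns `N` (nodes) and `L` (edges).
#' @export
network_size <- function(net) {
  assert_network(net)
  tibble::tibble(N = length(net$nodes), L = nrow(net$edges))
}

assert_network <- function(net) {
  if (!inherits(net, "grn_network")) {
    stop("expected a `grn_network` object", call. = FALSE)
  }
  invisible(net)
}

# integer-encoded edge list for the matching kernel
edge_index <- function(net) {
  list(
    n = length(net$nodes),
    src = match(net$edges$source, net$nodes),
    tgt = match(net$edges$target, net$nodes)
  )
}

#' Per-node degrees of a directed network
#'
#' @param net a [grn_network()].
#' @param mode which degree to count: `"total"` (in + out), `"in"`, or
#'   `"out"`.
#' @return Tibble with columns `node` and `degree`, one row per node
#'   (degree-zero nodes included).
#' @export
node_degrees <- function(net, mode = c("total", "in", "out")) {
  assert_network(net)
  mode <- match.arg(mode)
  outd <- tabulate(match(net$edges$source, net$nodes), length(net$nodes))
  ind <- tabulate(match(net$edges$target, net$nodes), length(net$nodes))
  deg <- switch(mode, total = outd + ind, `in` = ind, out = outd)
  tibble::tibble(node = net$nodes, degree = deg)
}

#' Node and edge overlap between two networks
#'
#' Jaccard similarity of the node sets and of the directed edge sets,
#' quantifying how much two regulatory networks share -- e.g. networks
#' inferred for related cell types, which are typically subgraphs of a
#' common larger network.
#'
#' @param a,b [grn_network()] objects. At least one node between them.
#' @return One-row tibble with `node_overlap` and `edge_overlap`, each the
#'   Jaccard index `|A intersect B| / |A union B|` in `[0, 1]`. An empty
#'   union of edges yields `NA` for `edge_overlap`.
#' @export
network_overlap <- function(a, b) {
  assert_network(a)
  assert_network(b)
  if (length(a$nodes) == 0 && length(b$nodes) == 0) {
    stop("overlap is undefined for two empty networks", call. = FALSE)
  }
  jac <- function(x, y) {
    u <- length(union(x, y))
    if (u == 0) NA_real_ else length(intersect(x, y)) / u
  }
  ekey <- function(n) paste(n$edges$source, n$edges$target, sep = "\r")
  tibble::tibble(
    node_overlap = jac(a$nodes, b$nodes),
    edge_overlap = jac(ekey(a), ekey(b))
  )
}

# igraph view of the network (directions kept; used for connectivity and
# GraphML export)
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges),
    directed = TRUE,
    vertices = data.frame(name = net$nodes)
  )
}
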