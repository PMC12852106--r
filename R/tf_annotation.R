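#' Total-count normalization with log1p transform
#'
#' Normalizes a gene-by-sample table of raw count sums (e.g. counts summed
#' across all cells of a sample) by total-count scaling followed by a
#' `log1p` transform: `value = log(1 + scale * count / sample_total)`.
#' Within each sample the pre-log values sum to `scale`, and the transform
#' is strictly monotone in the raw count, so any rank-based downstream rule
#' (such as an upper-quartile cut) is invariant to the choice of `scale`.
#'
#' @param counts either a long data frame with columns `gene`, `sample`,
#'   `count`, or a numeric matrix / wide data frame with genes as rows
#'   (rownames) and samples as columns.
#' @param scale library-size scale factor (default `1e6`, CPM-style).
#' @return An object of class `grn_expression`: tibble with columns `gene`,
#'   `sample`, `count`, `normalized`.
#' @examples
#' m <- matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' normalize_expression(m, scale = 100)
#' @export
normalize_expression <- function(counts, scale = 1e6) {
  long <- as_long_counts(counts)
  if (any(long$count < 0) || anyNA(long$count)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  totals <- tapply(long$count, long$sample, sum)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total count: ",
         paste(names(totals)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  long$normalized <- log1p(scale * long$count /
                             as.numeric(totals[long$sample]))
  out <- tibble::as_tibble(long[c("gene", "sample", "count", "normalized")])
  class(out) <- c("grn_expression", class(out))
  attr(out, "scale") <- scale
  out
}

as_long_counts <- function(counts) {
  if (is.data.frame(counts) &&
      all(c("gene", "sample", "count") %in% names(counts))) {
    return(data.frame(gene = as.character(counts$gene),
                      sample = as.character(counts$sample),
                      count = as.numeric(counts$count)))
  }
  m <- as.matrix(counts)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix input needs gene rownames and sample colnames",
         call. = FALSE)
  }
  data.frame(
    gene = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    count = as.numeric(m)
  )
}

#' Categorize transcription factors within one network
#'
#' Flags each TF of a network along three axes of regulatory importance:
#' \describe{
#'   \item{Critical}{the TF is the source of at least one critical edge
#'     (see [classify_edges()]);}
#'   \item{high-outdegree (HO)}{out-degree strictly greater than
#'     `outdeg_threshold` (default 50);}
#'   \item{high-expression (HE)}{normalized expression strictly above the
#'     `he_quantile` quantile (default the 3rd quartile) of the TF
#'     expression values for this network's sample.}
#' }
#'
#' @param net a [grn_network()].
#' @param cls a [classify_edges()] result for `net`.
#' @param expr a [normalize_expression()] table covering the network's TFs,
#'   or `NULL` to skip the expression axis.
#' @param sample sample name inside `expr` for this network; defaults to
#'   the network name.
#' @param outdeg_threshold out-degree cut (strict `>`).
#' @param he_quantile expression quantile cut (strict `>`), computed over
#'   the TFs of this network present in the sample.
#' @return Tibble with one row per TF: `network`, `phase`, `tf`,
#'   `outdegree`, `expression`, `is_critical`, `is_high_outdegree`,
#'   `is_high_expression`, `expr_missing`. TFs absent from `expr` are
#'   flagged missing and excluded from HE (with a warning).
#' @export
categorize_tfs <- function(net, cls, expr = NULL, sample = net$name,
                           outdeg_threshold = 50, he_quantile = 0.75) {
  assert_network(net)
  if (!inherits(cls, "grn_edge_class") || cls$network != net$name) {
    stop("`cls` must be the edge classification of `net`", call. = FALSE)
  }
  tfs <- net$tf_nodes
  if (length(tfs) == 0) {
    warning("network ", net$name, " has no TFs to categorize", call. = FALSE)
  }
  outd <- node_degrees(net, "out")
  outdeg <- setNames(outd$degree, outd$node)[tfs]
  crit_src <- unique(cls$edges$source[cls$edges$label == "critical"])

  expression <- rep(NA_real_, length(tfs))
  missing <- rep(is.null(expr), length(tfs))
  if (!is.null(expr)) {
    ex <- expr[expr$sample == sample, ]
    idx <- match(tfs, ex$gene)
    expression <- ex$normalized[idx]
    missing <- is.na(idx)
    if (any(missing)) {
      warning(sum(missing), " TF(s) absent from expression sample '",
              sample, "'; excluded from the HE category", call. = FALSE)
    }
  }
  he <- rep(FALSE, length(tfs))
  if (!is.null(expr) && any(!missing)) {
    cut <- quantile(expression[!missing], he_quantile, names = FALSE)
    he[!missing] <- expression[!missing] > cut
  }

  tibble::tibble(
    network = net$name,
    phase = net$phase,
    tf = tfs,
    outdegree = as.integer(outdeg),
    expression = expression,
    is_critical = tfs %in% crit_src,
    is_high_outdegree = outdeg > outdeg_threshold,
    is_high_expression = he,
    expr_missing = missing
  )
}

venn_regions <- c("C_only", "HO_only", "HE_only",
                  "C_HO", "C_HE", "HO_HE", "C_HO_HE")

#' Integrate TF categories across a cohort of networks
#'
#' Union semantics: a TF belongs to a category if it was assigned to that
#' category in any network of the cohort. The three unioned categories are
#' then partitioned into the 7 disjoint regions of their Venn diagram
#' (`C_only`, `HO_only`, `HE_only`, `C_HO`, `C_HE`, `HO_HE`, `C_HO_HE`);
#' TFs in no category are dropped.
#'
#' @param flags a [categorize_tfs()] tibble, or a list of them (one per
#'   network), covering at least one network.
#' @return An object of class `grn_tf_categories`: `tf_table` (one row per
#'   categorized TF with the union flags and its Venn `region`) and `venn`
#'   (region, n, members list-column; regions are pairwise disjoint and
#'   cover all categorized TFs).
#' @export
integrate_categories <- function(flags) {
  if (is.data.frame(flags)) flags <- list(flags)
  stopifnot(length(flags) >= 1)
  all_flags <- dplyr::bind_rows(flags)
  per_tf <- all_flags %>%
    dplyr::group_by(.data$tf) %>%
    dplyr::summarise(
      is_critical = any(.data$is_critical),
      is_high_outdegree = any(.data$is_high_outdegree),
      is_high_expression = any(.data$is_high_expression),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$is_critical | .data$is_high_outdegree |
                    .data$is_high_expression) %>%
    dplyr::mutate(region = venn_region(.data$is_critical,
                                       .data$is_high_outdegree,
                                       .data$is_high_expression)) %>%
    dplyr::arrange(.data$tf)

  venn <- tibble::tibble(region = factor(venn_regions,
                                         levels = venn_regions)) %>%
    dplyr::left_join(
      per_tf %>% dplyr::group_by(.data$region) %>%
        dplyr::summarise(n = dplyr::n(),
                         members = list(.data$tf), .groups = "drop"),
      by = "region"
    ) %>%
    dplyr::mutate(
      n = ifelse(is.na(.data$n), 0L, .data$n),
      members = purrr::map(.data$members, ~ .x %||% character())
    )

  structure(list(tf_table = per_tf, venn = venn),
            class = "grn_tf_categories")
}

venn_region <- function(c, ho, he) {
  factor(
    dplyr::case_when(
      c & ho & he ~ "C_HO_HE",
      c & ho ~ "C_HO",
      c & he ~ "C_HE",
      ho & he ~ "HO_HE",
      c ~ "C_only",
      ho ~ "HO_only",
      he ~ "HE_only"
    ),
    levels = venn_regions
  )
}

#' @export
print.grn_tf_categories <- function(x, ...) {
  cat("<grn_tf_categories> ", nrow(x$tf_table), " categorized TFs\n",
      sep = "")
  print(x$venn[c("region", "n")])
  invisible(x)
}

#' @describeIn integrate_categories per-TF union flags and Venn region.
#' @param x a `grn_tf_categories` object.
#' @param ... unused.
#' @export
tidy.grn_tf_categories <- function(x, ...) {
  x$tf_table
}

#' @describeIn integrate_categories Venn region counts as one wide row.
#' @export
glance.grn_tf_categories <- function(x, ...) {
  out <- as.list(setNames(x$venn$n, as.character(x$venn$region)))
  tibble::as_tibble(out) %>%
    dplyr::mutate(n_tfs = nrow(x$tf_table))
}

#' Write Venn-region gene lists
#'
#' Exports each region of the integrated Venn partition as a plain gene
#' list (one symbol per line), suitable for submission to a pathway
#' enrichment service.
#'
#' @param categories a [integrate_categories()] result.
#' @param dir output directory (created if needed).
#' @return The file paths, invisibly.
#' @export
write_venn_gene_lists <- function(categories, dir) {
  stopifnot(inherits(categories, "grn_tf_categories"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_len(nrow(categories$venn)), function(i) {
    region <- as.character(categories$venn$region[i])
    p <- file.path(dir, paste0(region, ".txt"))
    writeLines(categories$venn$members[[i]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Top out-degree hub genes
#'
#' Ranks the transcription factors of a network by out-degree (number of
#' distinct targets) and returns the top `k`, the conventional shortlist of
#' putative master regulators. Ties are broken lexicographically so the
#' ranking is stable across runs.
#'
#' @param net a [grn_network()].
#' @param k number of hubs to return (default 10).
#' @return Tibble with columns `tf`, `outdegree`, sorted by decreasing
#'   out-degree. Empty (with a warning) when no TF has out-degree >= 1.
#' @export
hub_genes <- function(net, k = 10) {
  assert_network(net)
  outd <- node_degrees(net, "out")
  tf <- outd[outd$node %in% net$tf_nodes & outd$degree >= 1, ]
  if (nrow(tf) == 0) {
    warning("network ", net$name, " has no TF sources; no hubs to rank",
            call. = FALSE)
    return(tibble::tibble(tf = character(), outdegree = integer()))
  }
  ord <- order(-tf$degree, tf$node, method = "radix")
  out <- tf[ord, ][seq_len(min(k, nrow(tf))), ]
  tibble::tibble(tf = out$node, outdegree = as.integer(out$degree))
}
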