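#' Maximum matching of a directed network
#'
#' A matching of a directed graph, in the structural-controllability sense,
#' is an edge set in which no two edges share a source node or share a
#' target node: each node is split into an out-copy and an in-copy and edge
#' `u -> v` becomes the bipartite edge `(u+, v-)`. The size of a maximum
#' matching determines the minimum number of driver nodes,
#' `N_D = max(N - |M*|, 1)`. The matching itself is generally not unique;
#' its cardinality is.
#'
#' @param net a [grn_network()].
#' @return Tibble of the matched edges (columns `source`, `target`) with
#'   attribute `matching_size`.
#' @examples
#' net <- grn_network(data.frame(source = c("a", "b"), target = c("b", "c")))
#' max_matching(net)
#' @export
max_matching <- function(net) {
  assert_network(net)
  ei <- edge_index(net)
  if (ei$n == 0 || length(ei$src) == 0) {
    out <- tibble::tibble(source = character(), target = character())
    attr(out, "matching_size") <- 0L
    return(out)
  }
  res <- max_matching_cpp(ei$n, ei$src, ei$tgt)
  ids <- res$match_from_source
  ids <- ids[ids > 0]
  out <- net$edges[sort(ids), ]
  attr(out, "matching_size") <- res$size
  out
}

#' Minimum driver-node set
#'
#' Computes the minimum number of driver nodes `N_D` -- the nodes that must
#' receive an independent external input for the network state to be fully
#' steerable -- via the maximum-matching criterion:
#' `N_D = max(N - |M*|, 1)`. The drivers are the nodes whose in-copy is
#' unmatched. When the matching is perfect the floor applies and a single
#' driver suffices; the lexicographically smallest node symbol is reported
#' for reproducibility. `N_D` and the driver fraction `n_D = N_D / N` are
#' invariant to which maximum matching is found.
#'
#' @param net a [grn_network()] with at least one node.
#' @return An object of class `grn_driver` with fields `matching_size`,
#'   `n_drivers`, `driver_fraction`, `driver_set`, `N`, `L`, `network`.
#'   See [tidy.grn_driver()] and [glance.grn_driver()].
#' @examples
#' path <- grn_network(data.frame(source = c("a", "b"), target = c("b", "c")))
#' glance(driver_nodes(path))
#' @export
driver_nodes <- function(net) {
  assert_network(net)
  N <- length(net$nodes)
  if (N == 0) stop("driver nodes are undefined for an empty node set",
                   call. = FALSE)
  ei <- edge_index(net)
  if (length(ei$src) == 0) {
    m <- 0L
    unmatched <- net$nodes
  } else {
    res <- max_matching_cpp(ei$n, ei$src, ei$tgt)
    m <- res$size
    unmatched <- net$nodes[res$match_into_target == 0]
  }
  if (N - m >= 1) {
    drivers <- sort_c(unmatched)
  } else {
    drivers <- net$nodes[1]  # perfect matching: floor rule, deterministic pick
  }
  structure(
    list(
      matching_size = as.integer(m),
      n_drivers = length(drivers),
      driver_fraction = length(drivers) / N,
      driver_set = drivers,
      N = N,
      L = nrow(net$edges),
      network = net$name
    ),
    class = "grn_driver"
  )
}

#' @export
print.grn_driver <- function(x, ...) {
  cat("<grn_driver> ", x$network, ": |M*| = ", x$matching_size,
      ", N_D = ", x$n_drivers, " of ", x$N,
      " (n_D = ", signif(x$driver_fraction, 4), ")\n", sep = "")
  invisible(x)
}

#' @describeIn driver_nodes one row per node with its driver status.
#' @param x a `grn_driver` object.
#' @param ... unused.
#' @export
tidy.grn_driver <- function(x, ...) {
  tibble::tibble(
    node = sort_c(unique(c(x$driver_set))),
    is_driver = TRUE
  )
}

#' @describeIn driver_nodes one-row summary (`matching_size`, `n_drivers`,
#'   `driver_fraction`, `N`, `L`).
#' @export
glance.grn_driver <- function(x, ...) {
  tibble::tibble(
    network = x$network,
    N = x$N,
    L = x$L,
    matching_size = x$matching_size,
    n_drivers = x$n_drivers,
    driver_fraction = x$driver_fraction
  )
}

#' Critical / redundant / ordinary edge classification
#'
#' Classifies every edge by its role in structural controllability:
#' \describe{
#'   \item{critical}{removal increases the number of driver nodes `N_D`;}
#'   \item{redundant}{the edge belongs to no maximum matching, so it can be
#'     removed without affecting any minimum driver configuration;}
#'   \item{ordinary}{neither -- the edge lies in some but not every maximum
#'     matching, or sustains a perfect matching whose loss is absorbed by
#'     the driver-count floor.}
#' }
#' The redundancy test deletes the edge's endpoint copies from the bipartite
#' representation: the edge lies in no maximum matching exactly when the
#' maximum matching of the remainder plus one is strictly smaller than
#' `|M*|`.
#'
#' @param net a [grn_network()] with at least one edge.
#' @param method `"incremental"` (default; single augmenting-path searches
#'   against a frozen maximum matching) or `"recompute"` (naive full
#'   recomputation per edge). Both return identical labels; `"recompute"`
#'   exists as an internal cross-check and for small graphs.
#' @return An object of class `grn_edge_class`: per-edge labels plus the
#'   class fractions `l_c`, `l_r`, `l_o` (which sum to one).
#' @examples
#' tri <- grn_network(data.frame(source = c("a", "b", "a"),
#'                               target = c("b", "c", "c")))
#' glance(classify_edges(tri))
#' @export
classify_edges <- function(net, method = c("incremental", "recompute")) {
  assert_network(net)
  method <- match.arg(method)
  L <- nrow(net$edges)
  if (L == 0) stop("edge classification is undefined for L = 0",
                   call. = FALSE)
  ei <- edge_index(net)
  if (method == "incremental") {
    res <- classify_edges_cpp(ei$n, ei$src, ei$tgt)
    labels <- res$labels
    m <- res$matching_size
  } else {
    full <- max_matching_cpp(ei$n, ei$src, ei$tgt)
    m <- full$size
    labels <- vapply(seq_len(L), function(e) {
      drop <- max_matching_cpp(ei$n, ei$src[-e], ei$tgt[-e])$size
      if (drop < m && ei$n - m >= 1) return(1L)
      keep <- !(ei$src == ei$src[e] | ei$tgt == ei$tgt[e])
      reduced <- max_matching_cpp(ei$n, ei$src[keep], ei$tgt[keep])$size
      if (reduced + 1 < m) 2L else 3L
    }, integer(1))
  }
  lab <- factor(c("critical", "redundant", "ordinary")[labels],
                levels = c("critical", "redundant", "ordinary"))
  counts <- table(lab)
  structure(
    list(
      edges = tibble::tibble(source = net$edges$source,
                             target = net$edges$target,
                             label = lab),
      matching_size = as.integer(m),
      l_c = unname(counts[["critical"]]) / L,
      l_r = unname(counts[["redundant"]]) / L,
      l_o = unname(counts[["ordinary"]]) / L,
      N = length(net$nodes),
      L = L,
      network = net$name
    ),
    class = "grn_edge_class"
  )
}

#' @export
print.grn_edge_class <- function(x, ...) {
  cat("<grn_edge_class> ", x$network, ": L = ", x$L,
      "  l_c = ", signif(x$l_c, 4),
      "  l_r = ", signif(x$l_r, 4),
      "  l_o = ", signif(x$l_o, 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn classify_edges per-edge tibble (`source`, `target`, `label`).
#' @param x a `grn_edge_class` object.
#' @param ... unused.
#' @export
tidy.grn_edge_class <- function(x, ...) {
  x$edges
}

#' @describeIn classify_edges one-row summary with the class fractions.
#' @export
glance.grn_edge_class <- function(x, ...) {
  tibble::tibble(
    network = x$network,
    N = x$N,
    L = x$L,
    matching_size = x$matching_size,
    l_c = x$l_c,
    l_r = x$l_r,
    l_o = x$l_o
  )
}
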