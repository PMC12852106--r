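#' Giant-component fraction
#'
#' Fraction of nodes in the largest weakly connected component (edge
#' directions are ignored for connectivity).
#'
#' @param net a [grn_network()] with at least one node.
#' @return Scalar in `(0, 1]`.
#' @export
gcc_fraction <- function(net) {
  assert_network(net)
  N <- length(net$nodes)
  if (N == 0) stop("GCC fraction is undefined for an empty network",
                   call. = FALSE)
  if (nrow(net$edges) == 0) return(1 / N)
  comp <- igraph::components(as_igraph(net), mode = "weak")
  max(comp$csize) / N
}

#' Robustness to random edge removal
#'
#' Simulates random edge failure: for each of `n_perm` independent
#' permutations of the edge set, edges are removed one at a time and the
#' giant-component (GCC) fraction is recorded after every removal. The
#' per-permutation trajectories are aggregated pointwise into a mean and
#' standard deviation on the grid `0, 1/L, ..., 1` of removal fractions,
#' and robustness is summarised as the trapezoidal area under the mean
#' curve.
#'
#' Internally each trajectory is computed in reverse with a union-find
#' structure (edges are added back one at a time), which makes a full curve
#' cost nearly linear in `L` and guarantees the per-run trajectory is
#' non-increasing in the removal fraction.
#'
#' @param net a [grn_network()] with `L >= 1`.
#' @param n_perm number of independent edge permutations (default 20).
#' @param seed master seed; per-permutation child seeds are derived from it
#'   deterministically, so the whole curve is reproducible.
#' @return An object of class `grn_robustness`: `curve` tibble
#'   (`removal_fraction`, `gcc_mean`, `gcc_sd`), `auc`, `run_auc`
#'   (per-permutation AUCs), `runs` matrix, `n_perm`, `seed`.
#' @examples
#' cyc <- grn_network(data.frame(source = c("a", "b", "c"),
#'                               target = c("b", "c", "a")))
#' edge_removal_curve(cyc, n_perm = 5, seed = 1)$auc  # 7/9
#' @export
edge_removal_curve <- function(net, n_perm = 20, seed = 1) {
  assert_network(net)
  L <- nrow(net$edges)
  N <- length(net$nodes)
  if (L < 1) stop("edge-removal curve requires at least one edge",
                  call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be at least 1", call. = FALSE)

  ei <- edge_index(net)
  child <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_perm))
  runs <- matrix(NA_real_, nrow = L + 1, ncol = n_perm)
  for (j in seq_len(n_perm)) {
    ord <- withr::with_seed(child[j], sample.int(L))
    # reverse time: add edges back in reverse removal order, track the GCC
    gcc <- gcc_growth(N, ei$src[rev(ord)], ei$tgt[rev(ord)])
    runs[, j] <- rev(gcc) / N  # row i = GCC fraction after (i - 1) removals
  }
  fractions <- (0:L) / L
  curve <- tibble::tibble(
    removal_fraction = fractions,
    gcc_mean = rowMeans(runs),
    gcc_sd = apply(runs, 1, sd)
  )
  structure(
    list(
      curve = curve,
      auc = trapezoid(fractions, rowMeans(runs)),
      run_auc = apply(runs, 2, function(y) trapezoid(fractions, y)),
      runs = runs,
      n_perm = as.integer(n_perm),
      seed = as.integer(seed),
      network = net$name
    ),
    class = "grn_robustness"
  )
}

# largest component size after each successive edge addition
# (union-find with path halving; sizes are monotone non-decreasing)
gcc_growth <- function(N, src, tgt) {
  parent <- seq_len(N)
  csize <- rep(1L, N)
  best <- 1L
  L <- length(src)
  out <- integer(L + 1)
  out[1] <- best
  for (i in seq_len(L)) {
    a <- src[i]
    while (parent[a] != a) {
      parent[a] <- parent[parent[a]]
      a <- parent[a]
    }
    b <- tgt[i]
    while (parent[b] != b) {
      parent[b] <- parent[parent[b]]
      b <- parent[b]
    }
    if (a != b) {
      if (csize[a] < csize[b]) {
        tmp <- a
        a <- b
        b <- tmp
      }
      parent[b] <- a
      csize[a] <- csize[a] + csize[b]
      if (csize[a] > best) best <- csize[a]
    }
    out[i + 1] <- best
  }
  out
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Area under a GCC removal curve
#'
#' Trapezoidal integral of the mean GCC fraction over the removal-fraction
#' grid. Accepts either a [edge_removal_curve()] result or a data frame
#' with columns `removal_fraction` and `gcc_mean`.
#'
#' @param curve a `grn_robustness` object or curve data frame with a
#'   strictly increasing `removal_fraction` grid of at least two points.
#' @return Scalar AUC.
#' @export
robustness_auc <- function(curve) {
  if (inherits(curve, "grn_robustness")) curve <- curve$curve
  stopifnot(is.data.frame(curve),
            all(c("removal_fraction", "gcc_mean") %in% names(curve)))
  x <- curve$removal_fraction
  if (length(x) < 2) stop("AUC requires at least two grid points",
                          call. = FALSE)
  if (is.unsorted(x, strictly = TRUE)) {
    stop("removal-fraction grid must be strictly increasing", call. = FALSE)
  }
  trapezoid(x, curve$gcc_mean)
}

#' @export
print.grn_robustness <- function(x, ...) {
  cat("<grn_robustness> ", x$network, ": ", x$n_perm,
      " permutations, AUC = ", signif(x$auc, 5), "\n", sep = "")
  invisible(x)
}

#' @describeIn edge_removal_curve the aggregated curve as a tibble.
#' @param x a `grn_robustness` object.
#' @param ... unused.
#' @export
tidy.grn_robustness <- function(x, ...) {
  x$curve
}

#' @describeIn edge_removal_curve one-row summary (`auc`, `n_perm`, `seed`).
#' @export
glance.grn_robustness <- function(x, ...) {
  tibble::tibble(
    network = x$network,
    auc = x$auc,
    n_perm = x$n_perm,
    seed = x$seed
  )
}
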