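# Fixtures are built in code; the oracles here are deliberately naive so
# they stay independent of the package's matching implementation.

make_net <- function(src, tgt, ...) {
  grn_network(data.frame(source = src, target = tgt), ...)
}

# small random simple digraph (no self-loops, no duplicates)
random_small_net <- function(seed, n_nodes = 6, n_edges = 8) {
  withr::with_seed(seed, {
    nodes <- paste0("n", seq_len(n_nodes))
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    take <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
    grn_network(pairs[take, ], nodes = nodes)
  })
}

# Exhaustive matching oracle: enumerate every subset of edges, keep those in
# which no two edges share a source or share a target.  One enumeration per
# graph yields the maximum matching size overall, without each edge, and
# restricted to subsets containing each edge.
brute_matching <- function(net) {
  src <- net$edges$source
  tgt <- net$edges$target
  L <- length(src)
  stopifnot(L <= 14)
  best <- 0L
  best_without <- integer(L)
  best_with <- rep(-1L, L)
  for (mask in 0:(2^L - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(L) - 1)) > 0)
    if (anyDuplicated(src[idx]) || anyDuplicated(tgt[idx])) next
    sz <- length(idx)
    best <- max(best, sz)
    out <- setdiff(seq_len(L), idx)
    best_without[out] <- pmax(best_without[out], sz)
    if (length(idx)) best_with[idx] <- pmax(best_with[idx], sz)
  }
  list(size = best, best_without = best_without, best_with = best_with)
}

# driver count by the matching criterion, from the brute-force size
brute_n_drivers <- function(net) {
  max(length(net$nodes) - brute_matching(net)$size, 1L)
}

# edge labels from first principles:
#   critical  - removal increases the driver count
#   redundant - no maximum matching contains the edge
#   ordinary  - neither
brute_edge_labels <- function(net) {
  b <- brute_matching(net)
  N <- length(net$nodes)
  nd <- max(N - b$size, 1L)
  vapply(seq_along(b$best_without), function(e) {
    nd_after <- max(N - b$best_without[e], 1L)
    if (nd_after > nd) return("critical")
    if (b$best_with[e] < b$size) return("redundant")
    "ordinary"
  }, character(1))
}
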