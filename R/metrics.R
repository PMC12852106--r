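#' Network density and average degree
#'
#' Two density summaries are in common use for directed graphs and both are
#' reported side by side to prevent silent mixing: `density` is the
#' fraction of realized directed edges, `L / (N * (N - 1))`, and
#' `avg_degree` is the mean number of edges per node, `L / N`. Published
#' per-network tables frequently print the latter under the name "density",
#' so cohort tables produced by this package carry `avg_degree` in the `D`
#' column and append `density_formula` separately.
#'
#' @param net a [grn_network()] with `N >= 2`.
#' @return One-row tibble with `density_formula` and `avg_degree`.
#' @export
network_density <- function(net) {
  assert_network(net)
  N <- length(net$nodes)
  L <- nrow(net$edges)
  if (N < 2) stop("density is undefined for N < 2", call. = FALSE)
  tibble::tibble(
    density_formula = L / (N * (N - 1)),
    avg_degree = L / N
  )
}

#' Degree distribution of a network
#'
#' @param net a [grn_network()].
#' @param mode degree flavour: `"total"`, `"in"`, or `"out"`.
#' @return Tibble with one row per distinct degree value: `degree`, `count`,
#'   `p` (probability, summing to one); attributes `mean_degree` and `mode`.
#' @export
degree_distribution <- function(net, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  deg <- node_degrees(net, mode)$degree
  tab <- table(deg)
  out <- tibble::tibble(
    degree = as.integer(names(tab)),
    count = as.integer(tab),
    p = as.integer(tab) / length(deg)
  )
  attr(out, "mean_degree") <- mean(deg)
  attr(out, "mode") <- mode
  out
}

#' Degree heterogeneity H
#'
#' The expected absolute degree difference between two randomly chosen
#' nodes, normalized by the mean degree:
#' `H = sum_ij |k_i - k_j| P(k_i) P(k_j) / <k>`. `H` is zero for a regular
#' network and grows when highly connected hubs coexist with sparsely
#' connected nodes.
#'
#' @param x a [grn_network()], a numeric vector of node degrees, or a
#'   degree-distribution tibble from [degree_distribution()].
#' @param mode degree flavour when `x` is a network.
#' @return Scalar `H >= 0`.
#' @examples
#' degree_heterogeneity(c(1, 3))   # 0.5
#' @export
degree_heterogeneity <- function(x, mode = c("total", "in", "out")) {
  dist <- as_degree_dist(x, match.arg(mode))
  k <- dist$degree
  p <- dist$p
  mk <- sum(k * p)
  if (mk <= 0) stop("heterogeneity is undefined when the mean degree is 0",
                    call. = FALSE)
  sum(abs(outer(k, k, "-")) * outer(p, p)) / mk
}

as_degree_dist <- function(x, mode) {
  if (inherits(x, "grn_network")) return(degree_distribution(x, mode))
  if (is.data.frame(x) && all(c("degree", "p") %in% names(x))) return(x)
  if (is.numeric(x)) {
    tab <- table(x)
    return(tibble::tibble(
      degree = as.numeric(names(tab)),
      count = as.integer(tab),
      p = as.integer(tab) / length(x)
    ))
  }
  stop("cannot interpret `x` as a degree distribution", call. = FALSE)
}

#' Scale-free degree exponent from a log-log CCDF regression
#'
#' Estimates the degree exponent gamma of an assumed power-law degree
#' distribution `P(k) ~ k^-gamma`. The complementary cumulative
#' distribution function `F(k) = P(degree >= k)` is evaluated at each
#' distinct observed degree `k >= 1` (zero degrees are excluded; one point
#' per distinct value, which removes the flat runs a plain per-node CCDF
#' would produce), both axes are log10-transformed, and an ordinary
#' least-squares line is fitted. For a power law the CCDF falls as
#' `k^(1 - gamma)`, so `gamma = 1 - slope`.
#'
#' @param x a [grn_network()], numeric degree vector, or
#'   [degree_distribution()] tibble.
#' @param mode degree flavour when `x` is a network.
#' @return An object of class `grn_gamma_fit` with fields `gamma`, `slope`,
#'   `intercept`, `n_points`, and the fitted `ccdf` tibble.
#' @examples
#' set.seed(1)
#' deg <- sample(1:50, 500, replace = TRUE, prob = (1:50)^-2.3)
#' glance(degree_exponent(deg))
#' @export
degree_exponent <- function(x, mode = c("total", "in", "out")) {
  dist <- as_degree_dist(x, match.arg(mode))
  dist <- dist[dist$degree >= 1, ]
  if (nrow(dist) < 3) {
    stop("degree-exponent fit requires at least 3 distinct positive degrees",
         call. = FALSE)
  }
  p <- dist$p / sum(dist$p)
  k <- dist$degree
  ccdf <- rev(cumsum(rev(p)))  # F(k) = P(degree >= k | degree >= 1)
  fit <- ccdf_regression(k, ccdf)
  fit$ccdf <- tibble::tibble(degree = k, ccdf = ccdf)
  fit
}

#' Ordinary least squares on a log-log CCDF
#'
#' The fitting primitive behind [degree_exponent()], exposed so that an
#' exact analytic CCDF can be fitted directly. Points are de-duplicated on
#' `k` before fitting.
#'
#' @param k positive degree values.
#' @param ccdf CCDF values `F(k)` in `(0, 1]`, non-increasing in `k`.
#' @return A `grn_gamma_fit` object (`gamma = 1 - slope`).
#' @export
ccdf_regression <- function(k, ccdf) {
  stopifnot(length(k) == length(ccdf))
  keep <- !duplicated(k) & k > 0 & ccdf > 0
  k <- k[keep]
  ccdf <- ccdf[keep]
  if (length(k) < 3) {
    stop("CCDF regression requires at least 3 distinct positive points",
         call. = FALSE)
  }
  fit <- lm(y ~ x, data = data.frame(x = log10(k), y = log10(ccdf)))
  slope <- unname(coef(fit)[2])
  structure(
    list(
      gamma = 1 - slope,
      slope = slope,
      intercept = unname(coef(fit)[1]),
      n_points = length(k),
      r_squared = stats::cor(log10(k), log10(ccdf))^2,
      ccdf = tibble::tibble(degree = k, ccdf = ccdf)
    ),
    class = "grn_gamma_fit"
  )
}

#' @export
print.grn_gamma_fit <- function(x, ...) {
  cat("<grn_gamma_fit> gamma = ", signif(x$gamma, 5),
      " (slope = ", signif(x$slope, 5), ", ",
      x$n_points, " CCDF points)\n", sep = "")
  invisible(x)
}

#' @describeIn ccdf_regression regression terms as a tibble.
#' @param x a `grn_gamma_fit` object.
#' @param ... unused.
#' @export
tidy.grn_gamma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @describeIn ccdf_regression one-row fit summary.
#' @export
glance.grn_gamma_fit <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma,
    slope = x$slope,
    intercept = x$intercept,
    n_points = x$n_points,
    r_squared = x$r_squared
  )
}

#' One metrics row for a network
#'
#' Assembles the per-network summary used in cohort tables: size,
#' controllability, edge-class fractions, density, heterogeneity and degree
#' exponent, in the column order `phase, grn, N, L, n_D, l_r, l_o, l_c, D,
#' H, gamma` plus an appended `density_formula`. The `D` column is the
#' average degree `L / N` (the convention of published per-network tables);
#' `density_formula` is `L / (N (N - 1))`.
#'
#' Fitted gamma values outside `(1.5, 3.5)` are flagged with a message:
#' exponents between 2 and 3 are the hallmark of scale-free topology, and a
#' value far outside that range usually means the network is too small or
#' too regular for the power-law fit to be meaningful.
#'
#' @param net a [grn_network()].
#' @param drv optional precomputed [driver_nodes()] result for `net`.
#' @param cls optional precomputed [classify_edges()] result for `net`.
#' @param degree_mode degree flavour for `H` and gamma.
#' @return One-row tibble.
#' @export
network_metrics <- function(net, drv = NULL, cls = NULL,
                            degree_mode = c("total", "in", "out")) {
  assert_network(net)
  degree_mode <- match.arg(degree_mode)
  drv <- drv %||% driver_nodes(net)
  cls <- cls %||% classify_edges(net)
  N <- length(net$nodes)
  L <- nrow(net$edges)
  if (drv$N != N || drv$L != L || drv$network != net$name) {
    stop("driver result was computed on a different network", call. = FALSE)
  }
  if (cls$N != N || cls$L != L || cls$network != net$name) {
    stop("edge classification was computed on a different network",
         call. = FALSE)
  }
  dens <- network_density(net)
  dist <- degree_distribution(net, degree_mode)
  gam <- tryCatch(degree_exponent(dist)$gamma, error = function(e) NA_real_)
  if (is.finite(gam) && (gam <= 1.5 || gam >= 3.5)) {
    message("network ", net$name, ": atypical degree exponent ",
            signif(gam, 4), " (outside (1.5, 3.5))")
  }
  tibble::tibble(
    phase = net$phase,
    grn = net$name,
    N = N,
    L = L,
    n_D = drv$driver_fraction,
    l_r = cls$l_r,
    l_o = cls$l_o,
    l_c = cls$l_c,
    D = dens$avg_degree,
    H = degree_heterogeneity(dist),
    gamma = gam,
    density_formula = dens$density_formula
  )
}
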