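#' Kruskal-Wallis rank-sum test
#'
#' Non-parametric comparison of a numeric variable across groups -- the
#' route taken when the normality gate ([normality_check()]) fails. The H
#' statistic is computed from mean ranks with the standard tie correction
#' `1 - sum(t^3 - t) / (n^3 - n)` and referred to a chi-squared
#' distribution with `k - 1` degrees of freedom.
#'
#' @param data a data frame.
#' @param value unquoted column with the numeric values.
#' @param group unquoted column with the group labels (>= 2 non-empty
#'   groups).
#' @return One-row tibble: `statistic` (chi-squared), `df`, `p_value`,
#'   `n_groups`, `n`, `method`. If every value is identical the statistic
#'   is 0 and `p_value` 1 (degenerate case, flagged with a warning).
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' kruskal_wallis(d, v, g)
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  check_groups(v, g)
  n <- length(v)
  k <- length(unique(g))
  r <- rank(v)
  mean_rank <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(sizes * mean_rank^2) - 3 * (n + 1)
  tie <- tie_term(v)
  denom <- 1 - tie / (n^3 - n)
  if (denom <= 0) {
    warning("all values tied; Kruskal-Wallis statistic set to 0",
            call. = FALSE)
    h <- 0
  } else {
    h <- h / denom
  }
  tibble::tibble(
    statistic = h,
    df = k - 1L,
    p_value = pchisq(h, df = k - 1, lower.tail = FALSE),
    n_groups = k,
    n = n,
    method = "Kruskal-Wallis rank-sum test"
  )
}

tie_term <- function(v) {
  t <- table(v)
  sum(t^3 - t)
}

check_groups <- function(v, g) {
  if (anyNA(v) || anyNA(g)) stop("missing values in `value` or `group`",
                                 call. = FALSE)
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes == 0)) stop("empty group(s)", call. = FALSE)
  invisible(NULL)
}

#' Dunn's post hoc test
#'
#' Pairwise mean-rank comparisons following a Kruskal-Wallis test. For each
#' pair of groups the statistic is
#' `z = (Rbar_a - Rbar_b) / sqrt((n(n+1)/12 - T/(12(n-1))) (1/n_a + 1/n_b))`
#' with `T = sum(t^3 - t)` the tie term; p-values are two-sided normal
#' tails, adjusted across all `choose(k, 2)` pairs (Bonferroni by default).
#'
#' @inheritParams kruskal_wallis
#' @param p_adjust multiplicity correction, passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return Tibble with one row per group pair: `group_a`, `group_b`,
#'   `mean_rank_a`, `mean_rank_b`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(data, value, group, p_adjust = "bonferroni") {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  check_groups(v, g)
  n <- length(v)
  r <- rank(v)
  mean_rank <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  labs <- sort_c(names(sizes))
  pooled <- n * (n + 1) / 12 - tie_term(v) / (12 * (n - 1))
  pairs <- utils::combn(labs, 2)
  z <- vapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    se <- sqrt(pooled * (1 / sizes[[a]] + 1 / sizes[[b]]))
    if (se == 0) return(0)
    (mean_rank[[a]] - mean_rank[[b]]) / se
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    group_a = pairs[1, ],
    group_b = pairs[2, ],
    mean_rank_a = as.numeric(mean_rank[pairs[1, ]]),
    mean_rank_b = as.numeric(mean_rank[pairs[2, ]]),
    z = z,
    p_value = p,
    p_adjusted = stats::p.adjust(p, method = p_adjust)
  )
}

#' Pearson correlation
#'
#' Product-moment correlation with a t-based p-value (`n - 2` degrees of
#' freedom).
#'
#' @param data a data frame.
#' @param x,y unquoted numeric columns, `n >= 3`, neither constant.
#' @return One-row tibble: `r`, `statistic` (t), `p_value`, `n`.
#' @export
cor_pearson <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  n <- length(xv)
  if (n < 3) stop("Pearson correlation requires n >= 3", call. = FALSE)
  if (sd(xv) == 0 || sd(yv) == 0) {
    stop("correlation is undefined for a constant variable", call. = FALSE)
  }
  r <- pearson_r(xv, yv)
  t <- r * sqrt((n - 2) / (1 - r^2))
  tibble::tibble(
    r = r,
    statistic = t,
    p_value = 2 * pt(-abs(t), df = n - 2),
    n = n
  )
}

pearson_r <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of a
#' single control variable `z`, by the first-order recursion
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`; the
#' p-value uses a t transform with `n - 3` degrees of freedom.
#'
#' @param data a data frame with `n >= 4` rows.
#' @param x,y unquoted numeric columns.
#' @param control unquoted numeric column to partial out.
#' @return One-row tibble: `r`, `statistic`, `p_value`, `n`,
#'   `controlled_for`.
#' @export
cor_partial <- function(data, x, y, control) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  zv <- dplyr::pull(data, {{ control }})
  n <- length(xv)
  if (n < 4) stop("partial correlation requires n >= 4", call. = FALSE)
  if (sd(xv) == 0 || sd(yv) == 0 || sd(zv) == 0) {
    stop("correlation is undefined for a constant variable", call. = FALSE)
  }
  rxy <- pearson_r(xv, yv)
  rxz <- pearson_r(xv, zv)
  ryz <- pearson_r(yv, zv)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop("control variable is collinear with `x` or `y`", call. = FALSE)
  }
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  t <- r * sqrt((n - 3) / (1 - r^2))
  tibble::tibble(
    r = r,
    statistic = t,
    p_value = 2 * pt(-abs(t), df = n - 3),
    n = n,
    controlled_for = rlang::as_name(rlang::enquo(control))
  )
}

#' Shapiro-Wilk normality gate
#'
#' Wrapper around [stats::shapiro.test()] used to decide between parametric
#' and rank-based group comparisons: `is_normal` is `FALSE` when the test
#' rejects normality at level `alpha`.
#'
#' @param x numeric vector, `3 <= n <= 5000`, not constant.
#' @param alpha rejection level (default 0.05).
#' @return One-row tibble: `statistic` (W), `p_value`, `is_normal`, `n`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (sd(x) == 0) stop("normality is undefined for a constant vector",
                       call. = FALSE)
  sw <- stats::shapiro.test(x)
  tibble::tibble(
    statistic = unname(sw$statistic),
    p_value = sw$p.value,
    is_normal = sw$p.value >= alpha,
    n = length(x)
  )
}
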