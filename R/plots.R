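#' @describeIn edge_removal_curve plot the mean GCC trajectory with a
#'   mean +/- sd ribbon.
#' @param object a `grn_robustness` object.
#' @export
autoplot.grn_robustness <- function(object, ...) {
  d <- object$curve
  ggplot2::ggplot(d, ggplot2::aes(x = .data$removal_fraction,
                                  y = .data$gcc_mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$gcc_mean - .data$gcc_sd, 0),
                   ymax = pmin(.data$gcc_mean + .data$gcc_sd, 1)),
      fill = "grey80"
    ) +
    ggplot2::geom_line(colour = "forestgreen") +
    ggplot2::labs(
      x = "fraction of edges removed",
      y = "GCC fraction",
      title = object$network,
      subtitle = sprintf("AUC = %.3f over %d permutations",
                         object$auc, object$n_perm)
    )
}

#' @describeIn ccdf_regression log-log CCDF points with the fitted line.
#' @param object a `grn_gamma_fit` object.
#' @export
autoplot.grn_gamma_fit <- function(object, ...) {
  d <- object$ccdf
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$degree),
                                  y = log10(.data$ccdf))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 k", y = "log10 F(k)",
      title = sprintf("degree exponent gamma = %.3f", object$gamma)
    )
}

#' Driver fraction by phase
#'
#' Box plot of the driver-node fraction `n_D` across phases for a cohort
#' metrics table -- the standard view for asking whether controllability
#' shifts over development.
#'
#' @param metrics a metrics tibble from [analyze_cohort()] (or
#'   [table1_metrics()]).
#' @return A ggplot object.
#' @export
plot_driver_fraction <- function(metrics) {
  stopifnot(all(c("phase", "n_D") %in% names(metrics)))
  ggplot2::ggplot(metrics, ggplot2::aes(x = factor(.data$phase),
                                        y = .data$n_D,
                                        fill = factor(.data$phase))) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "phase", y = expression(n[D]))
}

#' TF category scatter
#'
#' Out-degree versus normalized expression for every (network, TF) pair,
#' with Critical TFs outlined and the high-outdegree threshold drawn as a
#' dashed line.
#'
#' @param flags a [categorize_tfs()] tibble (possibly row-bound over
#'   networks).
#' @param outdeg_threshold where to draw the HO threshold line.
#' @return A ggplot object.
#' @export
plot_tf_categories <- function(flags, outdeg_threshold = 50) {
  stopifnot(all(c("outdegree", "expression", "is_critical") %in%
                  names(flags)))
  ggplot2::ggplot(flags, ggplot2::aes(x = .data$expression,
                                      y = .data$outdegree)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$phase)),
                        alpha = 0.6) +
    ggplot2::geom_point(data = flags[flags$is_critical, ],
                        shape = 21, colour = "black") +
    ggplot2::geom_hline(yintercept = outdeg_threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "normalized expression", y = "outdegree",
                  colour = "phase")
}
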