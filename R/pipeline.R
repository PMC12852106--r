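#' Analyze a cohort of networks end to end
#'
#' The full analysis workflow over a cohort of directed networks grouped
#' into phases: per-network controllability and topology metrics, the
#' phase-level comparison of the driver fraction (Kruskal-Wallis plus
#' Dunn's post hoc), the density-controllability correlation (Pearson, and
#' first-order partial correlation controlling for the redundant-edge
#' fraction), and optionally edge-removal robustness and TF
#' categorization. Per-network failures are isolated: a network whose
#' metrics cannot be computed is skipped with a warning rather than
#' aborting the run.
#'
#' The correlations are computed on `density_formula = L / (N (N - 1))`;
#' the metrics table also carries the average degree `L / N` in the `D`
#' column for comparability with published per-network tables (see the
#' package vignette for why both are kept).
#'
#' @param networks list of [grn_network()] objects (>= 1; >= 2 distinct
#'   phases for the group statistics).
#' @param degree_mode degree flavour for `H` and gamma.
#' @param outdeg_threshold,he_quantile TF-category cuts (defaults 50 and
#'   the 3rd quartile).
#' @param n_perm edge-removal permutations per network (default 20).
#' @param seed master seed driving every stochastic stage.
#' @param robustness compute [edge_removal_curve()] per network?
#' @param expression optional [normalize_expression()] table (samples keyed
#'   by network names) enabling the TF-category stage.
#' @return An object of class `grn_cohort_report`: `metrics` (one row per
#'   network, published-table column order plus `density_formula` and,
#'   when requested, `robustness_auc`), `kruskal`, `dunn`, `pearson`,
#'   `partial`, `normality`, `tf_categories` (or `NULL`), and a `manifest`
#'   recording the seed, configuration hash and package version.
#' @export
analyze_cohort <- function(networks, degree_mode = c("total", "in", "out"),
                           outdeg_threshold = 50, he_quantile = 0.75,
                           n_perm = 20, seed = 1, robustness = FALSE,
                           expression = NULL) {
  stopifnot(length(networks) >= 1)
  degree_mode <- match.arg(degree_mode)
  purrr::walk(networks, assert_network)

  flags <- list()
  rows <- purrr::map(networks, function(net) {
    tryCatch({
      cls <- classify_edges(net)
      row <- network_metrics(net, cls = cls, degree_mode = degree_mode)
      if (robustness) {
        row$robustness_auc <- edge_removal_curve(net, n_perm = n_perm,
                                                 seed = seed)$auc
      }
      if (!is.null(expression)) {
        flags[[net$name]] <<- categorize_tfs(
          net, cls, expression,
          outdeg_threshold = outdeg_threshold, he_quantile = he_quantile
        )
      }
      row
    }, error = function(e) {
      warning("skipping network ", net$name, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  metrics <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(metrics) == 0) stop("no network could be analyzed", call. = FALSE)

  have_phases <- length(unique(metrics$phase[!is.na(metrics$phase)])) >= 2
  kw <- dunn <- pearson <- partial <- norm <- NULL
  if (nrow(metrics) < 2 || !have_phases) {
    warning("fewer than 2 phases with metrics; group statistics skipped",
            call. = FALSE)
  } else {
    norm <- tryCatch(normality_check(metrics$n_D), error = function(e) NULL)
    kw <- kruskal_wallis(metrics, n_D, phase)
    dunn <- dunn_posthoc(metrics, n_D, phase)
    with_skip <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        warning(what, " skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    }
    pearson <- with_skip("Pearson correlation",
                         cor_pearson(metrics, density_formula, n_D))
    partial <- with_skip("partial correlation",
                         cor_partial(metrics, density_formula, n_D, l_r))
  }

  categories <- if (length(flags)) integrate_categories(flags) else NULL
  config <- list(degree_mode = degree_mode,
                 outdeg_threshold = outdeg_threshold,
                 he_quantile = he_quantile, n_perm = n_perm,
                 robustness = robustness, seed = seed)
  structure(
    list(
      metrics = metrics,
      normality = norm,
      kruskal = kw,
      dunn = dunn,
      pearson = pearson,
      partial = partial,
      tf_categories = categories,
      manifest = list(
        seed = seed,
        config = config,
        config_hash = rlang::hash(config),
        package_version = as.character(utils::packageVersion("grnctrl"))
      )
    ),
    class = "grn_cohort_report"
  )
}

#' @export
print.grn_cohort_report <- function(x, ...) {
  cat("<grn_cohort_report> ", nrow(x$metrics), " networks\n", sep = "")
  if (!is.null(x$kruskal)) {
    cat("  Kruskal-Wallis on n_D by phase: chi^2 = ",
        signif(x$kruskal$statistic, 5),
        " (df = ", x$kruskal$df, ", p = ",
        signif(x$kruskal$p_value, 3), ")\n", sep = "")
  }
  if (!is.null(x$pearson)) {
    cat("  Pearson r(density, n_D) = ", signif(x$pearson$r, 4),
        "; partial r | l_r = ", signif(x$partial$r, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Recompute the cohort statistics from the packaged published table
#'
#' Runs the cohort-level statistics on the packaged 40-network metrics
#' table ([table1_metrics()]): the Kruskal-Wallis test of `n_D` across
#' phases (group sizes 3/5/7/25), Dunn's post hoc comparisons, and the
#' Pearson and partial correlations between network density and `n_D`
#' (density recomputed as `L / (N (N - 1))` from the printed `N` and `L`
#' columns, which is the definition that reproduces the published
#' correlation coefficients).
#'
#' @return A list with `metrics`, `normality`, `kruskal`, `dunn`,
#'   `pearson`, `partial`.
#' @examples
#' rep <- analyze_table1()
#' rep$kruskal$statistic   # 16.155
#' @export
analyze_table1 <- function() {
  tab <- table1_metrics()
  tab$density_formula <- tab$L / (tab$N * (tab$N - 1))
  list(
    metrics = tab,
    normality = normality_check(tab$n_D),
    kruskal = kruskal_wallis(tab, n_D, phase),
    dunn = dunn_posthoc(tab, n_D, phase),
    pearson = cor_pearson(tab, density_formula, n_D),
    partial = cor_partial(tab, density_formula, n_D, l_r)
  )
}

#' Write a cohort report to disk
#'
#' Emits the machine-readable artifacts of an [analyze_cohort()] run:
#' `metrics.tsv` (per-network rows), `statistics.tsv` (stacked test
#' results), `tf_categories.tsv` and `venn.tsv` when the TF stage ran, and
#' `manifest.json` (requires the jsonlite package).
#'
#' @param report a `grn_cohort_report`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "grn_cohort_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(report$metrics, file.path(dir, "metrics.tsv"))
  stats_rows <- dplyr::bind_rows(
    if (!is.null(report$kruskal)) {
      dplyr::mutate(report$kruskal, test = "kruskal_wallis")
    },
    if (!is.null(report$pearson)) {
      dplyr::mutate(report$pearson, test = "pearson")
    },
    if (!is.null(report$partial)) {
      dplyr::mutate(report$partial, test = "partial")
    }
  )
  if (!is.null(stats_rows) && nrow(stats_rows)) {
    readr::write_tsv(stats_rows, file.path(dir, "statistics.tsv"))
  }
  if (!is.null(report$dunn)) {
    readr::write_tsv(report$dunn, file.path(dir, "dunn.tsv"))
  }
  if (!is.null(report$tf_categories)) {
    readr::write_tsv(report$tf_categories$tf_table,
                     file.path(dir, "tf_categories.tsv"))
    readr::write_tsv(report$tf_categories$venn[c("region", "n")],
                     file.path(dir, "venn.tsv"))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report$manifest,
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
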