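#' Percentile bootstrap confidence interval
#'
#' Resamples the input with replacement (`n_boot` resamples of the original
#' size, default 1000 iterations) and returns the percentile interval of
#' the chosen statistic. Deterministic for a fixed seed.
#'
#' @param values Nonempty numeric vector (NAs dropped with a warning).
#' @param statistic `"median"`, `"mean"`, or `"proportion"` (mean of a 0/1
#'   vector), or an arbitrary function of a numeric vector.
#' @param n_boot Number of bootstrap iterations.
#' @param level Confidence level.
#' @param seed Integer seed; when `NULL` the current RNG stream is used.
#' @return A `bootstrap_ci` list: `statistic_name`, `point` (statistic of
#'   the original sample), `lo`, `hi`, `n`, `n_boot`, `level`, `seed`.
#' @examples
#' bootstrap_ci(rnorm(50), "mean", seed = 1)
#' @export
bootstrap_ci <- function(values, statistic = "median", n_boot = 1000L,
                         level = 0.95, seed = NULL) {
  if (anyNA(values)) {
    warning("dropping NA values before bootstrap")
    values <- values[!is.na(values)]
  }
  n <- length(values)
  if (n == 0L) stop("cannot bootstrap an empty sample", call. = FALSE)
  if (is.character(statistic)) {
    stat_name <- match.arg(statistic, c("median", "mean", "proportion"))
    stat_fun <- switch(stat_name, median = stats::median, mean = mean,
                       proportion = mean)
    fast <- stat_name %in% c("mean", "proportion")
  } else {
    stat_fun <- match.fun(statistic)
    stat_name <- "custom"
    fast <- FALSE
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  draws <- matrix(sample(values, n * n_boot, replace = TRUE), nrow = n_boot)
  boot_stats <- if (fast) {
    rowMeans(draws)
  } else if (identical(stat_fun, stats::median)) {
    matrixStats::rowMedians(draws)
  } else {
    apply(draws, 1L, stat_fun)
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(boot_stats, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  structure(list(statistic_name = stat_name, point = stat_fun(values),
                 lo = qs[1], hi = qs[2], n = n, n_boot = n_boot,
                 level = level, seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%s %.4g (%.0f%% CI %.4g-%.4g), n=%d, %d bootstrap iterations\n",
              x$statistic_name, x$point, 100 * x$level, x$lo, x$hi,
              x$n, x$n_boot))
  invisible(x)
}

# one tidy row for a hypothesis-test result
test_result <- function(test_name, statistic, p_value, n, notes = "",
                        flag = NA_character_) {
  tibble::tibble(test = test_name, statistic = statistic,
                 p_value = p_value, n = n, notes = notes, flag = flag)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired test, used to compare metrics and contouring times
#' between the two contouring modes. Zero differences are dropped (the
#' classic Wilcoxon convention, as in SPSS); the exact null distribution is
#' used for effective n <= 25 without ties, otherwise the tie-corrected
#' normal approximation (without continuity correction). If every
#' difference is zero, p = 1 by convention, flagged.
#'
#' @param paired_a,paired_b Equal-length numeric vectors.
#' @return A one-row tibble: `test`, `statistic` (V), `p_value`, `n`
#'   (effective pairs), `notes`, `flag`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b) || length(paired_a) < 1L) {
    stop("paired samples must have equal nonzero length", call. = FALSE)
  }
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(test_result("wilcoxon_signed_rank", NA_real_, 1, 0L,
                       "all differences zero; p = 1 by convention",
                       "degenerate"))
  }
  has_ties <- any(duplicated(abs(d)))
  exact <- length(d) <= 25L && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = FALSE)
  )
  test_result("wilcoxon_signed_rank", unname(res$statistic),
              min(res$p.value, 1), length(d),
              paste0(if (exact) "exact" else "normal approximation with ties",
                     "; zero differences dropped"))
}

#' Mann-Whitney U test
#'
#' Two-sided unpaired rank test, e.g. for comparing Dice values between the
#' internal and external test sets. Exact when both groups are small and
#' tie-free, otherwise tie-corrected normal approximation. The statistic
#' reported is U (the rank-sum form of `wilcox.test`'s W for the first
#' group).
#'
#' @param a,b Nonempty numeric vectors.
#' @return A one-row tibble as in [wilcoxon_signed_rank()]; `n` holds
#'   `length(a) + length(b)`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  has_ties <- any(duplicated(c(a, b)))
  exact <- min(length(a), length(b)) < 50 && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  test_result("mann_whitney_u", unname(res$statistic), min(res$p.value, 1),
              length(a) + length(b),
              if (exact) "exact" else "normal approximation with ties")
}

#' Kruskal-Wallis H test
#'
#' Rank test across two or more groups (e.g. Dice across lesion-volume
#' strata), with tie correction and a chi-square reference distribution on
#' k - 1 degrees of freedom.
#'
#' @param groups List of two or more nonempty numeric vectors.
#' @return A one-row tibble; `statistic` is H.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of >= 2 vectors", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("every group must be nonempty", call. = FALSE)
  }
  res <- stats::kruskal.test(groups)
  test_result("kruskal_wallis", unname(res$statistic), res$p.value,
              sum(lengths(groups)),
              sprintf("df = %d, tie-corrected", unname(res$parameter)))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and the t-approximation
#' p-value. Used for volume agreement and quality-vs-time analyses.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return A one-row tibble: `test`, `rho`, `statistic` (t), `p_value`,
#'   `n`, `flag` (`"degenerate"` when either rank vector has zero
#'   variance, with `rho = NA`).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    out <- test_result("spearman", NA_real_, NA_real_, length(x),
                       "zero rank variance", "degenerate")
    out$rho <- NA_real_
    return(out[, c("test", "rho", "statistic", "p_value", "n", "notes", "flag")])
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) == 1) {
    tstat <- sign(rho) * Inf
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out <- test_result("spearman", tstat, p, n, "t approximation")
  out$rho <- rho
  out[, c("test", "rho", "statistic", "p_value", "n", "notes", "flag")]
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of `a - b`) and 95% limits of agreement
#' (`bias +/- 1.96 * SD(a - b)`, sample SD with n - 1), plus the per-pair
#' means and differences needed for the plot.
#'
#' @param a,b Equal-length numeric vectors (length >= 2).
#' @return A `bland_altman` list: `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `n`, and `pairs` (tibble with `mean` and `diff`).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("paired samples must have equal length >= 2", call. = FALSE)
  }
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s, n = length(a),
                 pairs = tibble::tibble(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, 95%% limits of agreement [%.4g, %.4g], n=%d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Mean of pair", y = "Difference (a - b)",
                  title = "Bland-Altman agreement")
}

#' Holm adjustment across a table of test results
#'
#' The primary analyses mirror the single-comparison reporting of a
#' crossover reader study and apply no multiplicity correction; this helper
#' adds a Holm-adjusted column for users who want one.
#'
#' @param results A tibble with a `p_value` column (rows = tests).
#' @return The tibble with an added `p_holm` column.
#' @export
adjust_holm <- function(results) {
  stopifnot("p_value" %in% names(results))
  dplyr::mutate(results, p_holm = stats::p.adjust(.data$p_value, "holm"))
}
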