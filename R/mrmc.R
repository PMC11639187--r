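#' Randomize readers into crossover arms
#'
#' Balanced randomization of readers into assisted-first or unassisted-first
#' sessions (arm sizes differ by at most one), plus an independent random
#' case presentation order per session. Deterministic per seed.
#'
#' @param reader_ids Vector of reader identifiers (a single reader is
#'   allowed and drawn into a random arm).
#' @param seed Integer seed.
#' @param case_ids Optional case identifiers; when given, the returned
#'   object carries a per-session random presentation order.
#' @return A list of class `session_plan`: `readers` (tibble: `reader`,
#'   `session_order`), and `case_order` (tibble: `session`, `position`,
#'   `case`) when `case_ids` were supplied.
#' @export
assign_sessions <- function(reader_ids, seed = 1L, case_ids = NULL) {
  if (length(reader_ids) < 1L) stop("need at least 1 reader", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(reader_ids)
  n_af <- floor(n / 2) + sample(0:(n %% 2), 1L)  # odd n: extra reader random arm
  af <- sample(seq_len(n), n_af)
  readers <- tibble::tibble(
    reader = reader_ids,
    session_order = ifelse(seq_len(n) %in% af, "assisted_first",
                           "unassisted_first")
  )
  case_order <- NULL
  if (!is.null(case_ids)) {
    case_order <- dplyr::bind_rows(lapply(1:2, function(s) {
      tibble::tibble(session = s,
                     position = seq_along(case_ids),
                     case = sample(case_ids))
    }))
  }
  structure(list(readers = readers, case_order = case_order, seed = seed),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat("<session_plan> seed", x$seed, "\n")
  print(dplyr::count(x$readers, .data$session_order))
  invisible(x)
}

#' Per-lesion contouring time saving
#'
#' Percent reduction of contouring time with assistance:
#' `(t_unassisted - t_assisted) / t_unassisted x 100`. Negative values are
#' legal (a reader slowed down by assistance).
#'
#' @param t_unassisted_s,t_assisted_s Times in seconds (vectorized);
#'   unassisted times must be strictly positive.
#' @return Time saving in percent.
#' @examples
#' time_saving(100, 58) # 42
#' @export
time_saving <- function(t_unassisted_s, t_assisted_s) {
  if (any(t_unassisted_s <= 0)) {
    stop("unassisted time must be > 0", call. = FALSE)
  }
  (t_unassisted_s - t_assisted_s) / t_unassisted_s * 100
}

# required study-table columns
study_key_cols <- c("reader", "experience_group", "session_order", "patient",
                    "lesion", "mode", "session", "time_s")

#' Validate crossover completeness of a study table
#'
#' A multi-reader multi-case crossover table is analyzable only when every
#' (reader, patient, lesion) unit has exactly one record per contouring
#' mode. Returns the table invisibly when complete; otherwise errors,
#' listing the incomplete units, so silently partial tables are never
#' analyzed.
#'
#' @param study A study tibble (see [simulate_reader_study()] for the
#'   column contract).
#' @return `study`, invisibly.
#' @export
validate_study <- function(study) {
  miss <- setdiff(study_key_cols, names(study))
  if (length(miss)) {
    stop("study table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(study$mode %in% c("assisted", "unassisted"))) {
    stop("mode must be 'assisted' or 'unassisted'", call. = FALSE)
  }
  bad <- study |>
    dplyr::count(.data$reader, .data$patient, .data$lesion, .data$mode) |>
    dplyr::filter(.data$n != 1L)
  counts <- study |>
    dplyr::count(.data$reader, .data$patient, .data$lesion) |>
    dplyr::filter(.data$n != 2L)
  if (nrow(bad) || nrow(counts)) {
    ex <- utils::head(dplyr::bind_rows(bad, counts), 5)
    stop("incomplete crossover: ", nrow(bad) + nrow(counts),
         " unit(s) lack exactly one record per mode, e.g. ",
         paste(sprintf("(%s, %s, %s)", ex$reader, ex$patient, ex$lesion),
               collapse = " "), call. = FALSE)
  }
  if (any(!is.finite(study$time_s)) || any(study$time_s < 0)) {
    stop("time_s must be finite and >= 0", call. = FALSE)
  }
  invisible(study)
}

# paired wide table: one row per (reader, patient, lesion) with both modes
paired_units <- function(study, value_col) {
  study |>
    dplyr::select(dplyr::all_of(c(study_key_cols[c(1:5, 6)], value_col))) |>
    tidyr::pivot_wider(names_from = "mode",
                       values_from = dplyr::all_of(value_col))
}

#' Compare assisted and unassisted contouring
#'
#' The core crossover analysis: per-mode medians with percentile-bootstrap
#' confidence intervals, a paired Wilcoxon signed-rank test over
#' (reader x lesion) pairs, and the median paired improvement with its own
#' bootstrap CI. For `metric = "time"` the paired quantity is the per-pair
#' percent time saving ([time_saving()]); for `"dsc"` improvement is
#' assisted minus unassisted; for `"rvd"` and `"asd"` it is unassisted
#' minus assisted (a reduction is an improvement). Pairs with an undefined
#' value in either mode are listed and excluded with a warning.
#'
#' @param study A validated study tibble.
#' @param metric `"dsc"`, `"rvd"`, `"asd"` or `"time"`.
#' @param n_boot Bootstrap iterations for every CI.
#' @param seed Integer seed for the bootstrap.
#' @return A `mode_comparison` object; see [tidy.mode_comparison()].
#' @export
compare_modes <- function(study, metric = c("dsc", "rvd", "asd", "time"),
                          n_boot = 1000L, seed = 1L) {
  metric <- match.arg(metric)
  validate_study(study)
  col <- switch(metric, dsc = "dsc", rvd = "rvd", asd = "asd_mm",
                time = "time_s")
  if (!col %in% names(study)) {
    stop("study table lacks metric column: ", col, call. = FALSE)
  }
  wide <- paired_units(study, col)
  bad <- wide[!is.finite(wide$assisted) | !is.finite(wide$unassisted), ]
  if (nrow(bad)) {
    warning(nrow(bad), " pair(s) with undefined values excluded")
    wide <- dplyr::anti_join(wide, bad,
                             by = c("reader", "patient", "lesion"))
  }
  improvement <- switch(metric,
    dsc = wide$assisted - wide$unassisted,
    rvd = wide$unassisted - wide$assisted,
    asd = wide$unassisted - wide$assisted,
    time = time_saving(wide$unassisted, wide$assisted))
  per_mode <- purrr::map_dfr(c("unassisted", "assisted"), function(m) {
    ci <- bootstrap_ci(wide[[m]], "median", n_boot, seed = seed)
    tibble::tibble(mode = m, median = ci$point, lo = ci$lo, hi = ci$hi,
                   n = ci$n)
  })
  imp_ci <- bootstrap_ci(improvement, "median", n_boot, seed = seed)
  wil <- wilcoxon_signed_rank(wide$assisted, wide$unassisted)
  structure(list(metric = metric, per_mode = per_mode,
                 improvement = tibble::tibble(
                   median = imp_ci$point, lo = imp_ci$lo, hi = imp_ci$hi,
                   n = imp_ci$n),
                 wilcoxon = wil, pairs = wide,
                 improvement_values = improvement,
                 excluded = bad, n_boot = n_boot, seed = seed),
            class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat("Mode comparison -", x$metric, "\n")
  print(x$per_mode)
  lab <- if (x$metric == "time") "median time saving (%)" else
    "median paired improvement"
  cat(sprintf("%s: %.4g (95%% CI %.4g to %.4g), Wilcoxon p = %.3g\n",
              lab, x$improvement$median, x$improvement$lo,
              x$improvement$hi, x$wilcoxon$p_value))
  invisible(x)
}

#' Tidy a mode comparison
#'
#' @param x A `mode_comparison`.
#' @param ... Unused.
#' @return Tibble with one row per mode plus one `improvement` row
#'   (`median`, `lo`, `hi`, `n`).
#' @export
tidy.mode_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$per_mode, metric = x$metric, .before = 1),
    tibble::tibble(metric = x$metric, mode = "improvement",
                   median = x$improvement$median, lo = x$improvement$lo,
                   hi = x$improvement$hi, n = x$improvement$n)
  )
}

#' @rdname tidy.mode_comparison
#' @export
glance.mode_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric,
                 improvement_median = x$improvement$median,
                 improvement_lo = x$improvement$lo,
                 improvement_hi = x$improvement$hi,
                 p_value = x$wilcoxon$p_value,
                 n_pairs = x$improvement$n)
}

#' @rdname tidy.mode_comparison
#' @param object A `mode_comparison`.
#' @export
autoplot.mode_comparison <- function(object, ...) {
  ggplot2::ggplot(object$per_mode,
                  ggplot2::aes(x = .data$mode, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = NULL, y = paste("median", object$metric),
                  title = "Assisted vs unassisted contouring")
}

#' Stratified mode comparison
#'
#' Compares the per-pair improvement distribution between two strata (reader
#' experience group, or session order) with a Mann-Whitney U test, alongside
#' each stratum's median improvement and bootstrap CI. This reproduces the
#' resident-vs-attending and order-effect analyses of a crossover reader
#' study.
#'
#' @param study A validated study tibble.
#' @param by `"experience_group"` or `"session_order"`.
#' @inheritParams compare_modes
#' @return A `group_comparison` object with `per_stratum` (tibble) and
#'   `mann_whitney` (tibble row).
#' @export
compare_groups <- function(study, by = c("experience_group", "session_order"),
                           metric = c("dsc", "rvd", "asd", "time"),
                           n_boot = 1000L, seed = 1L) {
  by <- match.arg(by)
  metric <- match.arg(metric)
  validate_study(study)
  strata <- unique(study[[by]])
  if (length(strata) < 2L) stop("need >= 2 strata in ", by, call. = FALSE)
  cmp_all <- compare_modes(study, metric, n_boot, seed)
  pairs <- cmp_all$pairs  # carries the stratum columns from the study table
  pairs$improvement <- cmp_all$improvement_values
  per_stratum <- purrr::map_dfr(sort(strata), function(s) {
    v <- pairs$improvement[pairs[[by]] == s]
    ci <- bootstrap_ci(v, "median", n_boot, seed = seed)
    tibble::tibble(stratum = s, median = ci$point, lo = ci$lo, hi = ci$hi,
                   n = ci$n)
  })
  mw <- mann_whitney_u(pairs$improvement[pairs[[by]] == sort(strata)[1]],
                       pairs$improvement[pairs[[by]] == sort(strata)[2]])
  structure(list(by = by, metric = metric, per_stratum = per_stratum,
                 mann_whitney = mw, pairs = pairs),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Improvement in", x$metric, "by", x$by, "\n")
  print(x$per_stratum)
  cat(sprintf("Mann-Whitney p = %.3g\n", x$mann_whitney$p_value))
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(x$per_stratum, by = x$by, metric = x$metric, .before = 1)
}

#' Roll a lesion-level study table up to patient level
#'
#' Per (reader, patient, mode): the patient-wise Dice from summed voxel
#' counts over the patient's lesions (equivalent to Dice on the union
#' masks when lesions and their matched predictions are disjoint), RVD from
#' summed volumes, and total contouring time. Requires the voxel-count
#' columns `n_gt`, `n_pred`, `n_overlap` and volume columns `gt_ml`,
#' `pred_ml` produced by the study simulator / scorer.
#'
#' @param study A validated lesion-level study tibble.
#' @return A patient-level tibble: one row per reader x patient x mode with
#'   `dsc` (patient-wise), `rvd`, `time_s`, `n_lesions`.
#' @export
patient_level_rollup <- function(study) {
  validate_study(study)
  need <- c("n_gt", "n_pred", "n_overlap", "gt_ml", "pred_ml")
  miss <- setdiff(need, names(study))
  if (length(miss)) {
    stop("patient rollup needs voxel/volume columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  study |>
    dplyr::group_by(.data$reader, .data$experience_group,
                    .data$session_order, .data$patient, .data$mode,
                    .data$session) |>
    dplyr::summarise(
      dsc = 2 * sum(.data$n_overlap) / (sum(.data$n_pred) + sum(.data$n_gt)),
      rvd = 2 * abs(sum(.data$pred_ml) - sum(.data$gt_ml)) /
        (sum(.data$pred_ml) + sum(.data$gt_ml)) * 100,
      time_s = sum(.data$time_s),
      n_lesions = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(lesion = .data$patient, .after = "patient")
}

#' Correlate contouring quality with contouring time
#'
#' Spearman correlations, in the assisted mode, of each quality metric
#' against the per-lesion contouring time, and of the per-pair time saving
#' against lesion volume and diameter. Confidence intervals use the Fisher
#' z approximation on the rank correlation.
#'
#' @param study A validated study tibble (with `volume_ml`/`diameter_mm`
#'   columns for the size correlations, when present).
#' @param metrics Metric columns to correlate with time.
#' @return Tibble: `pair`, `rho`, `lo`, `hi`, `p_value`, `n`, `flag`.
#' @export
correlate_quality_time <- function(study,
                                   metrics = c("dsc", "asd_mm", "rvd",
                                               "sensitivity", "specificity",
                                               "mcc")) {
  validate_study(study)
  assisted <- dplyr::filter(study, .data$mode == "assisted")
  if (nrow(assisted) == 0L) stop("no assisted records", call. = FALSE)
  rows <- purrr::map_dfr(intersect(metrics, names(assisted)), function(m) {
    ok <- is.finite(assisted[[m]]) & is.finite(assisted$time_s)
    sp <- spearman(assisted[[m]][ok], assisted$time_s[ok])
    spearman_row(paste0(m, " vs time"), sp)
  })
  # time saving vs lesion size, over paired units
  if (all(c("volume_ml", "diameter_mm") %in% names(study))) {
    wide <- paired_units(study, "time_s")
    sizes <- study |>
      dplyr::filter(.data$mode == "unassisted") |>
      dplyr::select("reader", "patient", "lesion", "volume_ml",
                    "diameter_mm")
    wide <- dplyr::left_join(wide, sizes,
                             by = c("reader", "patient", "lesion"))
    ts <- time_saving(wide$unassisted, wide$assisted)
    rows <- dplyr::bind_rows(
      rows,
      spearman_row("time saving vs volume", spearman(ts, wide$volume_ml)),
      spearman_row("time saving vs diameter", spearman(ts, wide$diameter_mm))
    )
  }
  rows
}

spearman_row <- function(label, sp) {
  n <- sp$n
  rho <- sp$rho
  if (is.na(rho) || n <= 3) {
    lo <- hi <- NA_real_
  } else {
    z <- atanh(pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12))
    se <- 1 / sqrt(n - 3)
    lo <- tanh(z - 1.96 * se); hi <- tanh(z + 1.96 * se)
  }
  tibble::tibble(pair = label, rho = rho, lo = lo, hi = hi,
                 p_value = sp$p_value, n = n, flag = sp$flag)
}
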