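#' Plot per-reader metric medians by contouring mode
#'
#' One point per reader and mode, the standard display of a crossover
#' reader study's per-reader results.
#'
#' @param study A validated study tibble.
#' @param metric Metric column to summarize (median per reader x mode).
#' @return A ggplot object.
#' @export
plot_reader_metric <- function(study, metric = "dsc") {
  validate_study(study)
  dat <- study |>
    dplyr::group_by(.data$reader, .data$experience_group, .data$mode) |>
    dplyr::summarise(value = stats::median(.data[[metric]], na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$reader, y = .data$value,
                                    colour = .data$mode,
                                    shape = .data$experience_group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(y = paste("median", metric), x = NULL,
                  title = "Per-reader performance by contouring mode")
}

#' Plot the per-pair time-saving distribution
#'
#' @param study A validated study tibble.
#' @return A ggplot object (histogram of per-pair percent time saving).
#' @export
plot_time_saving <- function(study) {
  validate_study(study)
  wide <- paired_units(study, "time_s")
  dat <- tibble::tibble(saving = time_saving(wide$unassisted,
                                             wide$assisted))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$saving)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = stats::median(dat$saving),
                        linetype = "dashed") +
    ggplot2::labs(x = "Per-lesion time saving (%)", y = "Pairs",
                  title = "Contouring time saving with assistance")
}
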