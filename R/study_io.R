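#' Write a study table to a study directory
#'
#' Serializes a crossover study as the on-disk layout
#' `records.csv` (one row per reader x lesion x mode) plus `study.yaml`
#' (readers, session orders, washout metadata, generating configuration).
#' Ground-truth patient masks can be included under `masks/GT/` when the
#' phantom object is supplied.
#'
#' @param study A validated study tibble.
#' @param dir Output directory (created if missing).
#' @param gt Optional `phantom_gt`; its patient volumes are written as
#'   NIfTI under `masks/GT/`.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, gt = NULL) {
  validate_study(study)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study, file.path(dir, "records.csv"), row.names = FALSE)
  cfg <- attr(study, "study_config")
  meta <- list(
    readers = unique(study$reader),
    experience_groups = as.list(stats::setNames(
      dplyr::distinct(study, .data$reader, .data$experience_group)$experience_group,
      dplyr::distinct(study, .data$reader, .data$experience_group)$reader)),
    session_orders = as.list(stats::setNames(
      dplyr::distinct(study, .data$reader, .data$session_order)$session_order,
      dplyr::distinct(study, .data$reader, .data$session_order)$reader)),
    washout_days = if (!is.null(cfg$washout_days)) cfg$washout_days else 42,
    seed = cfg$seed
  )
  yaml::write_yaml(meta, file.path(dir, "study.yaml"))
  if (!is.null(gt)) {
    mdir <- file.path(dir, "masks", "GT")
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (pat in gt$patients) {
      save_mask(pat$volume, file.path(mdir, sprintf("%03d.nii.gz",
                                                    pat$patient)))
    }
  }
  invisible(dir)
}

#' Read a study directory back into a study table
#'
#' @param dir A directory written by [write_study()].
#' @return A validated study tibble with `study.yaml` metadata attached as
#'   `attr(, "study_config")`.
#' @export
read_study <- function(dir) {
  rec <- file.path(dir, "records.csv")
  if (!file.exists(rec)) stop("no records.csv in ", dir, call. = FALSE)
  study <- tibble::as_tibble(utils::read.csv(rec, stringsAsFactors = FALSE))
  yml <- file.path(dir, "study.yaml")
  if (file.exists(yml)) {
    attr(study, "study_config") <- yaml::read_yaml(yml)
  }
  validate_study(study)
  study
}
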