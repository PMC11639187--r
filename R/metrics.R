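#' Dice similarity coefficient
#'
#' Voxel-count overlap between a predicted volume (PV) and a ground-truth
#' volume (GV): `2 |PV ∩ GV| / (|PV| + |GV|)`. 1 means complete consistency,
#' 0 means no overlap.
#'
#' @param pv,gv [label_volume()] objects on the same grid, or bare logical/
#'   0-1 arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`. An empty prediction against a
#'   nonempty ground truth returns 0 (a missed lesion); two empty masks are
#'   undefined and raise an error.
#' @examples
#' a <- empty_volume(c(16, 16, 16)); a$data[1:10, 1:10, 1:10] <- 1L
#' dsc(a, a) # 1
#' @export
dsc <- function(pv, gv) {
  m <- as_mask_pair(pv, gv)
  np <- sum(m$p); ng <- sum(m$g)
  if (np + ng == 0L) {
    stop("DSC undefined: both masks are empty", call. = FALSE)
  }
  2 * sum(m$p & m$g) / (np + ng)
}

# accepts label_volumes (geometry-checked) or bare arrays of equal shape
as_mask_pair <- function(pv, gv) {
  if (is_label_volume(pv) && is_label_volume(gv)) {
    assert_same_geometry(pv, gv)
    list(p = pv$data > 0L, g = gv$data > 0L)
  } else {
    p <- if (is_label_volume(pv)) pv$data > 0L else pv > 0
    g <- if (is_label_volume(gv)) gv$data > 0L else gv > 0
    if (!identical(dim(p), dim(g))) stop("mask shapes differ", call. = FALSE)
    list(p = p, g = g)
  }
}

#' Relative volume difference
#'
#' Symmetric percent difference between two scalar volumes:
#' `2 |V_P - V_G| / (V_P + V_G) x 100`. 0 means no volumetric revision is
#' needed. The scalar-volume form is used (not a set difference), so the
#' value is unclamped: a completely missed lesion (V_P = 0) gives 200%.
#'
#' @param pv_volume,gv_volume Scalar volumes (any common unit, e.g. mL), or
#'   [label_volume()] objects whose [volume_ml()] is taken.
#' @return RVD in percent, `>= 0`.
#' @examples
#' rvd(1, 1)   # 0
#' rvd(3, 1)   # 100
#' @export
rvd <- function(pv_volume, gv_volume) {
  vp <- if (is_label_volume(pv_volume)) volume_ml(pv_volume) else as.numeric(pv_volume)
  vg <- if (is_label_volume(gv_volume)) volume_ml(gv_volume) else as.numeric(gv_volume)
  if (vp < 0 || vg < 0) stop("volumes must be nonnegative", call. = FALSE)
  if (vp + vg == 0) {
    stop("RVD undefined: both volumes are zero", call. = FALSE)
  }
  2 * abs(vp - vg) / (vp + vg) * 100
}

#' Boundary voxels of a mask
#'
#' A foreground voxel is a boundary (surface) voxel when at least one of its
#' six face neighbours is background; the volume border counts as
#' background, so a mask touching the array edge still has a closed surface.
#'
#' @param v A [label_volume()].
#' @return n x 3 matrix of 1-based array indices of boundary voxels.
#' @export
boundary_voxels <- function(v) {
  stopifnot(is_label_volume(v))
  d <- dim(v$data)
  fgl <- v$data > 0L
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    n <- d[ax]
    lo <- shift_logical(fgl, ax, 1L)   # neighbour at index-1
    hi <- shift_logical(fgl, ax, -1L)  # neighbour at index+1
    interior <- interior & lo & hi
  }
  which(fgl & !interior, arr.ind = TRUE)
}

# shift a logical array along axis `ax` by `by` voxels, padding with FALSE
shift_logical <- function(x, ax, by) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) {       # out[i] <- x[i - by]
    dst[[ax]] <- (by + 1L):d[ax]; src[[ax]] <- 1L:(d[ax] - by)
  } else {
    dst[[ax]] <- 1L:(d[ax] + by); src[[ax]] <- (1L - by):d[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Average surface distance (mm)
#'
#' Mean over the predicted mask's boundary voxel centers of the minimum
#' Euclidean mm-distance to any ground-truth boundary voxel center. The
#' directed version averages over the prediction side only; `symmetric =
#' TRUE` returns the mean of the two directed values. Identical masks give
#' 0 mm; the metric is not symmetric in general.
#'
#' @param pv,gv Nonempty [label_volume()] objects on the same grid.
#' @param symmetric Average the two directed distances?
#' @return ASD in mm, or `NA_real_` (with a warning) when either mask is
#'   empty — an undefined value to be excluded from aggregation.
#' @export
asd <- function(pv, gv, symmetric = FALSE) {
  stopifnot(is_label_volume(pv), is_label_volume(gv))
  assert_same_geometry(pv, gv)
  if (sum(pv$data) == 0L || sum(gv$data) == 0L) {
    warning("ASD undefined for an empty mask; returning NA")
    return(NA_real_)
  }
  bp <- index_to_mm(boundary_voxels(pv), pv$geometry)
  bg <- index_to_mm(boundary_voxels(gv), gv$geometry)
  fwd <- mean(min_dist_to_set(bp, bg))
  if (!symmetric) return(fwd)
  (fwd + mean(min_dist_to_set(bg, bp))) / 2
}

#' Voxel-wise confusion counts
#'
#' TP/FP/FN/TN counts of a prediction against a ground truth, restricted to
#' an evaluation region. Specificity over a whole head-sized volume is
#' trivially near 1, so the region should normally be a brain mask or a
#' dilated bounding box around GT and prediction (see
#' [evaluation_region()]); the default is the whole volume.
#'
#' @param pv,gv [label_volume()] objects on the same grid.
#' @param region Optional [label_volume()] region mask; must contain every
#'   GT foreground voxel.
#' @return A `confusion_counts` list: `tp`, `fp`, `fn`, `tn`,
#'   `region_voxels` (their sum).
#' @export
voxel_confusion <- function(pv, gv, region = NULL) {
  m <- as_mask_pair(pv, gv)
  if (is.null(region)) {
    r <- array(TRUE, dim(m$g))
  } else {
    rm <- as_mask_pair(region, gv)
    r <- rm$p
    if (any(m$g & !r)) {
      stop("evaluation region excludes ground-truth voxels", call. = FALSE)
    }
  }
  p <- m$p[r]; g <- m$g[r]
  out <- list(tp = sum(p & g), fp = sum(p & !g),
              fn = sum(!p & g), tn = sum(!p & !g))
  out$region_voxels <- out$tp + out$fp + out$fn + out$tn
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %d fp %d fn %d tn %d (region %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$region_voxels))
  invisible(x)
}

#' Evaluation region around two masks
#'
#' The union bounding box of GT and prediction foreground, dilated by a
#' margin (in voxels per axis), clipped to the volume. Used as the default
#' confusion-count region so that specificity reflects the local contouring
#' neighbourhood rather than empty background.
#'
#' @param pv,gv [label_volume()] objects on the same grid.
#' @param margin_voxels Dilation of the bounding box, voxels.
#' @return A [label_volume()] region mask.
#' @export
evaluation_region <- function(pv, gv, margin_voxels = 5L) {
  stopifnot(is_label_volume(pv), is_label_volume(gv))
  assert_same_geometry(pv, gv)
  d <- dim(gv$data)
  fg <- which(pv$data > 0L | gv$data > 0L, arr.ind = TRUE)
  out <- array(0L, d)
  if (nrow(fg) == 0L) {
    out[] <- 1L  # nothing to bound: whole volume
  } else {
    lo <- pmax(apply(fg, 2, min) - margin_voxels, 1L)
    hi <- pmin(apply(fg, 2, max) + margin_voxels, d)
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  }
  label_volume(out, gv$geometry)
}

#' Ratios from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and the Matthews
#' correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' A zero denominator makes the value undefined: `NA_real_` is returned
#' rather than propagating NaN.
#'
#' @param c A `confusion_counts` from [voxel_confusion()].
#' @return A ratio, or `NA_real_` when undefined.
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0) return(NA_real_)
  c$tp / (c$tp + c$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(c) {
  if (c$tn + c$fp == 0) return(NA_real_)
  c$tn / (c$tn + c$fp)
}

#' @rdname sensitivity
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  fn <- as.numeric(c$fn); tn <- as.numeric(c$tn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Patient-wise Dice coefficient
#'
#' Dice computed on the union of all of a patient's lesions as single
#' whole-volume binary masks (the per-patient analogue of the per-lesion
#' Dice).
#'
#' @param gt Nonempty ground-truth [label_volume()].
#' @param pred Predicted [label_volume()] on the same grid.
#' @return Dice in `[0, 1]`; an empty prediction gives 0.
#' @export
patient_dsc <- function(gt, pred) {
  if (is_label_volume(gt) && sum(gt$data) == 0L) {
    stop("patient DSC undefined: ground truth is empty", call. = FALSE)
  }
  dsc(pred, gt)
}

#' Full metric record for one mask pair
#'
#' Computes the whole metric battery — Dice, RVD, ASD, confusion ratios —
#' for a prediction against a ground truth, as one tidy row. Undefined
#' values (empty masks, zero denominators) appear as `NA` with flags and
#' must be excluded from medians rather than imputed.
#'
#' @param gt,pred [label_volume()] objects on the same grid; `gt` nonempty.
#' @param region Confusion-count region: `"bbox"` (default; dilated union
#'   bounding box), `"whole"`, or a [label_volume()] mask.
#' @param margin_voxels Bounding-box dilation for `region = "bbox"`.
#' @param symmetric_asd Use symmetric ASD?
#' @param unit Optional identifier copied into the `unit` column.
#' @return A one-row tibble: `unit`, `dsc`, `rvd`, `asd_mm`, `sensitivity`,
#'   `specificity`, `mcc`, `missed_lesion`, `empty_prediction`,
#'   `region_policy`.
#' @export
evaluate_masks <- function(gt, pred, region = "bbox", margin_voxels = 5L,
                           symmetric_asd = FALSE, unit = NA_character_) {
  stopifnot(is_label_volume(gt), is_label_volume(pred))
  assert_same_geometry(gt, pred)
  if (sum(gt$data) == 0L) stop("ground truth is empty", call. = FALSE)
  empty_pred <- sum(pred$data) == 0L
  reg_policy <- if (is_label_volume(region)) "mask" else region
  reg <- if (is_label_volume(region)) {
    region
  } else if (identical(region, "whole")) {
    NULL
  } else if (identical(region, "bbox")) {
    evaluation_region(pred, gt, margin_voxels)
  } else {
    stop("`region` must be 'bbox', 'whole' or a label_volume", call. = FALSE)
  }
  cc <- voxel_confusion(pred, gt, reg)
  tibble::tibble(
    unit = unit,
    dsc = dsc(pred, gt),
    rvd = rvd(volume_ml(pred), volume_ml(gt)),
    asd_mm = if (empty_pred) NA_real_ else asd(pred, gt, symmetric_asd),
    sensitivity = sensitivity(cc),
    specificity = specificity(cc),
    mcc = mcc(cc),
    missed_lesion = empty_pred,
    empty_prediction = empty_pred,
    region_policy = reg_policy
  )
}
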