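#' Configuration for the synthetic lesion phantom
#'
#' The phantom emulates the statistical structure of a multi-center brain
#' metastasis test set: per-patient lesion counts capped at 15 (patients
#' with more metastases are excluded from such studies), a right-skewed
#' axial-diameter distribution (log-normal, moment-matched to a target
#' mean +/- SD of 12.8 +/- 7.7 mm), and lesion shapes rasterized from
#' spheroids perturbed by band-limited spherical-harmonic noise.
#'
#' @param shape Volume shape (voxels), length 3.
#' @param spacing Voxel spacing (mm), length 3.
#' @param n_patients Number of patients.
#' @param mean_lesions Mean of the (shifted, truncated) Poisson lesion
#'   count; counts are always in 1..15.
#' @param diameter_mean_mm,diameter_sd_mm Target mean and SD of the lesion
#'   axial diameter (mm).
#' @param diameter_min_mm Smallest diameter rasterized (resolvability floor).
#' @param irregularity Relative amplitude of the spherical-harmonic radius
#'   perturbation, in `[0, 1]`; 0 gives perfect spheres.
#' @param seed Integer seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                           n_patients = 10L, mean_lesions = 4,
                           diameter_mean_mm = 12.8, diameter_sd_mm = 7.7,
                           diameter_min_mm = 3, irregularity = 0.15,
                           seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8),
            diameter_mean_mm > 0, diameter_sd_mm >= 0,
            irregularity >= 0, irregularity <= 1, n_patients >= 1)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_patients = as.integer(n_patients),
                 mean_lesions = mean_lesions,
                 diameter_mean_mm = diameter_mean_mm,
                 diameter_sd_mm = diameter_sd_mm,
                 diameter_min_mm = diameter_min_mm,
                 irregularity = irregularity, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Sample lesion diameters (mm)
#'
#' Log-normal draws moment-matched to the target mean and SD: with
#' coefficient of variation `cv = sd/mean`, `sigma^2 = log(1 + cv^2)` and
#' `mu = log(mean) - sigma^2/2`, so the draws reproduce the target moments
#' exactly in expectation. A floor keeps every lesion resolvable on the
#' voxel grid.
#'
#' @param n Number of draws.
#' @param mean_mm,sd_mm Target moments.
#' @param min_mm Lower floor (applied by resampling, so moments stay close
#'   for realistic floors).
#' @return Numeric vector of diameters in mm.
#' @export
sample_diameters <- function(n, mean_mm = 12.8, sd_mm = 7.7, min_mm = 0) {
  cv <- sd_mm / mean_mm
  s2 <- log(1 + cv^2)
  mu <- log(mean_mm) - s2 / 2
  d <- stats::rlnorm(n, mu, sqrt(s2))
  while (any(d < min_mm)) {
    k <- d < min_mm
    d[k] <- stats::rlnorm(sum(k), mu, sqrt(s2))
  }
  d
}

# sample per-patient lesion counts: 1 + Poisson, truncated to [1, 15]
sample_lesion_counts <- function(n, mean_lesions) {
  k <- 1L + stats::rpois(n, max(mean_lesions - 1, 0))
  pmin(k, 15L)
}

# band-limited angular noise: random combination of low-order harmonics of
# the direction cosines, normalized to approximately unit RMS over the
# sphere. Returns f(u) for an n x 3 matrix of unit vectors.
harmonic_field <- function(coefs = stats::rnorm(9)) {
  basis <- function(u) {
    x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
    cbind(x * y, y * z, z * x, x^2 - y^2, 3 * z^2 - 1,
          x * y * z, x * (y^2 - z^2), y * (z^2 - x^2), z * (x^2 - y^2))
  }
  # normalize against RMS over a fixed quasi-uniform direction sample
  th <- seq(0.05, pi - 0.05, length.out = 24)
  ph <- seq(0, 2 * pi, length.out = 25)[-25]
  gr <- expand.grid(th = th, ph = ph)
  ref <- cbind(sin(gr$th) * cos(gr$ph), sin(gr$th) * sin(gr$ph), cos(gr$th))
  scale <- sqrt(mean((basis(ref) %*% coefs)^2))
  if (scale == 0) scale <- 1
  function(u) as.numeric(basis(u) %*% coefs) / scale
}

# rasterize one perturbed spheroid into an existing array (in place value 1)
# center_mm in mm; returns logical array of the full shape
rasterize_lesion <- function(center_mm, radius_mm, irregularity, field,
                             shape, spacing) {
  rmax <- radius_mm * (1 + irregularity)
  lo <- pmax(floor((center_mm - rmax) / spacing), 1)
  hi <- pmin(ceiling((center_mm + rmax) / spacing), shape)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  pts <- sweep(g, 2, spacing, `*`)
  dv <- sweep(pts, 2, center_mm, `-`)
  r <- sqrt(rowSums(dv^2))
  u <- dv / pmax(r, 1e-9)
  # radius in each direction, clipped so the surface stays star-shaped
  rad <- radius_mm * pmin(pmax(1 + irregularity * field(u), 0.3), 2)
  inside <- r <= rad
  out <- array(FALSE, shape)
  out[g[inside, , drop = FALSE]] <- TRUE
  out
}

#' Generate ground-truth phantom volumes
#'
#' Places non-overlapping perturbed-spheroid lesions in each patient volume.
#' With `irregularity = 0` every lesion is a rasterized sphere whose
#' realized axial diameter is within about one in-plane voxel of the
#' intended diameter. Deterministic per config seed.
#'
#' @param cfg A [phantom_config()].
#' @return A `phantom_gt` list: `patients` — a list of
#'   `list(patient, volume, lesions)` where `lesions` is a tibble with the
#'   intended center/radius/diameter and the realized voxel count — and
#'   `config`.
#' @export
generate_gt <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  geom <- voxel_geometry(cfg$spacing)
  extent <- cfg$shape * cfg$spacing
  counts <- sample_lesion_counts(cfg$n_patients, cfg$mean_lesions)
  patients <- vector("list", cfg$n_patients)
  for (p in seq_len(cfg$n_patients)) {
    n_les <- counts[p]
    arr <- array(FALSE, cfg$shape)
    placed <- list()
    meta <- vector("list", n_les)
    for (l in seq_len(n_les)) {
      ok <- FALSE
      for (try in 1:200) {
        dia <- sample_diameters(1, cfg$diameter_mean_mm, cfg$diameter_sd_mm,
                                cfg$diameter_min_mm)
        r0 <- dia / 2
        rmax <- r0 * (1 + cfg$irregularity)
        if (any(2 * rmax + 2 * max(cfg$spacing) > extent)) next
        ctr <- stats::runif(3, rmax + cfg$spacing, extent - rmax - cfg$spacing)
        clear <- TRUE
        for (q in placed) {
          gap <- sqrt(sum((ctr - q$center)^2)) -
            (rmax + q$rmax + 2 * max(cfg$spacing))
          if (gap <= 0) { clear <- FALSE; break }
        }
        if (!clear) next
        fld <- harmonic_field(stats::rnorm(9))
        les <- rasterize_lesion(ctr, r0, cfg$irregularity, fld,
                                cfg$shape, cfg$spacing)
        if (sum(les) == 0L || any(arr & les)) next
        arr <- arr | les
        placed[[length(placed) + 1L]] <- list(center = ctr, rmax = rmax)
        meta[[l]] <- tibble::tibble(
          lesion = l, center_x = ctr[1], center_y = ctr[2],
          center_z = ctr[3], radius_mm = r0, intended_diameter_mm = dia,
          n_voxels = sum(les))
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("could not place lesion ", l, " for patient ", p,
             " without overlap after 200 retries", call. = FALSE)
      }
    }
    patients[[p]] <- list(patient = p,
                          volume = label_volume(array(as.integer(arr),
                                                      cfg$shape), geom),
                          lesions = dplyr::bind_rows(meta))
  }
  structure(list(patients = patients, config = cfg), class = "phantom_gt")
}

#' @export
print.phantom_gt <- function(x, ...) {
  n_les <- sum(vapply(x$patients, function(p) nrow(p$lesions), integer(1)))
  cat("<phantom_gt>", length(x$patients), "patient(s),", n_les,
      "lesion(s)\n")
  invisible(x)
}

# signed distance (mm) to the mask surface at the given voxel indices:
# negative inside, with the zero level on the voxel-face surface (an
# adjacent voxel pair straddling the surface gets +/- half a voxel step).
# Exploits that the nearest background voxel to any foreground point lies
# in the background shell, and vice versa.
signed_distance_at <- function(v, g) {
  d <- dim(v$data)
  geom <- v$geometry
  bf <- boundary_voxels(v)                 # foreground boundary
  fgl <- v$data > 0L
  # background shell: background voxels with a foreground 6-neighbour
  shell <- array(FALSE, d)
  for (ax in 1:3) {
    shell <- shell | shift_logical(fgl, ax, 1L) | shift_logical(fgl, ax, -1L)
  }
  bs <- which(shell & !fgl, arr.ind = TRUE)
  pts <- index_to_mm(g, geom)
  inside <- fgl[g]
  h <- min(geom$spacing) / 2
  sd <- numeric(nrow(g))
  if (any(inside)) {
    sd[inside] <- -(min_dist_to_set(pts[inside, , drop = FALSE],
                                    index_to_mm(bs, geom)) - h)
  }
  if (any(!inside)) {
    sd[!inside] <- min_dist_to_set(pts[!inside, , drop = FALSE],
                                   index_to_mm(bf, geom)) - h
  }
  list(idx = g, sd = sd, inside = inside)
}

# perturb a single-lesion mask by thresholding its signed distance against
# a smooth angular noise field of RMS `noise_mm` (about the lesion
# centroid). Only voxels within ~3 * noise_mm of the surface can change
# side, so the signed distance is evaluated on a morphological band of that
# width; everything deeper keeps its original label.
perturb_lesion <- function(v, noise_mm) {
  if (noise_mm == 0) return(v)
  d <- dim(v$data)
  geom <- v$geometry
  fg <- foreground_indices(v)
  ctr <- colMeans(index_to_mm(fg, geom))
  fgl <- v$data > 0L
  w <- as.integer(ceiling(3 * noise_mm / min(geom$spacing))) + 1L
  dil <- fgl; ero <- fgl
  for (t in seq_len(w)) {
    dn <- dil; en <- ero
    for (ax in 1:3) {
      dn <- dn | shift_logical(dil, ax, 1L) | shift_logical(dil, ax, -1L)
      en <- en & shift_logical(ero, ax, 1L) & shift_logical(ero, ax, -1L)
    }
    dil <- dn; ero <- en
  }
  band <- which(dil & !ero, arr.ind = TRUE)
  sdb <- signed_distance_at(v, band)
  dv <- sweep(index_to_mm(sdb$idx, geom), 2, ctr, `-`)
  r <- sqrt(rowSums(dv^2))
  u <- dv / pmax(r, 1e-9)
  fld <- harmonic_field(stats::rnorm(9))
  keep <- sdb$sd <= noise_mm * fld(u)
  out <- array(0L, d)
  out[ero] <- 1L                           # deep interior always kept
  out[sdb$idx[keep, , drop = FALSE]] <- 1L
  label_volume(out, geom)
}

#' Simulate a model prediction for a ground-truth mask
#'
#' Emulates an automated segmentation's error process: each lesion
#' (connected component) is independently dropped with probability
#' `miss_rate`; surviving lesions have their boundary displaced by a
#' smooth random radial field of the given mm scale (so the expected
#' surface distance grows with `boundary_noise_mm`, and `0` reproduces the
#' ground truth exactly).
#'
#' @param gt A [label_volume()] ground truth.
#' @param boundary_noise_mm Boundary displacement scale (RMS, mm), `>= 0`.
#' @param miss_rate Per-lesion miss probability in `[0, 1]`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param connectivity Component connectivity.
#' @return A [label_volume()] prediction.
#' @export
simulate_prediction <- function(gt, boundary_noise_mm = 0.6, miss_rate = 0,
                                seed = NULL, connectivity = 26) {
  stopifnot(is_label_volume(gt), boundary_noise_mm >= 0,
            miss_rate >= 0, miss_rate <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ls <- label_components(gt, connectivity)
  out <- array(0L, dim(gt$data))
  for (l in seq_len(ls$n_lesions)) {
    if (stats::runif(1) < miss_rate) next
    single <- label_volume(array(as.integer(ls$labels == l), dim(out)),
                           gt$geometry)
    pert <- perturb_lesion(single, boundary_noise_mm)
    out <- out | pert$data
  }
  label_volume(array(as.integer(out), dim(gt$data)), gt$geometry)
}

#' Reader behaviour models for the simulated crossover study
#'
#' Residents carry a larger boundary-noise scale than attendings (they
#' contour less precisely unassisted); assistance multiplies the residual
#' noise a reader adds on top of the model prediction by `assist_effect`.
#' Because the residual is applied to the model prediction, the effective
#' assisted deviation from ground truth compounds as
#' `sqrt(model_noise^2 + (assist_effect * skill_noise)^2)`; the default
#' factors are small so that assisted accuracy sits just below the model's
#' own accuracy for both groups, which makes the generating Dice
#' improvement positive for every reader (large for residents, small for
#' attendings).
#' Contouring time is log-normal with a volume-dependent location and a
#' mode-specific speed factor calibrated so the median per-pair time saving
#' equals `median_time_saving` (42% by default); the log-normal session
#' noise makes occasional negative savings a natural outcome.
#'
#' @param n_residents,n_attendings Reader counts per experience group.
#' @param skill_noise_mm Named numeric: unassisted boundary-noise scale per
#'   group (mm).
#' @param assist_effect Named numeric: multiplicative residual-noise factor
#'   when assisted, per group.
#' @param base_time_s Median unassisted time for a 1 mL lesion (seconds).
#' @param time_volume_exp Exponent of lesion volume in the time location.
#' @param time_sd_log SD of the log-time session noise.
#' @param median_time_saving Generating median per-pair time saving (fraction).
#' @return Tibble of reader models: one row per reader.
#' @export
reader_models <- function(n_residents = 5L, n_attendings = 5L,
                          skill_noise_mm = c(resident = 0.8, attending = 0.65),
                          assist_effect = c(resident = 0.1, attending = 0.15),
                          base_time_s = 140, time_volume_exp = 0.2,
                          time_sd_log = 0.25, median_time_saving = 0.42) {
  grp <- c(rep("resident", n_residents), rep("attending", n_attendings))
  tibble::tibble(
    reader = sprintf("R%02d", seq_along(grp)),
    experience_group = grp,
    skill_noise_mm = unname(skill_noise_mm[grp]),
    assist_effect = unname(assist_effect[grp]),
    base_time_s = base_time_s,
    time_volume_exp = time_volume_exp,
    time_sd_log = time_sd_log,
    median_time_saving = median_time_saving
  )
}

#' Simulate a full crossover reader study
#'
#' For every reader x lesion x mode the simulator draws a contour and a
#' contouring time, scores the contour against the ground truth, and
#' returns the complete lesion-level study table. Unassisted contours are
#' perturbations of the ground truth at the reader's full skill noise;
#' assisted contours are perturbations of the simulated model prediction at
#' the reader's residual (assistance-reduced) noise — the reader edits the
#' model proposal rather than starting from scratch. All metrics are
#' computed on a per-lesion crop with a dilated bounding-box confusion
#' region. Deterministic per seed.
#'
#' @param gt A `phantom_gt` from [generate_gt()].
#' @param readers A tibble from [reader_models()].
#' @param plan A `session_plan` from [assign_sessions()] covering the same
#'   readers; `NULL` randomizes one from `seed`.
#' @param seed Integer seed.
#' @param model_noise_mm Boundary noise of the simulated model prediction.
#' @param model_miss_rate Per-lesion miss rate of the model prediction.
#' @param crop_margin_voxels Margin around each lesion's bounding box for
#'   the per-lesion evaluation crop.
#' @return A lesion-level study tibble (one row per reader x lesion x mode)
#'   with metric, voxel-count, volume and time columns, carrying the
#'   generating configuration in `attr(, "study_config")`.
#' @export
simulate_reader_study <- function(gt, readers = reader_models(),
                                  plan = NULL, seed = 1L,
                                  model_noise_mm = 0.6,
                                  model_miss_rate = 0,
                                  crop_margin_voxels = 4L) {
  stopifnot(inherits(gt, "phantom_gt"))
  set.seed(as.integer(seed))
  if (is.null(plan)) plan <- assign_sessions(readers$reader, seed)
  readers <- dplyr::left_join(readers, plan$readers, by = "reader")
  set.seed(as.integer(seed) + 1L)  # plan assignment consumed its own stream
  geom <- voxel_geometry(gt$config$spacing)
  rows <- list()
  for (pat in gt$patients) {
    ls <- label_components(pat$volume)
    for (l in seq_len(ls$n_lesions)) {
      # per-lesion crop, shared by all readers
      idx <- which(ls$labels == l, arr.ind = TRUE)
      d <- dim(ls$labels)
      lo <- pmax(apply(idx, 2, min) - crop_margin_voxels, 1L)
      hi <- pmin(apply(idx, 2, max) + crop_margin_voxels, d)
      crop <- ls$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      gt_crop <- label_volume(array(as.integer(crop == l), dim(crop)), geom)
      gt_meta <- lesion_table(label_components(gt_crop))
      pred_crop <- simulate_prediction(gt_crop, model_noise_mm,
                                       model_miss_rate)
      for (r in seq_len(nrow(readers))) {
        rd <- readers[r, ]
        for (mode in c("unassisted", "assisted")) {
          contour <- if (mode == "unassisted") {
            perturb_lesion(gt_crop, rd$skill_noise_mm)
          } else if (sum(pred_crop$data) == 0L) {
            # model missed the lesion: reader falls back to manual contouring
            perturb_lesion(gt_crop, rd$skill_noise_mm)
          } else {
            perturb_lesion(pred_crop, rd$skill_noise_mm * rd$assist_effect)
          }
          met <- evaluate_masks(gt_crop, contour,
                                margin_voxels = crop_margin_voxels)
          cc_gt <- sum(gt_crop$data); cc_pr <- sum(contour$data)
          n_ov <- sum(gt_crop$data & contour$data)
          loc <- log(rd$base_time_s) +
            rd$time_volume_exp * log(gt_meta$volume_ml[1])
          t_s <- exp(loc + stats::rnorm(1, 0, rd$time_sd_log) +
                       if (mode == "assisted") log(1 - rd$median_time_saving)
                       else 0)
          session <- if ((mode == "assisted") ==
                         (rd$session_order == "assisted_first")) 1L else 2L
          rows[[length(rows) + 1L]] <- tibble::tibble(
            reader = rd$reader, experience_group = rd$experience_group,
            session_order = rd$session_order, patient = pat$patient,
            lesion = l, mode = mode, session = session,
            time_s = t_s, dsc = met$dsc, rvd = met$rvd,
            asd_mm = met$asd_mm, sensitivity = met$sensitivity,
            specificity = met$specificity, mcc = met$mcc,
            missed_lesion = met$missed_lesion,
            n_gt = cc_gt, n_pred = cc_pr, n_overlap = n_ov,
            gt_ml = volume_ml(cc_gt, geom),
            pred_ml = volume_ml(cc_pr, geom),
            volume_ml = gt_meta$volume_ml[1],
            diameter_mm = gt_meta$diameter_mm[1]
          )
        }
      }
    }
  }
  study <- dplyr::bind_rows(rows)
  attr(study, "study_config") <- list(
    seed = seed, model_noise_mm = model_noise_mm,
    model_miss_rate = model_miss_rate, readers = readers,
    phantom = gt$config, washout_days = 42
  )
  validate_study(study)
  study
}
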