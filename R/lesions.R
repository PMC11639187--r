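#' Label connected lesion components of a binary mask
#'
#' Partitions the foreground of a mask into maximal connected components
#' under a 6-, 18- or 26-neighbourhood. 26-connectivity (faces, edges and
#' corners) is the default for lesion counting in 3D, as it avoids splitting
#' lesions joined by diagonal necks.
#'
#' @param v A [label_volume()].
#' @param connectivity One of 6, 18, 26.
#' @return A `lesion_set`: list with `source` (the input volume), `labels`
#'   (integer array, 0 = background, 1..K = component id) and `n_lesions`.
#'   Components are numbered in order of their first voxel in array order.
#' @examples
#' v <- empty_volume(c(16, 16, 16))
#' v$data[2:4, 2:4, 2:4] <- 1L
#' v$data[10:12, 10:12, 10:12] <- 1L
#' label_components(label_volume(v$data))$n_lesions # 2
#' @export
label_components <- function(v, connectivity = 26) {
  stopifnot(is_label_volume(v))
  if (!connectivity %in% c(6, 18, 26)) {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  d <- dim(v$data)
  fg <- which(v$data > 0L)
  labels <- array(0L, d)
  if (length(fg) == 0L) {
    return(structure(list(source = v, labels = labels, n_lesions = 0L,
                          connectivity = connectivity),
                     class = "lesion_set"))
  }
  # vertex id per foreground voxel, 0 elsewhere
  vid <- array(0L, d)
  vid[fg] <- seq_along(fg)
  idx <- arrayInd(fg, d)
  offs <- neighbour_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    ni <- idx[, 1] + o[1]; nj <- idx[, 2] + o[2]; nk <- idx[, 3] + o[3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    if (!any(ok)) next
    nb <- vid[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- nb > 0L
    if (any(hit)) {
      edges[[k]] <- cbind(which(ok)[hit], nb[hit])
    }
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) {
    memb <- seq_along(fg)
  } else {
    g <- igraph::make_graph(t(edges), n = length(fg), directed = FALSE)
    memb <- igraph::components(g)$membership
  }
  # renumber components by first appearance in array order
  first <- match(unique(memb), memb)
  ord <- order(first)
  remap <- integer(max(memb))
  remap[unique(memb)[ord]] <- seq_along(ord)
  labels[fg] <- remap[memb]
  structure(list(source = v, labels = labels,
                 n_lesions = length(unique(memb)),
                 connectivity = connectivity),
            class = "lesion_set")
}

# lexicographically positive half of the neighbourhood offsets
neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  g <- g[keep, , drop = FALSE]
  # keep one of each +/- pair
  pos <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  g[pos, , drop = FALSE]
}

#' @export
print.lesion_set <- function(x, ...) {
  cat("<lesion_set>", x$n_lesions, "lesion(s), connectivity",
      x$connectivity, "\n")
  invisible(x)
}

#' Per-lesion descriptor table
#'
#' One row per lesion with voxel count, physical volume (mL) and the axial
#' largest cross-sectional dimension (mm) — the clinical brain-metastasis
#' size definition: the maximum in-plane distance between voxel centers on
#' any single axial slice.
#'
#' @param ls A `lesion_set` from [label_components()].
#' @return A tibble with columns `lesion`, `n_voxels`, `volume_ml`,
#'   `diameter_mm`, `slice_min`, `slice_max` (axial slice range).
#' @export
lesion_table <- function(ls) {
  stopifnot(inherits(ls, "lesion_set"))
  geom <- ls$source$geometry
  if (ls$n_lesions == 0L) {
    return(tibble::tibble(lesion = integer(), n_voxels = integer(),
                          volume_ml = numeric(), diameter_mm = numeric(),
                          slice_min = integer(), slice_max = integer()))
  }
  fg <- which(ls$labels > 0L)
  lab <- ls$labels[fg]
  idx <- arrayInd(fg, dim(ls$labels))
  ax <- geom$axial_axis
  purrr::map_dfr(seq_len(ls$n_lesions), function(id) {
    li <- idx[lab == id, , drop = FALSE]
    tibble::tibble(
      lesion = id,
      n_voxels = nrow(li),
      volume_ml = volume_ml(nrow(li), geom),
      diameter_mm = lesion_diameter_axial(li, geom),
      slice_min = min(li[, ax]),
      slice_max = max(li[, ax])
    )
  })
}

#' Axial largest cross-sectional dimension of a lesion
#'
#' For every axial slice the lesion intersects, the maximum pairwise
#' Euclidean in-plane distance between voxel centers; the lesion diameter is
#' the maximum over slices. A single-voxel lesion has diameter 0 (the metric
#' is between voxel centers, so it under-reports physical extent by about
#' one voxel).
#'
#' @param voxel_idx n x 3 matrix of 1-based array indices of lesion voxels.
#' @param geometry A [voxel_geometry()].
#' @return Diameter in mm.
#' @export
lesion_diameter_axial <- function(voxel_idx, geometry) {
  if (!is.matrix(voxel_idx)) voxel_idx <- matrix(voxel_idx, ncol = 3)
  if (nrow(voxel_idx) == 0L) stop("lesion is empty", call. = FALSE)
  ax <- geometry$axial_axis
  plane <- in_plane_axes(geometry)
  sp <- geometry$spacing[plane]
  slices <- split.data.frame(voxel_idx[, plane, drop = FALSE],
                             voxel_idx[, ax])
  max(vapply(slices, function(pts) {
    pts <- sweep(unique(pts), 2, sp, `*`)
    n <- nrow(pts)
    if (n == 1L) return(0)
    if (n > 400L) {
      hull <- grDevices::chull(pts[, 1], pts[, 2])
      pts <- pts[hull, , drop = FALSE]
    }
    max(stats::dist(pts))
  }, numeric(1)))
}

#' Match predicted components to ground-truth lesions
#'
#' Ground-truth-centric pairing for per-lesion scoring of segmentations.
#' Each GT lesion is matched to the union of all predicted connected
#' components that overlap it; a predicted component overlapping several GT
#' lesions has its voxels partitioned among them by nearest GT lesion
#' (mm distance to the nearest voxel of each candidate lesion; ties go to
#' the lower GT id). Predicted components overlapping no GT lesion are
#' reported separately as false-positive candidates and take no part in
#' per-lesion scores. A GT lesion with no overlapping prediction keeps an
#' empty match (per-lesion Dice 0, `missed_lesion` flag downstream).
#'
#' @param gt A `lesion_set` (from [label_components()]) of the ground truth.
#' @param pred A [label_volume()] prediction on the same grid.
#' @param connectivity Connectivity for labelling the prediction.
#' @return A `match_table`: list with `matches` (tibble: `gt_lesion`,
#'   `n_gt`, `n_pred`, `n_overlap`, `dsc`, and a list column `pred_voxels`
#'   of linear indices) and `unmatched` (tibble: `pred_component`,
#'   `n_voxels`).
#' @export
match_lesions <- function(gt, pred, connectivity = 26) {
  stopifnot(inherits(gt, "lesion_set"), is_label_volume(pred))
  assert_same_geometry(gt$source, pred)
  d <- dim(pred$data)
  geom <- pred$geometry
  pls <- label_components(pred, connectivity)
  # overlap counts between gt lesions and pred components
  both <- which(gt$labels > 0L & pls$labels > 0L)
  ov <- if (length(both)) {
    dplyr::count(
      tibble::tibble(gt_lesion = gt$labels[both],
                     pred_component = pls$labels[both]),
      .data$gt_lesion, .data$pred_component, name = "n_overlap")
  } else {
    tibble::tibble(gt_lesion = integer(), pred_component = integer(),
                   n_overlap = integer())
  }
  pred_fg <- which(pls$labels > 0L)
  pred_lab <- pls$labels[pred_fg]
  # assignment of each predicted voxel: gt lesion id or 0 (unmatched)
  assign_to <- integer(length(pred_fg))
  for (pc in seq_len(pls$n_lesions)) {
    cands <- ov$gt_lesion[ov$pred_component == pc]
    sel <- which(pred_lab == pc)
    if (length(cands) == 0L) {
      assign_to[sel] <- 0L
    } else if (length(cands) == 1L) {
      assign_to[sel] <- cands
    } else {
      cands <- sort(cands)
      pts <- index_to_mm(arrayInd(pred_fg[sel], d), geom)
      dm <- vapply(cands, function(g) {
        gidx <- arrayInd(which(gt$labels == g), d)
        min_dist_to_set(pts, index_to_mm(gidx, geom))
      }, numeric(length(sel)))
      if (!is.matrix(dm)) dm <- matrix(dm, nrow = length(sel))
      # which.min returns the first minimum -> lower gt id wins ties
      assign_to[sel] <- cands[apply(dm, 1L, which.min)]
    }
  }
  matches <- purrr::map_dfr(seq_len(gt$n_lesions), function(g) {
    vox <- pred_fg[assign_to == g]
    n_gt <- sum(gt$labels == g)
    n_ov <- sum(gt$labels[vox] == g)
    tibble::tibble(
      gt_lesion = g, n_gt = n_gt, n_pred = length(vox), n_overlap = n_ov,
      dsc = 2 * n_ov / (length(vox) + n_gt),
      pred_voxels = list(vox)
    )
  })
  un <- setdiff(seq_len(pls$n_lesions), ov$pred_component)
  unmatched <- tibble::tibble(
    pred_component = as.integer(un),
    n_voxels = vapply(un, function(pc) sum(pred_lab == pc), integer(1))
  )
  structure(list(matches = matches, unmatched = unmatched),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat("<match_table>", nrow(x$matches), "GT lesion(s),",
      nrow(x$unmatched), "unmatched predicted component(s)\n")
  print(dplyr::select(x$matches, -"pred_voxels"))
  invisible(x)
}

#' Write a lesion descriptor table to CSV
#'
#' @param ls A `lesion_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lesion_csv <- function(ls, path) {
  utils::write.csv(lesion_table(ls), path, row.names = FALSE)
  invisible(path)
}
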