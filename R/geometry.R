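#' Voxel geometry of a 3D mask
#'
#' Physical geometry of a voxel grid: the spacing of each array axis in
#' mm/voxel, which array axis carries the axial (superior-inferior) slice
#' direction, and an informational physical origin. All distances inside the
#' package are computed between voxel centers as `index * spacing` per axis;
#' the origin is ignored for intra-volume distances.
#'
#' @param spacing Numeric length-3, mm per voxel along the three array axes.
#'   All components must be strictly positive and finite.
#' @param axial_axis Integer in 1..3: the array axis perpendicular to axial
#'   slices (i.e., slices `[ , , k]` are axial when `axial_axis = 3`).
#' @param origin Numeric length-3, physical offset in mm (informational).
#'
#' @return An object of class `voxel_geometry`.
#' @examples
#' voxel_geometry(c(1, 1, 1))
#' voxel_geometry(c(3, 0.5, 0.5), axial_axis = 1)
#' @export
voxel_geometry <- function(spacing = c(1, 1, 1), axial_axis = 3L,
                           origin = c(0, 0, 0)) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive finite values (mm/voxel), got: ",
         paste(format(spacing), collapse = ", "), call. = FALSE)
  }
  axial_axis <- as.integer(axial_axis)
  if (length(axial_axis) != 1L || is.na(axial_axis) || !axial_axis %in% 1:3) {
    stop("`axial_axis` must be 1, 2 or 3", call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3", call. = FALSE)
  structure(
    list(spacing = spacing, axial_axis = axial_axis, origin = origin),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat("<voxel_geometry> spacing", paste(format(x$spacing), collapse = " x "),
      "mm, axial axis", x$axial_axis, "\n")
  invisible(x)
}

#' @rdname voxel_geometry
#' @param x Object to test.
#' @export
is_voxel_geometry <- function(x) inherits(x, "voxel_geometry")

# mm^3 of one voxel
voxel_volume_mm3 <- function(geometry) prod(geometry$spacing)

# indices of the two in-plane axes for the configured axial axis
in_plane_axes <- function(geometry) setdiff(1:3, geometry$axial_axis)
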