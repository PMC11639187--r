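#' Read a binary mask from a NIfTI file
#'
#' Loads a 3D NIfTI image and binarizes it: any strictly positive voxel
#' becomes foreground. Spacing is taken from the header `pixdim`; the axial
#' axis is derived from the orientation (qform/sform) matrix as the array
#' axis whose world direction is closest to the superior-inferior axis. When
#' the file carries no orientation code the third array axis is assumed
#' axial (the NIfTI default layout).
#'
#' @param path Path to a `.nii` or `.nii.gz` file with 3 spatial dimensions.
#' @param axial_axis Optional override (1..3) of the derived axial axis.
#' @return A [label_volume()].
#' @seealso [save_mask()]
#' @export
load_mask <- function(path, axial_axis = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), " dimensions: ", path,
         call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("non-finite or non-positive voxel spacing in header of ", path,
         call. = FALSE)
  }
  xf <- RNifti::xform(img)
  if (is.null(axial_axis)) {
    axial_axis <- axial_axis_from_xform(xf)
  }
  origin <- as.numeric(xf[1:3, 4])
  arr <- array(as.numeric(img), d)
  label_volume(arr, voxel_geometry(spacing, axial_axis, origin))
}

# array axis whose world direction is closest to superior-inferior (world z)
axial_axis_from_xform <- function(xf) {
  r <- xf[1:3, 1:3]
  norms <- sqrt(colSums(r^2))
  if (any(norms == 0) || any(!is.finite(norms))) return(3L)
  as.integer(which.max(abs(r[3, ]) / norms))
}

#' Write a binary mask to a NIfTI file
#'
#' The header spacing is set to the volume's geometry spacing; the
#' orientation matrix is written so that the configured axial axis maps to
#' the world superior-inferior direction, making [load_mask()] an exact
#' inverse for voxel data, spacing and axial axis.
#'
#' @param v A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly usable in pipelines.
#' @export
save_mask <- function(v, path) {
  stopifnot(is_label_volume(v))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  img <- RNifti::asNifti(array(as.integer(v$data), dim(v$data)))
  RNifti::pixdim(img) <- v$geometry$spacing
  mat <- diag(4)
  sp <- v$geometry$spacing
  ax <- v$geometry$axial_axis
  plane <- setdiff(1:3, ax)
  mat[1:3, 1:3] <- 0
  mat[1, plane[1]] <- sp[plane[1]]
  mat[2, plane[2]] <- sp[plane[2]]
  mat[3, ax] <- sp[ax]
  mat[1:3, 4] <- v$geometry$origin
  RNifti::qform(img) <- structure(mat, code = 2L)
  RNifti::sform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
  path
}
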