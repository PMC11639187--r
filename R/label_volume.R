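#' Binary 3D label volume with physical geometry
#'
#' The central mask container: a 3D array holding 0/1 voxel occupancy plus a
#' [voxel_geometry()] describing spacing and the axial axis. Any strictly
#' positive voxel value in `data` is treated as foreground, so probability
#' maps and multi-label images binarize consistently.
#'
#' @param data A 3D numeric/integer/logical array. Non-finite values are
#'   rejected; any value > 0 becomes foreground (1).
#' @param geometry A [voxel_geometry()]; defaults to 1 mm isotropic spacing
#'   with axial axis 3.
#'
#' @return An object of class `label_volume` with elements `data`
#'   (integer 0/1 array) and `geometry`.
#' @examples
#' v <- label_volume(array(0L, c(8, 8, 8)))
#' v$data[3:6, 3:6, 3:6] <- 1L
#' v <- label_volume(v$data)
#' volume_ml(v)
#' @export
label_volume <- function(data, geometry = voxel_geometry()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (!is_voxel_geometry(geometry)) {
    stop("`geometry` must be a voxel_geometry", call. = FALSE)
  }
  if (is.logical(data)) {
    bin <- array(as.integer(data), dim(data))
  } else {
    if (any(!is.finite(data))) {
      stop("`data` contains non-finite voxel values", call. = FALSE)
    }
    bin <- array(as.integer(data > 0), dim(data))
  }
  structure(list(data = bin, geometry = geometry), class = "label_volume")
}

#' @rdname label_volume
#' @param x Object to test.
#' @export
is_label_volume <- function(x) inherits(x, "label_volume")

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume>", paste(dim(x$data), collapse = " x "),
      "voxels,", sum(x$data), "foreground,",
      format(volume_ml(x), digits = 4), "mL\n")
  print(x$geometry)
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$data)

#' Foreground volume in millilitres
#'
#' Voxel count times the physical voxel volume, converted from mm^3 to mL
#' (1000 mm^3 = 1 mL).
#'
#' @param v A [label_volume()], or a voxel count (with `geometry` supplied).
#' @param geometry Required when `v` is a bare voxel count.
#' @return Volume in mL.
#' @examples
#' cube <- empty_volume(c(32, 32, 32))
#' cube$data[1:10, 1:10, 1:10] <- 1L
#' volume_ml(label_volume(cube$data)) # 1 mL
#' @export
volume_ml <- function(v, geometry = NULL) {
  if (is_label_volume(v)) {
    sum(v$data) * voxel_volume_mm3(v$geometry) / 1000
  } else {
    if (is.null(geometry)) stop("`geometry` required for a bare voxel count")
    as.numeric(v) * voxel_volume_mm3(geometry) / 1000
  }
}

#' All-background volume of a given shape
#'
#' @param shape Integer length-3 array dimensions.
#' @param geometry A [voxel_geometry()].
#' @return An empty [label_volume()].
#' @export
empty_volume <- function(shape, geometry = voxel_geometry()) {
  label_volume(array(0L, as.integer(shape)), geometry)
}

#' Check that two volumes share a voxel grid
#'
#' Two masks are comparable only when their shapes match and their spacings
#' agree within tolerance. Returns a report rather than throwing, so callers
#' can decide whether a mismatch is fatal.
#'
#' @param a,b [label_volume()] objects.
#' @param tol_mm Componentwise spacing tolerance in mm.
#' @return A list of class `geometry_report`: `pass` (logical), `messages`
#'   (character, naming the failing axis where applicable).
#' @examples
#' a <- empty_volume(c(16, 16, 16))
#' check_geometry(a, a)$pass
#' @export
check_geometry <- function(a, b, tol_mm = 1e-4) {
  stopifnot(is_label_volume(a), is_label_volume(b))
  msgs <- character()
  da <- dim(a$data); db <- dim(b$data)
  for (ax in 1:3) {
    if (da[ax] != db[ax]) {
      msgs <- c(msgs, sprintf("shape mismatch on axis %d: %d vs %d",
                              ax, da[ax], db[ax]))
    }
  }
  ds <- abs(a$geometry$spacing - b$geometry$spacing)
  for (ax in 1:3) {
    if (ds[ax] > tol_mm) {
      msgs <- c(msgs, sprintf(
        "spacing mismatch on axis %d: %g vs %g mm (tol %g)",
        ax, a$geometry$spacing[ax], b$geometry$spacing[ax], tol_mm))
    }
  }
  structure(list(pass = length(msgs) == 0L, messages = msgs),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(if (x$pass) "geometry check: PASS\n" else "geometry check: FAIL\n")
  for (m in x$messages) cat(" -", m, "\n")
  invisible(x)
}

#' @rdname check_geometry
#' @param path Optional file to write the JSON report to.
#' @export
geometry_report_json <- function(a, b, tol_mm = 1e-4, path = NULL) {
  rep <- check_geometry(a, b, tol_mm)
  js <- jsonlite::toJSON(list(pass = rep$pass, messages = rep$messages),
                         auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  js
}

# stop unless a and b are comparable
assert_same_geometry <- function(a, b, tol_mm = 1e-4) {
  rep <- check_geometry(a, b, tol_mm)
  if (!rep$pass) {
    stop("incompatible volumes: ", paste(rep$messages, collapse = "; "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# voxel-center coordinates (mm) for an n x 3 index matrix (1-based indices)
index_to_mm <- function(idx, geometry) {
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = 3)
  sweep(idx, 2, geometry$spacing, `*`)
}

# n x 3 array-index matrix of foreground voxels
foreground_indices <- function(v) {
  which(v$data > 0L, arr.ind = TRUE)
}
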