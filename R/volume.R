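#' CT volume in Hounsfield units
#'
#' Canonical in-memory representation of a CT scan: a 3D numeric array of
#' Hounsfield units (HU) with voxel spacing and origin in millimetres. The
#' axis convention is fixed throughout the package:
#'
#' * axis 1 (`x`): subject left to subject right
#' * axis 2 (`y`): anterior to posterior
#' * axis 3 (`z`): inferior to superior
#'
#' All readers reorient into this convention, so downstream code can define
#' anterior-posterior and lateral views unambiguously. HU values are kept as
#' signed numbers without clamping: metal implants routinely exceed the
#' +3071 ceiling of 12-bit storage and the red compositing rule depends on
#' values above +2800.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing Numeric length-3, voxel spacing in mm per axis; all
#'   components must be strictly positive.
#' @param origin Numeric length-3, position (mm) of the centre of voxel
#'   `[1, 1, 1]` in the canonical coordinate frame.
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(-1000, dim = c(4, 4, 4)), spacing = c(1, 1, 2))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  storage.mode(voxels) <- "double"
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  if (any(dim(voxels) < 2L))
    stop("all three volume dimensions must be >= 2 voxels", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("volume contains non-finite HU values", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

is_ct_volume <- function(x) inherits(x, "ct_volume")

stopifnot_volume <- function(volume) {
  if (!is_ct_volume(volume))
    stop("expected a `ct_volume` object", call. = FALSE)
  invisible(volume)
}
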