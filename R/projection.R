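#' Sentinel HU for fully masked minIP rays
#'
#' Value assigned to a selective-minIP pixel whose ray contains only
#' exterior-air voxels. +3071 HU is the top of the conventional 12-bit CT
#' range: it is guaranteed to sit above every gas threshold, so such pixels
#' can never be coloured blue, while keeping the image in a valid HU range
#' (no infinities).
#'
#' @export
MINIP_SENTINEL_HU <- 3071

#' 2D projection image
#'
#' A 2D HU image produced by collapsing a CT volume along one axis. Rows run
#' superior-to-inferior (head at the top), columns left-to-right across the
#' subject for the anterior-posterior view and anterior-to-posterior for the
#' lateral view.
#'
#' @param values Numeric matrix of HU values (rows x columns).
#' @param pixel_spacing Numeric length-2, mm per (row, column) step.
#' @param view `"anterior_posterior"` or `"lateral"`.
#' @param kind `"mip"`, `"minip"` or `"average"`.
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(values, pixel_spacing, view, kind) {
  view <- match.arg(view, c("anterior_posterior", "lateral"))
  kind <- match.arg(kind, c("mip", "minip", "average"))
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  pixel_spacing <- as.double(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("`pixel_spacing` must be 2 positive numbers (mm)", call. = FALSE)
  structure(
    list(values = values, pixel_spacing = pixel_spacing,
         view = view, kind = kind),
    class = "projection_image"
  )
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %s %s, %d x %d px, spacing %.3g x %.3g mm\n",
              x$view, x$kind, nrow(x$values), ncol(x$values),
              x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

# Collapse a 3D array with `fun` along the axis a view looks through, and
# orient the result head-up: anterior_posterior collapses y (image z x x),
# lateral collapses x (image z x y).
collapse_volume <- function(vox, view, fun) {
  keep <- switch(view, anterior_posterior = c(1L, 3L), lateral = c(2L, 3L))
  m <- apply(vox, keep, fun)       # (x or y) x z
  t(m)[dim(vox)[3]:1, , drop = FALSE]
}

projection_spacing <- function(volume, view) {
  s <- volume$spacing
  switch(view,
         anterior_posterior = c(s[3], s[1]),
         lateral = c(s[3], s[2]))
}

#' Maximum intensity projection
#'
#' Each pixel is the maximum HU along the orthographic ray through the
#' volume, highlighting bone and radiopaque foreign material.
#'
#' @param volume A [ct_volume()].
#' @param view `"anterior_posterior"` (collapses the anterior-posterior
#'   axis) or `"lateral"` (collapses the left-right axis).
#' @return A [projection_image()] of kind `"mip"`.
#' @export
project_mip <- function(volume, view = c("anterior_posterior", "lateral")) {
  stopifnot_volume(volume)
  view <- match.arg(view)
  projection_image(collapse_volume(volume$voxels, view, max),
                   projection_spacing(volume, view), view, "mip")
}

#' Average projection
#'
#' Each pixel is the arithmetic mean HU along the full ray (no masking),
#' producing an image resembling a plain radiograph that supplies faint
#' soft-tissue context.
#'
#' @inheritParams project_mip
#' @return A [projection_image()] of kind `"average"`.
#' @export
project_average <- function(volume, view = c("anterior_posterior", "lateral")) {
  stopifnot_volume(volume)
  view <- match.arg(view)
  projection_image(collapse_volume(volume$voxels, view, mean),
                   projection_spacing(volume, view), view, "average")
}

#' Selective minimum intensity projection
#'
#' Each pixel is the minimum HU along the ray over the voxels *not* flagged
#' in the exterior-air mask, so only gas inside the body (and any other
#' unflagged low-density voxel) can reach the image. Rays consisting
#' entirely of flagged voxels get the sentinel [MINIP_SENTINEL_HU], which
#' lies above every threshold and therefore never renders as gas.
#'
#' @inheritParams project_mip
#' @param mask Logical array from [region_grow_exterior()], same shape as
#'   the volume.
#' @return A [projection_image()] of kind `"minip"`.
#' @export
project_minip_selective <- function(volume, mask,
                                    view = c("anterior_posterior", "lateral")) {
  stopifnot_volume(volume)
  view <- match.arg(view)
  if (!is.array(mask) || !identical(dim(mask), dim(volume$voxels)))
    stop("`mask` must be a logical array with the same shape as the volume",
         call. = FALSE)
  vox <- volume$voxels
  vox[mask] <- Inf
  vals <- collapse_volume(vox, view, min)
  vals[!is.finite(vals)] <- MINIP_SENTINEL_HU
  projection_image(vals, projection_spacing(volume, view), view, "minip")
}

#' Resample a projection to square pixels
#'
#' CT reconstructions are usually anisotropic (slice spacing differs from
#' in-plane spacing), which would stretch the projections vertically.
#' Linear interpolation resamples both image axes to the smaller of the two
#' input spacings. Interpolation is linear, so output values never leave
#' the input value range, and an already-isotropic image is returned
#' unchanged.
#'
#' @param image A [projection_image()].
#' @return A [projection_image()] with equal row and column spacing.
#' @export
resample_isotropic <- function(image) {
  if (!inherits(image, "projection_image"))
    stop("expected a `projection_image`", call. = FALSE)
  s <- image$pixel_spacing
  if (isTRUE(all.equal(s[1], s[2]))) return(image)
  target <- min(s)
  vals <- image$values
  for (axis in 1:2) {
    n <- dim(vals)[axis]
    if (isTRUE(all.equal(s[axis], target))) next
    old_pos <- (seq_len(n) - 1) * s[axis]
    n_new <- floor(old_pos[n] / target + 1e-9) + 1L
    new_pos <- (seq_len(n_new) - 1) * target
    if (axis == 1L) {
      vals <- apply(vals, 2, function(v)
        stats::approx(old_pos, v, xout = new_pos)$y)
      if (!is.matrix(vals)) vals <- matrix(vals, nrow = n_new)
    } else {
      vals <- t(apply(vals, 1, function(v)
        stats::approx(old_pos, v, xout = new_pos)$y))
      if (!is.matrix(vals)) vals <- matrix(vals, ncol = n_new)
    }
  }
  projection_image(vals, c(target, target), image$view, image$kind)
}
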