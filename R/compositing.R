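#' Map HU values to 8-bit display levels
#'
#' Standard clamped linear CT windowing: values at or below
#' `center - width/2` map to 0, values at or above `center + width/2` map to
#' 255, and the mapping is linear in between. Results are rounded half-up to
#' integers. The defaults (center 500, width 1000) are the window applied to
#' the blended gray background of the overview image; this relatively hard
#' window keeps bone bright while leaving soft tissue as a faint context.
#'
#' @param values Numeric vector/matrix of HU values.
#' @param center_hu,width_hu Window centre and width in HU; width must be
#'   positive.
#' @return Integer display levels in `[0, 255]`, same shape as `values`.
#' @examples
#' apply_window(c(0, 500, 1000))   # 0, 128, 255
#' @export
apply_window <- function(values, center_hu = 500, width_hu = 1000) {
  if (!is.finite(width_hu) || width_hu <= 0)
    stop("`width_hu` must be > 0", call. = FALSE)
  p <- (values - (center_hu - width_hu / 2)) / width_hu
  p <- pmin(pmax(p, 0), 1)
  out <- as.integer(round_half_up(p * 255))
  if (is.matrix(values)) dim(out) <- dim(values)
  out
}

#' Composite overview image
#'
#' A 2D 8-bit RGB image, the final product of the pipeline. Every pixel is
#' one of exactly three classes: gray (`r == g == b`, windowed blend of MIP
#' and average projection), pure red `(255, 0, 0)` for radiopaque material,
#' or pure blue `(0, 0, 255)` for intracorporeal gas.
#'
#' @param pixels Integer array `rows x cols x 3` with values in `[0, 255]`.
#' @param pixel_spacing Numeric length-2, mm per (row, column).
#' @param view `"anterior_posterior"` or `"lateral"`.
#' @return An object of class `composite_image`.
#' @export
composite_image <- function(pixels, pixel_spacing, view) {
  view <- match.arg(view, c("anterior_posterior", "lateral"))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a rows x cols x 3 array", call. = FALSE)
  if (any(pixels < 0L) || any(pixels > 255L))
    stop("channel values must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, pixel_spacing = as.double(pixel_spacing), view = view),
    class = "composite_image"
  )
}

#' @export
print.composite_image <- function(x, ...) {
  r <- x$pixels[, , 1]; g <- x$pixels[, , 2]; b <- x$pixels[, , 3]
  n_red <- sum(r == 255L & g == 0L & b == 0L)
  n_blue <- sum(r == 0L & g == 0L & b == 255L)
  cat(sprintf("<composite_image> %s, %d x %d px, %d red px, %d blue px\n",
              x$view, nrow(r), ncol(r), n_red, n_blue))
  invisible(x)
}

#' Combine the three projections into the color-coded overview
#'
#' Applies the three per-pixel rules, in order:
#'
#' 1. the gray level is the display-windowed blend
#'    `mip_weight * MIP + avg_weight * average` (blended in HU, then
#'    windowed once with the configured display window);
#' 2. if the MIP value is *strictly above* `red_threshold_hu`, the pixel
#'    becomes pure red — radiopaque foreign material;
#' 3. if the selective-minIP value is *strictly below* `blue_threshold_hu`,
#'    the pixel becomes pure blue — intracorporeal gas.
#'
#' Rules are applied sequentially, so blue overrides red in the rare case
#' that a ray holds both metal and gas. Threshold values themselves never
#' trigger a color (strict inequalities).
#'
#' @param mip_img,minip_img,avg_img [projection_image()]s sharing shape,
#'   spacing and view (kinds `"mip"`, `"minip"`, `"average"`).
#' @param config A [pmct_config()].
#' @return A [composite_image()].
#' @export
composite_overview <- function(mip_img, minip_img, avg_img,
                               config = pmct_config()) {
  validate_pmct_config(config)
  imgs <- list(mip_img, minip_img, avg_img)
  for (im in imgs)
    if (!inherits(im, "projection_image"))
      stop("all inputs must be `projection_image`s", call. = FALSE)
  dims <- lapply(imgs, function(im) dim(im$values))
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]]))
    stop("projection images differ in shape", call. = FALSE)
  views <- vapply(imgs, function(im) im$view, character(1))
  if (length(unique(views)) != 1L)
    stop("projection images differ in view", call. = FALSE)
  mip <- mip_img$values
  minip <- minip_img$values
  avg <- avg_img$values

  blend_hu <- config$mip_weight * mip + config$avg_weight * avg
  g <- apply_window(blend_hu, config$window_center_hu, config$window_width_hu)
  px <- array(0L, c(dim(g), 3L))
  px[, , 1] <- g; px[, , 2] <- g; px[, , 3] <- g

  red <- mip > config$red_threshold_hu
  blue <- minip < config$blue_threshold_hu
  ch <- function(m, r, b, red_val, blue_val) { m[r] <- red_val; m[b] <- blue_val; m }
  px[, , 1] <- ch(px[, , 1], red, blue, 255L, 0L)
  px[, , 2] <- ch(px[, , 2], red, blue, 0L, 0L)
  px[, , 3] <- ch(px[, , 3], red, blue, 0L, 255L)

  composite_image(px, mip_img$pixel_spacing, views[1])
}
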