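#' Write a composite image as PNG
#'
#' Exports the final overview as an 8-bit RGB PNG (no alpha). The encoding
#' is lossless: re-reading the file yields bit-identical channel values.
#'
#' @param image A [composite_image()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_png_image <- function(image, path) {
  if (!inherits(image, "composite_image"))
    stop("expected a `composite_image`", call. = FALSE)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Read an RGB PNG back as 8-bit channel values
#'
#' Inverse of [write_png_image()]; used for round-trip verification and by
#' tests. Gray/paletted PNGs are expanded to RGB.
#'
#' @param path PNG file path.
#' @return Integer array `rows x cols x 3` in `[0, 255]`.
#' @export
read_png_image <- function(path) {
  if (!file.exists(path))
    stop("PNG file not found: ", path, call. = FALSE)
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 2L)
    raw <- array(rep(raw, 3), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  px <- as.integer(round_half_up(raw * 255))
  dim(px) <- dim(raw)
  px
}
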