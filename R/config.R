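#' Algorithm configuration
#'
#' Collects every tunable constant of the overview-image algorithm, with the
#' published values as defaults:
#'
#' * `air_threshold_hu` (-200): voxels at or below this HU are candidate
#'   "air" for the exterior region growing ("-200 or less").
#' * `red_threshold_hu` (+2800): a pixel whose MIP value is strictly above
#'   this is painted pure red (radiopaque foreign material).
#' * `blue_threshold_hu` (-220): a pixel whose selective-minIP value is
#'   strictly below this is painted pure blue (intracorporeal gas).
#' * `mip_weight` / `avg_weight` (0.7 / 0.3): linear blend of the MIP and
#'   average projections that forms the gray background; must sum to 1.
#' * `window_center_hu` / `window_width_hu` (500 / 1000): display window
#'   mapping the blended HU value to 8-bit gray levels.
#' * `table_seeds_enabled` (TRUE): whether to search for the hollow,
#'   air-filled interior of the scanner table and seed it as exterior air.
#' * `connectivity` ("face"): neighbourhood used by region growing; "face"
#'   is 6-connectivity, "face+edge+corner" is 26-connectivity. Face
#'   connectivity is the conservative default: it cannot leak through
#'   diagonal single-voxel gaps in the body surface.
#' * `table_shell_max_mm` (25): maximum thickness of an above-threshold run
#'   that the table-seed scans accept as a table shell. The scanner table
#'   shell is a few millimetres of plastic/carbon; the body wall is much
#'   thicker, so this bound stops the scans from ever seeding through the
#'   body surface into enclosed gas.
#'
#' @param air_threshold_hu,red_threshold_hu,blue_threshold_hu Thresholds in HU.
#' @param mip_weight,avg_weight Blend weights, must sum to 1.
#' @param window_center_hu,window_width_hu Display window (HU); width > 0.
#' @param table_seeds_enabled Logical.
#' @param connectivity `"face"` or `"face+edge+corner"`.
#' @param table_shell_max_mm Maximum accepted table-shell thickness (mm).
#' @return An object of class `pmct_config` (a validated list).
#' @examples
#' cfg <- pmct_config()
#' cfg$red_threshold_hu
#' @export
pmct_config <- function(air_threshold_hu = -200,
                        red_threshold_hu = 2800,
                        blue_threshold_hu = -220,
                        mip_weight = 0.7,
                        avg_weight = 0.3,
                        window_center_hu = 500,
                        window_width_hu = 1000,
                        table_seeds_enabled = TRUE,
                        connectivity = c("face", "face+edge+corner"),
                        table_shell_max_mm = 25) {
  connectivity <- match.arg(connectivity)
  cfg <- list(
    air_threshold_hu = as.double(air_threshold_hu),
    red_threshold_hu = as.double(red_threshold_hu),
    blue_threshold_hu = as.double(blue_threshold_hu),
    mip_weight = as.double(mip_weight),
    avg_weight = as.double(avg_weight),
    window_center_hu = as.double(window_center_hu),
    window_width_hu = as.double(window_width_hu),
    table_seeds_enabled = isTRUE(table_seeds_enabled),
    connectivity = connectivity,
    table_shell_max_mm = as.double(table_shell_max_mm)
  )
  validate_pmct_config(structure(cfg, class = "pmct_config"))
}

validate_pmct_config <- function(cfg) {
  if (!inherits(cfg, "pmct_config"))
    stop("expected a `pmct_config` object", call. = FALSE)
  if (abs(cfg$mip_weight + cfg$avg_weight - 1) > 1e-9)
    stop("`mip_weight` and `avg_weight` must sum to 1", call. = FALSE)
  if (!is.finite(cfg$window_width_hu) || cfg$window_width_hu <= 0)
    stop("`window_width_hu` must be > 0", call. = FALSE)
  if (!(cfg$blue_threshold_hu < 0 && cfg$red_threshold_hu > 0))
    stop("`blue_threshold_hu` must be negative and `red_threshold_hu` positive",
         call. = FALSE)
  if (!is.finite(cfg$table_shell_max_mm) || cfg$table_shell_max_mm <= 0)
    stop("`table_shell_max_mm` must be > 0", call. = FALSE)
  cfg
}

#' @export
print.pmct_config <- function(x, ...) {
  cat("<pmct_config>\n")
  cat(sprintf("  air threshold     : %g HU (exterior region growing)\n", x$air_threshold_hu))
  cat(sprintf("  red threshold     : %g HU (MIP > threshold -> red)\n", x$red_threshold_hu))
  cat(sprintf("  blue threshold    : %g HU (minIP < threshold -> blue)\n", x$blue_threshold_hu))
  cat(sprintf("  blend weights     : %g * MIP + %g * average\n", x$mip_weight, x$avg_weight))
  cat(sprintf("  display window    : center %g, width %g HU\n",
              x$window_center_hu, x$window_width_hu))
  cat(sprintf("  table seeds       : %s\n", if (x$table_seeds_enabled) "enabled" else "disabled"))
  cat(sprintf("  connectivity      : %s\n", x$connectivity))
  invisible(x)
}

#' Read a configuration file
#'
#' Parses a flat `key = value` text file (lines starting with `#` and blank
#' lines are ignored) into a [pmct_config()]. Keys are the argument names of
#' [pmct_config()]; unknown keys are an error. Values given in the file
#' override the defaults; anything not mentioned keeps its default.
#'
#' @param path Path to the configuration file.
#' @param base Configuration supplying defaults for keys absent from the
#'   file; defaults to `pmct_config()`.
#' @return A `pmct_config`.
#' @export
read_config_file <- function(path, base = pmct_config()) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed configuration line (expected `key = value`): ", ln,
           call. = FALSE)
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    overrides[[key]] <- val
  }
  allowed <- names(formals(pmct_config))
  bad <- setdiff(names(overrides), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- unclass(base)
  for (key in names(overrides)) {
    val <- overrides[[key]]
    args[[key]] <- switch(key,
      table_seeds_enabled = as.logical(val),
      connectivity = val,
      as.double(val)
    )
  }
  do.call(pmct_config, args)
}
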