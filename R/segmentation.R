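#' Corner seed points
#'
#' The eight corner voxels of the CT volume. On a thorax/abdomen scan the
#' corners always lie outside the body, so they are safe seeds for growing
#' the exterior-air region.
#'
#' @param volume A [ct_volume()].
#' @return An 8 x 3 integer matrix of 1-based voxel indices `(i, j, k)`.
#' @examples
#' vol <- ct_volume(array(-1000, dim = c(5, 7, 3)))
#' corner_seeds(vol)
#' @export
corner_seeds <- function(volume) {
  stopifnot_volume(volume)
  d <- dim(volume$voxels)
  as.matrix(expand.grid(i = c(1L, d[1]), j = c(1L, d[2]), k = c(1L, d[3]),
                        KEEP.OUT.ATTRS = FALSE))
}

#' Grow the exterior-air mask from seed points
#'
#' Seeded region growing over voxels with HU at or below
#' `config$air_threshold_hu` (default -200, inclusive). Starting from every
#' seed that itself lies on an at-or-below-threshold voxel, the region
#' expands across neighbouring below-threshold voxels under the configured
#' connectivity until it stops at the body surface. Seeds that fall on
#' above-threshold voxels are silently skipped. Gas fully enclosed by the
#' body is never reached, which is what makes the subsequent minimum
#' intensity projection "selective" for intracorporeal gas.
#'
#' The fill is breadth-first but vectorised: each iteration dilates the
#' current frontier by one voxel and intersects it with the unvisited
#' below-threshold set, so the cost is a handful of array operations per
#' graph-distance level rather than per voxel.
#'
#' @param volume A [ct_volume()].
#' @param seeds Integer matrix with 3 columns of 1-based voxel indices
#'   (rows are seeds), e.g. from [corner_seeds()] and [table_seeds()].
#' @param config A [pmct_config()].
#' @return Logical 3D array of the same shape as the volume; `TRUE` marks
#'   exterior air (and the table interior, if seeded).
#' @export
region_grow_exterior <- function(volume, seeds, config = pmct_config()) {
  stopifnot_volume(volume)
  validate_pmct_config(config)
  vox <- volume$voxels
  d <- dim(vox)
  mask <- array(FALSE, d)
  if (is.null(seeds) || NROW(seeds) == 0L) {
    warning("empty seed list: exterior-air mask is empty", call. = FALSE)
    return(mask)
  }
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  if (any(seeds < 1L) || any(seeds > matrix(d, nrow(seeds), 3, byrow = TRUE)))
    stop("seed indices out of volume bounds", call. = FALSE)
  air <- vox <= config$air_threshold_hu
  keep <- air[seeds]
  if (!any(keep)) return(mask)
  mask[seeds[keep, , drop = FALSE]] <- TRUE
  grow <- switch(config$connectivity,
                 "face" = neighbours_face,
                 "face+edge+corner" = neighbours_box)
  frontier <- mask
  repeat {
    fresh <- grow(frontier) & air & !mask
    if (!any(fresh)) break
    mask <- mask | fresh
    frontier <- fresh
  }
  mask
}

# Walk along `values`: skip a (possibly empty) leading run of at-or-below
# threshold voxels, then require a contiguous above-threshold run of at most
# `max_shell` voxels (the table shell). Return the index of the first
# below-threshold voxel after the shell, or NA if the line never crosses an
# acceptable shell.
scan_through_shell <- function(values, threshold, max_shell) {
  n <- length(values)
  i <- 1L
  while (i <= n && values[i] <= threshold) i <- i + 1L
  if (i > n) return(NA_integer_)
  run_start <- i
  while (i <= n && values[i] > threshold) i <- i + 1L
  if (i > n) return(NA_integer_)            # shell never ends on this line
  if ((i - run_start) > max_shell) return(NA_integer_)  # too thick: body, not table
  i
}

#' Seed points inside the hollow scanner table
#'
#' Many CT tables are hollow and air-filled; that air is not connected to
#' the background reachable from the volume corners, so without extra seeds
#' it would survive the exterior removal and be rendered as (false)
#' intracorporeal gas. This detector scans each axial slice for the table:
#'
#' 1. the posterior-most above-threshold structure in the slice is located
#'    and a scan line is cast anteriorly ("upward" in the image) through it:
#'    leading background air is skipped, a thin above-threshold run (the
#'    table shell, at most `config$table_shell_max_mm` thick) is crossed,
#'    and the first below-threshold voxel beyond it becomes a seed
#'    candidate;
#' 2. at the height of that candidate, the same scan is repeated inward from
#'    the left and right image borders, yielding candidates behind the
#'    table's side walls.
#'
#' A candidate is only accepted if it is *not* part of the corner-reachable
#' background: table seeds exist precisely to reach air the corners cannot,
#' so candidates in the gap between table and body (e.g. over a solid table
#' top) are discarded. Scans that never cross a shell — or only cross runs
#' thicker than a plausible table shell, such as the body wall — emit
#' nothing, so volumes without a table yield an empty seed list.
#'
#' @param volume A [ct_volume()].
#' @param config A [pmct_config()]; returns an empty seed set when
#'   `config$table_seeds_enabled` is `FALSE`.
#' @param exterior Optional precomputed corner-seeded exterior mask (logical
#'   array from [region_grow_exterior()]); computed internally when `NULL`.
#' @return Integer matrix with 3 columns of 1-based voxel indices; zero rows
#'   when no table-like structure is found.
#' @export
table_seeds <- function(volume, config = pmct_config(), exterior = NULL) {
  stopifnot_volume(volume)
  validate_pmct_config(config)
  empty <- matrix(integer(0), ncol = 3L,
                  dimnames = list(NULL, c("i", "j", "k")))
  if (!config$table_seeds_enabled) return(empty)
  vox <- volume$voxels
  d <- dim(vox)
  thr <- config$air_threshold_hu
  if (is.null(exterior))
    exterior <- region_grow_exterior(volume, corner_seeds(volume), config)
  max_shell_y <- max(1L, ceiling(config$table_shell_max_mm / volume$spacing[2]))
  max_shell_x <- max(1L, ceiling(config$table_shell_max_mm / volume$spacing[1]))
  seeds <- list()
  for (k in seq_len(d[3])) {
    slice <- vox[, , k]
    material_rows <- which(apply(slice > thr, 2, any))
    if (!length(material_rows)) next
    j_bottom <- max(material_rows)           # posterior-most structure
    cols <- which(slice[, j_bottom] > thr)
    i0 <- cols[ceiling(length(cols) / 2)]
    # posterior-to-anterior scan through the table bottom
    line <- slice[i0, d[2]:1]
    hit <- scan_through_shell(line, thr, max_shell_y)
    if (is.na(hit)) next
    jc <- d[2] - hit + 1L
    cand <- rbind(c(i0, jc, k))
    # left and right scans at the cavity's height
    row <- slice[, jc]
    hl <- scan_through_shell(row, thr, max_shell_x)
    if (!is.na(hl)) cand <- rbind(cand, c(hl, jc, k))
    hr <- scan_through_shell(rev(row), thr, max_shell_x)
    if (!is.na(hr)) cand <- rbind(cand, c(d[1] - hr + 1L, jc, k))
    keep <- !exterior[cand]
    if (any(keep)) seeds[[length(seeds) + 1L]] <- cand[keep, , drop = FALSE]
  }
  if (!length(seeds)) return(empty)
  out <- unique(do.call(rbind, seeds))
  storage.mode(out) <- "integer"
  colnames(out) <- c("i", "j", "k")
  out
}
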