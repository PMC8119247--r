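#' Run the full overview pipeline
#'
#' Orchestrates the four steps of the algorithm: (1) load the CT volume
#' (DICOM series directory or NIfTI file), (2) region-grow the exterior air
#' from the eight volume corners plus, if enabled, seeds inside the hollow
#' scanner table, (3) compute MIP, selective minIP and average projections
#' for each requested view and resample them to square pixels, (4)
#' composite and export one color-coded PNG per view, named
#' `<stem>_<view>.png`.
#'
#' The exterior mask is computed once and shared by all views. Two runs on
#' the same input with the same configuration produce bit-identical PNGs:
#' the pipeline contains no randomness.
#'
#' @param input_path Path to a DICOM series directory or a `.nii`/`.nii.gz`
#'   file; alternatively a [ct_volume()] may be passed directly.
#' @param output_dir Directory for the PNGs (created if missing).
#' @param config A [pmct_config()].
#' @param views Character subset of `c("anterior_posterior", "lateral")`.
#' @param resample Resample projections to isotropic pixels before
#'   compositing (default `TRUE`; identity for isotropic volumes).
#' @param save_mask Also write the exterior-air mask as a NIfTI label
#'   volume `<stem>_exterior_mask.nii.gz`.
#' @param save_projections Also write each projection as a NIfTI image
#'   `<stem>_<view>_<kind>.nii.gz` for debugging.
#' @param stem Output file stem; defaults to the input file/directory name.
#' @param quiet Suppress progress messages (they go to standard error).
#' @return A `pmct_run_report`: list with `input_path`, `views_rendered`,
#'   `seed_counts` (corner, table), `mask_voxel_count`, `output_files` and
#'   `elapsed` seconds.
#' @export
run_pipeline <- function(input_path, output_dir,
                         config = pmct_config(),
                         views = c("anterior_posterior", "lateral"),
                         resample = TRUE,
                         save_mask = FALSE,
                         save_projections = FALSE,
                         stem = NULL,
                         quiet = FALSE) {
  t0 <- Sys.time()
  validate_pmct_config(config)
  bad <- setdiff(views, c("anterior_posterior", "lateral"))
  if (length(bad) || !length(views))
    stop("unknown view name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  views <- unique(views)
  say <- function(...) if (!quiet) message("[pmctviz] ", sprintf(...))

  if (is_ct_volume(input_path)) {
    volume <- input_path
    input_label <- "<in-memory volume>"
    if (is.null(stem)) stem <- "volume"
  } else {
    input_label <- input_path
    if (dir.exists(input_path)) {
      say("loading DICOM series from %s", input_path)
      volume <- read_dicom_series(input_path)
    } else if (file.exists(input_path)) {
      say("loading NIfTI volume %s", input_path)
      volume <- read_nifti_volume(input_path)
    } else {
      stop("input not found: ", input_path, call. = FALSE)
    }
    if (is.null(stem))
      stem <- sub("\\.nii(\\.gz)?$", "", basename(input_path))
  }
  d <- dim(volume$voxels)
  say("volume %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm",
      d[1], d[2], d[3],
      volume$spacing[1], volume$spacing[2], volume$spacing[3])

  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)

  corners <- corner_seeds(volume)
  mask <- region_grow_exterior(volume, corners, config)
  n_table <- 0L
  if (config$table_seeds_enabled) {
    tseeds <- table_seeds(volume, config, exterior = mask)
    n_table <- nrow(tseeds)
    if (n_table > 0L)
      mask <- mask | region_grow_exterior(volume, tseeds, config)
  }
  say("exterior air: %d voxels (%d corner seeds, %d table seeds)",
      sum(mask), nrow(corners), n_table)
  if (save_mask)
    write_nifti_volume(array(as.integer(mask), d),
                       file.path(output_dir,
                                 paste0(stem, "_exterior_mask.nii.gz")),
                       like = volume)

  outputs <- character(0)
  for (view in views) {
    mip_img <- project_mip(volume, view)
    minip_img <- project_minip_selective(volume, mask, view)
    avg_img <- project_average(volume, view)
    if (resample) {
      mip_img <- resample_isotropic(mip_img)
      minip_img <- resample_isotropic(minip_img)
      avg_img <- resample_isotropic(avg_img)
    }
    if (save_projections) {
      for (im in list(mip_img, minip_img, avg_img)) {
        proj_path <- file.path(output_dir,
                               sprintf("%s_%s_%s.nii.gz", stem, view, im$kind))
        nim <- RNifti::asNifti(im$values)
        RNifti::pixdim(nim) <- im$pixel_spacing
        RNifti::writeNifti(nim, proj_path)
      }
    }
    overview <- composite_overview(mip_img, minip_img, avg_img, config)
    path <- file.path(output_dir, sprintf("%s_%s.png", stem, view))
    write_png_image(overview, path)
    say("wrote %s (%d x %d px)", path,
        nrow(overview$pixels), ncol(overview$pixels))
    outputs <- c(outputs, path)
  }

  structure(
    list(
      input_path = input_label,
      views_rendered = views,
      seed_counts = c(corner = nrow(corners), table = n_table),
      mask_voxel_count = sum(mask),
      output_files = outputs,
      elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "pmct_run_report"
  )
}

#' @export
print.pmct_run_report <- function(x, ...) {
  cat("<pmct_run_report>\n")
  cat("  input            :", x$input_path, "\n")
  cat("  views rendered   :", paste(x$views_rendered, collapse = ", "), "\n")
  cat(sprintf("  seeds            : %d corner, %d table\n",
              x$seed_counts[["corner"]], x$seed_counts[["table"]]))
  cat(sprintf("  exterior voxels  : %d\n", x$mask_voxel_count))
  cat("  outputs          :", paste(x$output_files, collapse = ", "), "\n")
  cat(sprintf("  elapsed          : %.2f s\n", x$elapsed))
  invisible(x)
}
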