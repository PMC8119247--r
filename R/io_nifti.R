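# Canonical frame: x left->right, y anterior->posterior, z inferior->superior.
# In RNifti's RAS-based orientation strings that is "RPS"; relative to RAS
# world coordinates the canonical y axis is flipped.

#' Read a NIfTI volume
#'
#' Loads a 3D NIfTI file and reorients it into the canonical axis convention
#' of [ct_volume()] (x: left-right, y: anterior-posterior, z:
#' inferior-superior) using the file's qform/sform, so that volumes stored
#' z-first, flipped, etc. all come out identically oriented. Voxel values
#' are taken as Hounsfield units (NIfTI carries no modality rescale beyond
#' its own scl slope/intercept, which the reader applies).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path))
    stop("NIfTI file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3D volume, got ", nd, " dimensions", call. = FALSE)
  RNifti::orientation(img) <- "RPS"
  spacing <- RNifti::pixdim(img)[1:3]
  world1 <- RNifti::voxelToWorld(c(1, 1, 1), img)   # RAS mm of voxel [1,1,1]
  origin <- c(world1[1], -world1[2], world1[3])
  ct_volume(array(as.double(img), dim(img)), spacing = spacing,
            origin = origin)
}

#' Write a CT volume to NIfTI
#'
#' Stores the canonical volume with a diagonal qform encoding the canonical
#' orientation and spacing, so [read_nifti_volume()] round-trips exactly.
#' Mainly used to export phantoms and debug masks.
#'
#' @param volume A [ct_volume()], or a logical mask array paired with
#'   `like` supplying geometry.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param like When `volume` is a plain array (e.g. a mask), a [ct_volume()]
#'   providing spacing and origin.
#' @return The path, invisibly.
#' @export
write_nifti_volume <- function(volume, path, like = NULL) {
  if (!is_ct_volume(volume)) {
    if (is.null(like))
      stop("writing a plain array requires `like` for geometry", call. = FALSE)
    arr <- volume
    storage.mode(arr) <- "double"
    volume <- ct_volume(arr, spacing = like$spacing, origin = like$origin)
  }
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  s <- volume$spacing
  o <- volume$origin
  aff <- rbind(c(s[1], 0, 0, o[1]),
               c(0, -s[2], 0, -o[2]),
               c(0, 0, s[3], o[3]),
               c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
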