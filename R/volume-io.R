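#' Construct a brain volume
#'
#' A light container for a 3D scalar grid with the package's fixed
#' anatomical axis convention: axis 1 runs left-right (sagittal index),
#' axis 2 anterior-posterior (coronal index) and axis 3 inferior-superior
#' (axial index). On a 256 x 256 x 208 grid this makes axial projections
#' 256 x 256 and sagittal/coronal projections 256 x 208.
#'
#' @param data numeric 3D array.
#' @param subject_id subject label (optional).
#' @param age age in years (optional at this layer).
#' @return an object of class `brain_volume`.
#' @export
brain_volume <- function(data, subject_id = NA_character_, age = NA_integer_) {
  if (length(dim(data)) != 3L)
    stop("brain_volume needs a 3D array, got ", length(dim(data)), "D")
  if (any(!is.finite(data))) stop("volume contains NaN/Inf values")
  structure(list(data = data, shape = dim(data),
                 subject_id = subject_id, age = age),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("brain_volume", paste(x$shape, collapse = "x"),
      if (!is.na(x$subject_id)) paste0("(", x$subject_id,
                                       if (!is.na(x$age)) paste0(", age ", x$age), ")"),
      "\n")
  invisible(x)
}

#' Read a 3D volume from a NIfTI file
#'
#' The image is reoriented to the package's canonical axis convention
#' (left-right, anterior-posterior, inferior-superior; i.e. RAS axis order)
#' using the orientation stored in the NIfTI header, and cast to double.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param subject_id,age optional metadata attached to the result.
#' @return a [brain_volume()].
#' @export
load_volume <- function(path, subject_id = NA_character_, age = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3D single-channel image, got a ", nd, "D image: ", path)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (!is.null(orient) && nzchar(orient) && orient != "RAS")
    RNifti::orientation(img) <- "RAS"
  arr <- array(as.double(img), dim = dim(img))
  if (any(!is.finite(arr))) stop("volume contains NaN/Inf values: ", path)
  brain_volume(arr, subject_id = subject_id, age = age)
}

#' Write a brain volume as NIfTI
#'
#' @param vol a [brain_volume()].
#' @param path destination (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "brain_volume"))
  RNifti::writeNifti(RNifti::asNifti(vol$data), path, datatype = "float")
  invisible(path)
}

#' Common grid specification
#'
#' @param target_shape integer vector of 3 voxel counts; the grid every
#'   volume is zero-padded to. Default 256 x 256 x 208, the full-scale
#'   acquisition grid.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(target_shape = c(256L, 256L, 208L)) {
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L, all(target_shape >= 1L))
  structure(list(target_shape = target_shape), class = "grid_spec")
}

#' Symmetrically zero-pad a volume to a common grid
#'
#' The original data is centred; padding voxels are exactly zero. When a
#' margin is odd the extra voxel goes to the high-index side, so outputs
#' are reproducible.
#'
#' @param vol a [brain_volume()].
#' @param grid a [grid_spec()] (or integer vector of 3).
#' @return a [brain_volume()] with shape `grid$target_shape`.
#' @export
pad_to_grid <- function(vol, grid) {
  stopifnot(inherits(vol, "brain_volume"))
  if (!inherits(grid, "grid_spec")) grid <- grid_spec(grid)
  target <- grid$target_shape
  if (any(vol$shape > target))
    stop("volume of shape ", paste(vol$shape, collapse = "x"),
         " exceeds the target grid ", paste(target, collapse = "x"))
  if (all(vol$shape == target)) return(vol)
  lo <- (target - vol$shape) %/% 2L      # low-index margin; extra voxel high side
  out <- array(0, dim = target)
  out[lo[1] + seq_len(vol$shape[1]),
      lo[2] + seq_len(vol$shape[2]),
      lo[3] + seq_len(vol$shape[3])] <- vol$data
  brain_volume(out, subject_id = vol$subject_id, age = vol$age)
}
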