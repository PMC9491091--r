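#' 4D dynamic PET image
#'
#' Couples a 4D activity array (x, y, z, frame; arbitrary activity units,
#' frame-averaged) with its frame schedule and a voxel-to-world RAS affine
#' in mm. Negative activities are clipped to zero (reconstruction
#' artifacts), with a message stating how many voxels were affected.
#'
#' @param data 4D numeric array; 4th dimension must match the schedule.
#' @param schedule a [frame_schedule()].
#' @param affine 4x4 invertible voxel-to-world matrix (RAS, mm).
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule, affine = diag(4)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(dim(data)) != 4)
    stop("expected 4D activity array, got ", length(dim(data)), "D")
  if (dim(data)[4] != schedule$n_frames)
    stop("frame-count mismatch: image has ", dim(data)[4],
         " frames, schedule has ", schedule$n_frames)
  check_affine(affine)
  nneg <- sum(data < 0)
  if (nneg > 0) {
    message("clipped ", nneg, " negative voxel values to 0")
    data[data < 0] <- 0
  }
  structure(list(data = data, schedule = schedule, affine = affine),
            class = "dynamic_image")
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("affine is not invertible")
  invisible(affine)
}

# All volumes in one analysis must live on one grid; registration is out of
# scope, so a mismatch is an error, not something to resample away.
check_same_grid <- function(dim_a, affine_a, dim_b, affine_b, what = "volumes") {
  if (!all(dim_a[1:3] == dim_b[1:3]))
    stop(what, " have different grids: ",
         paste(dim_a[1:3], collapse = "x"), " vs ",
         paste(dim_b[1:3], collapse = "x"))
  if (max(abs(affine_a - affine_b)) > 1e-4)
    stop(what, " have different affines")
  invisible(TRUE)
}

# build an RNifti image carrying the affine (sform+qform, code 2)
as_nifti_with_affine <- function(arr, affine) {
  img <- RNifti::asNifti(arr)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(spacing, rep(1, max(0, nd - 3)))
  RNifti::`sform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(affine, code = 2L)) -> img
  img
}

#' Read a dynamic PET image with its timing sidecar
#'
#' @param image_path NIfTI-1 4D image (.nii or .nii.gz).
#' @param timing_path JSON frame-timing sidecar (see
#'   [read_frame_schedule()]).
#' @return A [dynamic_image()].
#' @export
read_dynamic_image <- function(image_path, timing_path) {
  schedule <- read_frame_schedule(timing_path)
  img <- RNifti::readNifti(image_path)
  d <- dim(img)
  if (length(d) != 4)
    stop("expected 4D image, got ", length(d), "D: ", image_path)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  dynamic_image(array(as.numeric(img), dim = d), schedule, affine)
}

#' Write a dynamic PET image and its timing sidecar
#'
#' @param image a [dynamic_image()].
#' @param image_path output NIfTI path (.nii.gz recommended).
#' @param timing_path output JSON sidecar path.
#' @return `image_path`, invisibly.
#' @export
write_dynamic_image <- function(image, image_path, timing_path) {
  stopifnot(inherits(image, "dynamic_image"))
  nii <- as_nifti_with_affine(image$data, image$affine)
  RNifti::writeNifti(nii, image_path, datatype = "float")
  write_frame_schedule(image$schedule, timing_path)
  invisible(image_path)
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic PET image: %dx%dx%d voxels, %d frames (%.1f min)\n",
              d[1], d[2], d[3], d[4], x$schedule$total_duration / 60))
  invisible(x)
}

#' Extract the mean time-activity curve over a voxel mask
#'
#' @param image a [dynamic_image()].
#' @param mask 3D logical array on the image grid.
#' @return A [tac()] (frame-averaged activity per frame).
#' @export
mask_tac <- function(image, mask) {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$data)
  if (!all(dim(mask) == d[1:3])) stop("mask grid does not match image")
  if (!any(mask)) stop("empty mask")
  flat <- matrix(image$data, nrow = prod(d[1:3]), ncol = d[4])
  tac(colMeans(flat[as.vector(mask), , drop = FALSE]), image$schedule)
}
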