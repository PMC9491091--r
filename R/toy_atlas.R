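#' Build a deterministic toy label atlas
#'
#' A synthetic, purely geometric stand-in for an anatomical parcellation,
#' hosting the five reserved roles on one grid: a cerebellar-gray reference
#' slab at the bottom of the volume, a cortical gray-matter shell wrapped
#' around a white-matter core, a subcortical block inside the core, and a
#' choroid-plexus block inside the subcortical territory. Regions are
#' axis-aligned blocks scaled proportionally with the grid, pairwise
#' disjoint, and each holds at least 30 voxels from 16^3 upward (the
#' choroid plexus holds >= 200 voxels at 32^3, enough for stable ROI
#' means). The construction is deterministic: the same shape always yields
#' the same volume.
#'
#' @param shape integer vector of 3 grid sizes, each >= 16.
#' @param voxel_mm isotropic voxel size in mm (default 2, giving the affine).
#' @return A [label_atlas()] with labels 1 = cerebellar gray (reference),
#'   2 = cortical gray, 3 = white matter, 4 = subcortical, 5 = choroid
#'   plexus.
#' @examples
#' atlas <- make_toy_atlas(c(16, 16, 16))
#' table(atlas$labels)
#' @export
make_toy_atlas <- function(shape = c(32, 32, 32), voxel_mm = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop("toy atlas needs a grid of at least 16 voxels per axis")
  lab <- array(0L, dim = shape)
  # block coordinates defined on a 32-reference grid, rescaled to shape
  sc <- function(i, n) pmax(1L, pmin(n, as.integer(round(i / 32 * n))))
  blk <- function(x, y, z) {
    list(x = sc(x[1], shape[1]):sc(x[2], shape[1]),
         y = sc(y[1], shape[2]):sc(y[2], shape[2]),
         z = sc(z[1], shape[3]):sc(z[2], shape[3]))
  }
  assign_blk <- function(lab, b, value) {
    lab[b$x, b$y, b$z] <- value
    lab
  }
  lab <- assign_blk(lab, blk(c(8, 25), c(8, 25), c(2, 7)), 1L)    # cerebellum
  lab <- assign_blk(lab, blk(c(6, 27), c(6, 27), c(10, 29)), 2L)  # gray shell
  lab <- assign_blk(lab, blk(c(10, 23), c(10, 23), c(13, 26)), 3L) # white core
  lab <- assign_blk(lab, blk(c(13, 20), c(13, 20), c(15, 22)), 4L) # subcortical
  lab <- assign_blk(lab, blk(c(14, 19), c(14, 19), c(16, 21)), 5L) # choroid plexus
  counts <- tabulate(lab, nbins = 5)
  if (any(counts < 30))
    stop("grid too small to host all regions (a region has < 30 voxels)")
  dict <- data.frame(
    id = 1:5,
    name = c("cerebellar_gray", "cortical_gray", "white_matter",
             "subcortical", "choroid_plexus"),
    role = c("reference_region", "gray_matter_mask", "white_matter_mask",
             "subcortical_mask", "choroid_plexus"),
    stringsAsFactors = FALSE)
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- -voxel_mm * shape / 2
  label_atlas(lab, dict, affine)
}
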