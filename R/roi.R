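#' Per-label ROI statistics from a DVR map
#'
#' Means and SDs of DVR over every dictionary label (background excluded).
#' Undefined (`NaN`) voxels are excluded from the statistics; a label with
#' no defined voxel gets a missing mean. Volume labels absent from the
#' dictionary are ignored (the atlas constructor already warned about
#' them).
#'
#' @param map a [dvr_map()].
#' @param atlas a [label_atlas()] on the same grid.
#' @return A data.frame: `label`, `name`, `role`, `n_voxels`, `n_defined`,
#'   `mean_dvr`, `sd_dvr`.
#' @export
roi_means <- function(map, atlas) {
  stopifnot(inherits(map, "dvr_map"), inherits(atlas, "label_atlas"))
  check_same_grid(dim(map$data), map$affine, dim(atlas$labels), atlas$affine,
                  "map and atlas")
  dict <- atlas$dictionary[atlas$dictionary$id != 0, , drop = FALSE]
  labv <- as.vector(atlas$labels)
  vals <- as.vector(map$data)
  out <- lapply(seq_len(nrow(dict)), function(i) {
    idx <- which(labv == dict$id[i])
    v <- vals[idx]
    v <- v[is.finite(v)]
    data.frame(label = dict$id[i], name = dict$name[i], role = dict$role[i],
               n_voxels = length(idx), n_defined = length(v),
               mean_dvr = if (length(v)) mean(v) else NA_real_,
               sd_dvr = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Atlas label with the highest overlap with a significance mask
#'
#' Counts, per non-background atlas label, how many significant voxels fall
#' inside it, and returns the label with the largest count. Overlap is a
#' plain voxel count (not normalized by region size). Ties are broken by
#' the smallest label id, with a warning.
#'
#' @param sig_mask 3D logical array of significant voxels.
#' @param atlas a [label_atlas()] on the same grid.
#' @return A list: `label` (id), `name`, `overlap` (data.frame of per-label
#'   counts, decreasing).
#' @export
highest_overlap_label <- function(sig_mask, atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (!all(dim(sig_mask) == dim(atlas$labels)))
    stop("mask and atlas grids differ")
  if (!any(sig_mask)) stop("empty significance mask")
  hits <- atlas$labels[sig_mask]
  hits <- hits[hits != 0]
  if (length(hits) == 0)
    stop("significance mask overlaps no labelled voxel")
  counts <- table(hits)
  dict <- atlas$dictionary
  overlap <- data.frame(label = as.integer(names(counts)),
                        n_overlap = as.integer(counts),
                        stringsAsFactors = FALSE)
  overlap$name <- dict$name[match(overlap$label, dict$id)]
  overlap <- overlap[order(-overlap$n_overlap, overlap$label), , drop = FALSE]
  rownames(overlap) <- NULL
  top <- overlap$n_overlap == overlap$n_overlap[1]
  if (sum(top) > 1)
    warning("overlap tie between labels ",
            paste(overlap$label[top], collapse = ", "),
            "; choosing the smallest id")
  list(label = overlap$label[1], name = overlap$name[1], overlap = overlap)
}
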