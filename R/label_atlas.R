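#' Reserved atlas roles
#'
#' Every analysis atlas must resolve these five roles: the reference region
#' for Logan quantification (cerebellar gray), the three tissue analysis
#' masks, and the choroid plexus.
#' @export
ATLAS_ROLES <- c("reference_region", "gray_matter_mask",
                 "white_matter_mask", "subcortical_mask", "choroid_plexus")

#' Integer label atlas
#'
#' A 3D integer label volume (0 = background) plus a dictionary mapping
#' label ids to names and, for the reserved roles, to their function in the
#' pipeline. Labels are inherently pairwise disjoint; the constructor
#' checks that each reserved role resolves to a distinct label present in
#' the volume.
#'
#' @param labels 3D integer array, 0 for background.
#' @param dictionary data.frame with columns `id`, `name`, `role`
#'   (`role` is `""`/`NA` for plain ROIs).
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, dictionary, affine = diag(4)) {
  if (length(dim(labels)) != 3)
    stop("labels must be a 3D array")
  if (any(abs(labels - round(labels)) > 0))
    stop("label volume must be integer-valued")
  storage.mode(labels) <- "integer"
  check_affine(affine)
  need <- c("id", "name", "role")
  if (!all(need %in% names(dictionary)))
    stop("label dictionary needs columns: ", paste(need, collapse = ", "))
  dictionary$id <- as.integer(dictionary$id)
  dictionary$role <- ifelse(is.na(dictionary$role), "", dictionary$role)
  if (anyDuplicated(dictionary$id))
    stop("duplicate label ids in dictionary")
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0]
  roles <- list()
  for (r in ATLAS_ROLES) {
    hit <- dictionary$id[dictionary$role == r]
    if (length(hit) != 1)
      stop("dictionary must assign role '", r, "' to exactly one label")
    if (!(hit %in% present))
      stop("role '", r, "' label ", hit, " is absent from the volume")
    roles[[r]] <- hit
  }
  if (anyDuplicated(unlist(roles)))
    stop("reserved roles must map to distinct labels")
  missing_dict <- dictionary$id[!(dictionary$id %in% present)]
  if (length(missing_dict))
    warning("dictionary label(s) absent from volume: ",
            paste(missing_dict, collapse = ", "))
  extra <- present[!(present %in% dictionary$id)]
  if (length(extra))
    warning("volume label(s) not in dictionary (ignored in ROI tables): ",
            paste(extra, collapse = ", "))
  structure(list(labels = labels, dictionary = dictionary,
                 roles = roles, affine = affine),
            class = "label_atlas")
}

#' Read a label atlas from NIfTI + TSV dictionary
#'
#' @param labels_path NIfTI-1 integer label volume.
#' @param dictionary_path TSV with columns `id`, `name`, `role`.
#' @return A [label_atlas()].
#' @export
read_label_atlas <- function(labels_path, dictionary_path) {
  img <- RNifti::readNifti(labels_path)
  d <- dim(img)
  if (length(d) != 3) stop("expected 3D label volume, got ", length(d), "D")
  vals <- array(as.numeric(img), dim = d)
  if (any(abs(vals - round(vals)) > 1e-6))
    stop("label volume is not integer-valued: ", labels_path)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  dict <- utils::read.delim(dictionary_path, stringsAsFactors = FALSE,
                            colClasses = c(role = "character"))
  label_atlas(round(vals), dict, affine)
}

#' Write a label atlas to NIfTI + TSV dictionary
#'
#' @param atlas a [label_atlas()].
#' @param labels_path output NIfTI path.
#' @param dictionary_path output TSV path.
#' @return `labels_path`, invisibly.
#' @export
write_label_atlas <- function(atlas, labels_path, dictionary_path) {
  stopifnot(inherits(atlas, "label_atlas"))
  nii <- as_nifti_with_affine(atlas$labels, atlas$affine)
  RNifti::writeNifti(nii, labels_path, datatype = "int16")
  utils::write.table(atlas$dictionary, dictionary_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(labels_path)
}

#' Logical mask for an atlas role or label
#'
#' `role_mask()` returns the voxels of one reserved role's label.
#' `tissue_mask()` returns the analysis mask for the three voxelwise
#' comparisons; for `"subcortical"` this is the union of the subcortical
#' label and the choroid plexus, which sits anatomically inside the
#' subcortical territory but carries its own label.
#'
#' @param atlas a [label_atlas()].
#' @param role one of [ATLAS_ROLES].
#' @return 3D logical array.
#' @export
role_mask <- function(atlas, role) {
  stopifnot(inherits(atlas, "label_atlas"))
  role <- match.arg(role, ATLAS_ROLES)
  atlas$labels == atlas$roles[[role]]
}

#' @rdname role_mask
#' @param tissue one of `"gray"`, `"white"`, `"subcortical"`.
#' @export
tissue_mask <- function(atlas, tissue = c("gray", "white", "subcortical")) {
  tissue <- match.arg(tissue)
  switch(tissue,
    gray = role_mask(atlas, "gray_matter_mask"),
    white = role_mask(atlas, "white_matter_mask"),
    subcortical = role_mask(atlas, "subcortical_mask") |
                  role_mask(atlas, "choroid_plexus"))
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("Label atlas: %s grid, %d labels\n",
              paste(dim(x$labels), collapse = "x"),
              sum(x$dictionary$id != 0)))
  for (r in ATLAS_ROLES)
    cat(sprintf("  %-18s -> label %d (%s), %d voxels\n", r, x$roles[[r]],
                x$dictionary$name[x$dictionary$id == x$roles[[r]]],
                sum(x$labels == x$roles[[r]])))
  invisible(x)
}
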