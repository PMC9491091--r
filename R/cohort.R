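#' Cohort groups and assessment battery
#'
#' The four study groups (cognitively healthy, delirium, dementia, delirium
#' superimposed on dementia) and the nine clinical/cognitive assessments
#' regressed against ROI DVR.
#' @export
COHORT_GROUPS <- c("CH", "DELIRIUM", "DEMENTIA", "DSD")

#' @rdname COHORT_GROUPS
#' @export
ASSESSMENTS <- c("CAM", "MoCA_execution", "MoCA_attention", "MoCA_memory",
                 "MoCA_language", "MoCA_orientation", "IQCODE_SF", "GDS",
                 "NPI")

#' Read a cohort table
#'
#' Reads a TSV with one row per subject: `subject_id`, `group` (one of
#' CH/DELIRIUM/DEMENTIA/DSD), the nine assessment scores (missing values
#' allowed), and the QC flags `movement_artifact` and `technical_issue`
#' (0/1). QC-excluded subjects are retained in the table but flagged;
#' [qc_pass()] gives the analyzable subset.
#'
#' @param path TSV path.
#' @return A `data.frame` of class `pet_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("cohort file is empty: ", path)
  validate_cohort(df)
}

validate_cohort <- function(df) {
  need <- c("subject_id", "group", ASSESSMENTS,
            "movement_artifact", "technical_issue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop("duplicate subject id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(df$group)) stop("missing group label(s)")
  bad <- setdiff(unique(df$group), COHORT_GROUPS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(COHORT_GROUPS, collapse = "/"), ")")
  df$movement_artifact <- as.logical(df$movement_artifact)
  df$technical_issue <- as.logical(df$technical_issue)
  class(df) <- c("pet_cohort", "data.frame")
  df
}

#' Write a cohort table
#' @param cohort a cohort `data.frame`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$movement_artifact <- as.integer(out$movement_artifact)
  out$technical_issue <- as.integer(out$technical_issue)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Which subjects pass quality control?
#'
#' A subject is analyzable when neither the movement-artifact nor the
#' technical-issue flag is set.
#'
#' @param cohort a cohort `data.frame`.
#' @return Logical vector, one element per subject.
#' @export
qc_pass <- function(cohort) {
  !(as.logical(cohort$movement_artifact) | as.logical(cohort$technical_issue))
}
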