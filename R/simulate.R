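#' Cohort simulation design
#'
#' Defines the synthetic four-group study: group sizes, the true
#' choroid-plexus DVR per group (all other labels have DVR 1 in every
#' group, mirroring the absence of gray/white-matter group differences),
#' the per-group MoCA distribution, and the noise level. The defaults are
#' the study conditions: 7 cognitively healthy + 4 delirium + 4 dementia +
#' 4 delirium-superimposed-on-dementia subjects; choroid-plexus DVR 0.856,
#' 0.601, 0.614, 0.559 respectively; MoCA mean (SD) 19.9 (4.62), 6.5
#' (4.95), 6.0 (1.73), 5.3 (2.01).
#'
#' @param n_per_group named integer vector over CH/DELIRIUM/DEMENTIA/DSD.
#' @param choroid_dvr named numeric vector of per-group true
#'   choroid-plexus DVR.
#' @param other_dvr DVR assigned to every non-choroid label in all groups.
#' @param moca_mean,moca_sd named numeric vectors of per-group MoCA
#'   moments.
#' @param noise_scale multiplier of the frame-duration-scaled noise SD
#'   (see [simulate_subject()]).
#' @param R1,k2 SRTM nuisance parameters shared by all tissues.
#' @param A,tau reference input-curve amplitude and washout (min).
#' @param seed master seed; per-subject child seeds derive from it.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(CH = 7, DELIRIUM = 4,
                                          DEMENTIA = 4, DSD = 4),
                          choroid_dvr = c(CH = 0.856, DELIRIUM = 0.601,
                                          DEMENTIA = 0.614, DSD = 0.559),
                          other_dvr = 1.0,
                          moca_mean = c(CH = 19.9, DELIRIUM = 6.5,
                                        DEMENTIA = 6.0, DSD = 5.3),
                          moca_sd = c(CH = 4.62, DELIRIUM = 4.95,
                                      DEMENTIA = 1.73, DSD = 2.01),
                          noise_scale = 0.05, R1 = 1, k2 = 0.4,
                          A = 1, tau = 15, seed = 1L) {
  for (v in list(n_per_group, choroid_dvr, moca_mean, moca_sd))
    if (!all(COHORT_GROUPS %in% names(v)))
      stop("design vectors must be named over ",
           paste(COHORT_GROUPS, collapse = "/"))
  if (any(n_per_group < 0)) stop("group sizes must be >= 0")
  if (any(choroid_dvr <= 0) || other_dvr <= 0) stop("DVRs must be positive")
  if (any(moca_sd < 0)) stop("SDs must be >= 0")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  structure(list(n_per_group = n_per_group[COHORT_GROUPS],
                 choroid_dvr = choroid_dvr[COHORT_GROUPS],
                 other_dvr = other_dvr,
                 moca_mean = moca_mean[COHORT_GROUPS],
                 moca_sd = moca_sd[COHORT_GROUPS],
                 noise_scale = noise_scale, R1 = R1, k2 = k2,
                 A = A, tau = tau, seed = as.integer(seed)),
            class = "cohort_design")
}

# deterministic child seed below 2^31, from a master seed and an index
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %%
               2147483629)
}

#' Simulate one subject's dynamic PET image
#'
#' Every voxel of a non-background atlas label gets the noiseless SRTM
#' forward TAC for that label's DVR (`BP = DVR - 1`, shared `R1`, `k2`;
#' the reference label is forced to DVR 1), plus independent zero-mean
#' Gaussian noise with per-frame standard deviation
#' `noise_scale * sqrt(max(signal, 1e-6) / frame_duration)` — a
#' Poisson-like count model where longer frames are less noisy. Background
#' voxels stay exactly zero. Reproducible: the same seed gives a
#' bit-identical image.
#'
#' @param atlas a [label_atlas()].
#' @param label_dvr named numeric vector: true DVR per atlas label
#'   (names = label names from the dictionary); every non-background label
#'   present in the volume must have an entry.
#' @param schedule a [frame_schedule()].
#' @param noise_scale noise multiplier (0 disables noise).
#' @param seed integer seed.
#' @param R1,k2 SRTM parameters shared by all labels.
#' @param A,tau reference input-curve parameters (see [reference_tac()]).
#' @return A [dynamic_image()].
#' @export
simulate_subject <- function(atlas, label_dvr, schedule, noise_scale = 0.05,
                             seed = 1L, R1 = 1, k2 = 0.4, A = 1, tau = 15) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(schedule, "frame_schedule"))
  dict <- atlas$dictionary
  present <- setdiff(sort(unique(as.vector(atlas$labels))), 0L)
  names_present <- dict$name[match(present, dict$id)]
  miss <- names_present[!(names_present %in% names(label_dvr))]
  if (length(miss))
    stop("label_dvr is missing label(s): ", paste(miss, collapse = ", "))
  dvr_by_id <- stats::setNames(label_dvr[names_present], present)
  dvr_by_id[as.character(atlas$roles$reference_region)] <- 1.0

  fine <- reference_tac_fine(schedule, A = A, tau = tau, dt = 1)
  nf <- schedule$n_frames
  # one noiseless frame-averaged TAC per distinct DVR value
  uniq <- unique(as.numeric(dvr_by_id))
  tac_by_dvr <- lapply(uniq, function(dvr)
    srtm_tac(fine, srtm_params(R1 = R1, k2 = k2, BP = dvr - 1),
             schedule)$values)
  names(tac_by_dvr) <- as.character(uniq)

  d3 <- dim(atlas$labels)
  data <- array(0, dim = c(d3, nf))
  flat <- matrix(0, nrow = prod(d3), ncol = nf)
  labv <- as.vector(atlas$labels)
  for (id in present) {
    idx <- which(labv == id)
    sig <- tac_by_dvr[[as.character(as.numeric(dvr_by_id[as.character(id)]))]]
    flat[idx, ] <- matrix(sig, nrow = length(idx), ncol = nf, byrow = TRUE)
  }
  if (noise_scale > 0) {
    set.seed(derive_seed(seed, 0L))
    brain <- which(labv > 0)
    sd_mat <- noise_scale *
      sqrt(pmax(flat[brain, , drop = FALSE], 1e-6) /
             matrix(schedule$duration, nrow = length(brain), ncol = nf,
                    byrow = TRUE))
    flat[brain, ] <- flat[brain, ] +
      stats::rnorm(length(sd_mat)) * sd_mat
  }
  suppressMessages(
    dynamic_image(array(flat, dim = c(d3, nf)), schedule, atlas$affine))
}

#' Simulate a full cohort
#'
#' Generates one dynamic image per subject under the design's group DVR
#' targets and a cohort table. The MoCA group signal is carried by the
#' `MoCA_attention` column (drawn from the design's per-group MoCA
#' moments, truncated at 0); the other eight assessments are independent
#' standard-normal placeholders with no group structure. Child seeds are
#' derived deterministically from the design's master seed, so the same
#' design reproduces the same cohort bit for bit.
#'
#' @param design a [cohort_design()].
#' @param atlas a [label_atlas()].
#' @param schedule a [frame_schedule()].
#' @param image_handler optional `function(subject_id, image)` called with
#'   each simulated image as it is produced; when supplied, images are not
#'   accumulated in memory and the `images` element of the result is
#'   `NULL`. Useful for streaming large grids through [dvr_map()] or to
#'   disk.
#' @return A list with `cohort` (data.frame) and `images` (named list of
#'   [dynamic_image()], unless a handler was given).
#' @export
simulate_cohort <- function(design, atlas, schedule, image_handler = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- rep(COHORT_GROUPS, times = design$n_per_group)
  n <- length(groups)
  ids <- sprintf("sub-%02d", seq_len(n))

  label_names <- atlas$dictionary$name
  cp_name <- atlas$dictionary$name[atlas$dictionary$id ==
                                     atlas$roles$choroid_plexus]
  images <- if (is.null(image_handler)) stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    label_dvr <- stats::setNames(rep(design$other_dvr, length(label_names)),
                                 label_names)
    label_dvr[cp_name] <- design$choroid_dvr[[groups[i]]]
    img <- simulate_subject(atlas, label_dvr, schedule,
                            noise_scale = design$noise_scale,
                            seed = derive_seed(design$seed, i),
                            R1 = design$R1, k2 = design$k2,
                            A = design$A, tau = design$tau)
    if (is.null(image_handler)) images[[i]] <- img
    else image_handler(ids[i], img)
  }

  set.seed(derive_seed(design$seed, 10000L))
  scores <- matrix(stats::rnorm(n * length(ASSESSMENTS)), nrow = n,
                   dimnames = list(NULL, ASSESSMENTS))
  scores[, "MoCA_attention"] <- pmax(0, stats::rnorm(
    n, mean = design$moca_mean[groups], sd = design$moca_sd[groups]))
  cohort <- data.frame(subject_id = ids, group = groups,
                       as.data.frame(scores),
                       movement_artifact = FALSE, technical_issue = FALSE,
                       stringsAsFactors = FALSE)
  cohort <- validate_cohort(cohort)
  list(cohort = cohort, images = if (is.null(image_handler)) images)
}
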