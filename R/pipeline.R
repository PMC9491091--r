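#' Default pipeline configuration
#'
#' Two scales are provided: `"reduced"` (16^3 grid, 200 permutations), the
#' desk-scale default, and `"full"` (32^3 grid, 5000 permutations)
#' matching the full analysis conditions. All other knobs (group sizes,
#' DVR targets, noise, t*, TFCE settings) default to the study conditions
#' of [cohort_design()] and [tfce_config()].
#'
#' @param seed master seed for every stage.
#' @param scale `"reduced"` or `"full"`.
#' @return A nested configuration list, writable as YAML.
#' @export
default_pipeline_config <- function(seed = 1L, scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  list(seed = as.integer(seed),
       simulate = list(grid = if (scale == "reduced") 16L else 32L,
                       n_per_group = list(CH = 7L, DELIRIUM = 4L,
                                          DEMENTIA = 4L, DSD = 4L),
                       choroid_dvr = list(CH = 0.856, DELIRIUM = 0.601,
                                          DEMENTIA = 0.614, DSD = 0.559),
                       noise_scale = 0.05),
       logan = list(tstar = 30, k2prime = NULL),
       voxelstats = list(n_perm = if (scale == "reduced") 200L else 5000L,
                         alpha = 0.05, connectivity = 26L,
                         directions = c("A>B", "B>A")),
       regress = list(outlier_k = 3))
}

#' Run the full simulate -> DVR -> ROI -> inference -> regression pipeline
#'
#' Orchestrates the end-to-end analysis from a single configuration (a
#' YAML path or a list shaped like [default_pipeline_config()]): simulate
#' the cohort, stream each subject through the Logan fit to a DVR map,
#' extract ROI means, run the voxelwise permutation comparisons of the
#' cognitively healthy group against each impaired group in the three
#' tissue masks (both directions), pick the atlas region with the highest
#' overlap with the pooled significance mask, and regress its mean DVR
#' against the nine-assessment battery. Every stage is seeded from the one
#' master seed; rerunning the same configuration reproduces the same
#' summary.
#'
#' @param config YAML file path or configuration list.
#' @param run_dir output directory (created); stage outputs land in
#'   subdirectories and a machine-readable `summary.json` plus a
#'   `manifest.json` at the top.
#' @param write_images write the simulated 4D images to `run_dir/images`
#'   (default `FALSE`; they are large and reproducible from the manifest).
#' @return The summary list, invisibly; the run directory holds
#'   `summary.json`, `manifest.json`, `roi/roi_means.tsv` (subjects x
#'   labels), `stats/` significance maps and `regression/battery.tsv`.
#' @export
run_pipeline <- function(config, run_dir = tempfile("neuropet_run_"),
                         write_images = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("seed", "simulate", "logan", "voxelstats", "regress")) {
    if (is.null(config[[key]])) stop("config is missing key: ", key)
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("images", "dvr", "roi", "stats", "regression"))
    dir.create(file.path(run_dir, d), showWarnings = FALSE)

  seed <- as.integer(config$seed)
  grid <- rep(as.integer(config$simulate$grid %||% 16L), 3)
  atlas <- make_toy_atlas(grid)
  schedule <- pk11195_frame_schedule()
  design <- cohort_design(
    n_per_group = unlist(config$simulate$n_per_group),
    choroid_dvr = unlist(config$simulate$choroid_dvr),
    noise_scale = config$simulate$noise_scale %||% 0.05,
    seed = seed)
  tstar <- config$logan$tstar %||% 30
  k2prime <- config$logan$k2prime

  # stage 1+2: simulate and quantify, streaming one subject at a time
  dvr_maps <- list()
  handler <- function(id, img) {
    if (write_images)
      write_dynamic_image(img,
                          file.path(run_dir, "images", paste0(id, ".nii.gz")),
                          file.path(run_dir, "images", paste0(id, ".json")))
    m <- suppressMessages(dvr_map(img, atlas, tstar = tstar,
                                  k2prime = k2prime))
    write_dvr_map(m, file.path(run_dir, "dvr", paste0(id, "_dvr.nii.gz")))
    dvr_maps[[id]] <<- m
  }
  sim <- simulate_cohort(design, atlas, schedule, image_handler = handler)
  cohort <- sim$cohort
  write_cohort(cohort, file.path(run_dir, "cohort.tsv"))

  # stage 3: ROI means, wide table subjects x labels
  roi_tables <- lapply(dvr_maps, roi_means, atlas = atlas)
  label_names <- roi_tables[[1]]$name
  means <- t(vapply(roi_tables, function(tb) tb$mean_dvr,
                    numeric(length(label_names))))
  colnames(means) <- label_names
  wide <- data.frame(subject_id = names(roi_tables),
                     group = cohort$group[match(names(roi_tables),
                                                cohort$subject_id)],
                     means, stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(wide, file.path(run_dir, "roi", "roi_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cp_name <- atlas$dictionary$name[atlas$dictionary$id ==
                                     atlas$roles$choroid_plexus]
  group_cp <- tapply(wide[[cp_name]], wide$group, mean)

  # stage 4: voxelwise CH vs each impaired group, 3 tissue masks, both
  # directions, each its own one-sided FWE-corrected run
  vx <- config$voxelstats
  directions <- unlist(vx$directions) %||% c("A>B", "B>A")
  contrasts <- setdiff(COHORT_GROUPS, "CH")
  sig_counts <- list()
  pooled_sig <- array(FALSE, dim = grid)
  run_i <- 0L
  for (tissue in c("gray", "white", "subcortical")) {
    mask <- tissue_mask(atlas, tissue)
    for (grp in contrasts) {
      if (sum(cohort$group == grp) < 2) next  # contrast not estimable
      sel <- cohort$group %in% c("CH", grp)
      maps <- dvr_maps[cohort$subject_id[sel]]
      glab <- factor(cohort$group[sel], levels = c("CH", grp))
      for (dir in directions) {
        run_i <- run_i + 1L
        cfg <- tfce_config(n_perm = as.integer(vx$n_perm %||% 200L),
                           alpha = vx$alpha %||% 0.05,
                           connectivity = vx$connectivity %||% 26L,
                           seed = derive_seed(seed, 20000L + run_i),
                           direction = dir)
        res <- permutation_fwe(maps, glab, mask, cfg)
        key <- sprintf("%s_CH_vs_%s_%s", tissue, grp,
                       if (dir == "A>B") "CHgt" else "CHlt")
        sig_counts[[key]] <- sum(res$sig_mask)
        if (sum(res$sig_mask) > 0) {
          pooled_sig <- pooled_sig | res$sig_mask
          nii <- as_nifti_with_affine(res$p_fwe_map, atlas$affine)
          RNifti::writeNifti(nii, file.path(run_dir, "stats",
                                            paste0(key, "_pfwe.nii.gz")),
                             datatype = "float")
        }
      }
    }
  }

  # stage 5: highest-overlap region and the nine-assessment battery
  overlap <- if (any(pooled_sig))
    highest_overlap_label(pooled_sig, atlas) else NULL
  roi_for_regression <- if (is.null(overlap)) cp_name else overlap$name
  roi_dvr <- stats::setNames(wide[[roi_for_regression]], wide$subject_id)
  battery <- run_assessment_battery(cohort, roi_dvr,
                                    k = config$regress$outlier_k %||% 3)
  utils::write.table(battery$results,
                     file.path(run_dir, "regression", "battery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(battery$diagnostics))
    utils::write.table(battery$diagnostics,
                       file.path(run_dir, "regression", "diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = seed, grid = grid[1],
    group_choroid_dvr = as.list(group_cp),
    significant_voxels = sig_counts,
    highest_overlap = if (is.null(overlap)) NA else overlap$name,
    regression = lapply(seq_len(nrow(battery$results)), function(i)
      as.list(battery$results[i, ])))
  jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("neuropet")),
         seed = seed, config = config),
    file.path(run_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  invisible(summary)
}
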