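# neuropet

Dynamic TSPO-PET quantification and group inference for small clinical
cohorts. The package implements, end to end and with synthetic ground
truth, the analysis chain used to ask whether neuroinflammation — imaged
with the translocator-protein (TSPO) ligand [11C]-PK11195 — differs
between cognitively healthy older adults and patients with delirium,
dementia, or delirium superimposed on dementia (DSD) during acute
systemic infection, and whether regional binding tracks cognition.

Who it is for: imaging methodologists who need a fully seeded, testable
reference implementation of the Logan/TFCE/permutation stack, and anyone
who wants to run power or calibration experiments for small four-group
PET designs without access to patient data.

## What it computes

* **Logan reference-region DVR.** For frames with mid-time beyond t*,
  ordinary least squares of ∫C_T/C_T on ∫C_ref/C_T (optionally with the
  C_ref/k2′ term); the slope is the distribution volume ratio
  DVR = 1 + BP. Voxelwise maps (`dvr_map()`) use the cerebellar-gray
  reference TAC and leave voxels with non-positive activity undefined.
* **SRTM forward simulation.** `simulate_cohort()` generates dynamic
  images on the 22-frame/60-min schedule from the simplified reference
  tissue model (R1 = 1, k2 = 0.4/min, BP = DVR − 1) with
  frame-duration-scaled Gaussian noise, group-specific choroid-plexus DVR
  (0.856 / 0.601 / 0.614 / 0.559 for CH / delirium / dementia / DSD) and
  cognition scores with the corresponding group structure.
* **Voxelwise permutation inference.** Two-sample pooled-variance t maps,
  threshold-free cluster enhancement (E = 0.5, H = 2, 26-connectivity;
  C++ kernel), and max-statistic family-wise error correction from group
  relabelings (exhaustive when feasible), per tissue mask and direction
  (`permutation_fwe()`).
* **ROI statistics and cognition regression.** Atlas ROI means, the
  highest-overlap region under a significance mask, and simple
  regressions of ROI DVR on a nine-assessment battery with a 3-SD outlier
  screen and Bonferroni-9 correction (`run_assessment_battery()`).

## Worked example

A noiseless SRTM curve generated at DVR 0.856 and fit by the Logan
method recovers the value exactly:

```r
library(neuropet)
sch  <- pk11195_frame_schedule()
ref  <- reference_tac(sch)                       # gamma-variate input
fine <- reference_tac_fine(sch)
ct   <- srtm_tac(fine, srtm_params(R1 = 1, k2 = 0.4, BP = -0.144), sch)
logan_fit(ct, ref)
#> Logan reference fit: DVR = 0.8560 (intercept 0.360 min)
#>   t* = 30 min, 6 frames, R^2 = 1.00000
```

The full pipeline — simulate 19 subjects, map DVR, run the voxelwise
contrasts in three tissue masks (both directions), pick the
best-overlap region, regress cognition — from one seed:

```r
s <- run_pipeline(default_pipeline_config(seed = 7), run_dir = "run7")
unlist(s$group_choroid_dvr)
#>        CH  DELIRIUM  DEMENTIA       DSD
#> 0.8559972 0.6010244 0.6140462 0.5590335
Filter(function(v) v > 0, s$significant_voxels)
#> $subcortical_CH_vs_DELIRIUM_CHgt  [1] 48
#> $subcortical_CH_vs_DEMENTIA_CHgt  [1] 48
#> $subcortical_CH_vs_DSD_CHgt       [1] 48
#> $subcortical_CH_vs_DSD_CHlt       [1] 1
s$highest_overlap
#> [1] "choroid_plexus"
```

Reading: the recovered group means sit on the simulation targets; all 48
choroid-plexus voxels (16³ grid) are significant for healthy > impaired
in the subcortical mask and nowhere else except a single
opposite-direction voxel — the occasional familywise false positive a 5%
FWE procedure is designed to allow. The regression battery then flags
only the MoCA attention score (`s$regression`): Pearson r = 0.76,
Bonferroni-corrected p = 0.0013 in this run; the other eight assessments
are simulated as pure noise and stay non-significant.

A command-line wrapper with `simulate | dvr | roi | voxelstats | regress
| pipeline` subcommands is in `inst/cli/neuropet.R`.

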