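---
title: "Quantifying TSPO PET with Logan reference-region analysis and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TSPO PET with Logan reference-region analysis and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropet)
```

## The scientific problem

Activated microglia upregulate the 18-kDa translocator protein (TSPO), so
the brain uptake of the TSPO ligand [11C]-PK11195 indexes
neuroinflammation. In small hospitalized cohorts — cognitively healthy
older adults versus patients with delirium, dementia, or delirium
superimposed on dementia (DSD), all with an acute systemic infection —
the question is whether the neuroinflammatory response differs by
cognitive status, where in the brain it differs, and whether regional
tracer binding tracks cognition.

`neuropet` implements that analysis chain as a reusable, fully testable
pipeline:

1. simulate dynamic PET images for a four-group cohort with known ground
   truth (`simulate_cohort()`),
2. estimate a voxelwise distribution volume ratio (DVR) map per subject by
   Logan reference-region graphical analysis (`dvr_map()`),
3. extract atlas ROI means (`roi_means()`),
4. compare groups voxelwise with permutation t-tests, threshold-free
   cluster enhancement (TFCE) and max-statistic family-wise error (FWE)
   correction within tissue masks (`permutation_fwe()`),
5. regress the best-overlap region's mean DVR on a nine-assessment
   cognitive battery with z-score outlier screening and Bonferroni
   correction (`run_assessment_battery()`).

Because no patient-level data are public, the synthetic cohort module is a
first-class citizen: it generates data with exactly the statistical
structure the downstream stages assume, so every stage can be validated by
parameter recovery.

## Acquisition model and data containers

The dynamic acquisition is the 22-frame, 60-minute schedule
(4×30 s + 4×60 s + 4×120 s + 4×240 s + 6×300 s), started at bolus
injection; `pk11195_frame_schedule()` builds it and
`read_frame_schedule()` reads the BIDS-style JSON sidecar (frame start
times and durations, in seconds). A `dynamic_image` couples the 4D
frame-averaged activity array with that schedule and a voxel-to-world RAS
affine in mm. All volumes in one analysis must share one grid and affine;
registration is deliberately out of scope, so a mismatch is an error.
Negative reconstructed activities are clipped to zero with a logged count
rather than rejected — they are routine reconstruction artifacts.

The anatomical side is a `label_atlas`: an integer label volume plus a
dictionary that must resolve five reserved roles — the cerebellar-gray
reference region, gray/white/subcortical analysis masks, and the choroid
plexus. `make_toy_atlas()` provides a deterministic geometric phantom with
all five roles (axis-aligned blocks scaled with the grid). It is a
synthetic stand-in for an anatomical parcellation such as the Hammers
atlas: topologically much simpler, but sufficient for every contract the
pipeline relies on. The subcortical *analysis mask* is the union of the
subcortical label and the choroid-plexus label (`tissue_mask()`): the
choroid plexus is anatomically part of the subcortical territory but keeps
its own label so it can be an ROI and an overlap target.

## The forward model: SRTM as a simulator

The study estimates DVR only; it never commits to a compartment model. As
a generator we therefore use the minimal model consistent with
reference-region quantification, the simplified reference tissue model
(SRTM):

$$C_T(t) = R_1 C_{ref}(t) + \left(k_2 - R_1 k_{2a}\right)
  \int_0^t C_{ref}(s)\, e^{-k_{2a}(t-s)}\, ds, \qquad
  k_{2a} = \frac{k_2}{1 + BP},$$

with delivery ratio $R_1$, target efflux $k_2$ (1/min) and binding
potential $BP$; the implied distribution volume ratio is $DVR = 1 + BP$.
The reference input is a gamma variate
$C_{ref}(t) = A\,t\,e^{-t/\tau}$ ($\tau$ = 15 min by default, peaking at
$t=\tau$), the usual single-bump bolus shape. The convolution is evaluated
on a 1-second grid with an exact exponential-decay recursion and
trapezoidal source integration, then frame-averaged. At $R_1 = 1, BP = 0$
the model collapses to $C_T \equiv C_{ref}$, which the tests assert.

Defaults $R_1 = 1$ and $k_2 = 0.4$/min are fixed across tissues; only $BP$
varies, set from the target DVR per label. This is a deliberate
simplification: the study conditions are encoded entirely in the DVR
targets (choroid plexus 0.856 / 0.601 / 0.614 / 0.559 for CH / delirium /
dementia / DSD; 1.0 everywhere else in every group, mirroring the absence
of cortical group differences), and perfusion differences are not
simulated. Whether a reported DVR below 1 reflects genuine binding below
the reference or reference-region contamination cannot be decided from
DVR data; the simulator treats the values as true DVR targets.

Noise is zero-mean Gaussian per voxel and frame with standard deviation
`noise_scale * sqrt(max(signal, 1e-6) / frame_duration)` — variance
proportional to count rate over frame duration, the usual post-
reconstruction approximation of Poisson counting noise. `noise_scale`
defaults to 0.05. Background (unlabelled) voxels stay exactly zero; they
are outside every analysis mask, so nothing downstream sees them, and
skipping them keeps desk-scale simulation fast. What the generator does
*not* emulate: scanner point-spread and partial-volume effects, motion,
attenuation/scatter residuals, anatomical variability, and spatially
correlated noise. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators and inference machinery, not
robustness to real-scanner physics.

The MoCA group signal (means/SDs 19.9/4.62, 6.5/4.95, 6.0/1.73, 5.3/2.01)
is carried by the `MoCA_attention` column — the subscore whose variance
the final regression model explains — truncated at 0; the other eight
assessments are independent standard-normal placeholders, since only the
MoCA association is treated as real signal.

## Logan reference-region graphical analysis

For frames with mid-time at or beyond $t^*$,

$$\frac{\int_0^{t} C_T}{C_T(t)} \;=\; DVR \cdot
  \frac{\int_0^{t} C_{ref} + C_{ref}(t)/k_2'}{C_T(t)} + b,$$

and the OLS slope estimates DVR. Conventions, chosen once and documented:
integrals are evaluated at frame **end** times (exact cumulative sums for
frame-averaged data, `cumulative_integral()`), instantaneous values are
the frame averages, and time is in minutes so the intercept has units of
minutes. The $C_{ref}/k_2'$ term is omitted by default (the classic
simplified reference formulation); `k2prime` is available as an option.
With the gamma-variate input and $t^* = 30$ min, the omission biases the
recovered DVR by well under 1% across $BP \in [-0.5, 1]$ — the round-trip
tests enforce exactly that — because by 30 min the reference-to-target
ratio is nearly constant and the omitted term folds into the intercept.

$t^* = 30$ min (the last six frames) is the default; it is late enough for
linearity under the default kinetics and leaves enough points for a stable
slope. Voxels with any non-positive activity in the fit window get `NaN`
instead of a fit — avoiding division blow-ups without imputation — and are
excluded from every downstream statistic. The self-reference identity
(`logan_fit(x, x)` has slope exactly 1 and intercept 0 for any positive
TAC) holds analytically and is asserted to 1e-6; the voxelwise path is the
same algebra vectorised, so the reference region's mean DVR is 1 by
construction up to noise.

## Voxelwise permutation inference with TFCE

Group contrasts use the unpaired pooled-variance t statistic per voxel,
computed within one tissue mask at a time; voxels undefined for any
subject drop out of the mask. TFCE integrates cluster extent and height
over all thresholds:

$$\mathrm{TFCE}(v) = \sum_{h = dh,\,2dh,\ldots}^{\;\le\, t(v)}
  e(h, v)^{E}\, h^{H}\, dh,$$

with $e(h,v)$ the size of the connected supra-threshold component
containing $v$. Defaults $E = 0.5$, $H = 2$, 26-connectivity — the
standard 3D choices — and $dh$ adaptive at (observed max)/100, held fixed
across all permutations of a run so observed and null values are
comparable; a fixed `dh` is available and is what the brute-force oracle
tests use. The kernel is C++ (an incremental union-find over descending
thresholds); an independent R flood-fill implementation verifies it
exactly on random maps.

FWE correction uses the permutation distribution of the mask-wide maximum
TFCE under group relabelings. The observed labeling is always a member of
the null set; with $m$ total relabelings,
$p(v) = \#\{\max\text{-null} \ge \mathrm{TFCE}_{obs}(v)\}/m \ge 1/m$.
When `n_perm` reaches the number of distinct relabelings the test
enumerates them exhaustively (as FSL's `randomise` does); tiny instances
let the sampled and exhaustive routes be compared exactly. Each direction
(CH > impaired, impaired > CH) is its own one-sided run with its own
correction, and the three tissue masks are three independent analyses with
no cross-mask correction — matching per-region reporting practice. No
variance smoothing and no spatial smoothing are applied; under the null
simulator the familywise rejection rate calibrates to the nominal 5%
within Monte-Carlo error, which the acceptance suite measures over 200
runs.

## ROI extraction and the cognition regression

`roi_means()` averages defined voxels per label; `highest_overlap_label()`
picks the atlas region holding the most significant voxels (plain counts,
not fractions of region size — the plain reading of "highest overlap";
background is never eligible; ties go to the smallest id with a warning).
That region's per-subject mean DVR is regressed on each of the nine
assessments (CAM, five MoCA subscores, IQCODE-SF, GDS, NPI):
pairwise-complete cases, then a single-pass screen removing points more
than 3 SD from the full-sample mean of either variable, then OLS with
Pearson $r$, adjusted $R^2 = 1 - (1 - r^2)(n-1)/(n-2)$, and a two-sided p
from $t_{n-2}$. The analytic identity `adjusted_r2(0.66, 19) == 0.40` (2
dp) is asserted directly. Bonferroni correction always divides by 9 — the
battery size — even when some assessments are skipped for lack of data,
so the correction never becomes more lenient as data degrade.

## Pipeline, problem sizes and reproducibility

`run_pipeline()` chains all stages from one configuration (YAML or list)
and one master seed; subject-level simulation seeds, permutation seeds per
run, and the score generator all derive deterministically from it, so a
rerun is bit-identical. Two scales are bundled: the desk-scale default
(16³ grid, 200 permutations), which runs the full 19-subject pipeline in
a few seconds and is what the test suite exercises, and `"full"` scale
(32³, 5000 permutations). The acceptance computations use 32³ for ROI
recovery (the choroid-plexus block holds 216 voxels there) and the
desk scale for the repeated calibration studies; these sizes are the
package's chosen trade-off between resolution and the number of Monte
Carlo replicates worth spending.

## Numerical choices and degenerate inputs, collected

* Fine-grid SRTM evaluation at 1 s; exponential-integrator recursion is
  stable for any $k_{2a} dt$.
* Cumulative TAC integrals are exact sums for step-constant data — no
  quadrature error enters the Logan fit.
* Zero pooled variance in a t contrast yields t = 0 (identical constant
  groups), not `NaN`.
* An observed t map with no positive values short-circuits: TFCE is zero
  everywhere and every corrected p is 1.
* An all-zero dynamic image yields an all-`NaN` DVR map with a logged
  count, not an error.
* Empty groups are valid in a design; contrasts involving them are
  skipped by the pipeline and are errors in the two-sample functions.
* Outlier screening on a zero-variance variable treats no point as an
  outlier (z-scores are undefined; the screen passes everything).

## Known limitations

The toy atlas is geometric; overlap logic is atlas-agnostic but has only
been exercised against block-shaped regions. DVR below ~0.3 with strong
noise can produce non-positive late-frame activities and hence undefined
voxels. The regression battery models linear associations only, and the
simulator's group-mean-driven cognition signal produces stronger
correlations than the within-group mixing of real data. Partial-volume
and motion effects, the dominant practical confounds of choroid-plexus
TSPO imaging, are out of the generator's scope by design.
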