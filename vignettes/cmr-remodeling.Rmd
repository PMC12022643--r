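---
title: "Quantifying left-ventricular remodeling from cardiac MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-ventricular remodeling from cardiac MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmremodel)
```

# The problem

In hypertrophic obstructive cardiomyopathy (HOCM), surgical septal myectomy
relieves outflow-tract obstruction and is followed by regression of
left-ventricular (LV) hypertrophy. Cardiac MRI can split that regression
into its tissue compartments: cine imaging yields LV mass and volumes, T1
mapping before and after gadolinium yields the extracellular volume
fraction (ECV, a surrogate of diffuse interstitial fibrosis), and late
gadolinium enhancement (LGE) marks focal replacement fibrosis. Combining
them gives the indexed extracellular and cellular volumes (iECV, iCV),
which separate interstitial from cellular remodeling in paired pre/post
studies.

`cmremodel` implements this quantification pipeline end to end — segmental
geometry, tissue characterization, volumetrics, compartment metrics, and
the paired-cohort statistics — together with a synthetic short-axis phantom
generator whose analytic ground truth makes every stage testable without
patient data.

# Models and formulas

## ECV from T1 relaxation

With native and post-contrast T1 (ms) of myocardium and blood-pool, and the
hematocrit Hct,

$$\mathrm{ECV} = (1 - \mathrm{Hct}) \cdot
\frac{1/T1_{\mathrm{myo,post}} - 1/T1_{\mathrm{myo,native}}}
     {1/T1_{\mathrm{blood,post}} - 1/T1_{\mathrm{blood,native}}}.$$

ECV is computed per AHA segment from the segmental mean T1 values (not
voxelwise and then averaged): the segment is the unit at which T1 values
are reported and quality controlled. Blood T1 is taken from a blood-pool
ROI on the mid slice — a single per-study value; per-slice blood sampling
would be a straightforward extension but the package records the mid-slice
choice explicitly.

## Segmental geometry

The myocardium of each short-axis slice is the set difference of the
epicardial and endocardial rasters. For T1/ECV measurement a **10% radial
offset** trims both edges: along each 1-degree ray from the cavity
centroid, voxels within 10% of the *local wall thickness* of either edge
are removed. The offset is interpreted as a fraction of wall thickness per
ray rather than a fixed-millimetre erosion because walls in this population
vary roughly 10–30 mm; a uniform erosion would remove a very different
fraction of a thin lateral wall than of a hypertrophied septum.

Segments follow the AHA 16-segment model (no apex cap): six 60-degree
sectors on basal and mid slices, four 90-degree sectors apically. Angles
start at the anterior right-ventricular insertion point and sweep through
the LV free wall; a sector boundary belongs to the sector it starts. The
sweep direction is inferred from the inferior insertion point (which must
fall 240 degrees along the sweep); when absent, a counterclockwise sweep in
array coordinates is assumed.

Edge radii along rays are estimated as the largest voxel-centre radius
within a small angular window of the ray plus a quarter-voxel correction.
Because voxel centres always lie strictly inside the true contour, this
estimator can never overshoot the contour by more than the correction; the
window widens adaptively at small radii where a 1-degree sector is narrower
than a voxel. Maximal wall thickness additionally smooths the per-ray wall
over ±8 degrees before taking the maximum, suppressing the rasterization
zigzag — on 1 mm rasters the resulting accuracy is about half a voxel.

## LGE quantification

Enhanced myocardium is `intensity > mean + 6·SD` of a remote reference ROI,
with the *sample* (n−1) standard deviation and a strict inequality — an
explicit, deterministic reading of the 6-SD rule. No minimum-cluster filter
is applied by default (manual mask editing is out of scope); LGE volume is
voxel count × voxel volume, mass uses density 1.05 g/mL, and percentage is
relative to the myocardial band volume. A segment is excluded from global
T1/ECV if it contains any enhanced voxel (`exclusion_fraction = 0`); the
fraction is configurable because the exclusion rule is stated in the
literature without one.

## Compartment metrics

Global ECV and native T1 are area-weighted means over LGE-free segments.
With end-diastolic myocardial volume $V_m$ (mL), LGE volume $V_l$, and body
surface area $B$ (Mosteller by default, Du Bois selectable):

$$\mathrm{iECV} = \left(\frac{V_m}{B} - \frac{V_l}{B}\right)\mathrm{ECV},
\qquad
\mathrm{iCV} = \left(\frac{V_m}{B} - \frac{V_l}{B}\right)(1-\mathrm{ECV}).$$

Both terms are indexed before subtraction; this reading of the published
formula is confirmed by a worked single-case cross-check (LVMI 114 g/m²,
LGE 1.2 g, ECV 27.9%, density 1.05 g/mL, BSA 1.70 m² reproduce the printed
iCV of 77.8 mL/m²). The identity `iCV + iECV = (V_m − V_l)/B` holds to
machine precision for every subject and is asserted in the tests. LV mass
is myocardial volume × 1.05 g/mL; volumes use slice summation (area ×
8 mm thickness, no gap).

Two sign conventions are reported for changes: descriptive tables use
`delta = post − pre` (regression is negative); regression outcomes use
`reduction = pre − post` (regression is positive).

# The phantom generator

A synthetic subject is a stack of short-axis slices in which the LV is a
concentric annulus around a circular blood pool. Defaults describe the
study conditions: 9 slices (3 per AHA level) of 8 mm on a 1 mm, 112²
grid; tapered cavity radii and an 11.6 mm wall giving LVMI near
101 g/m² and EDVI near 86 mL/m² at BSA 1.67 m²; native myocardial T1
1313 ms, blood 1900 ms, post-contrast 645/450 ms and hematocrit 0.393,
jointly giving true ECV near 28.2%; end-systolic radii give an ejection
fraction near 66%. Focal lesions are annular sectors with configurable
transmural depth and a multiplicative hyperenhancement on the LGE image.
Noise is additive Gaussian per modality (default SD 15 ms on T1 maps,
5 a.u. on the LGE image against a myocardial level of 100); no noise
statistics are published for these acquisitions, so a single realistic
level was fixed once. Ground truth (ECV, mass, volumes, LGE volume) is
computed analytically from the generating parameters, never from the
rendered voxels.

What the phantom does *not* emulate: papillary muscles and trabeculae,
asymmetric (septal-dominant) hypertrophy within a slice, coil profiles,
partial-volume and motion artifacts, Rician noise floors, or long-axis
geometry. Passing tests therefore demonstrate the correctness of the
measurement pipeline on known geometry — not segmentation robustness on
real images, which is out of scope (contours are inputs here).

## Paired cohorts

`generate_paired_cohort()` draws per-subject baselines from the
study-population dispersion (LVMI 101 ± 28 g/m², ECV 28.2 ± 3.3%, EF
65.9 ± 4%, EDVI 86.6 ± 14 mL/m², LGE mass 4.5 ± 4.5 g truncated at 0,
hematocrit 39.3 ± 3.5%) and within-person changes from the configured
effect sizes (defaults: iECV −4.4 ± 2.6, iCV −16.6 ± 6.6 mL/m², LGE mass
+2.9 ± 3.3 g, EF −2.6 ± 3.1 points, EDVI −8.2 ± 13.0 mL/m²).

The compartment identity
`LVMI = 1.05 · (iECV + iCV) + LGE mass/BSA` makes it impossible to draw all
change metrics independently. The generator therefore draws the iECV and
iCV changes jointly (correlation 0.30 — chosen so the implied LVMI-change
dispersion matches the observed ±8.4 g/m²) plus the LGE, EF and EDVI
changes, and *derives* the LVMI change (implied mean ≈ −20.3 g/m², close to
the observed −19.8) and the ECV change (implied mean ≈ +1.9 points) from
the identity. A configurable correlation (default −0.3) links each
compartment change to the subject's standardized baseline, reproducing the
observation that larger baselines regress more.

Post-operative phantom parameters are solved analytically from the
targets: cavity radii are rescaled for the target EDV, a uniform wall
increment is solved for the target mass, end-systolic radii for the target
EF, the post-contrast myocardial T1 for the target ECV, and septal lesion
extents for the target LGE mass. Subjects whose solved geometry is
unphysical (negative wall, LGE beyond septal capacity, out-of-range ECV or
EF) are redrawn up to 25 times. The realized generating draws are recorded
per subject for oracle comparison against pipeline estimates.

The cohort object stores solved parameter sets, not rendered images;
bundles are materialized on demand, which keeps a 43-pair cohort at
megabytes instead of hundreds of megabytes.

# The statistics stage

Within-person changes are tested with a normality gate: Shapiro–Wilk on the
paired differences at 0.05 routes to a paired t-test or a Wilcoxon
signed-rank test. The signed-rank test drops zero differences, uses
midranks for ties, and computes the exact two-sided p-value for n ≤ 25 by
convolution of the signed-rank generating function (ranks doubled so
midranks are integers); larger samples use the normal approximation with
tie-corrected variance and continuity correction. Significance in the
change table is judged at the Bonferroni-adjusted level `alpha/family`
(default 0.05/20 = 0.0025, the size of the published change table).

Predictor analysis mirrors standard clinical practice: a univariable
screen (simple linear regressions, retain p < 0.05) followed by
bidirectional stepwise selection with p-value entry/removal criteria
0.05/0.10 (an AIC mode via `stats::step()` sits behind
`criterion = "aic"`). The final model reports coefficients with 95% CIs,
the Durbin–Watson test (`lmtest::dwtest`), and per-observation studentized
residuals and Cook's distances with flags at |r| > 3 and D > 0.5; a refit
excluding flagged observations is reported alongside, never silently
substituted. Restricted cubic splines (hand-built Harrell truncated-power
basis; knots at the conventional quantiles, default 4 knots at
5/35/65/95%) test nonlinearity by the F-test of the nonlinear basis terms
against the plain linear fit. Knot count, stepwise criteria, and the
Shapiro–Wilk operand are configuration choices, not assertions about any
particular prior analysis.

# Numerical choices and degenerate inputs

- Offset fraction 0 returns the band unchanged; retained windows thinner
  than one voxel keep their single most central voxel so near-limit
  offsets do not empty a ray; walls thinner than 3 voxels warn.
- An all-zero difference vector yields a degenerate test with p = 1 and a
  warning; paired tables with fewer than 3 pairs report no test.
- Constant predictors are skipped with a warning; perfectly collinear
  predictors are dropped in entry order; constant outcomes skip the
  regression stage.
- A constant spline outcome reports nonlinearity p = 1; a perfect linear
  fit (zero residual both ways) does likewise.
- Empty segments (possible after the offset on thin walls) report `NA`
  means, never zero, and drop out of area-weighted globals.
- Determinism: every stochastic step is seeded (`withr::with_seed`);
  identical parameters and seed give bit-identical subjects, and cohort
  subject seeds are derived from the cohort seed.

# Problem sizes used in the test-suite

Module tests run on compact 3-slice, 72² phantoms that quantify in well
under a second; pipeline-level and cohort checks use the full 9-slice,
112² study geometry. The simulation checks use 500–5000 replicates for
test calibration, 100 replicates for stepwise recovery and spline
specificity, and a single 43-pair cohort for the end-to-end round trip —
sizes at which the checked quantities have comfortably small Monte Carlo
error while the whole suite runs in a couple of minutes.

# Known limitations

- Contours are inputs; no image segmentation is performed or validated.
- Concentric geometry cannot represent asymmetric septal bulging; maximal
  wall thickness on phantoms therefore understates the clinical asymmetry.
- The LGE noise model is Gaussian on magnitude images; near-zero signal
  the Rician floor would matter, but lesions here sit far above it.
- Blood T1 uses one mid-slice ROI; B1/B0-related slice dependence of T1 is
  not modeled.
- The cohort generator reproduces first and second moments and simple
  baseline correlations of the within-person changes, not the full joint
  distribution of a clinical cohort.
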