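---
title: "Methods: quantifying visual function and eye growth in zebrafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying visual function and eye growth in zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfeye)
library(dplyr)
```

zfeye bundles the five bespoke computations behind behavioral and
structural phenotyping of zebrafish myopia models — optomotor tuning
curves with model-comparison F-tests, OCT biometry via Matthiessen's
ratio, ERG waveform features, inner-retinal layer intensity profiles, and
relative qPCR expression — together with seeded simulators for every input
modality. This vignette explains each model, its assumptions, the
parameters that matter, and the numerical choices made where the design
was genuinely open.

## The synthetic-data generators

Every analysis in the package is exercised on simulated data with known
ground truth (`ground_truth()` retrieves it from any `sim_*()` output).
The generators are pure functions of their parameters and a seed, restore
the global RNG state on exit, and are designed so that at zero noise every
downstream extraction recovers the generating truth exactly (to grid
resolution). What they emulate — and what they deliberately do not:

* **Swim trajectories** (`sim_trajectory()`) follow a drift–diffusion
  model: angular velocity is `gain * direction * speed` plus white noise,
  so displacement variance grows linearly with time and the analytic
  variance is available for tests. Real larval swimming is bouty and
  saccadic; none of that kinematic structure is modeled, because the
  optomotor index only consumes net displacement.
* **Optomotor cohorts** (`sim_omr_cohort()`) draw each trial's gain from
  the group's log-Gaussian tuning curve plus independent Gaussian noise
  (`noise_sd_omi`, default 0.1 — per-trial, on the normalized-OMI scale).
  Trial-to-trial variance structure in real fish is unknown; white noise
  is a declared stand-in, so calibration results (F-test size, power)
  speak to the method under these conditions, not to real-cohort error
  rates. Defaults mirror the study design: 14 fish per group, six
  frequencies (0.0078–0.2480 c/°), four trials per condition split
  clockwise/counter-clockwise, 0.5 rad/s for 30 s.
* **ERG traces** (`sim_erg_trace()`) sum two gamma-type kernels
  `K(t) = (t/tp)^s exp(s(1 - t/tp))`, each normalized to unit peak at an
  explicit peak time — a corneal-negative component (default 100 µV at
  20 ms) and a positive component (300 µV at 60 ms), shape `s = 4`,
  1 ms sampling. Because the components overlap, the realized trough and
  peak of the sum differ from the nominal kernel times; ground truth is
  therefore computed from a 100× oversampled evaluation of the closed
  form. Oscillatory potentials and photoreceptor adaptation are not
  modeled.
* **B-scans** (`sim_bscan()`) place Gaussian axial bands (3 px SD) at the
  cornea, both lens surfaces and the RPE, so the sub-pixel landmark truth
  is well defined as the band center. Additive Gaussian noise stands in
  for speckle; true OCT speckle statistics are out of scope.
* **Layer images** (`sim_layer_image()`) are stepwise-constant columns
  (ACL/IPL/GCL) plus noise; **Ct tables** (`sim_ct_table()`) encode true
  fold changes as `-log2(fold)` Ct shifts with a per-sample loading offset
  common to all genes (so per-sample ΔCt is exact) and per-replicate
  noise. Amplification efficiency is fixed at 2.

## Optomotor index and tuning curves

The optomotor index of a trial is the **net signed angular displacement**
of the fish, positive when moving with the grating: tracked angles wrapped
to (−π, π] are unwrapped (jumps > π corrected by ±2π, valid while true
per-sample rotation stays below π — comfortably satisfied at 30 Hz video),
and `OMI = (θ_end − θ_start) · direction`, in radians. Net displacement
rather than path length makes the statistic antisymmetric in stimulus
direction, which averaging clockwise and counter-clockwise trials relies
on. Per-fish OMIs are averaged over the four trials per frequency and
normalized by the control group's mean at a reference frequency (0.0155
c/° for larvae, 0.0620 c/° for juveniles — the condition of greatest
response at each age), pinning the control mean at 1 exactly.

Tuning is modeled as a log-Gaussian,

$$R(f) = A \exp\!\left(-\frac{(\log_{10} f - \log_{10} p)^2}{2\sigma^2}\right),$$

with amplitude $A$ (peak height, normalized OMI), peak frequency $p$
(c/°) and bandwidth $\sigma$ (log₁₀-frequency units; base 10 is a package
convention — another base only rescales $\sigma$). `fit_log_gaussian()`
minimizes the residual sum of squares. Numerically, $A$ enters the model
linearly and is profiled out in closed form, so the optimizer runs over
$(\log_{10} p, \sigma)$ only — identical to the 3-parameter problem but
faster and far less start-sensitive. Because the objective is still
multimodal in $p$, eight log-spaced initial peaks are tried, with bounds
$A \in [0, 10\max y]$, $p$ within the tested range × [1/4, 4], and
$\sigma \in [0.05, 2]$; ties among equally good starts break to the
smallest $\sigma$, then the smallest $p$, deterministically. L-BFGS-B runs
with a tight convergence factor and 1e-7 finite-difference steps so
noiseless data are recovered to machine precision. An all-zero response
returns amplitude 0 with an explicit unidentifiability flag rather than
arbitrary location/width estimates.

Fits use per-fish points by default (so the F-test's N is well defined);
`collapse_fish = TRUE` fits group means instead, since which of the two
the original workflow used is not stated.

### Model comparison

Group differences are tested by extra sum of squares. The **omnibus** test
compares independent per-group fits (3G parameters) against one fit to the
pooled data (3 parameters):

$$F = \frac{(\mathrm{RSS}_R - \mathrm{RSS}_F)/(3G-3)}{\mathrm{RSS}_F/(N-3G)},$$

which for a common dataset is the residual-form equivalent of comparing
goodness of fit (r²) between the two models. The **nested** test
constrains one named parameter to a shared value across groups — a joint
refit of the restricted model, not a post-hoc constraint on full-model
estimates — giving `df = (G − 1, N − 3G)`. Two numerical safeguards keep
the nesting inequality honest: the restricted optimum is injected as an
extra start into the full-model fits (so RSS_F ≤ RSS_R holds by
construction), and when the restricted model fits as well as the full one
to within 1e-10 relative the statistic is reported as exactly 0 rather
than 0/0 round-off noise. A zero full-model RSS with positive restricted
RSS reports F = ∞, p = 0. The α = 0.05 criterion is reporting only; no
decisions are automated.

On simulated null cohorts at the study design (14 fish/group, noise SD
0.1) the omnibus test holds its nominal size and the package's acceptance
checks verify rejection rates, parameter recovery and agreement of the
nested F with an independent dense grid-search refit oracle.

## ERG features

Features follow the clinical conventions: baseline is the mean voltage
over 50 ms before the flash; the a-trough is the minimum in a search
window of 3–100 ms post-onset (earliest sample on ties); the b-peak is
the maximum strictly after the trough up to 300 ms post-onset. The
a-amplitude runs baseline→trough, the b-amplitude trough→peak, and
implicit times are measured from stimulus onset. The window bounds are
package conventions — the original workflow does not state them — sized to
typical zebrafish flash-ERG morphology and fully configurable. A trough
that fails to descend more than `detection_floor` (default 3× the
baseline-window SD, which separates "no a-wave" from noise minima on flat
traces) is flagged absent with amplitude 0 and time `NA`; the b-peak is
then measured from baseline. No smoothing is applied before extremum
detection by default; an optional moving-average width is recorded in the
output when used. Group averages are pointwise means with SEM = SD/√n
(n − 1 denominator); traces must share a time grid — there is no implicit
resampling — and single-trace cells get `NA` SEM with a flag, not 0.

## OCT biometry

From axial landmark positions (µm along the central axis):
axial length = cornea apex → RPE; lens radius = half the lens thickness;
retinal radius = axial length − lens radius; and Matthiessen's ratio
R/L = retinal radius / lens radius, the standard relative-refraction proxy
for aquatic eyes. Retinal radius via the subtraction identity assumes the
cornea sits essentially against the lens (the fish-eye assumption); both
eyes are treated as independent observations. A positive case-minus-
control shift in R/L is labeled relative myopia, a negative one relative
hyperopia. `detect_axis_landmarks()` — a documented stand-in for the
original instrument-specific scripts, validated only on synthetic scans —
averages a central column band, ranks local maxima by topographic
prominence, keeps the four strongest, orders them by depth and refines
each by parabolic interpolation; output is in pixels, and calibrated
biometry requires an explicit px/µm conversion.

## Layer profiles

Straightened-section analysis starts from the image (the curvilinear
straightening of the original workflow happens upstream in an image tool):
`extract_profile()` takes columnwise means over a vertically centered
150-px band; `resample_to_control_ipl()` rescales the pixel axis by
`control IPL / this IPL` with linear interpolation (the original resize
operation's interpolation is unspecified; linear is the minimal, exactly
testable assumption); `normalize_profile()` divides by the maximum; and
`layer_sums()` sums over the inclusive 1-based windows ACL 1–90, IPL
91–300, GCL 301–390 (390-px two-day ROI) or ACL 1–90, IPL 91–330, GCL
331–455 (455-px four-week ROI). The windows partition the profile, so the
three sums always add to the total. Whether the original workflow
normalized before or after IPL resampling is unstated; this package
resamples first, then normalizes, and records the order in the profile
metadata. Note that max-normalization couples layers: dimming the
brightest layer inflates the relative sums of the others, which is a
property of the method, not an artifact of this implementation.

## Relative expression

`relative_expression()` implements 2^−ΔΔCt with technical replicates
averaged per sample first, ΔCt = target − reference per sample, and ΔΔCt
referenced to the **mean ΔCt of the calibrator group** (not a single
designated sample) — this group-mean convention makes the calibrator's
geometric-mean fold exactly 1, a checkable identity. When a `timepoint`
column is present, calibration is stratified per timepoint. Whether the
original analysis pooled replicates before or after ΔCt is unstated;
replicate-mean-then-ΔCt is this package's convention.

## Problem sizes and reproducibility

The package's acceptance checks run 200 recovery cohorts, 500 null
cohorts, 200 power cohorts (14 fish/group each), 200 noisy ERG traces,
100 speckled B-scans and the full two-group demo pipeline — sizes chosen
to estimate rates with usefully small Monte-Carlo error while completing
in a few minutes. `run_pipeline()` writes tidy CSVs, a JSON manifest
(config echo, seed, file hashes) sufficient to reproduce a run
byte-identically, and a text report whose every number is recomputed from
the tidy files.

## Known limitations

* The generators' noise models are stand-ins; passing tests demonstrate
  correctness of the computations and calibration under the stated
  conditions, not performance on real tracking, ERG or imaging data.
* Landmark detection is validated only on synthetic B-scans; real scans
  with specular artifacts or missing surfaces will need the prominence
  threshold and column band tuned, or manual landmarking.
* Factorial inference across ages, rearing conditions and genotypes
  (ANOVA + post-hoc) is deliberately out of scope: the pipeline exports
  tidy tables for any standard statistics environment.

```{r demo, eval = FALSE}
# the end-to-end demo: mutant with a 30% tuning-amplitude deficit and a
# +0.1 R/L elevation
out <- tempfile()
run_pipeline(demo_config(seed = 42), out)
cat(readLines(file.path(out, "report.txt")), sep = "\n")
```
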