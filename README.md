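# zfeye

Ocular phenotyping pipeline for zebrafish myopia models: a tidyverse-style
R package implementing the bespoke computations used to characterize
visual function and eye growth in mutant fish, plus seeded synthetic-data
generators so the whole pipeline runs and is testable end to end with no
external data.

## What it computes

Zebrafish are a workhorse model for emmetropization — the developmental
feedback that matches eye length to optical power. Phenotyping a myopia
model combines behavior, structure, electrophysiology, histology and gene
expression, each with its own niche computation that rarely ships as
reusable software:

* **Optomotor index (OMI)** — per trial, the net angular displacement of a
  fish following a rotating grating, signed with the stimulus direction:
  unwrap the tracked angle, take `(θ_end − θ_start) · direction` (rad).
  Trials are averaged per fish × spatial frequency and normalized to the
  control group's mean at a reference frequency.
* **Spatial-frequency tuning** — the log-Gaussian model
  `R(f) = A exp(−(log10 f − log10 p)² / (2σ²))` fit by least squares
  (amplitude `A`, peak frequency `p` in c/°, bandwidth `σ` in log10
  units), with **omnibus** and **nested extra-sum-of-squares F-tests**
  comparing full (per-group) against restricted (shared-parameter)
  models: `F = ((RSS_R − RSS_F)/Δk) / (RSS_F/(N − k_full))`.
* **OCT biometry** — from axial landmarks: axial length (cornea → RPE),
  lens radius (half lens thickness), retinal radius (axial − lens), and
  **Matthiessen's ratio** R/L = retinal/lens radius; a higher R/L than
  control is relative axial myopia. Includes peak-prominence landmark
  detection on synthetic B-scans.
* **ERG features** — a-wave amplitude (baseline → trough), b-wave
  amplitude (trough → peak), implicit times from flash onset; group
  mean ± SEM traces and tidy intensity-response tables.
* **Inner-retinal layer profiles** — columnwise intensity over a 150-px
  ROI band, IPL-thickness renormalization to the control mean, max
  normalization, and per-layer sums over the printed windows (ACL 1–90,
  IPL 91–300/91–330, GCL 301–390/331–455 for the 390/455-px schemes).
* **Relative expression** — 2^−ΔΔCt with replicate averaging, a
  housekeeping reference gene and a calibrator group (per timepoint), so
  the calibrator's geometric-mean fold is exactly 1.

Every input modality has a seeded generator (`sim_*()`) that attaches its
ground truth (`ground_truth()`), and `run_pipeline()` drives the whole
simulate → analyze → report loop from one config.

## Worked example

```r
library(zfeye)

out <- tempfile()
run_pipeline(demo_config(seed = 42), out)
cat(readLines(file.path(out, "report.txt")), sep = "\n")
```

```
zfeye pipeline report
=====================

Spatial-frequency tuning (log-Gaussian fits)
--------------------------------------------
  mutant     amplitude 0.708, peak 0.0623 c/deg, bandwidth 0.299
  wildtype   amplitude 0.998, peak 0.0613 c/deg, bandwidth 0.300
  => mutant shows the lower tuning amplitude (71% of wildtype)
  omnibus                F(3, 162) =  144.355, p = 1.485e-45
  nested:amplitude       F(1, 162) =  286.308, p = 1.217e-37
  nested:peak_frequency  F(1, 162) =    0.919, p = 0.3392
  nested:bandwidth       F(1, 162) =    0.018, p = 0.8945

Ocular biometry (Matthiessen's ratio)
-------------------------------------
  mutant     R/L 2.7 +/- 0.0099  (axial 923 um)
  wildtype   R/L 2.61 +/- 0.0092  (axial 900 um)
  => mutant vs wildtype: R/L shift +0.097 -> relative myopia
...
```

The demo simulates two cohorts of 14 fish in which the mutant group truly
has a 30% tuning-amplitude deficit and a +0.1 R/L elevation: the fitted
amplitudes recover the deficit (0.708 vs 0.998), the nested amplitude test
flags it while peak and bandwidth tests correctly do not, and the biometry
stage recovers the myopic shift (+0.097) with the right label. Piecewise
use is just as direct:

```r
ds <- sim_omr_cohort(
  tibble::tibble(group = c("wt", "mut"), amplitude = c(1, 0.7),
                 peak_frequency = 0.062, bandwidth = 0.3),
  n_fish_per_group = 14, seed = 1, return = "omi"
) |>
  average_trials() |>
  normalize_omi("wt", 0.0620)

fit_log_gaussian(ds[ds$group == "wt", ]) |> tidy()
omnibus_f_test(ds) |> glance()
```

Fitted objects have `tidy()`, `glance()`, `predict()` and `autoplot()`
methods; `plot_tuning_curves()` and `plot_erg_traces()` draw the standard
figures.

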