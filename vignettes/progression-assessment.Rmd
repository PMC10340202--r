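---
title: "Bidimensional vs volumetric progression assessment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidimensional vs volumetric progression assessment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranovol)
```

## The problem

Lower-grade gliomas (LGGs) are slow-growing, typically non-enhancing brain
tumors followed on serial T2/FLAIR MRI. The clinical progression criterion
(the RANO rule for LGGs) is bidimensional: on the axial slice with the
largest tumor cross-section, an operator draws the longest in-plane diameter
and the longest diameter perpendicular to it; progression is a >= 25%
increase of the product of the two diameters relative to a reference scan
(either the immediately previous scan or the baseline scan), with growth
declared when two of three clinicians agree. The competing quantitative arm
is 3D: segment the tumor on every slice, sum the cross-sectional areas,
multiply by the inter-slice distance, and test each new volume against the
subject's own history with a change-of-point procedure.

The bidimensional rule has structural blind spots: it sees one slice of one
connected component, so growth that is out-of-plane, infiltrative, or in
satellite lesions does not move the measured product. `ranovol` implements
both arms, the operator-variability and accuracy statistics used to compare
them, and a synthetic longitudinal cohort generator with known ground truth
so every claim in the pipeline is testable.

## The bidimensional engine

`bidiameter()` measures the largest 4-connected component of a slice.
The longest diameter `d1` is the exact maximum distance between
boundary-voxel centers, computed over convex-hull vertices (provably
equivalent to the exhaustive pair search, which the test suite also runs as
an independent oracle). The longest perpendicular diameter `d2` maximizes
distance over boundary pairs whose direction lies within a fixed +/- 5
degree tolerance of perpendicular to `d1`. Two numerical choices make the
measurement deterministic where a human would exercise judgment:

* ties in either diameter are broken by the lexicographically smallest
  endpoint pair;
* the perpendicularity tolerance is fixed (configurable) rather than left to
  discretion.

A single-voxel (or collinear) component cannot span a perpendicular chord;
both diameters then fall back to the voxel caliper width and the measurement
is flagged degenerate. The >= 25% threshold is applied inclusively by
default (`classify_growth(..., inclusive = TRUE)`): published phrasings
alternate between ">= 25%" and "more than 25%", so the boundary case is
configuration with an inclusive default.

Only the largest component is measured by design: satellite blindness is a
property of the bidimensional criterion that this package must reproduce,
not repair. The test suite asserts it as an invariant (adding a disjoint
smaller satellite never changes the measurement).

## Volumetrics and the change-of-point detector

`compute_volume()` is the slice-stack formula: summed foreground area times
the center-to-center inter-slice distance, in cm^3. It is additive over
disjoint components — satellites *are* counted, which is exactly where the
two arms part ways.

The change-of-point contract is that a new measurement is declared growth
when it differs significantly from all of the subject's prior measurements.
The concrete instantiation in `detect_change_point()` is a one-sided
prediction-bound scan:

* at candidate scan `k` (needing `min_prior = 3` earlier scans, mirroring
  the at-least-4-scans inclusion rule), fit a constant mean `m` and SD `s`
  to the prior volumes;
* floor `s` at 5% of `m` — a series digitized on a coarse grid can be
  noiseless, and a zero SD would make any increase "significant";
* declare growth at the earliest `k` whose volume exceeds
  `m + t(1 - alpha, k_prior - 1) * s * sqrt(1 + 1/k_prior)`, provided the
  exceedance persists at the next scan (or `k` is the last scan);
* detection is growth-only (one-sided), because the evaluation's ground
  truth is the first point of growth.

`alpha`, `min_prior`, the SD floor and the persistence rule are all exposed.
The procedure is scale-equivariant (multiplying all volumes by a positive
constant leaves the detected index unchanged); strict translation
equivariance does not hold because the SD floor is proportional to the mean.
Trend-following prior models (rather than a constant mean) would be a
reasonable alternative instantiation; constant mean is the documented
default and the Monte-Carlo suite pins its operating characteristics
(>= 95% correct-scan detection on an abrupt doubling with 5% noise; a
family-wise false-trigger rate at or below `alpha` plus binomial error on
stable series). One calibration choice deserves note: the final scan of a
series has no confirming follow-up, so it is exempt from the persistence
check — but an exemption at the full per-test level would push the
family-wise trigger rate of an 8-scan series visibly above `alpha` (the
unconfirmed terminal test contributes its whole level, on top of the rare
correlated double exceedances earlier in the series). The terminal test is
therefore taken at `terminal_alpha = alpha / 2`, a simple alpha-spending
rule that brings the measured family-wise rate to about 0.045 at
`alpha = 0.05` without touching mid-series power. Both levels are exposed.

## The segmentation sketch

The segmentation arm reproduces a published two-step sketch: decompose the
image into 8 regions ranked by intensity, then keep the regions brighter
than the gray-matter level. `decompose_regions()` represents each voxel by
soft Gaussian memberships over `n_bins = 8` intensity bins and factorizes
that non-negative voxel-by-feature matrix with multiplicative-update NMF
(implemented in-package; the objective trace is exposed and tested to be
non-increasing). Three numerical choices matter:

* **Bin width.** Bins are about as wide as a tissue class, so class-interior
  noise cannot profitably split one class across two components.
* **Anchored initialization.** Components are initialized at the modes of a
  kernel density estimate of the image intensities (extra components spread
  into the gaps, where they can die off). Without this, the dominant
  background class absorbs most components and the tumor — a few percent of
  the voxels — need not get one.
* **Characteristic intensity and threshold guard.** A segment's intensity is
  the bin center at the peak of its basis profile; it is therefore quantized
  to half a bin. `extract_tumor_mask()` compares it against
  `gray_level + bin_width/2` so that the gray-matter segment itself cannot
  quantize to "just above" its own level.

The level-set refinement of the original tool is out of scope; in its place
`extract_tumor_mask()` applies a morphological opening (removing the thin
scatter of noise-tail voxels), a closing (filling interior gaps), and
retains the largest component plus satellite components of at least 10
voxels. When the gray level is not known, `estimate_gray_level()` takes the
brightest major mode (>= 5% of voxels) of the intensity histogram — which
assumes the tumor is a minority class. All of these choices are validated
only through phantom Dice: the suite requires Dice = 1 on the noiseless
4-class phantom (without regularization) and Dice >= 0.90 at noise SD 5
against class contrast 40, with and without satellites.

## The synthetic cohort

The generator defines the study conditions for everything downstream.

* **Shape.** A subject is an ellipsoid (semi-axes ~18 x 14 x 10 mm, jittered
  +/- 15%) plus a low-order spherical-harmonic margin perturbation scaled by
  `margin_irregularity` (default 0.1): irregular enough to exercise the
  geometry, with an analytic volume at zero perturbation. Satellites are
  small spheres placed with a numerically checked clearance from the main
  surface (5 mm plus one grid step, so voxelization on coarse slices cannot
  bridge the gap).
* **Acquisition.** Axial stacks at 1 mm in-plane, 5 mm slices, 6.5 mm
  center-to-center — the median clinical FLAIR parameters of the cohorts
  this emulates; `sample_acquisition_params()` draws from the full reported
  ranges (thickness 1-6 mm, gap 0.6-7.5 mm).
* **Trajectories.** Eight scans at 0.5-year spacing (the year-scale of
  published delay analyses). Stable subjects keep constant true volume;
  growers switch abruptly after a change point sampled among scans 2-4, so
  that some onsets precede the change-point detector's minimum prior window
  — the structural source of small "test-first" (FP) leads — and every
  onset leaves enough follow-up for delayed detection to be observable.
* **Growth sites.** In-plane growers scale isotropically at +45% volume per
  scan (visible to the bidimensional rule); occult growers either stretch
  only the through-plane axis (+35%/scan) or grow satellites (+35%/scan)
  while the main lesion creeps at +12%/scan. The creep rate is chosen so
  the baseline-referenced product crosses 25% roughly three scans after
  volumetrics reacts — late, but within the series.
* **Operators.** Reads are multiplicative on diameters:
  `d * (1 + b_o + e)`, with a persistent per-operator bias
  (`inter_sd_frac = 0.15`) and per-read noise (`intra_sd_frac = 0.05`),
  truncated below at 10% of truth. The asymmetry mirrors reported rater
  behavior: between-operator products disagree widely while a single
  operator's serial comparisons are much tighter. Because growth calls
  compare two reads by the same operator, the bias cancels and the call
  noise is governed by the intra-operator term.
* **Visual arm.** Simulated raters threshold the true volume ratio with
  multiplicative perception noise (SD 0.1) and 2-of-3 consensus — a
  deliberately idealized stand-in for human visual assessment.

What the generator does **not** emulate: MR physics, bias fields,
registration error, infiltrative intensity gradients, rater drift, or
real LGG growth-rate distributions (which are not characterized by the
source material; the defaults are configuration, not biological claims).
Passing tests therefore demonstrate internal consistency of the methods
under these conditions, not clinical performance.

## Evaluation semantics

Confusion categories are timing-based and subject-level, keyed on
first-detection times: true negative when neither arm ever detects; true
positive when both detect at the same scan; false negative when the
reference standard detects first (including "test never detects"); false
positive when the test detects first. The reported overall accuracy is the
`TN% + TP%` identity. (The published table's fourth category label is
printed as "false positive" twice; its description — both methods at the
same time — identifies it as the true-positive row, and that reading is
adopted here.) `confusion_from_percent()` rebuilds integer subject counts
from printed percentages and recomputes the accuracy from counts, which is
how the published 66.67% / 65.08% / 20.97% / 56.45% figures are reproduced
exactly.

For a dichotomous predictor the ROC has one interior point, so
`AUC = (sensitivity + specificity)/2`, equal to the rank-statistic AUC (an
exhaustive pair-counting oracle in the tests). The AUC is tested against
0.5 with the one-curve DeLong variance; paired curves are compared with the
DeLong test (via pROC), with the degenerate identical-predictor case
defined as p = 1. Published volumetric-ground-truth AUCs (0.388 / 0.546)
are *not* reconstructible from the printed confusion table (the implied
balanced accuracies are 0.215 / 0.565); the package reproduces only the
visual-ground-truth AUCs (0.665 / 0.662) and documents the discrepancy
rather than resolving it.

Diagnosis delays are `t_test - t_ref` over false negatives and
`t_ref - t_test` over false positives, each non-negative by construction;
subjects where either arm never detects contribute no finite delay and are
excluded with their count reported. The two delay sets are compared with a
Wilcoxon rank-sum test (the concrete choice for an unnamed two-sample
comparison; named in the output).

## Problem sizes

The shipped defaults are chosen to keep a full desk run in minutes: the
demo cohort is 60 subjects by 8 scans on a 32 x 128 x 128 grid; the
change-point operating characteristics use 1000 stable and 400 step series;
geometry oracles run on 50 random blobs with at most ~400 boundary points.
All of them scale up by configuration.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(list(cohort = list(n_subjects = 12L)))
report <- run_pipeline(cfg, out_dir = "ranovol-demo")
print(report)
```

The report prints, per referencing mode, the timing-confusion accuracy of
the bidimensional arm against the visual and volumetric references and the
median FN vs FP diagnosis delays; the run directory holds the measurement,
call, volume and detection-time tables (TSV), the evaluation report (JSON)
and the resolved configuration (YAML).

## Known limitations

* The change-point procedure is *an* instantiation of the quoted contract,
  not the original reference implementation; its parameters are exposed and
  its operating characteristics are pinned by simulation instead.
* The NMF feature representation (intensity soft-binning) ignores spatial
  layout; spatial coherence enters only through the morphological
  regularization. This is faithful to the two-step sketch being
  implemented, not to the full level-set method it abbreviates.
* Segment characteristic intensities are quantized to the feature bins, so
  thresholds within half a bin of a class mean depend on the guard margin.
* The visual arm is synthetic by construction; nothing in this package
  models human perception.
* With tight intra-operator noise, previous-scan referencing rarely detects
  occult growth at all (those subjects are excluded from finite-delay
  medians); the delay-direction analysis is therefore most informative
  under baseline referencing, and the package reports both.
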