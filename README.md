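# ranovol

Automated bidimensional (RANO-style) tumor measurement and volumetric
change-of-point growth detection for longitudinal glioma imaging, with the
agreement, accuracy and diagnosis-delay statistics needed to compare the
two, exercised end-to-end on synthetic cohorts with known ground truth.

## The problem

Lower-grade gliomas are followed on serial T2/FLAIR MRI. The clinical
progression rule is bidimensional: on the axial slice with the largest
tumor cross-section, measure the longest diameter `d1` and the longest
diameter perpendicular to it `d2`; progression is a >= 25% increase of the
product `d1 * d2` (cm²) against a previous or baseline scan, with 2-of-3
clinician consensus. The quantitative alternative is volumetric: sum the
segmented cross-sectional areas over all slices, multiply by the
inter-slice distance, and flag the first scan whose volume is significantly
above the subject's own history (a change-of-point test). The
bidimensional rule is structurally blind to out-of-plane, infiltrative and
satellite growth; this package implements both arms and the statistical
machinery for quantifying that gap:

* geometry engine: exact longest-diameter / longest-perpendicular-diameter
  measurement on binary masks (convex-hull search with a ±5° perpendicular
  tolerance, deterministic tie-breaking), the 25% rule, k-of-n consensus;
* volumetrics: slice-stack volume and a one-sided prediction-bound
  change-of-point detector (`m + t_{1-α} · s · sqrt(1 + 1/k)`, SD floored
  at 5% of the mean, persistence-checked);
* segmentation sketch: an 8-component NMF of the intensity volume with
  segments ranked by intensity and thresholded at the gray-matter level,
  then morphological regularization;
* statistics: Pearson r² with interpretation bands, coefficient of
  variance, Bland–Altman percent differences, Cohen's kappa; timing-based
  confusion with the `TN% + TP%` accuracy identity; binary-predictor ROC
  (`AUC = (sens + spec)/2`), AUC-vs-0.5 testing, Youden operating point,
  paired DeLong comparison; median FN vs FP diagnosis delays;
* a synthetic cohort generator (ellipsoids with irregular margins,
  satellites, stable / abrupt-growth trajectories, simulated operator
  reads) that makes every stage testable without patient data.

## A worked example

```r
library(ranovol)

# a 4 cm digital disk on a single axial slice, 1 mm voxels
acq <- acquisition_params(1, 1, 1, c(5L, 64L, 64L))
mask <- array(FALSE, acq$grid_shape)
xy <- expand.grid(x = 1:64, y = 1:64)
sl <- matrix(FALSE, 64, 64)
sl[as.matrix(xy[(xy$x - 32)^2 + (xy$y - 32)^2 <= 20^2, ])] <- TRUE
mask[3, , ] <- sl
rano_measure(label_volume(mask, acq))
#> RANO measurement: slice 3, d1 = 4.00 cm, d2 = 4.00 cm, product = 16.00 cm^2

# the published worked example: 9.08 -> 9.43 cm^2 is only a 4% increase
classify_growth(9.43, 9.08)
#> $percent_change
#> [1] 3.854626
#> $call
#> [1] 0

# a volume series that doubles at scan 5 triggers the change-point test there
s <- volume_series("a", seq(0, 3.5, .5), c(10, 10.2, 9.9, 10.1, 20, 21, 20, 20.5))
detect_change_point(s)
#> Volume series a: 8 scans over 3.5 yr; change at 2.00 yr
```

The percent change of the diameter product (3.9%, printed to the nearest
percent as 4%) stays under the 25% rule, so the bidimensional call is "no
growth" — while a doubling of volume in the same kind of series is flagged
at the scan where it happens. Running the full demo pipeline,

```r
report <- run_pipeline(pipeline_config())   # 60 subjects, ~3 min
print(report)
#> Pipeline report: 60 subjects (36 growing), 0 failures
#>   [previous] vs visual: accuracy 76.66%; vs volumetric: accuracy 60.00%
#>   [previous] delay: median FN NA yr vs FP 0.50 yr
#>   [baseline] vs visual: accuracy 61.67%; vs volumetric: accuracy 63.33%
#>   [baseline] delay: median FN 1.00 yr vs FP 0.50 yr
```

the volumetric arm detects growth strictly before the bidimensional arm in
a majority of growing subjects, and late bidimensional detections (false
negatives) lag by more than early ones (false positives) lead — the
qualitative signature of single-slice measurement missing out-of-plane and
satellite growth.

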