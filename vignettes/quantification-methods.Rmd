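---
title: "Methods: redox imaging, morphometry, densitometry and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: redox imaging, morphometry, densitometry and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormquant)
```

wormquant implements the image-quantification computations used to compare
treatment groups in *C. elegans* aging experiments: ratiometric HyPer
H~2~O~2~-biosensor quantification with lifetime-gated autofluorescence
unmixing, mitochondrial %-area morphometry, Oil Red O fat densitometry, and
the cohort statistics applied to the resulting per-worm values. Every stage
is exercised against a synthetic-scene generator with known ground truth, so
the pipeline's recovery properties are tested, not assumed.

## HyPer redox quantification

### The unmixing model

The worm gut is strongly autofluorescent in the same emission band as the
HyPer sensor. Fluorescence-lifetime gating provides a third channel —
blue-shifted emission collected only at long photon-arrival times — that
contains autofluorescence and no sensor signal. The model assumes the
autofluorescence measured in each sensor channel is proportional,
pixel-by-pixel, to the autofluorescence channel:

$$F_{\mathrm{sensor\,channel}} = F_{\mathrm{signal}} + R \cdot F_{AF},$$

with one bleed ratio $R$ per channel per experimental group. In sensor-free
control animals $F_{\mathrm{signal}} \equiv 0$, so $R$ is estimated by
least squares through the origin over all pooled control pixels:
$\hat R = \sum F_t F_{AF} / \sum F_{AF}^2$. The fit has no intercept because
the correction formula has no offset term; `estimate_af_ratio()` offers a
free-intercept fit as a diagnostic only. A separate model is fitted per
experimental group so that drifts in laser power or detector gain between
imaging sessions are absorbed into each group's own $R$.

The corrected signal is $F = \max(F_{\mathrm{raw}} - R \cdot F_{AF},\, 0)$;
negative values are physically impossible signal and are clipped, with the
unclipped values retained in an attribute for diagnostics. By default only
the 405 nm-excited channel is corrected: after lifetime gating the
488-excited channel carries negligible autofluorescence, though a nonzero
$R_{488}$ can be supplied to test robustness.

### Per-worm summary

The redox readout is the corrected 488/405 ratio. For each animal the
focal plane is the z slice with the greatest combined corrected
fluorescence (405 + 488) inside the head ROI, ties resolved to the lowest
z. Within that plane two estimators are computed over valid ROI pixels:

* **ratio of sums** (default): $\sum F_{488} / \sum F_{405}$ — robust to
  dim pixels, equivalent to an intensity-weighted mean of per-pixel ratios;
* **mean of ratios**: the unweighted mean of per-pixel ratios — more
  sensitive to noise at dim pixels.

The acquisition protocol does not dictate which estimator to use, so both
are always reported; `mode` selects which one populates `roi_ratio`.

A pixel is *valid* when its corrected 405 denominator is at least
`denom_floor`. The default floor is 1% of the 99th percentile of corrected
405 within the ROI at the selected plane — large enough to suppress
ratio blow-up at near-zero denominators, small enough to retain virtually
all sensor-bearing pixels. INR renderings encode the ratio as hue on a
fixed perceptual colormap (clipped to the display range) and total signal
as brightness, with invalid pixels black.

### Plate-reader variant

For population-scale measurements, whole-well 405/488 fluorescence is
corrected by subtracting the mean of a sensor-free background group per
channel; wells whose corrected 405 is not positive are flagged invalid and
excluded from group means.

## Mitochondrial morphometry

Mitochondrial content is measured as thresholded percent area: project
`n_slices` consecutive optical sections (default 5, matching the
acquisition convention) by per-pixel maximum, then report
$100 \cdot |\{p \in \mathrm{mask}: I(p) \ge t\}| / |\mathrm{mask}|$ within
the operator-drawn cell boundary. The threshold policy is a config-fixed
absolute value applied identically to every image of an experiment; Otsu's
method computed from in-mask pixels only is offered as an automated
alternative, and the threshold actually used is always recorded in the
output. Because acquisition gain is typically maximized per image, a
shared absolute threshold interacts with gain variation; the function
warns when all in-mask intensities fall on one side of a fixed threshold,
the symptom of gross gain mismatch.

An optional Richardson–Lucy restoration step (`deconvolve_rl()`) is
provided, implemented with FFTs under periodic boundary conditions. It is
a standard multiplicative-update deconvolution, off by default; it is not
a replica of any particular acquisition software's regularized variant.

## Oil Red O densitometry

Oil Red O absorbs green light, so stain intensity is defined by inversion
of the green channel, $S = 255 - G$, after channel separation. Fat content
is the integrated density (sum of $S$, equivalently area × mean) over
pixels that pass the experiment-wide stain threshold *and* lie inside a
40-pixel-diameter circle placed by the operator over the anterior
intestinal cells. Circle membership uses the pixel-center rule (0-based
integer centers, boundary inclusive); out-of-image pixels contribute
nothing.

Uneven illumination is removed first by pseudo flat-field correction:
divide each channel by a heavily blurred copy of itself (Gaussian,
`sigma_px = 50` by default) and rescale. The rescale constant is
`max(B)` of the blurred channel rather than its mean: the vignette's upper
bound is the unattenuated illumination level, so anchoring to the blur
maximum places corrections of differently vignetted images on a common
intensity scale, which mean-anchoring does not (it preserves each image's
own global brightness, making images with different vignette strengths
incomparable). `rescale = "mean"` is available where single-image
brightness preservation is wanted.

A real limitation, visible in the tests: the blurred copy only tracks the
illumination field when the kernel is small relative to the image. At
micrograph-realistic scales (here 512 px images vs a 50 px kernel)
corrected integrated densities of one stain pattern under vignettes
spanning 0.6–1.0 agree to a fraction of a percent, while uncorrected
densities differ by tens of percent; on images only ~2.5 kernel widths
across, curvature and boundary bias in the blur leave several percent of
residual disagreement.

## Cohort statistics

Per-worm values are pooled across independent experiments after
normalizing each experiment to the mean of its own control group
(`relative_values()`; control rows normalize to mean 1, and the operation
is idempotent). Group comparisons use:

* two-sided two-sample t-tests with Bonferroni correction
  ($p_{adj} = \min(1, m\,p)$), Welch by default since equal variances are
  rarely defensible; a pooled-variance option exists for fidelity to the
  classical test. `m` defaults to the number of requested comparisons.
* one-way ANOVA with Bonferroni-corrected pooled-variance post-hoc pairs.
* the Wilcoxon rank-sum test for lifespan cohorts.
* scored proportions (e.g. % of animals with nuclear reporter
  localization), compared at the level of per-experiment percentages — the
  replicate unit is the experiment, not the worm.

Lifespan tables carry an `excluded` flag (lost or bagged animals) honored
by every operation; ruptured animals are retained as an age-related death.
No censoring machinery is implemented because complete death times are
analyzed.

### Rank-sum details

Death days are heavily tied (cohorts are scored every 1–3 days), so the
test uses midranks throughout. For combined $n \le 20$ the two-sided p is
computed by exhaustive enumeration of all $\binom{N}{n_a}$ rank
assignments — exact under arbitrary ties; two-sided means doubling the
smaller tail, capped at 1. Larger cohorts use a continuity-corrected
normal approximation sharpened by an Edgeworth expansion whose skewness
and kurtosis terms come from the exact finite-population moments of the
midrank sum (an $O(N)$ computation that adjusts for ties automatically).
The switch at 20 keeps paper-scale cohorts (tens to hundreds of animals)
on the fast path while letting test suites exercise the exact oracle. At
the smallest cohort sizes the exact two-sided p is a step function with
jumps near 0.03, which bounds how closely any smooth approximation can
track it pointwise; in operation the approximation is only reached beyond
the exact range, where its error is below 0.01.

## The synthetic-scene generator

`make_hyper_scene()`, `make_mito_scene()`, `make_oro_scene()` and
`make_lifespan_cohorts()` generate inputs with stored ground truth. They
emulate the *statistical structure* each stage assumes, not worm optics:

* **HyPer scenes**: autofluorescence as a sum of broad Gaussian blobs
  (smooth, positive, structureless — amplitude 50–150 counts by default),
  a sensor-bearing elliptical "head" with 488-channel brightness
  `sensor_mean` (300 counts) and 405 brightness `sensor_mean`/ρ so the
  true ratio field is exactly ρ, per-channel bleed `r_true` (0.35 into
  405, 0 into 488), and Poisson counting noise (gain 1) with optional
  Gaussian read noise. Sensor-free control subjects share the AF
  statistics. The acquisition protocol reports no intensity statistics,
  so these levels are engineering choices exposed in the parameters.
  The 405 = `sensor_mean`/ρ realization reflects oxidation depleting the
  405-excitable sensor fraction; it is what makes an uncorrected 405
  denominator bias compress between-group ratio contrasts, the failure
  mode the unmixing exists to prevent.
* **Mito scenes**: tubules as dilated random walks placed on single z
  slices, amplitude 500 counts, slice-wise Gaussian PSF blur, Poisson
  noise; the true %-area is counted on the pre-blur binary mask.
* **ORO scenes**: uniform stain plateaus absorbing green (and partially
  blue/red) from a white 8-bit background, under a radial multiplicative
  vignette spanning `vignette_range`; ground truth is pre-vignette.
* **Lifespan cohorts**: Gompertz death times (default shape 0.35/day,
  rate 0.003/day — median ≈ 13 days, typical of wild type at 25 °C),
  rounded *up* to the next scoring visit (default every 2 days),
  reproducing interval censoring by rounding.

All generators are bit-reproducible under a fixed seed, and ground-truth
fields are never touched by downstream stages. What passing tests on these
scenes shows is that the *computations* recover known truth under the
assumed structure (proportional bleed, smooth AF, multiplicative
vignette, Gompertz mortality); they cannot validate the assumptions
themselves against real tissue, nor anatomy-dependent steps such as head
outlining or circle placement, which remain operator input.

## Numerical conventions

* Voxel arrays are indexed `(z, y, x)`; z indices are 1-based in the R
  API; ROI/circle coordinates are 0-based pixel centers, and a pixel
  belongs to a polygon or circle iff its center lies inside or on the
  boundary.
* TIFF stacks store samples in `[0, 1]`; the declared `max_value`
  (default 65535) makes integer data round-trip bit-exactly. Channel
  identity comes from declared channel names, never plane order.
* Focal-plane ties go to the lowest z; Otsu thresholds are computed from
  in-mask pixels only; flat-field blurs use replicate boundaries with the
  kernel capped to the image size.
* Suite problem sizes: 64×64×7 stacks with 8 control subjects for
  unmixing recovery, 6 worms per group for end-to-end ratio recovery,
  512×512 ORO scenes, 1000 replicate null cohorts of 50 animals per group
  for the type-I error check.

## Known limitations

* Single-autofluorophore model: one AF channel, one bleed ratio; spectral
  unmixing with several autofluorophores is out of scope.
* HyPer ratios are reported as-is, not calibrated to absolute H~2~O~2~
  concentration.
* Flat-field correction assumes the illumination field varies slowly
  relative to both the stain features and the blur kernel, and the kernel
  must be small relative to the image (see above).
* No Kaplan–Meier/right-censoring machinery; `excluded` simply removes
  animals.
* The Richardson–Lucy step uses periodic boundaries; signals supported
  near stack edges will wrap.
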