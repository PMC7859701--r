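---
title: "Methods: quantifying transition-zone phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transition-zone phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tzpheno)
```

This vignette is the package's own account of its models, estimators and
design choices. The package grades hypomorphic ciliopathy alleles by
quantifying (i) how much of a tagged transition-zone (TZ) protein reaches
the TZ, (ii) how it is distributed there, and (iii) the downstream
ciliary phenotypes (dye filling, roaming, osmotic avoidance), with a
normality-gated statistical layer on top. Because the microscopy data
such studies rest on are rarely deposited, every estimator here is
validated against a synthetic-scene generator with exact ground truth.

## Architecture

The package is a base-R analysis toolkit, not a single fitted model:
there is no one estimator a classed "fit object + methods" design would
orbit around. Value objects (`plane_image`, `volume_stack`,
`intensity_profile`, `scene_truth`, `tz_scene`, `compartment_model`,
`tz_comparison`) are lightweight S3 classes with `print` methods, and the
closest analogue of a model object is the `tz_comparison` returned by
`compare_groups()`, which carries `print`/`summary` methods.

## Wide-field quantification

**Line profiles.** `extract_line_profile()` samples an image along a
user-supplied polyline (first anchor = proximal end) at one-pixel steps
by bilinear interpolation, averaging `width_px` perpendicular samples.
One pixel is 0.08 µm at the wide-field calibration, so a 1.6 µm scan is
the 20-sample profile used in axial-distribution figures. The default
line width for the primitive is 1 px (the common interactive default);
the pipeline-level `measure_tz_widefield()` averages 3 px because, at the
low amplitudes of severe variants, a single-pixel scan occasionally fails
to produce clean half-max crossings.

**FWHM length.** The half-max level is `baseline + (max - baseline)/2`
with the profile minimum as default baseline (profiles are taken on raw
images; no separate background subtraction enters the length metric).
The length is the distance between the *outermost* half-max crossings
flanking the global maximum, linearly interpolated between samples —
outermost, because axial modulation can push interior dips below the
half-max level without shortening the TZ. The estimator is invariant to
affine intensity rescaling when the baseline is rescaled identically.

**Box intensity.** `integrated_box_intensity()` sums a 40×40 px box
centred on the annotated TZ position, grows it by one pixel per side,
and uses the resulting one-pixel ring (164 px) as the local background
estimate. The ring is centre-symmetric about the box, so the net value
is exactly unbiased under constant and linear backgrounds; this is
verified by construction in the tests. Negative net values are retained
so group means stay unbiased. The box is placed on the user-annotated
centre (for simulated scenes, the known TZ centre); the TZ pair of a
phasmid neuron is measured jointly in one box.

**Normalisation and competition.** Values are divided by the reference
(wild-type) group *mean* (a `center = "median"` option exists, since the
convention is not universal). The competition index is
`100 × mean(het) / mean(homo)`; under the two-allele competition model
with incorporation efficiencies $k_t, k_u$ the expected index is
$100\,k_t/(k_t+k_u)$, i.e. exactly 50% for equally competent alleles,
100% when the untagged allele cannot compete, and 0% when the tagged
protein is not recruited.

**Asymmetry.** `asymmetry_index()` is this package's quantification of a
qualitative "proximally enriched" phenotype: the fraction of
background-subtracted signal *inside the FWHM window* lying in the
window's proximal half (0.5 = symmetric). Note the window adapts to the
signal: a profile whose mass is a single proximal spike has a narrow
window and scores 0.5, not 1 — the index measures skew within the
detected signal extent, not location within the scan. For a
right-triangle profile the index is 7/12 ≈ 0.58; it increases
monotonically as an exponential proximal decay sharpens over the ladder
of decay scales (∞, 2, 1, 0.5 µm) exercised in the tests, and the
G155S-like simulated condition scores clearly above 0.5.

**Leakage.** Periciliary-marker leakage into the cilium is measured on a
cross-section-*integrated* profile: at each arc position the channel is
summed across a perpendicular window (25 px) wide relative to the PSF.
Lateral blur conserves this integral, so a uniform in-cilium line source
of amplitude A reads A per pixel of arc length regardless of the PSF —
a centre-line average would read only ~30% of it at the wide-field PSF.
Background is the mean of the same summed profile over the final 0.5 µm
of the trace (beyond the tip, clear of tip smear), and the value is
reported at 4 µm from the base (RPI-2 convention) or averaged over
2–4 µm (TRAM-1 convention).

## Super-resolution volumetrics

Stacks (26.7 nm px, 0.2 µm z-steps) are linearly resampled to a 0.1 µm
modelling step. `segment_compartment()` estimates background as the
modal intensity (256-bin histogram — robust for mostly-empty stacks),
thresholds at background + 0.5 × (max − background) (configurable, and
recorded in the output, since commercial surface-rendering settings are
not standardised), and keeps the largest 26-connected component
(26-connectivity keeps thin shells connected). Volume is voxel count ×
voxel volume, monotonically non-increasing in the threshold.

The axial profile is the background-subtracted intensity summed, per
axial position, over the compartment's cross-sectional (y, z) footprint
taken from *all* thresholded components: severe variants are
discontinuous along the TZ, and a largest-component or per-voxel-masked
profile would delete or nonlinearly crush their dim distal peaks.
`axial_peak_count()` counts local maxima (plateaus collapsed, values
quantised at 1e-9 of the range to avoid float-tie artifacts) with
topographic prominence ≥ 20% of the profile's dynamic range — a
threshold that separates the wild-type 3–4-peak pattern from noise at
the simulated SNR while rejecting shallow ripple. At the 148.6 nm PSF,
4 peaks over a 0.8 µm TZ (0.2 µm period) sit at the resolution limit:
at the default 50% modulation depth the blurred ripple falls below the
prominence criterion, at full depth it is counted; the recovery studies
therefore use 3 peaks as the wild-type-like condition (within the 3–4
range wild-type TZs display).

`hollowness()` bins voxels by radial distance from the cilium axis
(x–y from a polyline, z at the intensity-weighted centroid) and returns
the background-subtracted core mean (radius ⅓ of the shell-peak radius)
over the shell-annulus mean. Solid signals peak on the axis and score
≈ 1; ideal shells score < 0.2; PSF-blurred 0.125 µm shells score ≈ 0.8.
A flat or monotonically increasing radial profile raises a "no shell
peak" error.

## The synthetic-data generator

`scene_truth()` + `simulate_phasmid_scene()` define the study
conditions; their defaults are fixed once and are not tuned per test:

| parameter | default | rationale |
|---|---|---|
| `tz_length_um` | 0.8 | typical measured TZ length in these neurons |
| `tz_shell_radius_um` | 0.125 | below wide-field resolution, resolvable at super-res (so the hollow core appears only there) |
| `tz_shell_thickness_um` | 0.06 | protein-layer-scale shell |
| `axial_peak_count` / depth | 3 / 0.5 | wild-type-like periodic pattern; envelope `1 − m·cos(2πPx/L)` keeps all P peaks interior so P is exact ground truth |
| `asymmetry_decay_um` | none (WT), 0.8 (G155S-like) | proximal enrichment of severe variants |
| `tz_amplitude` | 400 (wf) / 500 (sr) | photons/pixel giving centre-line SNR ≳ 10 over the 10-photon background |
| `psf_fwhm_um` | 0.25 (wf) / 0.1486 (sr) | typical 1.40 NA wide-field PSF; lateral resolution of the emulated super-res acquisition |
| `psf_axial_fwhm_um` | = lateral | stacks emulate *deconvolved* data with near-isotropic effective PSF; raw confocal axial blur (~2.5× worse) can be set explicitly |
| `pixel_size_um` | 0.08 / 0.0267 | 20 px = 1.6 µm; pixel size of the emulated super-res acquisition |
| `z_step_um` | 0.2 | acquisition step (modelling resamples to 0.1) |
| noise | Poisson + read σ = 2 | photon statistics plus camera noise, clipped at 0 |

Rendering details that matter: emission occupies pixel centres on the
half-open interval `[x0, x0 + L)` so a length-L segment emits from
exactly L/px pixels (length calibration is exact); the super-res shell
is antialiased by 4×4 radial subsampling so the thin band's emission
density is uniform (nearest-voxel rasterisation creates ±25% hot-spots
that corrupt max-based thresholds); the PSF kernel is truncated at 4σ
and renormalised, so convolution conserves photons to < 0.1%; z-slices
are point samples of the blurred object (optical sections), not slab
integrals. Scenes render a single phasmid cilium; the "TZ pair" box
measurement is emulated by the box capturing all TZ signal.

The two preset conditions (`condition_truth()`) are: **wt** — full
amplitude, 3 interior peaks, uniform envelope; **g155s** — 25%
amplitude, 2 peaks at full modulation depth (the severe variant's signal
is discontinuous along the TZ), 0.8 µm proximal decay.

The behavioural generator draws dye categories from an explicit
5-category distribution, roaming counts from a negative binomial (so
overdispersion relative to Poisson is representable), and escape times
from an exponential hazard right-censored at 10 min, split over 3
trials.

**What the generator does not emulate:** optical aberrations and
field-dependent PSFs, spectral bleed-through, photobleaching, stage
drift, annotation error (lines and centres are exact), TZ-to-TZ
biological variability within a genotype beyond photon noise, and any
TEM-level ultrastructure. Passing recovery tests therefore demonstrates
correctness of the estimators under the stated forward model, not
robustness to every real-world nuisance.

## Statistical layer

`compare_groups()` applies a Shapiro–Wilk test per group and uses
one-way ANOVA + Tukey's HSD (Tukey–Kramer on unequal n, via
`stats::aov`/`TukeyHSD`) when *all* groups pass at 0.05, otherwise
tie-corrected Kruskal–Wallis (`stats::kruskal.test`) + Dunn's pairwise
z-tests on the pooled ranks with Bonferroni adjustment over all pairs.
The gate rule ("all groups pass ⇒ parametric") and the Dunn correction
are design choices recorded in the result object; a `force_test`
override is honoured and flagged. Dunn's test is implemented in-package
(no implementation is available among the dependencies) and is checked
against direct rank arithmetic and a permutation oracle. Calibration:
over a 2000-replicate 4-group null simulation the full gated pipeline's
omnibus type-I error at α = 0.05 lies within [0.03, 0.07], and a 75%
intensity reduction at n = 44 and 30% CV is detected in ≥ 95% of
replicates.

## Numerical choices and degenerate inputs

Profiles failing to rise above baseline, or truncated at an edge before
crossing half-max, raise errors rather than return guesses. Identical
groups give F = 0, p = 1; zero within-group variance is an error, as are
all-identical values for rank tests and sub-3 groups for the normality
gate. The box measurement rejects placements whose outer ring leaves the
image. Scene parameters are validated with messages naming the offending
field. All simulation entry points take integer seeds and are
bit-reproducible; `run_pipeline()` derives per-scene seeds as
`seed + 1000·genotype + scene`, keeps timestamps out of `summary.json`,
and re-runs of an identical config reproduce it byte-for-byte.

## Problem sizes used in validation

Wide-field recovery uses 50 scenes (median FWHM within 10% of the
PSF-broadened truth; median net-intensity error under 2× its Poisson
standard error; equal-competition cohorts at 50 ± 5%). Super-res shape
recovery uses 100 stacks per condition (axial peak count correct in
≥ 90%). The statistical null uses 2000 replicates, and the end-to-end
direction check 10 replicate cohorts of 10 scenes per genotype plus 4
stacks per genotype. These sizes make the whole suite run in a few
minutes on a single core while keeping Monte-Carlo error well inside
the asserted margins.

## Known limitations

* **Thin-shell volumes are underestimated at the acquisition z-step.**
  With an isotropic 148.6 nm PSF, the blurred 0.06 µm shell has a radial
  half-max band of ≈ 0.15 µm, whose polar arcs fall *between* 0.2 µm
  z-slices; the thresholded volume recovers only ≈ 78% of the
  continuous-space half-max volume, and no estimator working from the
  acquired stack can restore the unsampled arcs. Relative and ordinal
  volume comparisons between conditions are unaffected and are what the
  pipeline relies on; absolute volumes should be read with this bias in
  mind.
* Absolute agreement with commercially rendered volumes is out of reach
  because those surface-creation parameters are unpublished; the
  threshold fraction here is explicit and recorded instead.
* The hollow-core ratio of a severe variant shifts towards 1 relative to
  wild type but does not cross it under the simulated conditions; "loss
  of hollowness" is therefore assessed as that shift, matching the
  qualitative "not always observed" character of the phenotype.
* The asymmetry index is windowed by the FWHM; profiles whose entire
  signal is one narrow peak are, by construction, symmetric within their
  own window.
* Annotations (lines, centres, point sets) are inputs, as in the manual
  workflow this package systematises; there is no automated TZ
  detection, deconvolution, or flat-field correction.
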