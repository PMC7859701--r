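# tzpheno

Quantitative phenotyping of ciliary transition-zone (TZ) defects in
*C. elegans* from fluorescence microscopy and behavioural assays.

## The problem

Missense variants in ciliopathy genes such as *mksr-2*/B9D2 do not abolish
the encoded protein; they degrade how well it is recruited to, and
organised within, the ciliary transition zone — the gate at the base of
the cilium. Grading such hypomorphic alleles requires quantitative
readouts rather than presence/absence calls:

* **TZ signal length** — full width at half maximum (FWHM) of a
  fluorescence line scan along the ciliary axis:
  the half-max level is `baseline + (max - baseline)/2` and the length is
  the distance between the outermost half-max crossings flanking the peak.
* **TZ fluorescence level** — integrated intensity in a 40×40 px box
  around the TZ pair, background-corrected with the surrounding 42×42 px
  ring (164 ring pixels), then normalised to the wild-type mean. The ring
  is centre-symmetric, so the estimate is exactly unbiased under constant
  and linear background gradients.
* **Allele competition** — in heterozygotes, tagged and untagged protein
  pools compete for TZ docking sites. With incorporation efficiencies
  k_t and k_u, the tagged signal is `k_t / (k_t + k_u)` of the tagged
  homozygote's; equal efficiency predicts exactly 50%, reported as a
  *competition index* (heterozygote fluorescence as % of the homozygote).
* **Axial distribution** — mean ± s.d. line-scan profiles (20 px = 1.6 µm
  at the wide-field calibration), a proximal-enrichment asymmetry index,
  and, at super-resolution (26.7 nm px, 148.6 nm PSF, 0.2 µm z-steps),
  compartment volume, axial peak count (topographic prominence ≥ 20% of
  the dynamic range) and hollow-core assessment (core/shell intensity
  ratio < 1).
* **Behavioural assays** — dye-filling category histograms (0–4 filled
  phasmid neurons), wild-type-normalised roaming indices, and
  osmotic-avoidance retention curves censored at 10 min.
* **Statistics** — a Shapiro–Wilk normality gate per group dispatches to
  one-way ANOVA + Tukey's HSD or Kruskal–Wallis + Dunn's test
  (Bonferroni), α = 0.05.

Because such image datasets are rarely deposited, the package ships a
**synthetic-scene simulator** with exact ground truth (hollow-shell TZ
with cosine axial modulation and optional proximal decay, pan-ciliary
marker, periciliary leakage channel; Gaussian PSF, Poisson + read noise),
so every estimator is validated by parameter recovery.

## Worked example

```r
library(tzpheno)

# one simulated wild-type-like wide-field scene, quantified
truth <- condition_truth("wt", "widefield", seed = 1)
scene <- simulate_phasmid_scene(truth)
measure_tz_widefield(scene)
#>   fwhm_length_um net_intensity asymmetry_index
#> 1      0.7903303      6843.495       0.5123904

# 12 scenes per genotype: severe-variant-like vs wild-type-like
wt  <- do.call(rbind, lapply(1:12, function(i) measure_tz_widefield(
  simulate_phasmid_scene(condition_truth("wt", "widefield", seed = i)))))
mut <- do.call(rbind, lapply(1:12, function(i) measure_tz_widefield(
  simulate_phasmid_scene(condition_truth("g155s", "widefield", seed = 100 + i)))))

competition_index(mut$net_intensity, wt$net_intensity)
#> [1] 14.6

compare_groups(list(WT = wt$net_intensity, G155S = mut$net_intensity),
               metric = "net_intensity")
#> Multi-group comparison of 'net_intensity' (2 groups)
#>   test: anova_tukey | omnibus F = 1580, p = 5.56e-22 (alpha 0.05)
#>   normality gate: parametric (min Shapiro-Wilk p = 0.118)
#>   significant pairs: 1 of 1
```

The recovered FWHM (0.79 µm) matches the simulated 0.8 µm TZ; the
severe-variant group retains ~15% of wild-type fluorescence (the
simulated truth is 25% amplitude, further reduced by its proximal decay),
and the normality-gated comparison lands on ANOVA + Tukey with an
adjusted p ≪ 0.05.

The full pipeline (simulate → quantify → compare → report) is driven by a
config list or YAML file:

```r
run_pipeline(list(
  mode = "simulate", modality = "widefield", seed = 1,
  metrics = c("fwhm_length_um", "net_intensity", "asymmetry_index"),
  reference = "WT", output_dir = "out",
  genotypes = list(WT    = list(condition = "wt",    n_scenes = 10),
                   G155S = list(condition = "g155s", n_scenes = 10))))
```

which writes `metrics.csv`, `comparisons.csv`, a deterministic
`summary.json` and a `run.log`.

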