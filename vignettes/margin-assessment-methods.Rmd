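---
title: "Methods: quantitative spectral-imaging margin assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative spectral-imaging margin assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginsense)
```

## The problem

During breast-conserving surgery the surgeon removes the tumor plus a rim of
normal tissue; if malignant cells reach (or come within 2 mm of) the specimen
surface, the margin is *positive* (or *close*) and the patient typically needs
repeat surgery. Quantitative diffuse reflectance imaging maps three optical
parameters over each excised margin at 5 mm pixel pitch: β-carotene
concentration \[µM\] (an absorber stored in adipocytes, i.e. a fat proxy),
total hemoglobin \[µM\], and the wavelength-averaged reduced scattering
coefficient ⟨µs′⟩ \[cm⁻¹\] (a collagen/glandular-density proxy). Residual
carcinoma displaces fat with fibroglandular and malignant tissue, so the local
landscape shifts toward **low β-carotene and high ⟨µs′⟩**; the ratio
β-carotene/⟨µs′⟩ \[µM·cm\] condenses this into a single fat-to-glandular
contrast and is the pipeline's primary discriminator.

`marginsense` implements the downstream analysis of such maps: distributional
feature reduction, blocked-permutation eCDF statistics, a breast-density
stratified conditional inference tree (CIT) with permutation significance, and
adipocyte morphometry from histology images — together with a synthetic-cohort
generator that emulates the statistical structure the analysis assumes, so
every stage can be validated against recorded ground truth.

## Feature reduction: 5 maps → 105 → 15 variables

Each margin's five maps (three measured + two ratios) are reduced to scalar
image-descriptive variables three ways:

1. **Image median** of the finite pixels.
2. **Fraction of pixels strictly below a threshold**, for 19 thresholds per
   parameter placed at the 0.05–0.95 quantiles (0.05 steps) of the *pooled*
   pixel vector of all margins. Pooled quantiles split the observed data
   evenly, unlike range-based grids which chase outliers. The
   linear-interpolation (type 7) quantile rule is used; strict `<` matches the
   convention "% image pixels < threshold".
3. **Two-sample Kolmogorov–Smirnov statistic** between the margin's pixels and
   the pooled pixels of all close+positive margins (the *positive reference*).
   A margin whose distribution mimics the positive pool scores near 0 and is
   thereby *more* suspicious.

That is 5 × (19 + 1 + 1) = **105** variables. Per parameter, the single
threshold whose fraction-below column best separates positive/close from
negative margins (minimum Wilcoxon rank-sum p; ties resolve to the lower
quantile) is retained, leaving 5 × 3 = **15** final variables. No
multiple-testing correction is applied inside the scan — the minimum-p column
*is* the selection rule being reproduced; its optimism is charged globally by
the permutation significance procedure below, which re-runs the selection on
every permuted label vector. By the same reproduced convention, the threshold
grid and positive reference include every margin (also the one being
described); a leave-one-margin-out reference is available via
`positive_reference(exclude_margin_id=)` but is off by default.

## Distributional statistics

`ks_two_sample()` computes D = supₓ|F₁(x) − F₂(x)| on the pooled support,
handling ties exactly. Pixels within a margin are spatially correlated, so
inference never treats pixels as independent: `blocked_permutation_pvalue()`
permutes group labels over whole margins (blocks), letting pixels travel with
their margin, and reports the add-one estimator
p = (1 + #{D\* ≥ D}) / (n_perm + 1), which never returns 0 and is valid for
any finite number of permutations. The permutation unit is the margin — the
only structure-preserving choice consistent with the purpose of blocking.
Default `n_perm = 1000`.

`wilcoxon_rank_sum()` uses midranks for ties everywhere; for combined n ≤ 12
the two-sided p comes from exact enumeration over all assignments of the
observed midranks (so ties are handled exactly, which off-the-shelf exact
implementations refuse), otherwise from the normal approximation with tie
correction and 0.5 continuity correction. The two branches agree within
|Δp| ≤ 0.02 at the crossover.

## The stratified conditional inference tree

Mammographic breast density (MBD 1–4) shifts baseline optics: denser breasts
show higher β-carotene and higher ⟨µs′⟩ in *cancer-free* tissue. The
classifier therefore splits **first** on density group (MBD 1–2 = low,
3–4 = high) — a fixed stratum split, not a data-driven one — and grows a
conditional inference tree inside each stratum:

* each candidate variable is tested against the binary diagnosis with the
  Wilcoxon rank-sum (the conditional-inference association test for a numeric
  variable vs a binary response);
* p-values are Bonferroni-adjusted across the candidates; growth stops when
  the smallest adjusted p exceeds `alpha` (default 0.05);
* the winning variable is split at the cutpoint maximizing the standardized
  two-sample linear statistic over midpoints of its sorted unique values,
  subject to `min_leaf` (default 7) cases per side;
* leaves carry majority labels, ties resolving to *negative* (a tie carries no
  evidence of malignancy, and the cost of a false alarm is re-excision).

When several variables separate the classes perfectly, a rank test saturates:
their p-values collide at the enumeration floor and differ only through
tie-correction noise, making "minimum p" an arbitrary pick. Exact ties in the
adjusted p are therefore broken by the standardized linear statistic with
identity scores — a continuous, scale-free effect size from the same
conditional-inference family. Defaults (`alpha = 0.05`, Bonferroni,
`min_leaf = 7`, `max_depth = 5`) are conventional and recorded in the model
JSON.

Performance is summarized by resubstitution sensitivity, specificity, PPV,
NPV, and accuracy (`confusion_metrics()`; zero-denominator ratios are
reported as `NA`, never 0). Resubstitution is deliberate: the quantity being
reproduced is an in-sample estimate of model accuracy, and the honesty check
lives in the permutation test, not in cross-validation.

## Model significance

`model_significance()` shuffles the margin diagnosis vector without
replacement and **rebuilds the entire model** per permutation — threshold
selection, variable selection, tree growth — then compares the discrepancy
F = (1 − Se)² + (1 − Sp)² of observed vs permuted models. Two estimates are
returned:

* `p` (primary): the add-one, tie-inclusive estimator
  (1 + #{F\* ≤ F}) / (n_perm + 1). Because resubstitution F takes few distinct
  values (every confusion table maps to an atom; fits that make no split
  collapse to majority-leaf atoms), an estimator that excludes ties is
  anti-conservative — in pure-noise simulations it rejected at ~25% at nominal
  0.05. The add-one tie-inclusive form is valid for any finite `n_perm` and is
  the same convention the blocked KS test uses.
* `p_strict`: the plain fraction #{F\* < F} / n_perm — the probability that a
  permuted model strictly outperforms the observed one — kept for
  comparability with the classical description of the procedure.

## Adipocyte morphometry

High-density breasts show smaller, more densely packed adipocytes, which is
the proposed mechanism for their higher β-carotene per pixel (more
membrane-bound carotenoid stores per unit volume). `segment_adipocytes()`
measures this from RGB histology images (1.1 µm/pixel): green channel →
bilateral filter (spatial σ 3 px, range σ 0.1 of dynamic range) → Canny edges
(Gaussian σ 1.5, hysteresis 0.1/0.2 of the gradient maximum) → morphological
closing → fill → erosion by the closing brush → connected components → area
gate **129.3–22,569 µm²** → count, density (cells/mm²), per-cell areas.

Numerical choices that matter:

* A membrane produces a *double* Canny contour (interior→membrane and
  membrane→stroma transitions). A 5 px disc-shaped closing merges the two
  rings into one solid band; the subsequent erosion by the same brush undoes
  the closing's outward dilation, so the measured region sits at the outer
  membrane contour and the area approximates πr². A box brush of the same
  width reaches further diagonally and can bridge adjacent cells across a thin
  stromal septum; the disc shape avoids this.
* "Interior of each outlined shape" is read as the filled outer outline — the
  membrane belongs to the cell.
* Regions touching the border are kept by default (`exclude_border = FALSE`).
* Filter/edge parameters have no canonical published values; the defaults here
  were calibrated only against the synthetic fixtures and are all exposed in
  `morphometry_config()`.

`compare_density_groups()` applies Wilcoxon rank-sum tests to per-image cell
density and mean area between density groups.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes — it is a
validation instrument, not a physical simulation. Per margin:

* **Tissue landscape**: Gaussian-smoothed white noise (correlation length 2
  px ≈ 10 mm patches) ranked and cut at class-proportion quantiles gives
  spatially clustered adipose / fibroadipose / fibroglandular tissue; default
  map shape 8×12 px at 5 mm pitch (24 cm², inside the typical 20–40 cm² margin
  range).
* **Class distributions**: lognormal (right-skewed, positive), medians
  ordered adipose > fibroadipose > fibroglandular > malignant for β-carotene
  (12/7/3/1.5 µM — adipose ≈ 4× fibroglandular) and the reverse for ⟨µs′⟩
  (7/10/14/17 cm⁻¹). These are qualitative emulation defaults; no calibrated
  class-conditional values exist for the study cohort, only orderings.
* **Malignant patch**: positive and close margins carry one contiguous patch
  (nearest pixels to a random center under a randomly stretched metric)
  occupying a fraction drawn from (0.15, 0.45). *Close* margins reuse the
  positive landscape with patch parameters attenuated on the log scale toward
  fibroglandular values (weight 0.6 toward malignant) — sub-surface disease
  seen through overlying benign tissue, which is why close margins are harder
  to detect.
* **Between-margin variability**: a lognormal baseline factor *shared* by all
  three measured parameters (sdlog 0.20) plus small independent per-parameter
  factors (sdlog 0.08). The shared factor models inter-patient composition and
  probe-coupling scale differences and *cancels in the ratio maps* — the
  standard rationale for ratiometric reflectance parameters, and the mechanism
  that makes β-carotene/⟨µs′⟩ the robust discriminator here.
* **Density effects**: high-MBD margins multiply β-carotene in the
  fat-bearing classes (adipose, fibroadipose) by 1.6 and ⟨µs′⟩ globally by
  1.3, with a small composition shift (+0.05 fibroglandular). Applying the
  β-carotene boost only to adipose while also shifting composition toward
  fibroglandular would drag the pooled β-carotene eCDF in the wrong
  direction; boosting both fat-bearing classes keeps the pooled shift
  consistent with the density effect the classifier exploits.
* **Mixes**: labels and density groups are allocated by round-half-up
  (`floor(n·f + 0.5)`), default 52% close+positive (half of those close) and
  45% high MBD; MBD scores within groups draw 1/2 at 0.3/0.7 and 3/4 at
  0.78/0.22, roughly the typical clinical mix. Every margin's seed derives
  deterministically from the master seed; regeneration is bit-identical.

The adipocyte generator places non-overlapping disks by random sequential
adsorption (lognormal radii, default CV 0.15; means 32 µm low-MBD / 22 µm
high-MBD), fully inside the field with ≥ 8.8 µm inter-membrane clearance,
rendering near-white interiors and darker membranes (≥ 2 px wide, ≥ 20%
green-channel contrast) on a pink stromal background at 1.1 µm/px (default
field 1 mm × 1.3 mm).

**What the generator does not emulate** — and hence what passing tests do not
show about real data: reflectance spectra and the inverse Monte Carlo fit,
hemoglobin oxygenation kinetics, irregular margin outlines, spatially varying
illumination, shared adipocyte membranes (real adipose tissue has no stromal
septum between every cell pair), staining variability, and realistic H&E
color. Clinical sensitivity/specificity of the original cohort cannot be
reproduced (patient data were never deposited); the synthetic cohorts test
direction-of-effect, calibration, and recovery of the planted structure only.

## Problem sizes used in validation

The shipped validation suite exercises: cohorts of 60 margins (8×12 px maps)
for classifier recovery over 50 seeds; 25 margins/arm for blocked-KS
direction checks (n_perm = 999); 200-seed null calibrations at n_perm = 199
for both permutation procedures; and 20 adipocyte fixtures of ~35 cells at
~480×480 µm (plus the full-field default for interactive use). These sizes
give stable Monte-Carlo estimates while keeping the whole suite quick on one
CPU.

## Known limitations

* The CIT is the simplest member of the conditional-inference family
  (univariate Wilcoxon associations); it does not implement quadratic test
  statistics, surrogate splits, or missing-value handling.
* Resubstitution Se/Sp overstate out-of-sample accuracy by construction; the
  permutation p is the only honesty check shipped.
* The morphometry defaults assume membrane-contrast imagery like the
  fixtures; heavily confluent or torn tissue will need re-tuned
  `morphometry_config()` parameters.
* Asymptotic KS p-values are deliberately absent — inference is by
  permutation only.
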