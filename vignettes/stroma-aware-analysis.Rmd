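---
title: "Stroma-aware analysis of tumour sections and expression profiles"
author: "stromalens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stroma-aware analysis of tumour sections and expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromalens)
```

## The problem

Bulk expression profiles of solid tumours are mixtures: every measured value
averages carcinoma cells and the surrounding stroma in unknown proportions.
For a gene such as *PTEN* — expressed constitutively by stromal fibroblasts
but variably lost in tumour cells through copy-number alteration — the
mixture is actively misleading: a stroma-rich section can report high *PTEN*
even when every tumour cell has lost the locus. `stromalens` implements a
stroma-aware analysis chain for this situation: it estimates the stromal
area fraction of H&E-stained sections directly from the image, ties that
fraction to expression through a stromal gene signature, and carries the
correction through differential expression, gene-set enrichment,
compartment-specific contrasts and survival analysis. Everything runs on
synthetic cohorts with known ground truth, so each stage's claims are
testable end to end.

## Stromal fraction from an H&E image

`segment_slide()` composes five steps, each exported on its own:

1. **Entropy tissue mask.** Bare glass is nearly uniform; stained tissue is
   textured. For every pixel we compute the Shannon entropy (bits) of the
   256-level gray histogram in a disk window (default radius 5 px,
   luminance weights 0.299/0.587/0.114) and keep pixels above a threshold.
   By default the threshold is chosen by Otsu's method on the entropy map;
   a fixed cutoff (default 4 bits) is available via
   `segment_config(entropy_mode = "fixed")`. The adaptive default needs no
   per-scanner tuning; the fixed mode is there for images whose background
   is not the majority class.
2. **Optical density.** Intensities are converted with the Beer–Lambert
   transform $od = -\log_{10}(\max(I,1)/I_0)$, $I_0 = 255$ per channel by
   default, because stain concentrations combine *linearly* in OD space,
   not in intensity space.
3. **Colour deconvolution.** The 3×3 stain system $od = S\,c$ is inverted
   per pixel. The default $S$ holds the published Ruifrok–Johnston H&E
   vectors, unit-normalised, H = (0.650, 0.704, 0.286),
   E = (0.072, 0.990, 0.105), completed by an orthogonal residual vector
   (`ruifrok_basis()`). Scanner-specific bases can be supplied through
   `stain_basis()`; a 2-vector basis is completed automatically.
4. **Stromal signal.** Eosin minus haematoxylin concentration: collagenous,
   eosinophilic stroma comes out positive, nuclei-dense tumour negative.
5. **Otsu split and smoothing.** The E − H signal is thresholded by Otsu's
   method computed *only over tissue pixels* (256 bins; background values
   would otherwise dominate the histogram), then the stroma mask is
   smoothed by morphological opening and closing with a disk of radius 2 px.
   Smoothing after thresholding keeps the pipeline deterministic and lets
   the smoothing be tested as a pure set operation; a pre-threshold median
   filter on the signal is offered via `segment_config(median_radius = )`
   for noisier material.

The stromal fraction is $|stroma \cap tissue| / |tissue|$. When no tissue
survives the entropy mask the result carries an explicit `no_tissue` flag
rather than a silent zero. The implementation makes no claim at sub-pixel
resolution, does not normalise colour across scanners, and does not read
pyramidal whole-slide formats — tiles must arrive as 8-bit RGB arrays.

Numerical notes: local entropy is computed exactly by convolving one
indicator image per occurring gray level with the disk kernel (FFT round-off
is clamped before the $p\log p$ sum); the Otsu maximiser uses exact class
sums per candidate bin edge, so it coincides with a brute-force scan over
the same edges; `otsu_threshold()` refuses degenerate (constant) input.

## Linking fractions to expression

`signature_score()` averages a stromal gene set per sample, z-scoring each
gene across samples first (default) so that highly expressed genes do not
dominate; the raw mean is available since the scoring convention is a
choice, not a law. `rank_stromal_genes()` ranks signature genes by signed
Pearson r against the image fractions — the route by which a marker gene
like *ACTA2* is selected. `calibrate_and_predict()` fits the ordinary
least-squares line of fraction on score over the imaged samples and
predicts fractions for the rest, clipped to [0, 1]; a linear form is the
simplest defensible choice and its fit diagnostics (slope, intercept, r)
are returned so misfit is visible. Agreement between automated fractions
and ordinal manual scores is tested with the Jonckheere–Terpstra trend
test: $J = \sum_{k<l} \#\{x_k < x_l\} + \tfrac12\#\{x_k = x_l\}$, with a
seeded label-permutation p-value (default 10⁴ permutations) and a
tie-corrected normal approximation for large cohorts.

Quantile utilities follow one convention everywhere: type-7 empirical
quantiles, values equal to a boundary assigned to the *lower* bin, so group
assignments are deterministic and reproducible across stages.

## Stroma-corrected differential expression

The *PTEN* contrast compares the bottom against the top expression quartile
(`contrast_groups()`). `de_test()` computes a moderated t: the pooled
per-gene variance $s^2_g$ is shrunk toward the cohort mean variance
$s_0^2$ with `prior_df` pseudo-observations,
$\tilde s^2_g = (d_0 s_0^2 + d\, s^2_g)/(d_0 + d)$, and the t statistic is
referred to $d + d_0$ degrees of freedom. The default $d_0 = 4$ stabilises
small-sample variances; $d_0 = 0$ reproduces the classical pooled t exactly
(and is tested against the textbook formula to 10⁻¹⁰). This deliberately
simple empirical-Bayes shrinkage keeps the estimator self-contained and
oracle-testable; it is not a reimplementation of limma's full hierarchy.
False discovery control is Benjamini–Hochberg throughout. Note that the
step-up adjustment is not idempotent — re-adjusting already-adjusted values
inflates them — so q-values are computed once, from raw p-values.

Gene-set enrichment uses the classic Kolmogorov–Smirnov running sum
(`weight_exponent = 0`): walking down the ranked list, hits add $1/m$,
misses subtract $1/(N-m)$, and the enrichment score is the signed maximum
deviation. The score-weighted variant ($|t|$-weighted hits) is available
and agrees with an independent implementation. Genes are ranked by the
signed moderated t from `de_test()`; significance comes from permuting the
hit positions (equivalent to permuting gene labels at fixed set size),
one-sided on the sign of the observed score. The stroma-correction claim is
operational: the stromal set's enrichment in the *PTEN* contrast should
drop by at least half when the analysis is repeated inside the lowest
*ACTA2* quartile — *ACTA2* expression, not the image fraction, defines the
subset, since that is the gate available for samples without images.

`cssam_de()` provides the orthogonal compartment-specific check: within
each group, every gene is regressed (least squares, no intercept) on the
design $(f, 1-f)$, whose coefficients are the pure stroma and tumour
expression; compartment differences between groups get a plug-in FDR from
group-label permutations (default 200), FDR(threshold) = median permuted
call count / observed call count, capped at 1. Under the null this
estimator concentrates near 1 but is noisy at the extreme ranks, where a
single observed call divides the estimate — its output is a screening
quantity, not a calibrated p-value. Samples with fraction exactly 0 or 1,
or constant fractions within a group, are rejected (rank-deficient design).

Heat-map ordering uses Ward clustering on Euclidean distances
(`ward.D2` linkage, i.e. unsquared distances), validated against an
explicit centroid-formula agglomeration.

## Survival with delayed entry

Markers are dichotomised the way the staining scores are used clinically:
`reduced` = negative, weak positive or heterogeneous; `retained` =
positive. `km_estimate()` and `cox_fit()` wrap the survival package's
product-limit estimator and Cox partial-likelihood machinery with
counting-process intervals $(entry, exit]$, so a subject enters the risk
set only after their study-entry time. Left truncation is not optional
bookkeeping: when entry times are correlated with survival — a cohort that
recruits months after diagnosis necessarily misses early deaths — the naive
fit credits late-entering groups with immortal person-time and attenuates
the hazard ratio, a bias the test suite reproduces. Ties use the Breslow
approximation (the simplest form, and the one our grid-search oracle
maximises); Efron ties would be a straightforward extension. Stage and
grade enter as ordinal numerics, site as a factor; Wald intervals are
$\exp(\beta \pm 1.96\,SE)$, convergence tolerance 10⁻⁸, at most 50
iterations. Stratified-baseline pooling across studies is available by
fitting within site levels; the default pools with a site covariate.
Association tests (Fisher exact with Monte-Carlo fallback for R×C tables,
Pearson chi-squared without continuity correction, Wilcoxon rank-sum,
two-sample t, median dichotomisation with ties-low) follow the standard
base-R implementations behind stable interfaces.

## What the synthetic data emulate — and what they do not

`generate_he_image()` is a forward model of the segmentation chain's
assumptions: tissue carved from a smoothed Gaussian field (~80% coverage),
a stromal sub-region thresholded at the quantile matching the target
fraction (achieved within 0.02), tumour rendered haematoxylin-dominant with
nuclear speckles, stroma eosin-dominant, both textured; RGB follows
$I = I_0\,10^{-S c}$ with Gaussian noise (sd 2 intensity units) and 8-bit
quantisation. Default tiles are 128×128 px. Because the renderer uses the
same Ruifrok basis the segmenter assumes, recovery on these tiles tests the
pipeline's internal consistency, monotonicity and calibration — not
robustness to scanner-to-scanner stain variation, folds, pen marks or
out-of-focus regions, which real slides have and these tiles do not.

`generate_cohort_expression()` draws per-sample stromal fractions from
Beta(2, 2) (spanning low and high stroma), then mixes
$x_{ij} = f_j s_i + (1-f_j)t_{ij} + \varepsilon_{ij}$ in log2 units with
noise sd 0.3. The 100-gene signature is elevated by +2 log2 in the stroma
profile only; *ACTA2* is modelled as a clean stromal marker (stroma 9.5,
constant tumour 4.5), reflecting smooth-muscle actin's restriction to
stromal cells — this matters, because a gate on "low ACTA2" can only remove
stromal confounding if ACTA2 itself is not noisy in tumour. Tumour *PTEN*
is 6.5 + log2(copy factor) with factors 0.1 / 0.55 / 1.0 for homozygous
deletion (6%), hemizygous loss (36%) and diploid; stromal *PTEN* is
constant at 7.3. Tumour *AR* couples to standardised tumour *PTEN* at
ρ = 0.4. The copy factors and ρ are invented, config-exposed defaults
chosen so the confounding-then-correction pattern is reproducible; they are
not measured quantities. Mixing in log2 space is itself a simplification —
physical mixing is linear-scale — adopted because every downstream method
operates on log2 values.

`generate_staining()` draws staining categories from a per-copy-state
confusion matrix concentrating homozygous deletion on negative, hemizygous
loss on weak/heterogeneous and diploid on positive.
`generate_clinical()` uses an exponential baseline (0.012/month), hazard
ratio 1.8 for the reduced-PTEN group, entry Uniform(0, 36) months with
subjects dying before entry discarded and redrawn — the standard
delayed-entry sampling scheme — and administrative censoring at 150 months.
Covariates (age, stage, grade, site) are drawn from simple marginal laws
and are not linked to the hazard by default, so adjusted and unadjusted
fits estimate the same estimand. All generators are bit-identical functions
of (config, seed).

Passing tests on these cohorts show that the estimators recover what the
generators encode at realistic sizes; they cannot show that real HGSOC
stroma follows a Beta law, that staining confusion is as assumed, or that
hazards are proportional in patients.

## Problem sizes and seeds

The validation suite uses 20-tile ladders (fractions 0.05–0.95, 128 px) for
segmentation recovery, the default 300 × 2000 cohort for the
confounding-and-correction replay, n = 600 with 50 replicates for survival
recovery, and 1000-gene spike-in simulations (50 genes shifted 1.0 log2,
sd 0.5, 20 + 20 samples) for the moderated t's operating characteristics —
sizes at which each property is comfortably identified while the whole
suite stays quick on a laptop. Every stochastic step takes an explicit
seed; staged seeds are derived deterministically from a single master seed
and kept below 2³¹.

## Known limitations

- The entropy mask assumes background is near-uniform; heavily vignetted
  or dirty backgrounds need the fixed-threshold mode or pre-cleaning.
- Otsu assumes a bimodal E − H signal within tissue; sections that are
  essentially all stroma or all tumour sit at the method's edge (the
  synthetic ladder's 0.05/0.95 rungs bound this regime).
- The moderated t assumes a common variance target across genes; strongly
  variance-heterogeneous data would favour limma's trended prior.
- The csSAM-style FDR is a plug-in estimate; weak compartment effects near
  the detection floor get noisy FDRs.
- Cox fits assume proportional hazards; no diagnostics are shipped.
- Predicted fractions for unimaged samples inherit any bias of the linear
  calibration; the fit diagnostics should be inspected before use.
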