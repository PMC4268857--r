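# stromalens

Stroma-aware integration of histology images and expression profiles.

## The problem

Bulk tumour expression profiles mix carcinoma cells with stroma in unknown
proportions. For genes that stromal cells express constitutively — *PTEN*
is the motivating case in high-grade serous ovarian carcinoma — the mixture
biases the measurement: a stroma-rich section reports high *PTEN* even when
the tumour cells themselves have lost the locus through hemizygous loss or
homozygous deletion. `stromalens` is for analysts who have H&E section
images (or a stromal gene signature) alongside expression and clinical
data, and who want their differential expression, enrichment and survival
results to reflect tumour-cell biology rather than tissue composition.

## What it computes

**Stromal fraction from an image.** An entropy filter removes the unstained
background; pixels are mapped to optical density, $od = -\log_{10}(I/I_0)$,
and deconvolved through the Ruifrok–Johnston H&E stain matrix; the raw
stromal signal is eosin minus haematoxylin concentration; Otsu's threshold
(restricted to tissue pixels) and morphological smoothing yield a stroma
mask, and the fraction $|stroma|/|tissue|$.

**Signature link and calibration.** Per-sample stromal scores (z-scored
set means), per-gene Pearson ranking against image fractions, a
Jonckheere–Terpstra trend test against ordinal manual scores, and an OLS
calibration predicting fractions for samples without images.

**Corrected contrasts.** Bottom-vs-top *PTEN* quartile differential
expression with a moderated t ($s^2$ shrunk toward the cohort mean with
`prior_df` pseudo-observations, BH-adjusted), classic running-sum gene-set
enrichment $ES = $ signed max of the hit/miss walk, repeated inside the
lowest *ACTA2* quartile to strip the stromal component, and a csSAM-style
compartment-specific contrast regressing each gene on $(f, 1-f)$ with a
permutation plug-in FDR.

**Survival.** Kaplan–Meier and Cox proportional hazards with delayed entry
(risk set at $t$ = subjects with $entry < t \le exit$), Breslow ties, for
markers dichotomised as reduced (negative / weak / heterogeneous staining)
vs retained (positive); plus Fisher, chi-squared, Wilcoxon and t
association tests.

**Synthetic cohorts with known truth.** Generators for H&E-style tiles with
a known stromal fraction, two-compartment expression mixtures in which
observed *PTEN* is confounded with stroma while tumour *PTEN* tracks copy
state (homozygous deletion 6%, hemizygous loss 36%) and *AR* couples to
tumour *PTEN*, staining categories drawn from copy states, and
left-truncated survival tables with a true hazard ratio of 1.8.

## Worked example

```r
library(stromalens)

# a synthetic H&E tile with known 40% stroma, segmented back
img <- generate_he_image(target_fraction = 0.4, seed = 7)
seg <- segment_slide(img$pixels)
seg
#> segmentation_result: stromal fraction 0.378 (5081 / 13431 tissue px)

# a full synthetic cohort: expression + staining + survival + 12 tiles
bundle <- simulate_cohort(1, n_images = 12, image_size = 96)
report <- run_full_analysis(bundle, gsea_perm = 200, cssam_perm = 50)
report
#> analysis_report
#>   imaged tiles segmented : 12
#>   stromal ES (all / low-ACTA2): 0.996 / -0.073
#>   reduced-PTEN HR: 1.66 (95% CI 1.40-1.98)

head(report$gene_ranking, 3)
#>     gene         r             p rank
#> 1  ACTA2 0.9676803 2.445968e-180    1
#> 2 G00016 0.8248077  8.964701e-76    2
#> 3 G00039 0.8233124  2.819822e-75    3
```

Reading the output: the segmenter recovers the tile's known stromal
fraction (0.378 vs 0.40 true). In the cohort replay, the stromal gene set
is maximally enriched (ES 0.996) in the naive *PTEN* high-vs-low contrast —
the contrast is really sorting samples by stroma — and the enrichment
collapses (ES −0.073) once the analysis is restricted to the lowest *ACTA2*
quartile, where the same contrast now tracks tumour-cell *PTEN* copy state.
The delayed-entry Cox model on the simulated cohort recovers a hazard ratio
near the generating value of 1.8 for reduced-PTEN cases, and *ACTA2* ranks
first among signature genes correlated with the image-derived fractions.

See `vignettes/stroma-aware-analysis.Rmd` for the model, parameter and
design details.

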