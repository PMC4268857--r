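#' Simulate a self-contained analysis cohort
#'
#' Bundles every input the pipeline needs, with ground truth: an expression
#' mixture cohort, staining categories drawn from the sampled copy states, a
#' left-truncated survival table, and H&E-style tiles for the first
#' `n_images` samples whose target stromal fraction is that sample's true
#' fraction. Deterministic given (`seed`, configs).
#'
#' @param seed integer master seed; stage seeds are derived from it.
#' @param config a [cohort_config()].
#' @param clin_config a [clinical_config()].
#' @param n_images how many samples get an image (default 20).
#' @param image_size tile side in pixels.
#' @return list of class `synthetic_bundle` with `expr`, `truth`,
#'   `signature`, `staining`, `clinical`, `images` (named by sample id),
#'   `imaged_samples`, `seed`.
#' @export
simulate_cohort <- function(seed, config = cohort_config(),
                            clin_config = clinical_config(),
                            n_images = 20L, image_size = 96L) {
  co <- generate_cohort_expression(config, seed = derive_seed(seed, 1L))
  staining <- generate_staining(co$truth$copy_state,
                                seed = derive_seed(seed, 2L))
  clinical <- generate_clinical(clin_config, seed = derive_seed(seed, 3L))
  imaged <- colnames(co$expr)[seq_len(n_images)]
  images <- lapply(seq_along(imaged), function(i)
    generate_he_image(min(max(co$truth$fractions[imaged[i]], 0.02), 0.98),
                      size = image_size, seed = derive_seed(seed, 100L + i)))
  names(images) <- imaged
  structure(list(expr = co$expr, truth = co$truth, signature = co$signature,
                 staining = staining, clinical = clinical, images = images,
                 imaged_samples = imaged, seed = as.integer(seed)),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to a directory
#'
#' Produces `expression.tsv`, `fractions_truth.tsv`, `clinical.csv`,
#' `staining.tsv`, `genesets.gmt` and an `images/` directory of PNG tiles,
#' all re-readable by the package readers.
#'
#' @param bundle a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(bundle$expr, file.path(dir, "expression.tsv"))
  write.table(data.frame(sample_id = names(bundle$truth$fractions),
                         stromal_fraction = unname(bundle$truth$fractions)),
              file.path(dir, "fractions_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_clinical_csv(bundle$clinical, file.path(dir, "clinical.csv"))
  write.table(data.frame(sample_id = names(bundle$staining),
                         staining = as.character(bundle$staining)),
              file.path(dir, "staining.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gmt(list(stromal_signature = bundle$signature),
            file.path(dir, "genesets.gmt"))
  for (id in names(bundle$images))
    write_image_png(bundle$images[[id]]$pixels,
                    file.path(dir, "images", paste0(id, ".png")))
  invisible(dir)
}

#' Run the full stroma-aware analysis on a synthetic bundle
#'
#' End-to-end replay: segment the imaged tiles; score the stromal signature
#' and calibrate a fraction predictor for the unimaged samples; rank
#' signature genes against the fractions; run the PTEN top-vs-bottom
#' quartile differential expression on all samples and again within the
#' lowest ACTA2 quartile; compute the stromal-set enrichment score for both
#' rankings; run compartment-specific DE on the predicted fractions; fit the
#' left-truncated Cox model for the dichotomised staining marker on the
#' survival cohort; and tabulate the staining-vs-copy-state association.
#' Deterministic given the bundle and seeds.
#'
#' @param bundle a [simulate_cohort()] result.
#' @param gsea_perm,cssam_perm permutation counts.
#' @param seed integer seed for the permutation draws.
#' @return list of class `analysis_report`; see the elements returned.
#' @export
run_full_analysis <- function(bundle, gsea_perm = 1000L, cssam_perm = 100L,
                              seed = bundle$seed) {
  expr <- bundle$expr
  seg <- segment_batch(lapply(bundle$images, `[[`, "pixels"))
  est_fractions <- setNames(seg$stromal_fraction, seg$image_id)
  est_fractions <- est_fractions[!is.na(est_fractions)]

  scores <- signature_score(expr, bundle$signature)
  calib <- calibrate_and_predict(est_fractions, scores)
  fractions <- pmin(pmax(calib$predicted, 0.02), 0.98)

  ranking_table <- rank_stromal_genes(expr, fractions, bundle$signature)

  pten_groups <- contrast_groups(expr, "PTEN")
  de_all <- de_test(expr, pten_groups$low, pten_groups$high)
  rank_all <- setNames(de_all$t, de_all$gene)
  es_all <- gsea_enrichment(rank_all, bundle$signature, n_perm = gsea_perm,
                            seed = derive_seed(seed, 11L))

  acta2_bins <- quantile_bin(expr["ACTA2", ], q = 4L)
  low_acta2 <- colnames(expr)[acta2_bins$bins == 1L]
  expr_low <- expr[, low_acta2, drop = FALSE]
  pten_low_groups <- contrast_groups(expr_low, "PTEN")
  de_low <- de_test(expr_low, pten_low_groups$low, pten_low_groups$high)
  es_low <- gsea_enrichment(setNames(de_low$t, de_low$gene), bundle$signature,
                            n_perm = gsea_perm,
                            seed = derive_seed(seed, 12L))

  grp <- setNames(rep("mid", ncol(expr)), colnames(expr))
  grp[pten_groups$low] <- "low"; grp[pten_groups$high] <- "high"
  keep <- grp != "mid"
  cssam <- cssam_de(expr[, keep, drop = FALSE], fractions[keep], grp[keep],
                    n_perm = cssam_perm, seed = derive_seed(seed, 13L))

  clin <- bundle$clinical
  cox <- cox_fit(clin, c("reduced_pten", "age", "stage", "grade", "site"),
                 use_entry = TRUE)
  km <- km_estimate(clin, group = ifelse(clin$reduced_pten == 1, "reduced",
                                         "retained"))

  stain_state <- table(bundle$staining, bundle$truth$copy_state)
  fisher <- fisher_exact(stain_state, seed = derive_seed(seed, 14L))

  structure(list(segmentation = seg, scores = scores, calibration = calib,
                 fractions = fractions, gene_ranking = ranking_table,
                 de_all = de_all, de_low_acta2 = de_low,
                 enrichment_all = es_all, enrichment_low_acta2 = es_low,
                 cssam = cssam, cox = cox, km = km,
                 staining_vs_state = list(table = stain_state, fisher = fisher),
                 provenance = list(seed = seed, gsea_perm = gsea_perm,
                                   cssam_perm = cssam_perm)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report\n")
  cat(sprintf("  imaged tiles segmented : %d\n", nrow(x$segmentation)))
  cat(sprintf("  stromal ES (all / low-ACTA2): %.3f / %.3f\n",
              x$enrichment_all$ES, x$enrichment_low_acta2$ES))
  hrrow <- x$cox$coefficients[x$cox$coefficients$term == "reduced_pten", ]
  cat(sprintf("  reduced-PTEN HR: %.2f (95%% CI %.2f-%.2f)\n",
              hrrow$hr, hrrow$ci_low, hrrow$ci_high))
  invisible(x)
}
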