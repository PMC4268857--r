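test_that("contrast groups take the extreme quartiles", {
  expr <- make_expr(c(8, 1, 5, 3, 7, 2, 6, 4), "PTEN", sprintf("s%d", 1:8))
  g <- contrast_groups(expr, "PTEN")
  expect_setequal(g$low, c("s2", "s6"))
  expect_setequal(g$high, c("s1", "s5"))
  expect_error(contrast_groups(expr, "TP53"), "not present")
  const <- make_expr(rep(1, 8), "PTEN", sprintf("s%d", 1:8))
  expect_error(contrast_groups(const, "PTEN"), "identical")
})

test_that("PTEN-low quartile is enriched for copy-loss states", {
  co <- generate_cohort_expression(cohort_config(n_samples = 200,
                                                 n_genes = 300,
                                                 signature_size = 30),
                                   seed = 17)
  g <- contrast_groups(co$expr, "PTEN")
  loss <- co$truth$copy_state %in% c("homdel", "hetloss")
  names(loss) <- names(co$truth$copy_state)
  a <- sum(loss[g$low]); b <- sum(!loss[g$low])
  c_ <- sum(loss[g$high]); d <- sum(!loss[g$high])
  expect_gt((a / b) / (c_ / d), 1)
})

test_that("moderated t with prior_df = 0 equals the classical pooled t", {
  set.seed(21)
  expr <- matrix(rnorm(50 * 12), 50, 12,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
  A <- sprintf("s%02d", 1:6); B <- sprintf("s%02d", 7:12)
  de <- de_test(expr, A, B, prior_df = 0)
  for (g in c("g01", "g25", "g50")) {
    o <- pooled_t_oracle(expr[g, A], expr[g, B])
    expect_equal(de$t[de$gene == g], o$t, tolerance = 1e-10)
    expect_equal(de$p[de$gene == g], o$p, tolerance = 1e-10)
  }
  expect_error(de_test(expr, A, c(A[1], B)), "overlap")
})

test_that("equal group means give t = 0 and p = 1", {
  expr <- make_expr(rep(c(1, 2, 1, 2), 2), c("g1", "g2"), sprintf("s%d", 1:4))
  de <- de_test(expr, c("s1", "s2"), c("s3", "s4"), prior_df = 0)
  expect_equal(de$t, c(0, 0))
  expect_equal(de$p, c(1, 1))
})

test_that("shifted genes are detected with controlled false positives", {
  set.seed(33)
  n_genes <- 1000; shifted <- 1:50
  expr <- matrix(rnorm(n_genes * 40, 0, 0.5), n_genes, 40)
  expr[shifted, 21:40] <- expr[shifted, 21:40] + 1.0
  dimnames(expr) <- list(sprintf("g%04d", 1:n_genes), sprintf("s%02d", 1:40))
  de <- de_test(expr, sprintf("s%02d", 1:20), sprintf("s%02d", 21:40))
  called <- which(de$q < 0.05)
  expect_gte(sum(called %in% shifted) / 50, 0.8)
  expect_lte(sum(!(called %in% shifted)), 10)
})

test_that("Benjamini-Hochberg matches the hand step-up formula", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(41)
  p <- runif(100)
  q <- benjamini_hochberg(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # order invariance
  perm <- sample(100)
  expect_equal(benjamini_hochberg(p[perm]), q[perm])
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("top_k selects by p with deterministic tie-breaks", {
  set.seed(43)
  expr <- matrix(rnorm(30 * 10), 30, 10,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  de <- de_test(expr, sprintf("s%02d", 1:5), sprintf("s%02d", 6:10))
  expect_setequal(top_k(de, 30), de$gene)
  top5 <- top_k(de, 5)
  expect_equal(top5, de$gene[order(de$p, -abs(de$diff), de$gene)][1:5])
  shuf <- de[sample(30), ]
  expect_equal(top_k(shuf, 5), top5)
  expect_error(top_k(de, 31), "exceeds")
})

test_that("Ward clustering matches the centroid-formula oracle", {
  pts <- rbind(c(0, 0), c(0, 1), c(4, 0), c(4, 1.5))
  rownames(pts) <- paste0("p", 1:4)
  wc <- ward_cluster(pts)
  expect_equal(sort(wc$tree$height), sort(ward_heights_oracle(pts)),
               tolerance = 1e-10)
  expect_setequal(wc$order, rownames(pts))

  trio <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  merged_first <- ward_cluster(trio)$tree$merge[1, ]
  expect_setequal(merged_first, c(-1, -2))   # identical rows merge first

  bad <- pts; bad[1, 1] <- NaN
  expect_error(ward_cluster(bad), "missing")
})

test_that("enrichment running sum matches hand enumeration", {
  # all m set genes at the top: maximal deviation 1
  ranking <- setNames(seq(10, 1), paste0("g", 1:10))
  es_top <- gsea_enrichment(ranking, paste0("g", 1:3), n_perm = 0)
  expect_equal(es_top$ES, 1)

  # N = 6, hits at ranks 1 and 4
  r6 <- setNames(seq(6, 1), paste0("g", 1:6))
  es6 <- gsea_enrichment(r6, c("g1", "g4"), n_perm = 0)
  expect_equal(es6$running_sum, c(1/2, 1/4, 0, 1/2, 1/4, 0))
  expect_equal(es6$ES, 0.5)
  expect_equal(es6$running_sum[6], 0)   # curve returns to zero

  expect_error(gsea_enrichment(r6, c("x", "y")), "no gene")
})

test_that("enrichment is antisymmetric under ranking reversal (w = 0)", {
  set.seed(51)
  ranking <- setNames(rnorm(40), sprintf("g%02d", 1:40))
  set <- sprintf("g%02d", sample(40, 8))
  es_f <- gsea_enrichment(ranking, set, n_perm = 0)$ES
  es_r <- gsea_enrichment(-ranking, set, n_perm = 0)$ES
  expect_equal(es_r, -es_f, tolerance = 1e-12)
})

test_that("null enrichment centres on zero and flags real enrichment", {
  set.seed(52)
  ranking <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  null_es <- vapply(1:200, function(i) {
    gsea_enrichment(ranking, sample(names(ranking), 15), n_perm = 0)$ES
  }, 0)
  expect_lt(abs(mean(null_es)), 0.05)

  enriched <- names(sort(ranking, decreasing = TRUE))[1:15]
  es <- gsea_enrichment(ranking, enriched, n_perm = 300, seed = 6)
  expect_gt(es$ES, 0.8)
  expect_lt(es$p, 0.01)
})

test_that("enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(53)
  stats <- sort(rnorm(50), decreasing = TRUE)
  names(stats) <- sprintf("g%02d", 1:50)
  sel <- sort(sample(50, 10))
  for (w in c(0, 1)) {
    ref <- fgsea::calcGseaStat(stats, selectedStats = sel, gseaParam = w)
    got <- gsea_enrichment(stats, names(stats)[sel], weight_exponent = w,
                           n_perm = 0)$ES
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("compartment deconvolution is exact on noiseless mixtures", {
  set.seed(61)
  n <- 16; g <- 30
  f <- runif(n, 0.2, 0.8); names(f) <- sprintf("s%02d", 1:n)
  grp <- setNames(rep(c("A", "B"), each = 8), names(f))
  s_prof <- cbind(A = runif(g, 4, 9), B = runif(g, 4, 9))
  t_prof <- cbind(A = runif(g, 4, 9), B = runif(g, 4, 9))
  expr <- sapply(seq_len(n), function(j) {
    lv <- grp[j]
    f[j] * s_prof[, lv] + (1 - f[j]) * t_prof[, lv]
  })
  dimnames(expr) <- list(sprintf("g%02d", 1:g), names(f))
  res <- cssam_de(expr, f, grp, n_perm = 20, seed = 7)
  expect_equal(unname(res$table$stroma_diff),
               unname(s_prof[, "B"] - s_prof[, "A"]), tolerance = 1e-8)
  expect_equal(unname(res$table$tumour_diff),
               unname(t_prof[, "B"] - t_prof[, "A"]), tolerance = 1e-8)
})

test_that("a tumour-only difference is attributed to the tumour compartment", {
  set.seed(62)
  n <- 40; g <- 60
  f <- runif(n, 0.2, 0.8); names(f) <- sprintf("s%02d", 1:n)
  grp <- setNames(rep(c("A", "B"), each = 20), names(f))
  s_prof <- runif(g, 4, 9)           # stroma identical in both groups
  t_base <- runif(g, 4, 9)
  expr <- sapply(seq_len(n), function(j) {
    t_j <- t_base
    if (grp[j] == "B") t_j[1] <- t_j[1] + 3   # gene 1: tumour-only shift
    f[j] * s_prof + (1 - f[j]) * t_j + rnorm(g, 0, 0.15)
  })
  dimnames(expr) <- list(c("PTEN", sprintf("g%02d", 2:g)), names(f))
  res <- cssam_de(expr, f, grp, n_perm = 100, seed = 8)
  pt_row <- res$table[res$table$gene == "PTEN", ]
  expect_lt(pt_row$tumour_fdr, 0.2)
  expect_gt(pt_row$stroma_fdr, 0.2)
  expect_gt(abs(pt_row$tumour_diff), abs(pt_row$stroma_diff))
})

test_that("identical groups give null compartment differences", {
  set.seed(63)
  n <- 24; g <- 50
  f <- runif(n, 0.25, 0.75); names(f) <- sprintf("s%02d", 1:n)
  grp <- setNames(rep(c("A", "B"), each = 12), names(f))
  expr <- matrix(rnorm(g * n, 6, 1), g, n,
                 dimnames = list(sprintf("g%02d", 1:g), names(f)))
  res <- cssam_de(expr, f, grp, n_perm = 100, seed = 9)
  expect_lt(abs(mean(res$table$tumour_diff)), 0.5)
  expect_lt(abs(mean(res$table$stroma_diff)), 0.5)
  # plug-in FDR concentrates near 1 under the null (noisy only at the
  # extreme ranks, where a single observed call divides the estimate)
  expect_gte(mean(res$table$stroma_fdr), 0.7)
  expect_gte(mean(res$table$tumour_fdr), 0.7)
  expect_gte(median(res$table$tumour_fdr), 0.7)

  cf <- f; cf[grp == "A"] <- 0.5
  expect_error(cssam_de(expr, cf, grp, n_perm = 10, seed = 1),
               "rank-deficient")
})
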