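#' Per-sample stromal signature score
#'
#' Averages the expression of a gene set per sample. By default each gene is
#' z-scored across samples first, so genes on different scales contribute
#' equally; `standardise = FALSE` gives the plain mean of the raw log2
#' values.
#'
#' @param expr gene x sample log2 expression matrix with gene rownames and
#'   sample colnames.
#' @param set character vector of gene ids (or a list with `genes`).
#' @param standardise z-score each gene across samples before averaging.
#' @return named numeric vector of scores, one per sample.
#' @export
signature_score <- function(expr, set, standardise = TRUE) {
  check_expression(expr)
  genes <- if (is.list(set)) set$genes else set
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0L)
    stop_input("no signature gene found in the matrix; missing: %s",
               paste(head(genes, 10), collapse = ", "))
  sub <- expr[present, , drop = FALSE]
  if (standardise) {
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, sd)
    sdv[sdv == 0] <- 1       # constant genes contribute 0 after centring
    sub <- (sub - mu) / sdv
  }
  colMeans(sub)
}

#' Pearson correlation with a t-based p-value
#'
#' @param x,y aligned numeric vectors, n >= 3, neither constant.
#' @return list with `r` and two-sided `p` (t transform, n - 2 df).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must be the same length")
  if (length(x) < 3L) stop_input("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop_input("correlation undefined for constant input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Rank signature genes by correlation with stromal fraction
#'
#' Correlates each gene of a stromal signature with the image-derived
#' stromal fractions and ranks genes by descending signed r (rank 1 = most
#' positively correlated), the ordering used to pick marker genes such as
#' ACTA2.
#'
#' @param expr gene x sample expression matrix.
#' @param fractions named per-sample stromal fractions; names must match
#'   `colnames(expr)`.
#' @param set character vector of signature gene ids.
#' @return data.frame (`gene`, `r`, `p`, `rank`), sorted by rank.
#' @export
rank_stromal_genes <- function(expr, fractions, set) {
  check_expression(expr)
  if (is.null(names(fractions)))
    stop_input("fractions must be named by sample id")
  common <- intersect(colnames(expr), names(fractions))
  if (length(common) < 3L)
    stop_input("fewer than 3 samples shared between expression and fractions")
  genes <- intersect(if (is.list(set)) set$genes else set, rownames(expr))
  if (length(genes) == 0L) stop_input("no signature gene present in the matrix")
  f <- fractions[common]
  res <- lapply(genes, function(g) {
    v <- expr[g, common]
    if (sd(v) == 0) return(c(r = NA_real_, p = NA_real_))
    ct <- pearson_correlation(v, f)
    c(r = ct$r, p = ct$p)
  })
  tab <- data.frame(gene = genes,
                    r = vapply(res, `[[`, 0, "r"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  ord <- order(-tab$r, tab$gene, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

jt_statistic <- function(values, groups) {
  lev <- levels(groups)
  j <- 0
  for (k in seq_len(length(lev) - 1L)) {
    xk <- values[groups == lev[k]]
    for (l in (k + 1L):length(lev)) {
      xl <- values[groups == lev[l]]
      cmp <- outer(xk, xl, "<")
      ties <- outer(xk, xl, "==")
      j <- j + sum(cmp) + 0.5 * sum(ties)
    }
  }
  j
}

#' Jonckheere-Terpstra test for ordered trend
#'
#' Tests for a monotone increasing trend of `values` across ordered groups
#' (e.g. automated stromal fractions across manual scoring bins). The
#' statistic sums, over all group pairs (k < l), the number of pairs with the
#' lower-group value smaller (ties count one half). The p-value is one-sided
#' (increasing), obtained by seeded label permutation, or from the
#' tie-corrected normal approximation.
#'
#' @param values numeric vector.
#' @param groups ordered factor (or coercible vector whose sort order is the
#'   hypothesised order) of the same length.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutation draw.
#' @param method `"permutation"` (default) or `"normal"`.
#' @return list with `J`, `p`, `n_perm` and `method`.
#' @export
jonckheere_terpstra <- function(values, groups, n_perm = 10000L, seed,
                                method = c("permutation", "normal")) {
  method <- match.arg(method)
  groups <- if (is.factor(groups)) droplevels(as.factor(groups)) else
    factor(groups, levels = sort(unique(groups)))
  if (length(values) != length(groups)) stop_input("length mismatch")
  if (nlevels(groups) < 2L) stop_input("need at least 2 ordered groups")
  if (any(tabulate(groups) == 0L)) stop_input("every group must be non-empty")
  j_obs <- jt_statistic(values, groups)
  if (method == "normal") {
    ni <- tabulate(groups)
    n <- sum(ni)
    mu <- (n^2 - sum(ni^2)) / 4
    # tie-corrected variance (Hollander & Wolfe)
    tj <- as.vector(table(values))
    s2 <- (n * (n + 1) * (2 * n + 5) - sum(ni * (ni + 1) * (2 * ni + 5)) -
             sum(tj * (tj + 1) * (2 * tj + 5))) / 72 +
      sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2)) /
        (36 * n * (n - 1) * (n - 2)) +
      sum(ni * (ni - 1)) * sum(tj * (tj - 1)) / (8 * n * (n - 1))
    p <- pnorm((j_obs - mu) / sqrt(s2), lower.tail = FALSE)
    return(list(J = j_obs, p = p, n_perm = 0L, method = "normal"))
  }
  if (missing(seed)) stop_input("a seed is required for the permutation test")
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    jp <- jt_statistic(values, sample(groups))
    if (jp >= j_obs) exceed <- exceed + 1L
  }
  list(J = j_obs, p = (exceed + 1) / (n_perm + 1), n_perm = n_perm,
       method = "permutation")
}

#' Quantile binning of a numeric vector
#'
#' Bins samples by empirical (type-7) quantiles into `q` ordered groups,
#' as used for PTEN expression quartiles and AR/PTEN tertiles. Values equal
#' to a boundary go to the lower bin.
#'
#' @param values numeric vector, length >= q, not all identical.
#' @param q number of bins (>= 2); 4 for quartiles, 3 for tertiles.
#' @return list with `bins` (integer labels 1..q, named like `values`) and
#'   `boundaries` (the q - 1 inner quantiles).
#' @export
quantile_bin <- function(values, q = 4L) {
  if (q < 2L) stop_input("q must be >= 2")
  if (length(values) < q) stop_input("need at least q values")
  if (diff(range(values)) == 0)
    stop_input("all values identical; quantiles degenerate")
  bounds <- quantile(values, probs = seq_len(q - 1L) / q, type = 7,
                     names = FALSE)
  bins <- vapply(values, function(v) 1L + sum(bounds < v), 0L)
  names(bins) <- names(values)
  list(bins = bins, boundaries = bounds, q = q)
}

#' Calibrate a fraction predictor from signature scores
#'
#' Fits the ordinary least-squares line of image-derived stromal fraction on
#' signature score over the samples that have both, then predicts a fraction
#' for every scored sample (the route used to extend image-based stromal
#' content to samples without usable slides). Predictions are clipped to
#' \[0, 1\].
#'
#' @param fractions_scored named fractions for the imaged subset.
#' @param scores_all named signature scores for all samples (must cover the
#'   imaged subset).
#' @return list with `predicted` (named, all samples), `slope`, `intercept`,
#'   `r` (fit correlation) and `n_fit`.
#' @export
calibrate_and_predict <- function(fractions_scored, scores_all) {
  if (is.null(names(fractions_scored)) || is.null(names(scores_all)))
    stop_input("fractions and scores must be named by sample id")
  common <- intersect(names(fractions_scored), names(scores_all))
  if (length(common) < 10L)
    stop_input("need >= 10 samples with both a fraction and a score")
  s <- scores_all[common]
  if (sd(s) == 0) stop_input("scores are constant; cannot calibrate")
  f <- fractions_scored[common]
  fit <- lm(f ~ s)
  pred <- coef(fit)[1] + coef(fit)[2] * scores_all
  pred <- pmin(pmax(pred, 0), 1)
  names(pred) <- names(scores_all)
  list(predicted = pred, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r = if (sd(f) == 0) NA_real_ else cor(f, s), n_fit = length(common))
}
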