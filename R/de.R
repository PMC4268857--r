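#' Quartile contrast groups for a single gene
#'
#' Splits samples into the bottom and top quartiles of one gene's expression
#' (the PTEN-low / PTEN-high contrast), using the package quantile-binning
#' convention.
#'
#' @param expr gene x sample expression matrix.
#' @param gene_id gene to stratify on.
#' @param q number of bins (default quartiles).
#' @return list with `low` and `high` character vectors of sample ids.
#' @export
contrast_groups <- function(expr, gene_id, q = 4L) {
  check_expression(expr)
  if (!gene_id %in% rownames(expr))
    stop_input("gene '%s' not present in the matrix", gene_id)
  v <- expr[gene_id, ]
  if (length(v) < 2L * q) stop_input("need at least %d samples", 2L * q)
  qb <- quantile_bin(v, q = q)
  list(low = colnames(expr)[qb$bins == 1L],
       high = colnames(expr)[qb$bins == q])
}

#' Two-group differential expression with a moderated t-statistic
#'
#' Per gene: difference of group means (log2 units) and a t-statistic whose
#' pooled variance is shrunk toward the cohort-wide mean gene variance s0^2
#' with `prior_df` pseudo-degrees of freedom,
#' `s2_mod = (prior_df * s0^2 + df * s2) / (prior_df + df)`. Two-sided
#' p-values use `df + prior_df` degrees of freedom; q-values are
#' Benjamini-Hochberg. `prior_df = 0` is exactly the classical pooled
#' two-sample t-test.
#'
#' @param expr gene x sample expression matrix.
#' @param groupA,groupB disjoint character vectors of sample ids, each of
#'   size >= 2. The reported difference is mean(B) - mean(A).
#' @param prior_df prior degrees of freedom for the variance shrinkage
#'   (default 4; 0 disables moderation).
#' @return data.frame of class `de_result`: `gene`, `diff`, `t`, `p`, `q`,
#'   ordered as the input genes; attributes `nA`, `nB`, `s0_sq`.
#' @export
de_test <- function(expr, groupA, groupB, prior_df = 4) {
  check_expression(expr)
  if (length(intersect(groupA, groupB)) > 0L)
    stop_input("groups overlap")
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop_input("each group needs >= 2 samples")
  if (!all(c(groupA, groupB) %in% colnames(expr)))
    stop_input("group sample ids missing from the matrix")
  if (prior_df < 0) stop_input("prior_df must be >= 0")
  a <- expr[, groupA, drop = FALSE]
  b <- expr[, groupB, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  mA <- rowMeans(a); mB <- rowMeans(b)
  vA <- apply(a, 1, var); vB <- apply(b, 1, var)
  df <- nA + nB - 2
  s2 <- ((nA - 1) * vA + (nB - 1) * vB) / df
  s0_sq <- mean(s2)
  s2_mod <- (prior_df * s0_sq + df * s2) / (prior_df + df)
  se <- sqrt(s2_mod * (1 / nA + 1 / nB))
  tt <- ifelse(se == 0, 0, (mB - mA) / se)
  p <- 2 * pt(abs(tt), df = df + prior_df, lower.tail = FALSE)
  p[se == 0 & mA == mB] <- 1
  out <- data.frame(gene = rownames(expr), diff = mB - mA, t = tt, p = p,
                    q = benjamini_hochberg(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "nA") <- nA; attr(out, "nB") <- nB; attr(out, "s0_sq") <- s0_sq
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotone and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_input("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Top differentially expressed genes
#'
#' The `k` genes with smallest p (ties broken by larger |difference|, then
#' gene id), as selected for heat-map visualisation.
#'
#' @param de a [de_test()] result.
#' @param k number of genes (default 50).
#' @return character vector of k gene ids.
#' @export
top_k <- function(de, k = 50L) {
  if (k > nrow(de)) stop_input("k = %d exceeds the %d genes tested", k, nrow(de))
  ord <- order(de$p, -abs(de$diff), de$gene)
  de$gene[ord][seq_len(k)]
}

#' Ward hierarchical clustering of an expression submatrix
#'
#' Agglomerative clustering with the Euclidean metric and Ward's minimum-
#' variance criterion (the `ward.D2` linkage, which takes unsquared
#' distances), for ordering heat-map rows and columns.
#'
#' @param mat numeric matrix; rows are clustered.
#' @return list with `tree` (an `hclust` object) and `order` (leaf labels in
#'   dendrogram order).
#' @export
ward_cluster <- function(mat) {
  if (nrow(mat) < 2L) stop_input("need at least 2 rows to cluster")
  if (anyNA(mat)) stop_input("matrix contains missing values")
  hc <- hclust(dist(mat, method = "euclidean"), method = "ward.D2")
  list(tree = hc, order = if (is.null(rownames(mat))) hc$order else
    rownames(mat)[hc$order])
}
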