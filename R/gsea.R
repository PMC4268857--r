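#' Gene-set enrichment score by running sum
#'
#' Walks down a ranked gene list accumulating a running sum that increases at
#' gene-set hits and decreases at misses; the enrichment score (ES) is the
#' signed maximum deviation from zero. With `weight_exponent = 0` (classic
#' Kolmogorov-Smirnov form, the default) every hit increments by 1/m; with
#' `weight_exponent = 1` hits increment by |score| normalised over the set
#' hits. Misses always decrement by 1/(N - m). Significance is assessed by
#' permuting which ranks are hits (equivalent to permuting gene labels for a
#' fixed set size), one-sided on the sign of the observed ES.
#'
#' @param ranking named numeric vector of ranking scores (e.g. signed t
#'   statistics), names are unique gene ids. Sorted internally in decreasing
#'   order.
#' @param set character vector of gene ids (the stromal signature, say).
#' @param weight_exponent 0 (classic) or 1 (score-weighted).
#' @param n_perm number of permutations for the p-value (0 skips it).
#' @param seed integer seed for the permutation draw (required if n_perm > 0).
#' @return list of class `enrichment_result`: `ES`, `p`, `running_sum`
#'   (length N, the curve between its implicit 0 endpoints), `set_size`
#'   (hits in the ranking), `ranking_size`, `hit_ranks`.
#' @export
gsea_enrichment <- function(ranking, set, weight_exponent = 0, n_perm = 1000L,
                            seed = NULL) {
  if (is.null(names(ranking)) || anyDuplicated(names(ranking)))
    stop_input("ranking must be named by unique gene ids")
  if (!weight_exponent %in% c(0, 1))
    stop_input("weight_exponent must be 0 or 1")
  genes <- if (is.list(set)) set$genes else set
  ord <- order(ranking, decreasing = TRUE)
  ranked_genes <- names(ranking)[ord]
  scores <- ranking[ord]
  hits <- ranked_genes %in% genes
  m <- sum(hits)
  n <- length(ranking)
  if (m == 0L) stop_input("no gene of the set appears in the ranking")
  if (m == n) stop_input("the set covers the whole ranking; ES undefined")

  es_curve <- function(hit_idx) {
    hit <- logical(n); hit[hit_idx] <- TRUE
    if (weight_exponent == 0) {
      inc <- rep(1 / length(hit_idx), length(hit_idx))
    } else {
      w <- abs(scores[hit_idx])
      inc <- if (sum(w) == 0) rep(1 / length(hit_idx), length(hit_idx)) else
        w / sum(w)
    }
    step <- rep(-1 / (n - length(hit_idx)), n)
    step[hit_idx] <- inc
    cumsum(step)
  }
  obs_curve <- es_curve(which(hits))
  es <- obs_curve[which.max(abs(obs_curve))]

  p <- NA_real_
  if (n_perm > 0L) {
    if (is.null(seed)) stop_input("a seed is required for the permutation p")
    set.seed(as.integer(seed))
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      cv <- es_curve(sample.int(n, m))
      es_b <- cv[which.max(abs(cv))]
      if ((es >= 0 && es_b >= es) || (es < 0 && es_b <= es))
        exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(ES = es, p = p, running_sum = obs_curve, set_size = m,
                 ranking_size = n, hit_ranks = which(hits), n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: ES = %.3f (set %d of %d genes), p = %s\n",
              x$ES, x$set_size, x$ranking_size,
              if (is.na(x$p)) "not computed" else format(x$p, digits = 3)))
  invisible(x)
}
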