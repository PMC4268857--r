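#' Configuration for the synthetic expression cohort
#'
#' Defaults encode the study conditions the package is validated under:
#' 300 samples x 2000 genes, a 100-gene stromal signature containing ACTA2
#' (elevated in the stroma profile only, so tumour cells keep baseline
#' levels), PTEN copy-state frequencies of 6% homozygous deletion and 36%
#' hemizygous loss, copy-state expression factors 0.1 / 0.55 / 1.0 (linear
#' scale), tumour AR coupled to tumour PTEN with rho = 0.4, stromal
#' fractions drawn from Beta(2, 2), and measurement noise sigma = 0.3 (log2
#' units).
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param signature_size number of stromal signature genes.
#' @param copy_state_probs named probabilities for homdel / hetloss /
#'   diploid (must sum to 1).
#' @param copy_factors linear-scale multipliers applied to tumour PTEN per
#'   copy state.
#' @param rho tumour AR - tumour PTEN coupling in \[0, 1\].
#' @param noise_sd residual noise sigma (log2 units).
#' @param fraction_shape1,fraction_shape2 Beta law of the stromal fraction.
#' @param signature_shift log2 elevation of signature genes in stroma over
#'   tumour.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 300L, n_genes = 2000L,
                          signature_size = 100L,
                          copy_state_probs = c(homdel = 0.06, hetloss = 0.36,
                                               diploid = 0.58),
                          copy_factors = c(homdel = 0.1, hetloss = 0.55,
                                           diploid = 1.0),
                          rho = 0.4, noise_sd = 0.3,
                          fraction_shape1 = 2, fraction_shape2 = 2,
                          signature_shift = 2) {
  if (abs(sum(copy_state_probs) - 1) > 1e-8)
    stop_input("copy_state_probs must sum to 1")
  if (rho < 0 || rho > 1) stop_input("rho must lie in [0, 1]")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a two-compartment expression cohort with known truth
#'
#' Observed log2 expression is the stroma/tumour mixture
#' `x[i, j] = f[j] * s[i] + (1 - f[j]) * t[i, j] + eps[i, j]`
#' with per-sample stromal fraction `f ~ Beta(2, 2)` and Gaussian noise.
#' Signature genes are elevated in the stroma profile while tumour cells
#' keep their baseline; ACTA2 in particular is strongly eosinophilic-stromal
#' with constant low tumour expression, making it a clean stromal marker.
#' Stromal PTEN is constant and positive while tumour PTEN tracks the
#' sampled copy state (so observed PTEN is confounded with stromal content
#' even though tumour-cell PTEN is independent of it); tumour AR is
#' correlated with standardised tumour PTEN at `rho`. This reproduces,
#' with known ground truth, the confounding structure that motivates
#' stroma-aware correction.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; output is a deterministic function of
#'   (config, seed).
#' @return list with `expr` (gene x sample matrix, genes include `PTEN`,
#'   `ACTA2`, `AR`), `truth` (list: `fractions`, `stroma_profile`,
#'   `tumour_profiles`, `copy_state`, `signature_genes`, `rho`, `noise_sd`,
#'   `seed`) and `signature` (the stromal gene set).
#' @export
generate_cohort_expression <- function(config = cohort_config(), seed) {
  set.seed(as.integer(seed))
  n <- config$n_samples
  g <- config$n_genes
  samples <- sprintf("S%04d", seq_len(n))
  special <- c("PTEN", "ACTA2", "AR")
  genes <- c(special, sprintf("G%05d", seq_len(g - length(special))))
  sig <- c("ACTA2", sprintf("G%05d", seq_len(config$signature_size - 1L)))

  f <- rbeta(n, config$fraction_shape1, config$fraction_shape2)
  f <- pmin(pmax(f, 0.02), 0.98)
  names(f) <- samples

  # stroma profile: one value per gene, shared by all samples
  base <- rnorm(g, mean = 6, sd = 1)
  names(base) <- genes
  s <- base + rnorm(g, 0, 0.3)
  names(s) <- genes
  s[sig] <- base[sig] + config$signature_shift
  s["PTEN"] <- 7.3                    # stromal PTEN constant and positive
  s["AR"] <- 5.5
  s["ACTA2"] <- 9.5                   # smooth-muscle actin: strong in stroma

  cs <- sample(names(config$copy_state_probs), n, replace = TRUE,
               prob = config$copy_state_probs)
  names(cs) <- samples

  # tumour profiles: per-gene baseline plus per-sample variation; signature
  # genes keep their baseline (the elevation is stroma-specific), and tumour
  # cells express ACTA2 at a constant low level, making it a clean marker
  t_mat <- matrix(base, g, n) + matrix(rnorm(g * n, 0, 0.4), g, n)
  dimnames(t_mat) <- list(genes, samples)
  t_mat["ACTA2", ] <- 4.5
  t_mat["PTEN", ] <- 6.5 + log2(config$copy_factors[cs]) + rnorm(n, 0, 0.3)
  z_pten <- as.vector(scale(t_mat["PTEN", ]))
  rho <- config$rho
  t_mat["AR", ] <- 6 + 1.0 * (rho * z_pten +
                                sqrt(1 - rho^2) * rnorm(n))

  eps <- matrix(rnorm(g * n, 0, config$noise_sd), g, n)
  expr <- sweep(matrix(s, g, n), 2, f, "*") +
    sweep(t_mat, 2, 1 - f, "*") + eps
  dimnames(expr) <- list(genes, samples)

  list(expr = expr,
       truth = list(fractions = f, stroma_profile = s,
                    tumour_profiles = t_mat, copy_state = cs,
                    signature_genes = sig, rho = rho,
                    noise_sd = config$noise_sd, seed = as.integer(seed)),
       signature = sig)
}

#' Default copy-state to staining-category confusion matrix
#'
#' Rows are copy states, columns staining categories; rows sum to 1. The
#' defaults concentrate homozygous deletion on negative staining, hemizygous
#' loss on weak/heterogeneous, and diploid on positive, mirroring the
#' association observed between staining scores and copy-number state.
#'
#' @return 3 x 4 stochastic matrix.
#' @export
default_staining_confusion <- function() {
  m <- rbind(homdel  = c(0.80, 0.10, 0.08, 0.02),
             hetloss = c(0.05, 0.45, 0.35, 0.15),
             diploid = c(0.03, 0.12, 0.15, 0.70))
  colnames(m) <- STAINING_LEVELS
  m
}

#' Draw staining categories from copy states
#'
#' Each sample's category is a categorical draw from its copy state's row of
#' the confusion matrix.
#'
#' @param copy_states named character vector of copy states.
#' @param confusion stochastic matrix, rows = copy states present, columns =
#'   the four staining categories.
#' @param seed integer seed.
#' @return named factor of staining categories.
#' @export
generate_staining <- function(copy_states,
                              confusion = default_staining_confusion(),
                              seed) {
  if (!all(unique(copy_states) %in% rownames(confusion)))
    stop_input("confusion matrix lacks a row for some copy state")
  if (any(abs(rowSums(confusion) - 1) > 1e-8))
    stop_input("confusion rows must sum to 1")
  set.seed(as.integer(seed))
  cats <- vapply(copy_states, function(st)
    sample(colnames(confusion), 1L, prob = confusion[st, ]), "")
  factor(setNames(cats, names(copy_states)), levels = STAINING_LEVELS)
}
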