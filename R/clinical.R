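STAINING_LEVELS <- c("negative", "weak_positive", "heterogeneous", "positive")

#' Dichotomise PTEN staining categories
#'
#' Collapses the four-level staining score into the survival marker used for
#' Kaplan-Meier and Cox analyses: `reduced` = negative, weak positive or
#' heterogeneous; `retained` = positive.
#'
#' @param categories character vector (or factor) of staining categories.
#' @return factor with levels `retained`, `reduced` (reduced is the risk
#'   level).
#' @export
dichotomise_staining <- function(categories) {
  categories <- as.character(categories)
  if (length(categories) == 0L) stop_input("empty staining vector")
  bad <- setdiff(unique(categories), STAINING_LEVELS)
  if (length(bad) > 0L)
    stop_input("unknown staining category: %s", paste(bad, collapse = ", "))
  factor(ifelse(categories == "positive", "retained", "reduced"),
         levels = c("retained", "reduced"))
}

check_clinical <- function(table, use_entry) {
  need <- c("exit_time", "event")
  if (use_entry) need <- c("entry_time", need)
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L)
    stop_input("clinical table lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(table$event %in% c(0, 1))) stop_input("event must be 0/1")
  if (use_entry && any(table$exit_time < table$entry_time))
    stop_input("exit_time earlier than entry_time for %d row(s)",
               sum(table$exit_time < table$entry_time))
  invisible(table)
}

#' Kaplan-Meier survival curves with optional delayed entry
#'
#' Product-limit estimator per group. With `use_entry = TRUE` the risk set
#' at time t contains only subjects with `entry_time < t <= exit_time`
#' (left truncation), so early deaths that could never have been observed do
#' not bias the curve.
#'
#' @param table data.frame with `entry_time` (if used), `exit_time`, `event`
#'   (1 = death).
#' @param group optional vector of group labels (one curve per level).
#' @param use_entry honour delayed entry (default TRUE).
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(table, group = NULL, use_entry = TRUE) {
  check_clinical(table, use_entry)
  if (sum(table$event) < 1L) stop_input("need at least one event")
  if (is.null(group)) group <- rep("all", nrow(table))
  surv_obj <- if (use_entry)
    survival::Surv(table$entry_time, table$exit_time, table$event)
  else survival::Surv(table$exit_time, table$event)
  fit <- survival::survfit(surv_obj ~ grp,
                           data = data.frame(grp = factor(group)))
  sm <- summary(fit, censored = TRUE)
  lev <- levels(factor(group))
  strata <- if (is.null(sm$strata)) factor(rep(lev[1], length(sm$time))) else
    factor(sub("^grp=", "", sm$strata), levels = lev)
  data.frame(group = strata, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, surv = sm$surv, row.names = NULL)
}

#' Cox proportional hazards fit with optional left truncation
#'
#' Maximum partial likelihood (Breslow ties) via `survival::coxph`. With
#' `use_entry = TRUE`, counting-process intervals `(entry, exit]` implement
#' delayed entry, as required for cohorts recruited some months after
#' diagnosis. Wald 95% confidence intervals are `exp(beta +/- 1.96 SE)`.
#'
#' @param table clinical data.frame; must contain the covariate columns plus
#'   `entry_time` (if used), `exit_time`, `event`.
#' @param covariates character vector of covariate column names; the first
#'   is conventionally the marker of interest.
#' @param use_entry honour delayed entry (default TRUE).
#' @return list of class `cox_fit`: `coefficients` data.frame (term, beta,
#'   hr, ci_low, ci_high, se, p), `loglik`, `n`, `events`, `fit` (the
#'   underlying coxph object).
#' @export
cox_fit <- function(table, covariates, use_entry = TRUE) {
  check_clinical(table, use_entry)
  if (sum(table$event) < 2L) stop_input("need at least two events")
  miss <- setdiff(covariates, names(table))
  if (length(miss) > 0L)
    stop_input("missing covariate column(s): %s", paste(miss, collapse = ", "))
  resp <- if (use_entry) "survival::Surv(entry_time, exit_time, event)" else
    "survival::Surv(exit_time, event)"
  fml <- stats::as.formula(paste(resp, "~",
                                 paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = table, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-8,
                                                           iter.max = 50))
  if (any(is.na(coef(fit))))
    stop_input("collinear covariates: %s",
               paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  sm <- summary(fit)
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  out <- data.frame(term = names(beta), beta = unname(beta),
                    hr = unname(exp(beta)),
                    ci_low = unname(exp(beta - 1.96 * se)),
                    ci_high = unname(exp(beta + 1.96 * se)),
                    se = unname(se),
                    p = unname(sm$coefficients[, "Pr(>|z|)"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = out, loglik = fit$loglik[2],
                 n = fit$n, events = fit$nevent, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: n = %d, events = %d\n", x$n, x$events))
  print(format(x$coefficients, digits = 3))
  invisible(x)
}

#' Fisher's exact test for contingency tables
#'
#' Exact hypergeometric two-sided test for 2 x 2 tables; larger tables use
#' seeded Monte-Carlo sampling with fixed margins, reporting the estimate
#' and its binomial standard error.
#'
#' @param table matrix of non-negative integer counts.
#' @param n_mc Monte-Carlo replicates for tables larger than 2 x 2.
#' @param seed integer seed (required for the Monte-Carlo branch).
#' @return list with `p`, `method`, and `se` (NA for the exact branch).
#' @export
fisher_exact <- function(table, n_mc = 10000L, seed = NULL) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_input("counts must be non-negative integers")
  if (sum(table) == 0L) stop_input("empty table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, method = "degenerate-margin", se = NA_real_))
  if (all(dim(table) == c(2L, 2L))) {
    p <- fisher.test(table)$p.value
    return(list(p = p, method = "exact", se = NA_real_))
  }
  if (is.null(seed)) stop_input("a seed is required for the Monte-Carlo test")
  set.seed(as.integer(seed))
  ft <- fisher.test(table, simulate.p.value = TRUE, B = n_mc)
  p <- ft$p.value
  list(p = p, method = "monte-carlo", se = sqrt(p * (1 - p) / n_mc))
}

#' Pearson chi-squared test of independence
#'
#' Without continuity correction; warns when any expected count is below 5.
#'
#' @param table matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (sum(table) == 0) stop_input("empty table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_input("zero row or column margin; expected counts undefined")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(ct$expected < 5))
    warning("some expected counts < 5; chi-squared approximation is rough",
            call. = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration for small samples without ties, tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_threshold use the exact distribution when
#'   `length(x) + length(y)` is at most this (and there are no ties).
#' @param alternative two.sided (default), less, or greater.
#' @return list with `W` and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_threshold = 50L,
                              alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) stop_input("empty sample")
  exact <- (length(x) + length(y)) <= exact_threshold &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact,
                                     alternative = alternative))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Two-sample t-test
#'
#' @param x,y numeric samples, each n >= 2.
#' @param welch use the Welch-Satterthwaite unequal-variance form (default
#'   TRUE); FALSE pools the variance.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, welch = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop_input("each sample needs n >= 2")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2,
                                        p = 1))
    stop_input("zero variance in both samples with unequal means")
  }
  tt <- t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Median dichotomisation
#'
#' Splits values at the median; ties at the median go to the low group
#' (deterministic), as used for AR RNA expression.
#'
#' @param values numeric vector, n >= 2, not all equal.
#' @return factor with levels `low`, `high`.
#' @export
median_dichotomise <- function(values) {
  if (length(values) < 2L) stop_input("need at least 2 values")
  if (diff(range(values)) == 0) stop_input("all values identical")
  m <- median(values)
  factor(ifelse(values <= m, "low", "high"), levels = c("low", "high"))
}
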