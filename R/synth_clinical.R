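#' Configuration for the synthetic survival cohort
#'
#' @param n_samples cohort size after left truncation.
#' @param baseline_rate exponential baseline hazard per month (default
#'   0.012).
#' @param hazard_ratio multiplicative hazard for the reduced-PTEN group
#'   (default 1.8).
#' @param entry_max entry times are Uniform(0, entry_max) months since
#'   diagnosis (default 36); subjects dying before entry are discarded,
#'   inducing left truncation.
#' @param horizon administrative censoring time, months since diagnosis.
#' @param reduced_prevalence marginal probability of the reduced-PTEN marker
#'   when no indicator is supplied.
#' @return list of class `clinical_config`.
#' @export
clinical_config <- function(n_samples = 600L, baseline_rate = 0.012,
                            hazard_ratio = 1.8, entry_max = 36,
                            horizon = 150, reduced_prevalence = 0.55) {
  if (baseline_rate <= 0) stop_input("baseline_rate must be positive")
  if (hazard_ratio <= 0) stop_input("hazard_ratio must be positive")
  structure(as.list(environment()), class = "clinical_config")
}

#' Generate a left-truncated survival cohort with known hazard ratio
#'
#' Death times are exponential with hazard `baseline_rate *
#' hazard_ratio^reduced`; entry times are uniform on (0, entry_max) and
#' subjects who die before their entry time are discarded and redrawn, so
#' the delivered cohort is left-truncated exactly as a study that recruits
#' survivors months after diagnosis. Exit is the death time or the
#' administrative horizon, whichever comes first. Age, stage, grade and site
#' are drawn from simple laws and are not linked to the hazard by default.
#'
#' @param config a [clinical_config()].
#' @param reduced optional logical/0-1 vector of reduced-PTEN indicators to
#'   condition on (e.g. from [dichotomise_staining()] of a generated
#'   cohort); drawn Bernoulli otherwise. Recycled subjects keep redrawing
#'   until they survive past entry.
#' @param seed integer seed.
#' @return data.frame with `id`, `entry_time`, `exit_time`, `event`,
#'   `reduced_pten` (0/1), `age`, `stage`, `grade`, `site`; attribute
#'   `true_hr`.
#' @export
generate_clinical <- function(config = clinical_config(), reduced = NULL,
                              seed) {
  set.seed(as.integer(seed))
  n <- config$n_samples
  draw_reduced <- is.null(reduced)
  if (!draw_reduced) {
    reduced <- as.integer(reduced)
    if (length(reduced) != n)
      stop_input("reduced indicator must have length n_samples = %d", n)
  }
  lambda0 <- config$baseline_rate
  hr <- config$hazard_ratio

  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      ri <- if (draw_reduced) rbinom(1, 1, config$reduced_prevalence) else
        reduced[i]
      death <- rexp(1, rate = lambda0 * hr^ri)
      entry <- runif(1, 0, config$entry_max)
      if (death > entry) break   # died before entry: never observed
    }
    exit <- min(death, config$horizon)
    out[[i]] <- c(entry = entry, exit = exit,
                  event = as.numeric(death <= config$horizon), reduced = ri)
  }
  m <- do.call(rbind, out)
  tab <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    entry_time = m[, "entry"], exit_time = m[, "exit"],
    event = as.integer(m[, "event"]), reduced_pten = as.integer(m[, "reduced"]),
    age = round(rnorm(n, 58, 8), 1),
    stage = sample(1:4, n, replace = TRUE, prob = c(0.19, 0.11, 0.58, 0.12)),
    grade = sample(1:3, n, replace = TRUE, prob = c(0.01, 0.28, 0.71)),
    site = sample(c("siteA", "siteB"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  attr(tab, "true_hr") <- hr
  tab
}
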