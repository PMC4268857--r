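test_that("staining dichotomisation groups negative/weak/heterogeneous as reduced", {
  cats <- c("positive", "negative", "weak_positive", "heterogeneous")
  d <- dichotomise_staining(cats)
  expect_equal(as.character(d), c("retained", "reduced", "reduced", "reduced"))
  expect_equal(as.character(dichotomise_staining(rep("positive", 5))),
               rep("retained", 5))
  # published cohort category counts: 49/68/48 reduced of 214 assessable
  cohort <- rep(c("negative", "weak_positive", "heterogeneous", "positive"),
                c(49, 68, 48, 49))
  d2 <- dichotomise_staining(cohort)
  expect_equal(sum(d2 == "reduced"), 165)
  expect_equal(sum(d2 == "retained"), 49)
  expect_error(dichotomise_staining("faint"), "unknown")
  expect_error(dichotomise_staining(character(0)), "empty")
})

test_that("Kaplan-Meier matches the hand product-limit estimate", {
  tab <- data.frame(entry_time = c(0, 0, 0), exit_time = c(1, 2, 3),
                    event = c(1L, 1L, 1L))
  km <- km_estimate(tab, use_entry = FALSE)
  expect_equal(km$surv[km$n_event == 1], c(2/3, 1/3, 0))

  cens <- data.frame(entry_time = 0, exit_time = c(2, 4, 6),
                     event = c(0L, 0L, 0L))
  expect_error(km_estimate(cens), "event")
})

test_that("delayed entry changes the risk set of early deaths", {
  tab <- data.frame(entry_time = c(0, 1, 2.5), exit_time = c(2, 3, 4),
                    event = c(1L, 1L, 1L))
  with_entry <- km_estimate(tab, use_entry = TRUE)
  # at t=2 subject 3 has not entered: risk set {1, 2}, S = 1/2
  expect_equal(with_entry$surv, c(1/2, 1/4, 0))
  expect_equal(with_entry$n_risk, c(2, 2, 1))
  without <- km_estimate(tab, use_entry = FALSE)
  expect_equal(without$surv, c(2/3, 1/3, 0))

  zero_entry <- data.frame(entry_time = 0, exit_time = c(1, 3, 5, 7),
                           event = c(1L, 0L, 1L, 1L))
  expect_equal(km_estimate(zero_entry, use_entry = TRUE)$surv,
               km_estimate(zero_entry, use_entry = FALSE)$surv)

  bad <- data.frame(entry_time = 5, exit_time = 2, event = 1L)
  expect_error(km_estimate(bad), "earlier")
})

test_that("Cox fit maximises the Breslow partial likelihood", {
  tab <- data.frame(
    entry_time = c(0, 0, 1, 0, 2, 0, 1, 0),
    exit_time = c(3, 5, 4, 8, 9, 12, 7, 10),
    event = c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 0L),
    x = c(1, 1, 1, 0, 1, 0, 0, 0))
  fit <- cox_fit(tab, "x", use_entry = TRUE)
  grid <- seq(-3, 3, by = 0.001)
  ll <- vapply(grid, breslow_loglik, 0, entry = tab$entry_time,
               exit = tab$exit_time, event = tab$event, x = tab$x)
  expect_lt(abs(fit$coefficients$beta[1] - grid[which.max(ll)]), 1e-3)
  expect_equal(fit$coefficients$hr[1], exp(fit$coefficients$beta[1]))
  expect_lte(fit$coefficients$ci_low[1], fit$coefficients$hr[1])
  expect_gte(fit$coefficients$ci_high[1], fit$coefficients$hr[1])
})

test_that("two identical groups give a null hazard ratio", {
  set.seed(71)
  n <- 200
  tab <- data.frame(entry_time = 0, exit_time = rexp(n, 0.05),
                    event = 1L, x = rep(0:1, n / 2))
  fit <- cox_fit(tab, "x", use_entry = FALSE)
  expect_lt(abs(fit$coefficients$beta[1]), 0.3)
  expect_gt(fit$coefficients$p[1], 0.05)
})

test_that("simulated cohorts recover the generating hazard ratio", {
  clin <- generate_clinical(seed = 81)
  fit <- cox_fit(clin, c("reduced_pten", "age", "stage", "grade", "site"))
  hr <- fit$coefficients$hr[fit$coefficients$term == "reduced_pten"]
  expect_gt(hr, 1.5); expect_lt(hr, 2.1)
})

test_that("ignoring survival-correlated delayed entry biases the fit", {
  set.seed(82)
  n <- 1200
  x <- rbinom(n, 1, 0.5)
  rows <- t(vapply(seq_len(n), function(i) {
    repeat {
      death <- rexp(1, 0.03 * 1.8^x[i])
      entry <- runif(1, 0, if (x[i] == 1) 48 else 6)
      if (death > entry) break
    }
    c(entry, min(death, 120), as.numeric(death <= 120))
  }, numeric(3)))
  tab <- data.frame(entry_time = rows[, 1], exit_time = rows[, 2],
                    event = as.integer(rows[, 3]), x = x)
  hr_trunc <- cox_fit(tab, "x", use_entry = TRUE)$coefficients$hr[1]
  hr_naive <- cox_fit(tab, "x", use_entry = FALSE)$coefficients$hr[1]
  # naive analysis credits the late-entering risk group with immortal time
  expect_lt(hr_naive, hr_trunc - 0.2)
  expect_lt(abs(hr_trunc - 1.8), 0.45)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  res <- fisher_exact(matrix(c(3, 1, 1, 3), 2))
  # two-sided p: sum of table probabilities <= that of the observed table
  expect_equal(res$p, 0.4857143, tolerance = 1e-6)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$p, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")

  set.seed(91)
  tab34 <- matrix(c(5, 1, 2, 0, 1, 4, 1, 2, 0, 2, 3, 3), 3, 4)
  mc <- fisher_exact(tab34, n_mc = 20000, seed = 14)
  exact <- fisher.test(tab34)$p.value   # network-algorithm enumeration
  expect_lt(abs(mc$p - exact), 3 * mc$se + 1e-4)
})

test_that("Fisher type-I error is controlled under a fixed-margin null", {
  set.seed(92)
  tables <- r2dtable(2000, r = c(25, 35), c = c(30, 30))
  rejections <- vapply(tables, function(tb) fisher_exact(tb)$p < 0.05, TRUE)
  expect_lte(mean(rejections), 0.06)
})

test_that("chi-squared statistic follows the hand formula", {
  prop <- matrix(c(10, 20, 20, 40), 2)   # perfectly proportional
  cs <- chi_squared(prop)
  expect_equal(cs$statistic, 0, tolerance = 1e-12)
  expect_equal(cs$p, 1)

  cs2 <- chi_squared(matrix(c(10, 20, 20, 10), 2))
  expect_equal(cs2$statistic, 20/3, tolerance = 1e-10)
  expect_equal(cs2$df, 1)

  cs3 <- chi_squared(matrix(5 + seq_len(12), 4, 3))
  expect_equal(cs3$df, 6)
  expect_error(chi_squared(matrix(c(0, 0, 1, 2), 2, byrow = TRUE)), "margin")
  expect_warning(chi_squared(matrix(c(2, 3, 3, 2), 2)), "expected")
})

test_that("Wilcoxon rank-sum matches exact enumeration for small samples", {
  same <- wilcoxon_rank_sum(1:6, 1:6)
  expect_gt(same$p, 0.9)
  one_sided <- wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(one_sided$p, 1 / 6)   # 1 of C(4,2) arrangements as extreme
  # exhaustive check at n = 4 + 4: exact p equals enumeration over C(8,4)
  x <- c(1.3, 2.1, 5.0, 6.2); y <- c(3.4, 4.8, 7.7, 9.1)
  w_obs <- sum(outer(x, y, ">"))
  combos <- combn(8, 4)
  pool <- c(x, y)
  ws <- apply(combos, 2, function(idx)
    sum(outer(pool[idx], pool[-idx], ">")))
  exact_less <- mean(ws <= w_obs)
  expect_equal(wilcoxon_rank_sum(x, y, alternative = "less")$p, exact_less,
               tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
})

test_that("two-sample t matches the textbook formula", {
  eq <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)

  a <- c(4.1, 5.2, 6.3, 5.8); b <- c(6.9, 7.4, 8.1, 7.7, 8.8)
  pooled <- two_sample_t(a, b, welch = FALSE)
  o <- pooled_t_oracle(a, b)
  expect_equal(pooled$t, -o$t, tolerance = 1e-10)   # t.test orients x - y
  expect_equal(pooled$p, o$p, tolerance = 1e-10)
  welch <- two_sample_t(a, b, welch = TRUE)
  expect_lte(welch$df, length(a) + length(b) - 2)
})

test_that("median dichotomisation sends median ties to the low group", {
  expect_equal(as.character(median_dichotomise(1:4)),
               c("low", "low", "high", "high"))
  odd <- median_dichotomise(c(10, 20, 30))
  expect_equal(as.character(odd), c("low", "low", "high"))
  set.seed(95)
  lab <- median_dichotomise(rnorm(101))
  expect_lte(abs(diff(table(lab))), 1)
  expect_error(median_dichotomise(rep(7, 4)), "identical")
})
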