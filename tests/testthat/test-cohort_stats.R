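# cross-tabs, stratification, CDP, correlations and the regression models

lesion_fixture <- function(n_sp, n_s, n_p, n_0) {
  # counts: SEL&PRL, SEL only, PRL only, neither
  data.frame(
    sel = rep(c(TRUE, TRUE, FALSE, FALSE), c(n_sp, n_s, n_p, n_0)),
    prl = rep(c(TRUE, FALSE, TRUE, FALSE), c(n_sp, n_s, n_p, n_0)))
}

test_that("crosstab matches the published lesion-level table", {
  lesions <- lesion_fixture(43, 573, 37, 839)
  ct <- crosstab_sel_prl(lesions)
  expect_equal(unname(ct$table["SEL", ]), c(43, 573))
  expect_equal(unname(ct$table["non-SEL", ]), c(37, 839))
  expect_equal(round(unname(ct$row_prop), 2), c(0.07, 0.04))
  expect_false(ct$skipped)
  # Yates-corrected p, independently recomputed from the corrected statistic
  tab <- ct$table
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((abs(tab - E) - 0.5)^2 / E)
  expect_equal(ct$test$coef$p, pchisq(stat, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(ct$test$coef$p, 3), 0.027)
})

test_that("crosstab with an empty margin is skipped, not an error", {
  ct <- crosstab_sel_prl(lesion_fixture(0, 0, 5, 10))
  expect_true(ct$skipped)
  expect_null(ct$test)
  expect_equal(sum(ct$table), 15)
})

test_that("stratification reproduces the published patient subgroups", {
  # 31 SEL+PRL+, 25 SEL+PRL-, 3 SEL-PRL+, 2 SEL-PRL- (pooled to 5 SEL-)
  flags <- rbind(
    data.frame(sel = TRUE, prl = TRUE)[rep(1, 31), ],
    data.frame(sel = TRUE, prl = FALSE)[rep(1, 25), ],
    data.frame(sel = FALSE, prl = TRUE)[rep(1, 3), ],
    data.frame(sel = FALSE, prl = FALSE)[rep(1, 2), ])
  flags$patient_id <- seq_len(nrow(flags))
  lesions <- data.frame(patient_id = flags$patient_id, sel = flags$sel,
                        prl = flags$prl)
  patients <- data.frame(patient_id = flags$patient_id)
  st <- stratify_patients(patients, lesions)
  expect_equal(unname(c(st$counts)), c(31, 25, 5))
  expect_equal(sum(st$counts), 61)
  # a lesion-free patient is SEL-negative
  st2 <- stratify_patients(data.frame(patient_id = 1:2),
                           data.frame(patient_id = 1, sel = TRUE, prl = TRUE))
  expect_equal(as.character(st2$patients$stratum), c("SEL_PRL_BOTH", "SEL_NEG"))
})

test_that("CDP thresholds depend on baseline and require confirmation", {
  v <- function(...) {
    m <- rbind(...)
    data.frame(time = m[, 1], edss = m[, 2])
  }
  # baseline 0: needs 1.5, reached and confirmed
  expect_true(cdp_flag(v(c(0, 0), c(3, 1.5), c(3.6, 1.5))))
  # baseline > 0: 0.5 is not enough
  expect_false(cdp_flag(v(c(0, 2), c(3, 2.5), c(3.6, 2.5))))
  # reached but not sustained at confirmation
  expect_false(cdp_flag(v(c(0, 1), c(3, 2), c(3.6, 1))))
  # sustained 1.0 step from nonzero baseline
  expect_true(cdp_flag(v(c(0, 1), c(3, 2), c(3.6, 2.5))))
  # no confirmation visit -> undetermined, distinct from FALSE
  expect_identical(cdp_flag(v(c(0, 1), c(3, 2.5))), NA)
  expect_identical(cdp_flag(v(c(0, 1))), NA)
})

test_that("Spearman matches the rank-formula oracle; partials behave", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3, 2.3, 8.4, 6.2, 6.4,
         3.3, 8.3, 2.7, 9.5, 0.2, 8.8)   # tie-free
  y <- rev(x) + seq_along(x) * 0.01
  r <- spearman_corr(x, y)
  expect_equal(r$coef$beta, oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(spearman_corr(x, x)$coef$beta, 1)
  expect_equal(spearman_corr(x, -x)$coef$beta, -1)
  expect_match(spearman_corr(rep(1, 5), 1:5)$flags, "constant")
  # partial correlation controlling the shared driver collapses to ~ 0
  set.seed(31)
  n <- 100
  ctrl <- rnorm(n)
  x2 <- ctrl + rnorm(n, 0, 0.5)
  y2 <- ctrl + rnorm(n, 0, 0.5)
  raw <- spearman_corr(x2, y2)$coef$beta
  part <- partial_spearman(x2, y2, ctrl)$coef$beta
  expect_gt(raw, 0.5)
  expect_lt(abs(part), 0.3)
})

test_that("mixed model recovers a noiseless stratum slope exactly", {
  cfg <- sim_config(seed = 11, edss_noise_sd = 0, round_edss = FALSE,
                    edss_slopes = c(SEL_PRL_BOTH = 0.2, SEL_ONLY = 0,
                                    SEL_NEG = 0))
  sc <- simulate_clinical(cfg)
  fit <- fit_edss_mixed(sc$patients, sc$visits, "stratum")
  row <- fit$coef[fit$coef$term == "stratumSEL_PRL_BOTH:time", ]
  expect_equal(row$beta, 0.2, tolerance = 1e-6)
  expect_true(row$ci_lo <= row$beta & row$beta <= row$ci_hi)
})

test_that("permuting time within patients attenuates the slope", {
  cfg <- sim_config(seed = 13, edss_noise_sd = 0, round_edss = FALSE,
                    edss_slopes = c(SEL_PRL_BOTH = 0.3, SEL_ONLY = 0,
                                    SEL_NEG = 0))
  sc <- simulate_clinical(cfg)
  true_beta <- fit_edss_mixed(sc$patients, sc$visits, "stratum")$coef
  true_beta <- true_beta$beta[true_beta$term == "stratumSEL_PRL_BOTH:time"]
  set.seed(99)
  betas <- replicate(5, {
    vper <- do.call(rbind, lapply(split(sc$visits, sc$visits$patient_id),
                                  function(v) {
                                    v$time <- sample(v$time)
                                    v
                                  }))
    b <- fit_edss_mixed(sc$patients, vper, "stratum")$coef
    b$beta[b$term == "stratumSEL_PRL_BOTH:time"]
  })
  expect_lt(mean(abs(betas)), true_beta)
})

test_that("Poisson and log-volume models recover simple truths", {
  set.seed(3)
  d <- data.frame(patient_id = 1:200, cnt = rpois(200, 5),
                  age_baseline = rnorm(200, 40, 10))
  d$vol <- exp(0.5 + 0.02 * d$age_baseline)  # noiseless exponential law
  res <- fit_count_and_volume_models(d, cnt ~ 1, vol ~ age_baseline)
  expect_equal(exp(res$count$coef$beta[1]), 5, tolerance = 0.1 * 5)
  expect_equal(res$volume$r_squared, 1, tolerance = 1e-10)
  expect_equal(res$volume$coef$beta[2], 0.02, tolerance = 1e-10)
  expect_equal(res$volume$n_zero_excluded, 0)
  # zero volumes are excluded and counted
  d$vol[1:7] <- 0
  res2 <- fit_count_and_volume_models(d, cnt ~ 1, vol ~ age_baseline)
  expect_equal(res2$volume$n_zero_excluded, 7)
  # all-zero counts flagged
  d$cnt <- 0L
  res3 <- fit_count_and_volume_models(d, cnt ~ 1, vol ~ age_baseline)
  expect_match(res3$count$flags, "degenerate")
  expect_error(fit_count_and_volume_models(transform(d, cnt = cnt - 1),
                                           cnt ~ 1, vol ~ age_baseline),
               "non-negative")
})

test_that("CDP logistic: null recovery, effect recovery, separation flag", {
  set.seed(4)
  null_d <- data.frame(patient_id = 1:200, cdp = runif(200) < 0.3,
                       x = rnorm(200))
  fit0 <- fit_cdp_logistic(null_d, "x", covariates = character(0))
  orr <- fit0$coef[fit0$coef$term == "x", ]
  expect_true(orr$ci_lo <= 1 && 1 <= orr$ci_hi)
  # balanced synthetic effect OR = 2
  set.seed(5)
  x <- rnorm(500)
  pr <- plogis(log(2) * x)
  eff_d <- data.frame(patient_id = 1:500, cdp = runif(500) < pr, x = x)
  fit1 <- fit_cdp_logistic(eff_d, "x", covariates = character(0))
  o1 <- fit1$coef[fit1$coef$term == "x", ]
  expect_true(o1$ci_lo <= 2 && 2 <= o1$ci_hi)
  # perfect separation is flagged
  sep_d <- data.frame(patient_id = 1:40, cdp = rep(c(FALSE, TRUE), each = 20),
                      x = rep(c(0, 10), each = 20))
  fit2 <- fit_cdp_logistic(sep_d, "x", covariates = character(0))
  expect_match(fit2$flags, "separation")
  expect_error(fit_cdp_logistic(transform(null_d, cdp = TRUE), "x"),
               "non-event")
})

test_that("cohort summary reproduces published percentages and ratios", {
  # patient flags as published: 31/25/3/2
  pid <- 1:61
  sel <- rep(c(TRUE, TRUE, FALSE, FALSE), c(31, 25, 3, 2))
  prl <- rep(c(TRUE, FALSE, TRUE, FALSE), c(31, 25, 3, 2))
  lesions_pat <- data.frame(patient_id = pid, sel = sel, prl = prl)
  patients <- data.frame(patient_id = pid)
  s <- cohort_summary(patients, lesions_pat)
  expect_equal(unname(s$patient_pct), c(92, 56, 51))
  # lesion-level table with published counts
  lesions <- lesion_fixture(43, 573, 37, 839)
  lesions$patient_id <- rep_len(1:61, nrow(lesions))
  s2 <- cohort_summary(data.frame(patient_id = 1:61), lesions)
  expect_equal(unname(s2$ratios["prl_total"]), 0.05)
  expect_equal(unname(s2$ratios["sel_total"]), 0.41)
  expect_equal(unname(s2$ratios["pct_prl_that_are_sel"]), 54)
  expect_equal(s2$lesion_table$prop_prl, c(0.05, 0.07, 0.04))
  # empty cohort: no crash
  s0 <- cohort_summary(patients[0, , drop = FALSE], lesions[0, ])
  expect_equal(s0$n_patients, 0)
})

test_that("half-up rounding matches the published reporting convention", {
  expect_equal(round_half_up(c(91.8, 55.7, 50.8)), c(92, 56, 51))
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(1.5), 2)   # base round() would give 2 and 2
  expect_equal(round_half_up(2.5), 3)   # ...but 2.5 -> 2 under half-even
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(0.045, 2), 0.05)
})
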