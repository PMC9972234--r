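# Lesion- and patient-level statistics: the SEL x PRL cross-tab, patient
# stratification, confirmed disability progression, correlations, and the
# regression models (mixed-effects EDSS, Poisson counts, log-volume OLS,
# CDP logistic).

#' SEL x PRL contingency table and chi-square test
#'
#' Rows SEL / non-SEL, columns PRL / no PRL, with the per-row PRL
#' proportion. The chi-square uses Yates continuity correction on 1 df;
#' with an empty margin the test is skipped (flagged) but the table is
#' still returned.
#'
#' @param lesions data.frame with logical columns `sel` and `prl`.
#' @return List: `table` (2x2 integer matrix), `row_prop` (PRL share of
#'   SELs and of non-SELs), `test` (a model result, or NULL when
#'   skipped), `skipped`.
#' @export
crosstab_sel_prl <- function(lesions) {
  stopifnot(all(c("sel", "prl") %in% names(lesions)))
  sel <- as.logical(lesions$sel)
  prl <- as.logical(lesions$prl)
  if (anyNA(sel) || anyNA(prl)) stop("every lesion needs SEL and PRL flags")
  tab <- matrix(c(sum(sel & prl), sum(sel & !prl),
                  sum(!sel & prl), sum(!sel & !prl)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("SEL", "non-SEL"), c("PRL", "no PRL")))
  row_tot <- rowSums(tab)
  row_prop <- ifelse(row_tot > 0, tab[, "PRL"] / row_tot, NA_real_)
  skipped <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  test <- NULL
  if (!skipped) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    flags <- if (any(ct$expected < 5)) "small_expected_cells" else character(0)
    test <- model_result("CHI2", "sel_x_prl", unname(ct$statistic),
                         p = ct$p.value, flags = flags)
  }
  list(table = tab, row_prop = row_prop, test = test, skipped = skipped)
}

#' Stratify patients by SEL / PRL status
#'
#' `SEL_PRL_BOTH`: at least one SEL and one PRL; `SEL_ONLY`: at least one
#' SEL, no PRLs; `SEL_NEG`: no SELs (patients with PRLs but no SELs are
#' pooled here, as the SEL-negative subsets are too small to split).
#'
#' @param patients data.frame with a `patient_id` column.
#' @param lesions data.frame with `patient_id`, `sel`, `prl` columns
#'   (patients absent from it count as lesion-free, hence `SEL_NEG`).
#' @return List: `patients` with a `stratum` factor column, and `counts`
#'   (named vector over the three strata, summing to the cohort size).
#' @export
stratify_patients <- function(patients, lesions) {
  stopifnot("patient_id" %in% names(patients))
  has_sel <- tapply(lesions$sel, lesions$patient_id, any)
  has_prl <- tapply(lesions$prl, lesions$patient_id, any)
  pid <- as.character(patients$patient_id)
  s <- has_sel[pid]; s[is.na(s)] <- FALSE
  p <- has_prl[pid]; p[is.na(p)] <- FALSE
  stratum <- ifelse(!s, "SEL_NEG", ifelse(p, "SEL_PRL_BOTH", "SEL_ONLY"))
  patients$stratum <- factor(stratum,
                             levels = c("SEL_PRL_BOTH", "SEL_ONLY", "SEL_NEG"))
  list(patients = patients, counts = table(patients$stratum))
}

#' Confirmed disability progression flag
#'
#' CDP is an EDSS change from baseline of at least 1.5 when baseline EDSS
#' is 0, or at least 1.0 when baseline is above 0, reached at the final
#' MRI visit and sustained at a confirmation assessment at least
#' `confirmation_window` years later. The final MRI visit is the last
#' visit that has a later confirmation visit; with no such visit the flag
#' is undetermined (`NA`).
#'
#' @param visits data.frame with `time` (years since baseline, ordered)
#'   and `edss` columns; the first row is baseline.
#' @param confirmation_window Years between the final scan and the
#'   confirming assessment (default 0.5, i.e. 6 months).
#' @return TRUE / FALSE / NA (undetermined).
#' @export
cdp_flag <- function(visits, confirmation_window = 0.5) {
  stopifnot(all(c("time", "edss") %in% names(visits)))
  if (nrow(visits) < 3L) return(NA)  # baseline + final scan + confirmation
  if (is.unsorted(visits$time, strictly = FALSE)) stop("visits must be time-ordered")
  baseline <- visits$edss[1]
  thr <- if (baseline == 0) 1.5 else 1.0
  t <- visits$time
  scan_idx <- NA_integer_
  for (i in rev(seq(2L, nrow(visits) - 1L))) {
    if (any(t > t[i] + confirmation_window - 1e-9 & seq_along(t) > i)) {
      scan_idx <- i
      break
    }
  }
  if (is.na(scan_idx) || scan_idx < 1L) return(NA)
  conf_idx <- which(t > t[scan_idx] + confirmation_window - 1e-9)[1]
  change_scan <- visits$edss[scan_idx] - baseline
  change_conf <- visits$edss[conf_idx] - baseline
  isTRUE(change_scan >= thr && change_conf >= thr)
}

fisher_ci <- function(rho, n, level = 0.95) {
  if (n <= 3 || abs(rho) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(rho)
  se <- sqrt(1.06 / (n - 3))  # Fieller-style correction for rank correlations
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Spearman rank correlation
#'
#' @param x,y Equal-length numeric vectors, n >= 4.
#' @return A model result with rho, an approximate Fisher-transform CI,
#'   and the test p-value; flagged `constant_input` (rho NA) when either
#'   vector is constant.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(model_result("SPEARMAN", "rho", NA_real_,
                        flags = "constant_input"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  ci <- fisher_ci(unname(ct$estimate), length(x))
  model_result("SPEARMAN", "rho", unname(ct$estimate), ci[1], ci[2],
               ct$p.value)
}

#' Partial Spearman correlation
#'
#' Rank-residual method: ranks of `x` and `y` are each regressed on the
#' ranks of the control variable(s) and the residuals are correlated.
#'
#' @param x,y Numeric vectors.
#' @param control Numeric vector or data.frame of controls.
#' @return A model result with the partial rho.
#' @export
partial_spearman <- function(x, y, control) {
  control <- as.data.frame(control)
  stopifnot(length(x) == length(y), nrow(control) == length(x),
            length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(model_result("SPEARMAN", "partial_rho", NA_real_,
                        flags = "constant_input"))
  }
  rc <- as.data.frame(lapply(control, rank))
  rx <- stats::resid(stats::lm(rank(x) ~ ., data = rc))
  ry <- stats::resid(stats::lm(rank(y) ~ ., data = rc))
  ct <- suppressWarnings(stats::cor.test(rx, ry, method = "pearson"))
  ci <- fisher_ci(unname(ct$estimate), length(x))
  model_result("SPEARMAN", "partial_rho", unname(ct$estimate), ci[1], ci[2],
               ct$p.value)
}

wald_tidy <- function(kind, beta, se, flags = character(0), exp_beta = FALSE) {
  q <- stats::qnorm(0.975)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  lo <- beta - q * se
  hi <- beta + q * se
  if (exp_beta) {
    beta <- exp(beta); lo <- exp(lo); hi <- exp(hi)
  }
  out <- data.frame(term = names(beta), beta = unname(beta),
                    ci_lo = unname(lo), ci_hi = unname(hi), p = unname(p),
                    stringsAsFactors = FALSE)
  structure(list(kind = kind, coef = out, flags = flags),
            class = "chronact_model")
}

default_covariates <- c("age_baseline", "sex", "relapse_count",
                        "log_tlv", "treated_end")

#' Mixed-effects model of EDSS over time
#'
#' Linear mixed model of per-visit EDSS with a per-patient random
#' intercept, the chosen lesion metric, follow-up time, their interaction,
#' and clinical covariates, fitted by REML with lme4. For
#' `metric = "stratum"` the interaction is parameterised as per-stratum
#' time slopes (no global time term), so each `stratum:time` coefficient
#' is that group's own EDSS slope in points/year and is directly
#' comparable to a generating slope.
#'
#' @param patients Patient-level data.frame (one row per patient) with
#'   `patient_id`, the metric column and the covariates.
#' @param visits Long data.frame with `patient_id`, `time` (years) and
#'   `edss`.
#' @param metric One of `"sel_count"`, `"sel_logvol"`, `"prl_present"`,
#'   `"stratum"`.
#' @param covariates Character vector of patient-level adjustment columns
#'   (default: age, sex, relapse count, log baseline lesion volume,
#'   treatment status at end of study); only those present are used.
#' @return A model result with Wald 95% CIs and Wald-z p-values; flagged
#'   `singular_fit` when the random-effect variance collapses.
#' @export
fit_edss_mixed <- function(patients, visits,
                           metric = c("stratum", "sel_count", "sel_logvol",
                                      "prl_present"),
                           covariates = default_covariates) {
  metric <- match.arg(metric)
  covariates <- intersect(covariates, names(patients))
  d <- merge(visits, patients, by = "patient_id")
  if (!all(table(d$patient_id) >= 2)) {
    stop("fit_edss_mixed: every patient needs at least 2 visits")
  }
  rhs_cov <- if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  f <- if (metric == "stratum") {
    stats::as.formula(paste("edss ~ stratum + stratum:time", rhs_cov,
                            "+ (1 | patient_id)"))
  } else {
    stats::as.formula(paste("edss ~", metric, "* time", rhs_cov,
                            "+ (1 | patient_id)"))
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(f, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  flags <- character(0)
  if (lme4::isSingular(fit)) flags <- "singular_fit"
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  res <- wald_tidy("MIXED", beta, se, flags = flags)
  res$fit <- fit
  res
}

#' Poisson count model and log-volume linear model
#'
#' Poisson regression (log link) for a lesion count outcome and OLS for
#' the log-transformed volume outcome, with a Shapiro-Wilk residual
#' normality check on the linear model. Zero volumes cannot be
#' log-transformed; they are excluded and their number reported.
#'
#' @param data Patient-level data.frame.
#' @param count_formula Formula for the count model (Poisson).
#' @param volume_formula Formula whose response is a positive volume; the
#'   model is fitted on its log.
#' @return List of two model results (`count`, `volume`); the volume
#'   result carries `shapiro_w`/`shapiro_p` and an `n_zero_excluded`
#'   attribute, degenerate count fits are flagged.
#' @export
fit_count_and_volume_models <- function(data, count_formula,
                                        volume_formula) {
  yc <- stats::model.response(stats::model.frame(count_formula, data))
  if (any(yc < 0) || any(yc != round(yc)))
    stop("count outcome must be non-negative integers")
  flags <- character(0)
  if (all(yc == 0)) flags <- "degenerate_all_zero"
  cf <- stats::glm(count_formula, family = stats::poisson(), data = data)
  count_res <- wald_tidy("POISSON", stats::coef(cf),
                         sqrt(diag(stats::vcov(cf))), flags = flags)

  vars <- all.vars(volume_formula)
  resp <- vars[1]
  keep <- data[[resp]] > 0
  n_zero <- sum(!keep)
  dv <- data[keep, , drop = FALSE]
  dv$.logvol <- log(dv[[resp]])
  rhs <- paste(deparse(volume_formula[[3]]), collapse = " ")
  lf <- stats::lm(stats::as.formula(paste(".logvol ~", rhs)), data = dv)
  sh <- tryCatch(stats::shapiro.test(stats::resid(lf)),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  vol_res <- wald_tidy("LINEAR", stats::coef(lf), sqrt(diag(stats::vcov(lf))))
  vol_res$shapiro_w <- unname(sh$statistic)
  vol_res$shapiro_p <- sh$p.value
  vol_res$n_zero_excluded <- n_zero
  vol_res$r_squared <- summary(lf)$r.squared
  list(count = count_res, volume = vol_res)
}

#' Logistic model of confirmed disability progression
#'
#' @param patients Patient-level data.frame with a logical `cdp` column
#'   (undetermined CDP rows are dropped).
#' @param predictor Name of the predictor column.
#' @param covariates Adjustment columns (only those present are used).
#' @return A model result on the odds-ratio scale (betas exponentiated),
#'   flagged `separation` when the fit is separated.
#' @export
fit_cdp_logistic <- function(patients, predictor,
                             covariates = default_covariates) {
  covariates <- intersect(covariates, names(patients))
  d <- patients[!is.na(patients$cdp), , drop = FALSE]
  if (length(unique(d$cdp)) < 2L)
    stop("fit_cdp_logistic: need at least one event and one non-event")
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  f <- stats::as.formula(paste("cdp ~", rhs))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(abs(beta[-1]) > 15)) sep <- TRUE
  fv <- stats::fitted(fit)
  if (any(fv < 1e-8) || any(fv > 1 - 1e-8)) sep <- TRUE
  wald_tidy("LOGISTIC", beta, se,
            flags = if (sep) "separation" else character(0), exp_beta = TRUE)
}

#' Cohort summary in the style of the descriptive tables
#'
#' Patient-level prevalences (any SEL, any PRL, both), stratum counts,
#' lesion-level counts with the SEL x PRL breakdown and the PRL/total and
#' SEL/total ratios, and per-patient count medians/ranges. Percentages are
#' rounded half-up to whole percent; ratios to 2 decimals. An empty
#' cohort returns an empty (but well-formed) summary.
#'
#' @param patients Patient-level data.frame (may have 0 rows).
#' @param lesions Lesion-level data.frame with `patient_id`, `sel`, `prl`.
#' @return List of summary blocks.
#' @export
cohort_summary <- function(patients, lesions) {
  n <- nrow(patients)
  if (n == 0L) {
    return(list(n_patients = 0L, strata = NULL, patient_pct = NULL,
                lesion_table = NULL, ratios = NULL, per_patient = NULL))
  }
  strat <- stratify_patients(patients, lesions)
  pat <- strat$patients
  any_sel <- pat$stratum != "SEL_NEG"
  has_prl <- tapply(lesions$prl, lesions$patient_id, any)
  any_prl <- has_prl[as.character(pat$patient_id)]
  any_prl[is.na(any_prl)] <- FALSE
  both <- pat$stratum == "SEL_PRL_BOTH"
  pct <- function(k) round_half_up(100 * k / n)
  n_lesions <- nrow(lesions)
  n_sel <- sum(lesions$sel)
  n_prl <- sum(lesions$prl)
  n_both <- sum(lesions$sel & lesions$prl)
  lesion_table <- data.frame(
    group = c("total", "SEL", "non-SEL"),
    n = c(n_lesions, n_sel, n_lesions - n_sel),
    prl = c(n_prl, n_both, n_prl - n_both),
    no_prl = c(n_lesions - n_prl, n_sel - n_both,
               (n_lesions - n_sel) - (n_prl - n_both)),
    prop_prl = round_half_up(c(n_prl / n_lesions, n_both / n_sel,
                               (n_prl - n_both) / (n_lesions - n_sel)), 2)
  )
  counts_by_pat <- tapply(rep(1L, nrow(lesions)), lesions$patient_id, sum)
  cnt <- as.vector(counts_by_pat[as.character(pat$patient_id)])
  cnt[is.na(cnt)] <- 0L
  list(
    n_patients = n,
    strata = strat$counts,
    patient_pct = c(sel_pos = pct(sum(any_sel)),
                    prl_pos = pct(sum(any_prl)),
                    both = pct(sum(both))),
    lesion_table = lesion_table,
    ratios = c(prl_total = round_half_up(n_prl / n_lesions, 2),
               sel_total = round_half_up(n_sel / n_lesions, 2),
               pct_prl_that_are_sel =
                 if (n_prl > 0) round_half_up(100 * n_both / n_prl) else NA_real_),
    per_patient = data.frame(
      measure = "total_lesion_count",
      median = stats::median(cnt),
      min = min(cnt), max = max(cnt))
  )
}
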