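# Slowly-expanding-lesion (SEL) classification from the Jacobian
# determinant of a longitudinal displacement field. A lesion's expansion
# summary is its mean log-Jacobian annualized by the follow-up interval;
# within-patient z-scores grade SEL candidates into possible and definite.

#' Default SEL classification thresholds
#'
#' @param tau_abs Minimum detectable annualized mean log-Jacobian (per
#'   year); lesions below it are never SELs.
#' @param z_pos Within-patient z-score gate for the possible-SEL grade.
#'   The default `-Inf` makes detection purely absolute and reserves the
#'   z-score for grading (see the methods vignette for why a finite gate
#'   systematically misses slow-growing SELs in high-burden patients).
#' @param z_def Within-patient z-score above which a SEL candidate is
#'   graded definite.
#' @param min_volume_mm3 FLAIR-space eligibility threshold; only lesions
#'   strictly over this volume are classified.
#' @param zscore_scope `"patient"` (default) or `"cohort"`.
#' @return List of thresholds used by [classify_sel()].
#' @export
sel_config <- function(tau_abs = 0.002, z_pos = -Inf, z_def = 1.0,
                       min_volume_mm3 = 10, zscore_scope = c("patient", "cohort")) {
  list(tau_abs = tau_abs, z_pos = z_pos, z_def = z_def,
       min_volume_mm3 = min_volume_mm3,
       zscore_scope = match.arg(zscore_scope))
}

#' Lesions eligible for SEL classification
#'
#' Lesions whose baseline volume is strictly over the threshold
#' (default 10 mm^3), in ascending id order.
#'
#' @param labels A [label_volume()].
#' @param min_volume_mm3 Strict lower volume bound, mm^3.
#' @return Integer vector of lesion ids (possibly empty).
#' @export
eligible_lesions <- function(labels, min_volume_mm3 = 10) {
  stopifnot(inherits(labels, "label_volume"))
  ids <- label_set(labels)
  if (length(ids) == 0L) return(integer(0))
  counts <- tabulate(labels$labels, nbins = max(ids))
  vv <- voxel_volume(labels)
  ids[counts[ids] * vv > min_volume_mm3]
}

#' Per-lesion Jacobian summaries
#'
#' For each eligible lesion: baseline volume, arithmetic mean of J over the
#' lesion voxels, and the annualized mean log-Jacobian
#' `mean(log J) / follow_up_years`. The mean of log J (not log of mean J)
#' is used so that yearly field compositions add.
#'
#' @param labels A [label_volume()] on the same lattice as `J`.
#' @param J [scalar_volume()] of Jacobian determinants.
#' @param follow_up_years Positive scan interval in years.
#' @param min_volume_mm3 Eligibility threshold passed to
#'   [eligible_lesions()].
#' @return data.frame with columns `lesion_id`, `volume_mm3`, `mean_J`,
#'   `annualized_logJ` (and unset `z_J`, `sel_class`).
#' @export
summarize_jacobian <- function(labels, J, follow_up_years,
                               min_volume_mm3 = 10) {
  stopifnot(inherits(labels, "label_volume"), inherits(J, "scalar_volume"))
  if (!is.finite(follow_up_years) || follow_up_years <= 0)
    stop("follow_up_years must be positive")
  if (!all(vol_dim(labels) == vol_dim(J)))
    stop("labels and J must share a lattice")
  ids <- eligible_lesions(labels, min_volume_mm3)
  vv <- voxel_volume(labels)
  lab <- as.vector(labels$labels)
  jv <- as.vector(J$data)
  keep <- lab %in% ids
  lab <- lab[keep]; jv <- jv[keep]
  if (any(jv <= 0))
    stop("non-diffeomorphic field: J <= 0 inside lesion(s) ",
         paste(unique(lab[jv <= 0]), collapse = ", "))
  f <- factor(lab, levels = ids)
  n_vox <- as.vector(table(f))
  mean_J <- as.vector(tapply(jv, f, mean))
  mean_logJ <- as.vector(tapply(log(jv), f, mean))
  data.frame(
    lesion_id = ids,
    volume_mm3 = n_vox * vv,
    mean_J = if (length(ids)) mean_J else numeric(0),
    annualized_logJ = if (length(ids)) mean_logJ / follow_up_years else numeric(0),
    z_J = NA_real_,
    sel_class = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Within-patient z-score of the annualized log-Jacobian
#'
#' `z = (x - mean(x)) / sd(x)` with sample sd (ddof 1) over the patient's
#' eligible lesions. With fewer than 2 lesions, or a degenerate sd of 0,
#' z is left `NA` and `z_fallback` is set so classification falls back to
#' the absolute threshold alone.
#'
#' @param stats data.frame from [summarize_jacobian()].
#' @return `stats` with `z_J` filled and a logical `z_fallback` column.
#' @export
zscore_normalize <- function(stats) {
  stopifnot(is.data.frame(stats), "annualized_logJ" %in% names(stats))
  x <- stats$annualized_logJ
  n <- length(x)
  if (n >= 2L && stats::sd(x) > 0) {
    stats$z_J <- (x - mean(x)) / stats::sd(x)
    stats$z_fallback <- FALSE
  } else {
    stats$z_J <- NA_real_
    stats$z_fallback <- TRUE
  }
  stats
}

#' Classify lesions as non-SEL / possible SEL / definite SEL
#'
#' Definite: `annualized_logJ >= tau_abs` and `z_J >= z_def`. Possible:
#' `annualized_logJ >= tau_abs` and `z_def > z_J >= z_pos`. Everything
#' else (including all ineligible lesions) is non-SEL; the combined SEL
#' indicator is `sel_class != "NON_SEL"`. When the z-score is unavailable
#' (`z_fallback`), lesions over the absolute threshold are graded
#' possible.
#'
#' @param stats data.frame from [zscore_normalize()].
#' @param config Thresholds from [sel_config()].
#' @return `stats` with `sel_class` (factor NON_SEL/POSSIBLE_SEL/
#'   DEFINITE_SEL) and logical `sel` columns.
#' @export
classify_sel <- function(stats, config = sel_config()) {
  x <- stats$annualized_logJ
  z <- stats$z_J
  fallback <- if ("z_fallback" %in% names(stats)) stats$z_fallback else is.na(z)
  cls <- rep("NON_SEL", nrow(stats))
  abs_ok <- x >= config$tau_abs
  zz <- ifelse(fallback | is.na(z), config$z_pos, z)  # fallback: absolute only
  cls[abs_ok & zz >= config$z_def & !(fallback | is.na(z))] <- "DEFINITE_SEL"
  cls[abs_ok & zz >= config$z_pos & cls == "NON_SEL"] <- "POSSIBLE_SEL"
  stats$sel_class <- factor(cls, levels = c("NON_SEL", "POSSIBLE_SEL",
                                            "DEFINITE_SEL"))
  stats$sel <- stats$sel_class != "NON_SEL"
  stats
}

#' SEL detection for one patient
#'
#' Chains [summarize_jacobian()], [zscore_normalize()] and
#' [classify_sel()]: computes the Jacobian determinant of the displacement
#' field, summarizes it over every eligible lesion, z-normalizes within the
#' patient and grades SELs.
#'
#' @param labels Baseline [label_volume()].
#' @param field [displacement_field()] on the same lattice.
#' @param follow_up_years Positive scan interval, years.
#' @param config [sel_config()] thresholds.
#' @param sigma Field smoothing in mm forwarded to
#'   [jacobian_determinant()].
#' @return Tidy data.frame, one row per eligible lesion.
#' @export
detect_sels <- function(labels, field, follow_up_years,
                        config = sel_config(), sigma = 0) {
  J <- jacobian_determinant(field, sigma = sigma)
  stats <- summarize_jacobian(labels, J, follow_up_years,
                              min_volume_mm3 = config$min_volume_mm3)
  classify_sel(zscore_normalize(stats), config)
}
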