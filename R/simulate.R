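# Synthetic longitudinal-MRI cohort generator with known ground truth.
#
# The stated world mirrors the study cohort: 61 patients, negative-
# binomial lesion counts (median ~20, range to 80), 41% of lesions truly
# expanding with annual radial growth 2-5%/yr, rim probability 7% for
# expanding and 4% for non-expanding lesions (marginal ~5%), follow-up
# uniform on 0.7-8.3 years, EDSS slopes per stratum 0.15 / -0.02 / -0.11
# points/year. Displacement fields are analytic: a uniform radial scaling
# inside each expanding lesion, C1-tapered to identity at 3x the core
# radius, so every Jacobian has a closed form and fields of different
# lesions never overlap.

#' Simulation configuration
#'
#' Defaults encode the emulated study cohort; every stochastic draw is
#' reproducible from `seed`.
#'
#' @param seed Mandatory integer seed.
#' @param n_patients Cohort size.
#' @param lesion_nb_size,lesion_nb_mu Negative-binomial lesion-count
#'   parameters (median ~20); counts are clamped to `[1, lesion_max]`.
#' @param lesion_max Upper clamp on per-patient lesion count.
#' @param sel_fraction Probability a lesion truly expands.
#' @param prl_rate_sel,prl_rate_nonsel Rim probability given true SEL
#'   status (joint enrichment: 0.07 vs 0.04 gives the ~0.05 marginal).
#' @param flair_dim,flair_spacing Analysis (1 mm isotropic) lattice.
#' @param swi_spacing SWI lattice spacing (transverse 2-D acquisition).
#' @param lesion_radius_range Ellipsoid semi-axis range, mm.
#' @param growth_range Annual radial growth factor range for true SELs.
#' @param rim_contrast Rim depth in noise-SD units on the SWI channel.
#' @param rim_coverage Fraction of shell voxels carrying the rim.
#' @param n_veins Vein confounders implanted per patient.
#' @param vein_contrast,vein_width Vein darkness (noise-SD units) and
#'   tube width (mm).
#' @param noise_sd Gaussian intensity noise SD (image units; tissue
#'   contrast is O(1)).
#' @param edss_slopes Named generating EDSS slopes (points/year) for
#'   strata SEL_PRL_BOTH / SEL_ONLY / SEL_NEG.
#' @param edss_noise_sd Visit-level EDSS noise SD before rounding to the
#'   0.5-point scale.
#' @param followup_range Final-scan time range, years (uniform).
#' @param round_edss Round simulated EDSS to the 0.5 grid (clamped to
#'   0-10). Turn off only for noiseless identifiability checks.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_patients = 61L,
                       lesion_nb_size = 2, lesion_nb_mu = 23,
                       lesion_max = 80L,
                       sel_fraction = 0.41,
                       prl_rate_sel = 0.07, prl_rate_nonsel = 0.04,
                       flair_dim = c(96L, 96L, 96L),
                       flair_spacing = c(1, 1, 1),
                       swi_spacing = c(0.65, 0.65, 3),
                       lesion_radius_range = c(1.8, 4.0),
                       growth_range = c(1.02, 1.05),
                       rim_contrast = 3, rim_coverage = 0.9,
                       n_veins = 4L, vein_contrast = 3, vein_width = 0.8,
                       noise_sd = 0.05,
                       edss_slopes = c(SEL_PRL_BOTH = 0.15, SEL_ONLY = -0.02,
                                       SEL_NEG = -0.11),
                       edss_noise_sd = 0.5,
                       followup_range = c(0.7, 8.3),
                       round_edss = TRUE) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              lesion_nb_size = lesion_nb_size, lesion_nb_mu = lesion_nb_mu,
              lesion_max = as.integer(lesion_max),
              sel_fraction = sel_fraction,
              prl_rate_sel = prl_rate_sel, prl_rate_nonsel = prl_rate_nonsel,
              flair_dim = as.integer(flair_dim),
              flair_spacing = flair_spacing, swi_spacing = swi_spacing,
              lesion_radius_range = lesion_radius_range,
              growth_range = growth_range,
              rim_contrast = rim_contrast, rim_coverage = rim_coverage,
              n_veins = as.integer(n_veins), vein_contrast = vein_contrast,
              vein_width = vein_width,
              noise_sd = noise_sd, edss_slopes = edss_slopes,
              edss_noise_sd = edss_noise_sd,
              followup_range = followup_range, round_edss = round_edss)
  fr <- c(cfg$sel_fraction, cfg$prl_rate_sel, cfg$prl_rate_nonsel,
          cfg$rim_coverage)
  if (any(fr < 0 | fr > 1)) stop("sim_config: fractions must lie in [0, 1]")
  if (any(cfg$flair_spacing <= 0) || any(cfg$swi_spacing <= 0))
    stop("sim_config: spacings must be positive")
  if (any(cfg$growth_range < 1)) stop("sim_config: growth factors must be >= 1")
  if (cfg$n_patients < 1L) stop("sim_config: need at least one patient")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate one EDSS trajectory
#'
#' `EDSS(t) = baseline + slope * t + noise`, clamped to `[0, 10]` and
#' rounded to the 0.5-point scale (optionally).
#'
#' @param baseline Baseline EDSS (on the 0.5 grid).
#' @param slope Points/year.
#' @param times Increasing visit times, years.
#' @param noise_sd Visit-level noise SD.
#' @param round_to_scale Round/clamp onto the valid EDSS grid.
#' @return data.frame with `time` and `edss`.
#' @export
simulate_edss <- function(baseline, slope, times, noise_sd = 0,
                          round_to_scale = TRUE) {
  stopifnot(is.finite(slope), !is.unsorted(times))
  e <- baseline + slope * times + stats::rnorm(length(times), 0, noise_sd)
  if (round_to_scale) e <- pmin(pmax(round_half_up(e * 2) / 2, 0), 10)
  data.frame(time = times, edss = e)
}

# ---- lesion-level truth (no images) ----------------------------------

draw_lesions <- function(cfg, patient_id, followup_years) {
  n <- stats::rnbinom(1L, size = cfg$lesion_nb_size, mu = cfg$lesion_nb_mu)
  n <- min(max(n, 1L), cfg$lesion_max)
  sel <- stats::runif(n) < cfg$sel_fraction
  prl <- stats::runif(n) < ifelse(sel, cfg$prl_rate_sel, cfg$prl_rate_nonsel)
  rr <- cfg$lesion_radius_range
  ax <- matrix(stats::runif(3 * n, rr[1], rr[2]), ncol = 3)
  # a rim must span >= 2 of the 3 mm SWI slices and leave an in-plane
  # shell: rim-bearing lesions are drawn from the upper size range
  ax[prl, 3] <- pmax(ax[prl, 3], 3.3)
  ax[prl, 1] <- pmax(ax[prl, 1], 2.4)
  ax[prl, 2] <- pmax(ax[prl, 2], 2.4)
  growth <- ifelse(sel, stats::runif(n, cfg$growth_range[1], cfg$growth_range[2]), 1)
  data.frame(patient_id = patient_id, lesion_id = seq_len(n),
             true_sel = sel, true_prl = prl,
             ax1 = ax[, 1], ax2 = ax[, 2], ax3 = ax[, 3],
             growth_annual = growth,
             total_scale = growth^followup_years,
             analytic_volume_mm3 = 4 / 3 * pi * ax[, 1] * ax[, 2] * ax[, 3])
}

draw_patient_meta <- function(cfg, i) {
  fu <- stats::runif(1, cfg$followup_range[1], cfg$followup_range[2])
  t_int <- stats::runif(1, 0.3, 0.6) * fu
  data.frame(
    patient_id = i,
    age_baseline = min(max(stats::rnorm(1, 36, 12), 14.1), 64.9),
    sex = factor(if (stats::runif(1) < 0.69) "F" else "M", levels = c("F", "M")),
    disease_duration = min(max(stats::rlnorm(1, log(0.4), 1.2), 0.1), 16.6),
    relapse_count = stats::rpois(1, 0.7),
    treated_end = stats::runif(1) < 0.84,
    followup_years = fu,
    t_intermediate = t_int,
    edss_baseline = min(max(round_half_up(stats::rgamma(1, 2.2, scale = 0.8) * 2) / 2, 0), 4.5),
    nbv = stats::rnorm(1, 1505.7, 75.1),
    cgm = stats::rnorm(1, 839.9, 47.9),
    dgm = stats::rnorm(1, 49.4, 3.7),
    bpf = stats::rnorm(1, 0.77, 0.02))
}

patient_truth <- function(cfg, i) {
  set.seed(mix_seed(cfg$seed, i))
  meta <- draw_patient_meta(cfg, i)
  lesions <- draw_lesions(cfg, i, meta$followup_years)
  stratum <- if (!any(lesions$true_sel)) "SEL_NEG"
             else if (any(lesions$true_prl)) "SEL_PRL_BOTH" else "SEL_ONLY"
  meta$true_stratum <- factor(stratum, levels = names(cfg$edss_slopes))
  slope <- unname(cfg$edss_slopes[stratum])
  times <- c(0, meta$t_intermediate, meta$followup_years,
             meta$followup_years + 0.5)
  visits <- simulate_edss(meta$edss_baseline, slope, times,
                          cfg$edss_noise_sd, cfg$round_edss)
  visits$patient_id <- i
  visits$is_confirmation <- c(rep(FALSE, length(times) - 1L), TRUE)
  meta$generating_slope <- slope
  meta$cdp_true <- cdp_flag(visits[, c("time", "edss")])
  list(meta = meta, lesions = lesions, visits = visits)
}

#' Clinical-only synthetic cohort (no images)
#'
#' Same generating process as [generate_cohort()] for everything
#' downstream of the images: lesion-level truth flags, per-lesion volumes
#' taken as the analytic ellipsoid volumes, EDSS trajectories by true
#' stratum, CDP by construction. Useful for statistical recovery studies
#' where voxel data would only cost time.
#'
#' @param config A [sim_config()].
#' @return List of data.frames: `patients`, `lesions`, `visits`.
#' @export
simulate_clinical <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- lapply(seq_len(config$n_patients), function(i) patient_truth(config, i))
  patients <- do.call(rbind, lapply(out, `[[`, "meta"))
  lesions <- do.call(rbind, lapply(out, `[[`, "lesions"))
  visits <- do.call(rbind, lapply(out, `[[`, "visits"))
  vol_by_pat <- tapply(lesions$analytic_volume_mm3, lesions$patient_id, sum)
  patients$total_lesion_volume_ml <- as.vector(vol_by_pat[as.character(patients$patient_id)]) / 1000
  patients$log_tlv <- log(patients$total_lesion_volume_ml)
  patients$sel_count <- as.vector(tapply(lesions$true_sel, lesions$patient_id, sum)[as.character(patients$patient_id)])
  patients$prl_count <- as.vector(tapply(lesions$true_prl, lesions$patient_id, sum)[as.character(patients$patient_id)])
  patients$stratum <- patients$true_stratum
  patients$cdp <- patients$cdp_true
  list(patients = patients, lesions = lesions, visits = visits)
}

# ---- geometry --------------------------------------------------------

# place lesion centres so that no lesion intrudes into another lesion's
# displacement support (support radius 3*(rmax+1.5) for expanding
# lesions, rmax otherwise); returns a matrix of centres (mm, world) or
# fewer rows than requested when space runs out
place_lesions <- function(lesions, cfg) {
  rmax <- pmax(lesions$ax1, pmax(lesions$ax2, lesions$ax3))
  core_r <- rmax + 1.5
  support <- ifelse(lesions$true_sel, 3 * core_r, rmax)
  ord <- order(support, decreasing = TRUE)
  ext <- cfg$flair_dim * cfg$flair_spacing
  centres <- matrix(NA_real_, nrow = nrow(lesions), ncol = 3)
  placed <- integer(0)
  for (j in ord) {
    margin <- support[j] + 2
    if (any(ext - 2 * margin <= 0)) next
    ok <- FALSE
    for (try in seq_len(300L)) {
      cand <- stats::runif(3, margin, ext - margin)
      if (length(placed) == 0L) { ok <- TRUE; break }
      d <- sqrt(colSums((t(centres[placed, , drop = FALSE]) - cand)^2))
      need <- pmax(support[placed] + rmax[j], support[j] + rmax[placed]) + 1
      if (all(d > need)) { ok <- TRUE; break }
    }
    if (ok) {
      centres[j, ] <- cand
      placed <- c(placed, j)
    }
  }
  centres
}

random_rotation <- function() {
  # QR of a Gaussian matrix, determinant fixed to +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# paint one rotated ellipsoid into an integer label array (in place via
# return); grid is axis-aligned with spacing sp and zero origin
paint_ellipsoid <- function(lab, centre, semi, rot, sp, id) {
  d <- dim(lab)
  rmax <- max(semi)
  lo <- pmax(floor((centre - rmax) / sp) + 1L, 1L)
  hi <- pmin(ceiling((centre + rmax) / sp) + 1L, d)
  xs <- (lo[1]:hi[1] - 1) * sp[1] - centre[1]
  ys <- (lo[2]:hi[2] - 1) * sp[2] - centre[2]
  zs <- (lo[3]:hi[3] - 1) * sp[3] - centre[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  local_ <- t(rot) %*% rbind(g$x, g$y, g$z)
  inside <- (local_[1, ] / semi[1])^2 + (local_[2, ] / semi[2])^2 +
            (local_[3, ] / semi[3])^2 <= 1
  sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub[array(inside, dim = dim(sub)) & sub == 0L] <- id
  lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  lab
}

# C1 radial expansion displacement about a centre: pure scaling by factor
# s out to core radius r0, smoothstep taper to identity at 3*r0
add_radial_field <- function(vec, centre, r0, s, sp) {
  d <- dim(vec)[1:3]
  rsup <- 3 * r0
  lo <- pmax(floor((centre - rsup) / sp) + 1L, 1L)
  hi <- pmin(ceiling((centre + rsup) / sp) + 1L, d)
  xs <- (lo[1]:hi[1] - 1) * sp[1] - centre[1]
  ys <- (lo[2]:hi[2] - 1) * sp[2] - centre[2]
  zs <- (lo[3]:hi[3] - 1) * sp[3] - centre[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X <- array(rep(xs, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), dim = c(nx, ny, nz))
  rho <- sqrt(X^2 + Y^2 + Z^2)
  t_ <- pmin(pmax((rho - r0) / (2 * r0), 0), 1)
  w <- 1 - 3 * t_^2 + 2 * t_^3
  m <- (s - 1) * w
  for (c_ in 1:3) {
    comp <- list(X, Y, Z)[[c_]]
    vec[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], c_] <-
      vec[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], c_] + m * comp
  }
  vec
}

#' Implant a tubular hypointensity (vein confounder)
#'
#' Darkens every voxel whose centre lies within `width / 2` mm of the
#' polyline `path`. A width of 0 leaves the volume unchanged.
#'
#' @param swi [scalar_volume()] to modify.
#' @param path Matrix of world points (n x 3) defining the polyline.
#' @param width Tube diameter, mm.
#' @param depth Intensity decrement applied inside the tube.
#' @return The modified [scalar_volume()].
#' @export
implant_vein <- function(swi, path, width, depth) {
  if (width <= 0) return(swi)
  path <- as.matrix(path)
  sp <- swi$spacing
  d <- dim(swi$data)
  # densify the polyline well below the voxel scale
  pts <- do.call(rbind, lapply(seq_len(nrow(path) - 1L), function(i) {
    a <- path[i, ]; b <- path[i + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / (0.25 * min(sp))))
    cbind(seq(a[1], b[1], length.out = n), seq(a[2], b[2], length.out = n),
          seq(a[3], b[3], length.out = n))
  }))
  r <- width / 2
  rv <- ceiling(r / sp)
  marked <- array(FALSE, dim = d)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    ctr <- round(p / sp) + 1L
    if (any(ctr < 1L) || any(ctr > d)) next
    # rasterize the curve itself (keeps the tube connected even when it
    # is thinner than a voxel), then thicken to the requested width
    marked[ctr[1], ctr[2], ctr[3]] <- TRUE
    lo <- pmax(ctr - rv, 1L); hi <- pmin(ctr + rv, d)
    for (kk in lo[3]:hi[3]) for (jj in lo[2]:hi[2]) for (ii in lo[1]:hi[1]) {
      if (marked[ii, jj, kk]) next
      cx <- c((ii - 1) * sp[1], (jj - 1) * sp[2], (kk - 1) * sp[3])
      if (sum((cx - p)^2) <= r^2) marked[ii, jj, kk] <- TRUE
    }
  }
  swi$data[marked] <- swi$data[marked] - depth
  swi
}

# ---- full image bundle for one patient -------------------------------

# deterministic background: ellipsoidal "grey matter" rind around a
# white-matter core, axis-aligned grids with zero origin
tissue_background <- function(dims, sp, wm = 1.0, gm = 0.85) {
  ext <- dims * sp
  xs <- ((seq_len(dims[1]) - 1) * sp[1] - ext[1] / 2) / (0.42 * ext[1])
  ys <- ((seq_len(dims[2]) - 1) * sp[2] - ext[2] / 2) / (0.42 * ext[2])
  zs <- ((seq_len(dims[3]) - 1) * sp[3] - ext[3] / 2) / (0.42 * ext[3])
  R2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  ifelse(R2 <= 1, wm, gm)
}

#' Generate the full image bundle for one patient
#'
#' Baseline FLAIR-, T1- and SWI-like volumes, the lesion label volume,
#' the analytic displacement field (baseline to final follow-up), the
#' lesion ids resampled to SWI space, ground-truth lesion table, clinical
#' row and visit list. Deterministic given the config seed and patient
#' index.
#'
#' @param config A [sim_config()].
#' @param i Patient index (1-based).
#' @param followups Also synthesise the two follow-up T1-like volumes
#'   (only needed when writing a full bundle to disk).
#' @return List: `flair`, `t1`, `swi`, `labels`, `swi_labels`, `field`,
#'   `lesions` (ground truth, placed lesions only), `meta`, `visits`,
#'   optionally `t1_followups`.
#' @export
generate_patient <- function(config, i, followups = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  truth <- patient_truth(config, i)   # reseeds deterministically
  les <- truth$lesions
  sp <- config$flair_spacing
  dims <- config$flair_dim
  centres <- place_lesions(les, config)
  placed <- which(!is.na(centres[, 1]))
  les <- les[placed, , drop = FALSE]
  centres <- centres[placed, , drop = FALSE]
  les$lesion_id <- seq_len(nrow(les))
  lab <- array(0L, dim = dims)
  rots <- vector("list", nrow(les))
  for (j in seq_len(nrow(les))) {
    rots[[j]] <- random_rotation()
    lab <- paint_ellipsoid(lab, centres[j, ], unlist(les[j, c("ax1", "ax2", "ax3")]),
                           rots[[j]], sp, les$lesion_id[j])
  }
  les$centre_x <- centres[, 1]; les$centre_y <- centres[, 2]
  les$centre_z <- centres[, 3]
  labels <- label_volume(lab, sp)
  # displacement field: radial expansion at true SELs, identity elsewhere
  vec <- array(0, dim = c(dims, 3L))
  for (j in which(les$true_sel)) {
    rmax <- max(les$ax1[j], les$ax2[j], les$ax3[j])
    vec <- add_radial_field(vec, centres[j, ], rmax + 1.5,
                            les$total_scale[j], sp)
  }
  field <- displacement_field(vec, sp)
  # intensity channels
  bg <- tissue_background(dims, sp)
  lesion_mask <- lab > 0L
  flair_arr <- bg + 0.5 * lesion_mask +
    stats::rnorm(prod(dims), 0, config$noise_sd)
  t1_arr <- bg - 0.3 * lesion_mask +
    stats::rnorm(prod(dims), 0, config$noise_sd)
  flair <- scalar_volume(flair_arr, sp, channel = "FLAIR")
  t1 <- scalar_volume(t1_arr, sp, channel = "T1")
  # SWI lattice covering the same world extent
  swi_sp <- config$swi_spacing
  swi_dims <- as.integer(ceiling(dims * sp / swi_sp))
  swi_clean <- tissue_background(swi_dims, swi_sp)
  swi_geom <- scalar_volume(swi_clean, swi_sp, channel = "SWI")
  swi_labels <- resample_labels_nn(labels, swi_geom)
  # implant rims on true-PRL lesions (shell of the resampled lesion)
  rim_cov <- data.frame(lesion_id = les$lesion_id, rim_coverage = 0)
  for (j in which(les$true_prl)) {
    id <- les$lesion_id[j]
    if (!id %in% label_set(swi_labels)) next
    cr <- shell_masks_crop(swi_labels$labels, id, 1L, 2L)
    shell_idx <- which(array(FALSE, dim = swi_dims) |
                         replace_block(swi_dims, cr))
    take <- shell_idx[stats::runif(length(shell_idx)) < config$rim_coverage]
    swi_clean[take] <- swi_clean[take] -
      config$rim_contrast * config$noise_sd
    rim_cov$rim_coverage[j] <- length(take) / max(length(shell_idx), 1L)
  }
  les <- merge(les, rim_cov, by = "lesion_id", sort = TRUE)
  swi_vol <- scalar_volume(swi_clean, swi_sp, channel = "SWI")
  # vein confounders: random straight tubes through the volume
  ext <- dims * sp
  for (v in seq_len(config$n_veins)) {
    a <- stats::runif(3, 0.15, 0.85) * ext
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    len <- stats::runif(1, 20, 40)
    swi_vol <- implant_vein(swi_vol, rbind(a - dir * len / 2, a + dir * len / 2),
                            config$vein_width,
                            config$vein_contrast * config$noise_sd)
  }
  swi_vol$data <- swi_vol$data +
    stats::rnorm(prod(swi_dims), 0, config$noise_sd)
  out <- list(flair = flair, t1 = t1, swi = swi_vol, labels = labels,
              swi_labels = swi_labels, field = field, lesions = les,
              meta = truth$meta, visits = truth$visits)
  if (followups) {
    out$t1_followups <- lapply(1:2, function(k)
      scalar_volume(bg - 0.3 * lesion_mask +
                      stats::rnorm(prod(dims), 0, config$noise_sd),
                    sp, channel = "T1"))
  }
  out
}

# full-grid index vector of the cropped shell mask
replace_block <- function(dims, cr) {
  m <- array(FALSE, dim = dims)
  m[cr$i0[1]:cr$i1[1], cr$i0[2]:cr$i1[2], cr$i0[3]:cr$i1[3]] <- cr$shell
  m
}

#' Generate a full synthetic cohort
#'
#' Iterates [generate_patient()] over the cohort. When `out_dir` is given,
#' writes per-patient NIfTI bundles (`flair`, `t1`, `swi`, `labels`,
#' `field`, follow-up T1s), `clinical.csv`, `visits.csv`,
#' `ground_truth.csv` and `resolved_config.json`; config violations abort
#' before any file is written. Identical seeds give byte-identical CSVs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return List: `patients`, `lesions` (ground truth of placed lesions),
#'   `visits`; and `out_dir` when written.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  write_files <- !is.null(out_dir)
  if (write_files) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metas <- vector("list", config$n_patients)
  lesions <- vector("list", config$n_patients)
  visits <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    b <- generate_patient(config, i, followups = write_files)
    metas[[i]] <- b$meta
    lesions[[i]] <- b$lesions
    visits[[i]] <- b$visits
    if (write_files) {
      pd <- file.path(out_dir, sprintf("patient_%03d", i))
      dir.create(pd, showWarnings = FALSE)
      write_volume(b$flair, file.path(pd, "flair.nii.gz"))
      write_volume(b$t1, file.path(pd, "t1.nii.gz"))
      write_volume(b$swi, file.path(pd, "swi.nii.gz"))
      write_volume(b$labels, file.path(pd, "labels.nii.gz"))
      write_volume(b$field, file.path(pd, "field.nii.gz"))
      for (k in seq_along(b$t1_followups)) {
        write_volume(b$t1_followups[[k]],
                     file.path(pd, sprintf("t1_followup%d.nii.gz", k)))
      }
    }
  }
  patients <- do.call(rbind, metas)
  lesions <- do.call(rbind, lesions)
  visits <- do.call(rbind, visits)
  vox <- prod(config$flair_spacing)
  # patient-level aggregates from placed lesions
  agg <- function(v, f) as.vector(tapply(v, f, sum)[as.character(patients$patient_id)])
  patients$total_lesion_volume_ml <- agg(lesions$analytic_volume_mm3,
                                         lesions$patient_id) / 1000
  patients$log_tlv <- log(patients$total_lesion_volume_ml)
  patients$stratum <- patients$true_stratum
  patients$cdp <- patients$cdp_true
  out <- list(patients = patients, lesions = lesions, visits = visits)
  if (write_files) {
    utils::write.csv(patients, file.path(out_dir, "clinical.csv"),
                     row.names = FALSE)
    utils::write.csv(visits, file.path(out_dir, "visits.csv"),
                     row.names = FALSE)
    utils::write.csv(lesions, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    cfg_out <- config
    class(cfg_out) <- NULL
    jsonlite::write_json(cfg_out, file.path(out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$out_dir <- out_dir
  }
  out
}
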