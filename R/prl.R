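# Rule-based surrogate of the visual paramagnetic-rim-lesion (PRL)
# criteria on the SWI channel: (1) a partial or complete hypointense rim
# relative to the lesion core and the surrounding white matter, (2)
# correspondence to the FLAIR lesion edge (enforced by construction --
# lesion ids are carried into SWI space by nearest-neighbour resampling),
# (3) rim visible on at least two consecutive axial slices; tubular dark
# structures (veins) are excluded.

#' Default PRL scoring thresholds
#'
#' All cuts are expressed in perilesional-ring standard-deviation units or
#' as fractions, so scoring is invariant under affine rescaling of the SWI
#' intensities.
#'
#' @param k Rim-dark cut: a shell voxel is dark when its intensity is below
#'   `min(core mean, ring mean) - k * ring SD`.
#' @param c_min Minimum dark fraction of the shell ("partial" rims
#'   allowed).
#' @param c_slice Per-axial-slice dark fraction above which the slice
#'   counts as rim-bearing.
#' @param core_erosion,ring_dilation Shell geometry, voxels (6-connected
#'   element).
#' @param e_min Principal-axis elongation ratio at or above which a dark
#'   component is vein-like.
#' @param t_max Maximum cross-section thickness (mm, 2 SDs along the
#'   middle axis) for a vein-like component.
#' @param vein_overlap Fraction of a lesion's dark shell voxels that must
#'   belong to vein-like components before the lesion is discounted as a
#'   vein crossing.
#' @return List of thresholds used by [rim_score()].
#' @export
prl_config <- function(k = 1.5, c_min = 0.25, c_slice = 0.2,
                       core_erosion = 1L, ring_dilation = 2L,
                       e_min = 3, t_max = 2, vein_overlap = 0.5) {
  list(k = k, c_min = c_min, c_slice = c_slice,
       core_erosion = as.integer(core_erosion),
       ring_dilation = as.integer(ring_dilation),
       e_min = e_min, t_max = t_max, vein_overlap = vein_overlap)
}

#' Is a dark component tubular (vein-like)?
#'
#' Second-moment analysis of the component's voxel coordinates in world
#' (mm) units: vein-like when the principal-axis elongation ratio
#' `sqrt(l1/l2)` is at least `e_min` and the cross-section thickness
#' (2 SDs along the middle axis) is at most `t_max` mm -- a tube, not a
#' shell.
#'
#' @param swi [scalar_volume()] the component lives in (geometry source).
#' @param dark_component Non-empty logical 3-D array.
#' @param config [prl_config()] thresholds.
#' @return TRUE when the component is vein-like.
#' @export
vein_filter <- function(swi, dark_component, config = prl_config()) {
  idx <- which(dark_component)
  if (length(idx) == 0L) stop("vein_filter: empty component")
  if (length(idx) < 3L) return(FALSE)  # too small to call tubular
  ijk <- t(arrayInd(idx, dim(dark_component))) - 1
  xyz <- voxel_to_world(swi$affine, ijk)
  ev <- eigen(stats::cov(t(xyz)), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-12)
  elong <- sqrt(ev[1] / ev[2])
  thickness <- 2 * sqrt(ev[2])
  elong >= config$e_min && thickness <= config$t_max
}

#' Rim score for one lesion in SWI space
#'
#' Builds core/shell/ring masks on the SWI lattice, thresholds shell
#' voxels against `min(core mean, ring mean) - k * ring SD`, measures the
#' dark fraction of the shell overall and per axial slice, finds the
#' longest run of rim-bearing slices, and discounts dark structure that is
#' tubular (vein-like). A lesion absent from SWI space after resampling is
#' scored absent (criterion-2 failure) with `is_prl = FALSE`.
#'
#' @param swi SWI-like [scalar_volume()].
#' @param labels_in_swi Lesion ids resampled onto the SWI lattice (see
#'   [resample_labels_nn()]).
#' @param flair_labels Original FLAIR-space [label_volume()] (id source).
#' @param lesion_id Lesion to score.
#' @param config [prl_config()] thresholds.
#' @return One-row data.frame: `lesion_id`, `rim_contrast` (core mean
#'   minus shell mean in ring-SD units), `coverage_fraction`,
#'   `n_consecutive_slices`, `vein_like`, `absent_in_swi`, `is_prl`.
#' @export
rim_score <- function(swi, labels_in_swi, flair_labels, lesion_id,
                      config = prl_config()) {
  stopifnot(inherits(swi, "scalar_volume"),
            inherits(labels_in_swi, "label_volume"))
  if (!lesion_id %in% label_set(flair_labels))
    stop("lesion_id ", lesion_id, " absent from FLAIR labels")
  empty <- data.frame(lesion_id = lesion_id, rim_contrast = NA_real_,
                      coverage_fraction = 0, n_consecutive_slices = 0L,
                      vein_like = FALSE, absent_in_swi = TRUE,
                      is_prl = FALSE)
  if (!lesion_id %in% label_set(labels_in_swi)) return(empty)
  cr <- shell_masks_crop(labels_in_swi$labels, lesion_id,
                         config$core_erosion, config$ring_dilation)
  sub <- swi$data[cr$i0[1]:cr$i1[1], cr$i0[2]:cr$i1[2], cr$i0[3]:cr$i1[3],
                  drop = FALSE]
  shell_v <- sub[cr$shell]
  ring_v <- sub[cr$ring]
  if (length(shell_v) == 0L || length(ring_v) < 2L) return(empty)
  ring_mean <- mean(ring_v)
  ring_sd <- stats::sd(ring_v)
  if (!is.finite(ring_sd) || ring_sd == 0) return(empty)
  # a core emptied by erosion (thin lesion on thick slices) leaves the
  # surrounding white matter as the only intensity reference
  ref_mean <- if (cr$core_empty) ring_mean
              else min(mean(sub[cr$core]), ring_mean)
  cut <- ref_mean - config$k * ring_sd
  dark <- cr$shell & (sub < cut)
  coverage <- sum(dark) / sum(cr$shell)
  rim_contrast <- (ref_mean - mean(shell_v)) / ring_sd
  # criterion 3: per-axial-slice dark fraction, longest consecutive run
  shell_per_slice <- apply(cr$shell, 3, sum)
  dark_per_slice <- apply(dark, 3, sum)
  flagged <- shell_per_slice > 0 &
    dark_per_slice / pmax(shell_per_slice, 1L) >= config$c_slice
  n_consec <- longest_run(flagged)
  # vein discounting: dark voxels in shell or ring, labelled 26-connected;
  # the lesion is vein-like when most of its dark shell sits in tubular
  # components
  vein_like <- FALSE
  if (sum(dark) > 0L) {
    dark_all <- (cr$shell | cr$ring) & (sub < cut)
    comp <- array(.cc26_label(as.vector(dark_all), dim(dark_all)),
                  dim = dim(dark_all))
    sub_geom <- scalar_volume(sub, swi$spacing, crop_affine(swi$affine, cr$i0))
    dark_labels <- unique(comp[dark])
    vein_vox <- 0L
    for (lb in dark_labels) {
      m <- comp == lb
      if (vein_filter(sub_geom, m, config)) {
        vein_vox <- vein_vox + sum(m & dark)
      }
    }
    vein_like <- vein_vox / sum(dark) >= config$vein_overlap
  }
  is_prl <- coverage >= config$c_min && n_consec >= 2L && !vein_like
  data.frame(lesion_id = lesion_id, rim_contrast = rim_contrast,
             coverage_fraction = coverage, n_consecutive_slices = n_consec,
             vein_like = vein_like, absent_in_swi = FALSE, is_prl = is_prl)
}

longest_run <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

# affine of a cropped sub-grid whose 1-based full-grid origin is i0
crop_affine <- function(affine, i0) {
  shift <- affine %*% c(i0 - 1L, 1)
  out <- affine
  out[1:3, 4] <- shift[1:3]
  out
}

#' Score every FLAIR lesion for a paramagnetic rim
#'
#' @param swi SWI-like [scalar_volume()].
#' @param labels_in_swi Lesion ids on the SWI lattice; computed from
#'   `flair_labels` by [resample_labels_nn()] when omitted.
#' @param flair_labels FLAIR-space [label_volume()].
#' @param config [prl_config()] thresholds.
#' @return Tidy data.frame of rim scores, one row per FLAIR lesion
#'   (possibly zero rows), deterministic given inputs.
#' @export
classify_prls <- function(swi, flair_labels, labels_in_swi = NULL,
                          config = prl_config()) {
  if (is.null(labels_in_swi)) {
    labels_in_swi <- resample_labels_nn(flair_labels, swi)
  }
  ids <- label_set(flair_labels)
  if (length(ids) == 0L) {
    return(data.frame(lesion_id = integer(0), rim_contrast = numeric(0),
                      coverage_fraction = numeric(0),
                      n_consecutive_slices = integer(0),
                      vein_like = logical(0), absent_in_swi = logical(0),
                      is_prl = logical(0)))
  }
  do.call(rbind, lapply(ids, function(id) {
    rim_score(swi, labels_in_swi, flair_labels, id, config)
  }))
}
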