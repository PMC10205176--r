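#' Phantom configuration for the synthetic dynamic-PET cohort
#'
#' Collects everything the generator needs: grid geometry, the per-region
#' simplified-reference-tissue-model (SRTM) parameters, the noise level and
#' the group-specific texture correlation lengths.
#'
#' The default layout is an ellipsoidal brain with a central blood pool, a
#' white-matter core and a grey-matter shell split into eight named cortical
#' ROIs. Disease subjects receive (a) an elevated binding potential in
#' `ad_roi` and (b) a smoother multiplicative intensity field (longer spatial
#' correlation length), so that the two quantification branches see group
#' differences of controlled size.
#'
#' @param grid_shape integer length-3, voxels per axis (default 32 x 32 x 16).
#' @param amplitude peak of the reference input curve (kBq/mL, nominal units).
#' @param k2_grey,k2_white reference efflux rate constants (1/min).
#' @param r1_white delivery ratio of white matter relative to grey.
#' @param bp_ad binding potential added in `ad_roi` for disease subjects;
#'   the between-group DVR difference in that ROI.
#' @param bp_sd between-subject SD of the per-ROI baseline binding potential:
#'   each subject draws an independent `max(0, N(0, bp_sd))` per grey ROI, so
#'   no region is uniformly devoid of binding and ROI-mean DVRs vary across
#'   subjects at a realistic scale. 0 disables the jitter.
#' @param ad_roi character vector of ROI names with elevated binding in the
#'   disease group (default `"superior_frontal_gyrus"`).
#' @param noise_scale frame-noise scale: the per-frame Gaussian SD is
#'   `noise_scale / sqrt(duration_s)` (kBq/mL * sqrt(s)); 0 = noiseless.
#' @param texture_correlation_length named numeric `c(HC = , AD = )`, Gaussian
#'   smoothing SD (voxels) of the multiplicative texture field per group.
#' @param texture_len_sd between-subject SD of the correlation length
#'   (truncated below at 0.2 voxels); 0 makes all subjects of a group share
#'   the group value.
#' @param texture_amplitude relative SD of the multiplicative field; 0
#'   disables it.
#' @param schedule acquisition [frame_schedule()].
#' @param voxel_size_mm voxel edge lengths (mm).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32, 32, 16),
                           amplitude = 30,
                           k2_grey = 0.15, k2_white = 0.05,
                           r1_white = 0.35,
                           bp_ad = 0.03,
                           bp_sd = 0.07,
                           ad_roi = "superior_frontal_gyrus",
                           noise_scale = 2,
                           texture_correlation_length = c(HC = 1.2, AD = 1.5),
                           texture_len_sd = 0.25,
                           texture_amplitude = 0.05,
                           schedule = make_frame_schedule(),
                           voxel_size_mm = c(2, 2, 2)) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            amplitude > 0, k2_grey > 0, k2_white > 0, r1_white > 0,
            bp_ad >= 0, bp_sd >= 0, noise_scale >= 0,
            texture_amplitude >= 0, texture_len_sd >= 0,
            all(texture_correlation_length > 0),
            all(c("HC", "AD") %in% names(texture_correlation_length)))
  structure(list(grid_shape = as.integer(grid_shape), amplitude = amplitude,
                 k2_grey = k2_grey, k2_white = k2_white, r1_white = r1_white,
                 bp_ad = bp_ad, bp_sd = bp_sd, ad_roi = ad_roi,
                 noise_scale = noise_scale,
                 texture_correlation_length = texture_correlation_length,
                 texture_len_sd = texture_len_sd,
                 texture_amplitude = texture_amplitude, schedule = schedule,
                 voxel_size_mm = voxel_size_mm),
            class = "phantom_config")
}

#' Names of the grey-matter ROIs in the default phantom layout
#' @return character vector of eight ROI names (labels 1..8).
#' @export
phantom_roi_names <- function() {
  c("superior_frontal_gyrus", "middle_frontal_gyrus", "precentral_gyrus",
    "superior_temporal_gyrus", "middle_temporal_gyrus", "hippocampus",
    "inferior_parietal_lobule", "precuneus")
}

# Deterministic geometric layout: ellipsoidal brain mask, central blood pool,
# white-matter core, grey shell split into octants (ROI labels 1..8).
# Returns mask, atlas (grey ROI labels, 0 elsewhere), tissue codes
# (1 grey, 2 white, 3 blood) and the normalised radius field.
default_region_layout <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- 0.45 * nx; ay <- 0.45 * ny; az <- 0.45 * nz
  x <- ((1:nx) - cx) / ax
  y <- ((1:ny) - cy) / ay
  z <- ((1:nz) - cz) / az
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  mask <- array(as.integer(r2 <= 1), grid_shape)
  tissue <- array(0L, grid_shape)
  tissue[mask == 1] <- 1L                       # grey by default
  tissue[r2 <= 0.36 & mask == 1] <- 2L          # white core   (r <= 0.6)
  tissue[r2 <= 0.0225 & mask == 1] <- 3L        # blood pool   (r <= 0.15)
  octant <- array(0L, grid_shape)
  xs <- array(rep((1:nx) > cx, times = ny * nz), grid_shape)
  ys <- aperm(array(rep((1:ny) > cy, times = nx * nz), c(ny, nx, nz)),
              c(2, 1, 3))
  zs <- aperm(array(rep((1:nz) > cz, times = nx * ny), c(nz, nx, ny)),
              c(2, 3, 1))
  octant[] <- 1L + xs + 2L * ys + 4L * zs
  atlas <- array(0L, grid_shape)
  atlas[tissue == 1L] <- octant[tissue == 1L]
  list(mask = mask, atlas = atlas, tissue = tissue)
}

# Isotropic Gaussian random field: white noise smoothed by a separable
# Gaussian kernel of SD `corr_len` voxels, then standardised to zero mean and
# unit SD over the whole grid. Drawn from the current RNG state.
gaussian_random_field <- function(grid_shape, corr_len) {
  g <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  if (corr_len > 0) {
    half <- max(1L, ceiling(3 * corr_len))
    k <- stats::dnorm(seq(-half, half), sd = corr_len)
    k <- k / sum(k)
    g <- convolve_axis(g, k, 1)
    g <- convolve_axis(g, k, 2)
    g <- convolve_axis(g, k, 3)
  }
  (g - mean(g)) / stats::sd(g)
}

# 1D kernel convolution along one axis of a 3D array, replicate padding.
convolve_axis <- function(a, kernel, axis) {
  half <- (length(kernel) - 1L) / 2L
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  idx <- pmin(pmax(outer(seq_len(dp[1]), seq(-half, half), `+`), 1L), dp[1])
  out <- matrix(0, dp[1], ncol(m))
  for (j in seq_along(kernel)) out <- out + kernel[j] * m[idx[, j], ]
  res <- array(out, dp)
  aperm(res, order(perm))
}

#' Generate one synthetic dynamic-PET subject
#'
#' Builds the subject's dynamic image from the region layout: every grey ROI
#' gets an SRTM curve with `R1 = 1, k2 = k2_grey` and a subject-specific
#' binding potential `max(0, N(0, bp_sd))` (plus `bp_ad` inside `ad_roi` for
#' disease subjects); white matter gets low-delivery slow kinetics and the
#' blood pool the fast input-like class curve. The volume is multiplied by a
#' spatially correlated field whose correlation length is drawn around the
#' group value, and zero-mean Gaussian frame noise with SD
#' `noise_scale / sqrt(frame_duration_s)` is added. `true_dvr` stores the
#' ground-truth 1 + BP per voxel.
#'
#' @param config a [phantom_config()].
#' @param group `"AD"` or `"HC"`.
#' @param seed integer seed; identical seeds give bit-identical subjects.
#' @param subject_id optional id string.
#' @return Object of class `synthetic_subject`: list with `dynamic_image`
#'   ([dynamic_pet_image()]), `brain_mask`, `atlas`, `true_dvr`, `class_map`
#'   (voxel kinetic-class codes matching [make_kinetic_basis()] column order),
#'   `label`, `subject_id`.
#' @export
generate_subject <- function(config, group = c("HC", "AD"), seed = 1L,
                             subject_id = NULL) {
  group <- match.arg(group)
  lay <- default_region_layout(config$grid_shape)
  if (sum(lay$mask) == 0L) stop("empty brain mask")
  if (length(unique(lay$tissue[lay$mask == 1])) < 2L) {
    stop("degenerate region layout")
  }
  sched <- config$schedule
  basis <- make_kinetic_basis(sched, amplitude = config$amplitude)
  ref <- tac(basis$class_tacs[, "grey_no_binding"], sched)
  nf <- n_frames(sched)

  set.seed(as.integer(seed %% .Machine$integer.max))

  # per-ROI binding potential for this subject
  rois <- phantom_roi_names()
  bp_roi <- if (config$bp_sd > 0) {
    pmax(0, stats::rnorm(length(rois), 0, config$bp_sd))
  } else rep(0, length(rois))
  names(bp_roi) <- rois
  if (group == "AD" && config$bp_ad > 0) {
    if (any(is.na(match(config$ad_roi, rois)))) stop("unknown ad_roi name")
    bp_roi[config$ad_roi] <- bp_roi[config$ad_roi] + config$bp_ad
  }
  bp_map <- array(0, config$grid_shape)
  for (r in seq_along(rois)) {
    bp_map[lay$atlas == r & lay$tissue == 1L] <- bp_roi[r]
  }

  # region curves
  grey_curves <- lapply(unique(bp_roi), function(bp) {
    if (bp == 0) ref$values else {
      simulate_target_tac(ref, R1 = 1, k2 = config$k2_grey, BP = bp)$values
    }
  })
  names(grey_curves) <- as.character(unique(bp_roi))
  white <- simulate_target_tac(ref, R1 = config$r1_white,
                               k2 = config$k2_white, BP = 0)$values
  blood <- basis$class_tacs[, "blood"]

  idx <- which(lay$mask == 1L)
  nvox <- length(idx)
  tis <- lay$tissue[idx]
  bp_vox <- bp_map[idx]
  V <- matrix(0, nvox, nf)
  for (bp in unique(bp_roi)) {
    rows <- tis == 1L & bp_vox == bp
    if (any(rows)) {
      V[rows, ] <- rep(grey_curves[[as.character(bp)]], each = sum(rows))
    }
  }
  V[tis == 2L, ] <- rep(white, each = sum(tis == 2L))
  V[tis == 3L, ] <- rep(blood, each = sum(tis == 3L))

  if (config$texture_amplitude > 0) {
    len <- config$texture_correlation_length[[group]]
    if (config$texture_len_sd > 0) {
      len <- max(0.2, stats::rnorm(1, len, config$texture_len_sd))
    }
    field <- gaussian_random_field(config$grid_shape, len)
    mult <- pmax(1 + config$texture_amplitude * field[idx], 0.05)
    V <- V * mult
  }
  if (config$noise_scale > 0) {
    sd_f <- config$noise_scale / sqrt(sched$duration_s)
    V <- V + matrix(stats::rnorm(nvox * nf), nvox, nf) *
      rep(sd_f, each = nvox)
  }

  data4d <- array(0, c(config$grid_shape, nf))
  flat <- matrix(data4d, ncol = nf)
  flat[idx, ] <- V
  data4d <- array(flat, c(config$grid_shape, nf))

  true_dvr <- array(1, config$grid_shape)
  true_dvr[idx] <- 1 + bp_vox
  true_dvr[lay$mask == 0L] <- 0

  class_map <- array(0L, config$grid_shape)
  class_map[idx] <- ifelse(tis == 1L & bp_vox == 0, 1L,
                    ifelse(tis == 2L, 2L,
                    ifelse(tis == 3L, 3L, 4L)))

  structure(list(
    dynamic_image = dynamic_pet_image(data4d, sched, config$voxel_size_mm),
    brain_mask = lay$mask, atlas = lay$atlas, true_dvr = true_dvr,
    class_map = class_map, label = group,
    subject_id = if (is.null(subject_id)) sprintf("sub_%06d", seed) else subject_id),
    class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("Synthetic subject %s (%s): %s grid, %d brain voxels\n",
              x$subject_id, x$label,
              paste(dim(x$brain_mask), collapse = "x"), sum(x$brain_mask)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Disease subjects first, then controls. Per-subject seeds are derived
#' deterministically from the master seed as
#' `(seed %% 1e6) * 1000 + subject index`, so the whole cohort is reproduced
#' bit-for-bit by the master seed alone.
#'
#' @param n_ad,n_hc subject counts per group (default 19 and 21).
#' @param config a [phantom_config()].
#' @param seed master integer seed.
#' @return list of [generate_subject()] results, length `n_ad + n_hc`.
#' @export
generate_cohort <- function(n_ad = 19, n_hc = 21, config = phantom_config(),
                            seed = 1L) {
  if (n_ad < 1 || n_hc < 1) stop("cohort sizes must be >= 1")
  groups <- c(rep("AD", n_ad), rep("HC", n_hc))
  base <- (as.integer(seed) %% 1000000L) * 1000L
  lapply(seq_along(groups), function(i) {
    generate_subject(config, groups[i], seed = base + i,
                     subject_id = sprintf("sub%03d", i))
  })
}
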