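#' Dynamic PET image
#'
#' @param data 4D numeric array (x, y, z, frame) of activity (kBq/mL).
#' @param schedule a [frame_schedule()]; its length must equal the frame axis.
#' @param voxel_size_mm numeric length-3, voxel edge lengths in mm.
#' @return Object of class `dynamic_pet_image`.
#' @export
dynamic_pet_image <- function(data, schedule, voxel_size_mm = c(2, 2, 2)) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array")
  if (dim(data)[4] != n_frames(schedule)) {
    stop("frame axis length must equal the schedule length")
  }
  if (any(!is.finite(data))) stop("activity values must be finite")
  structure(list(data = data, schedule = schedule,
                 voxel_size_mm = voxel_size_mm),
            class = "dynamic_pet_image")
}

#' @export
print.dynamic_pet_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic PET image: %dx%dx%d voxels, %d frames, %.0f min\n",
              d[1], d[2], d[3], d[4], total_duration_s(x$schedule) / 60))
  invisible(x)
}

# In-mask voxel TACs as an (n_voxels x n_frames) matrix.
mask_tac_matrix <- function(img, mask) {
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("mask is empty")
  nf <- dim(img$data)[4]
  m <- matrix(img$data, ncol = nf)[idx, , drop = FALSE]
  list(tacs = m, idx = idx)
}

#' Extract a pseudo-reference TAC by supervised cluster analysis
#'
#' Decomposes every in-mask voxel TAC, after normalisation to unit area under
#' the curve, against the four area-normalised kinetic class TACs by
#' non-negative least squares. Voxels are ranked by the weight of the
#' grey-matter-without-specific-binding class and the top `fraction` of
#' in-mask voxels form the reference region; the reference TAC is the plain
#' mean of their unnormalised TACs. Alternatively an absolute weight
#' threshold may be supplied instead of a fraction.
#'
#' @param img a [dynamic_pet_image()].
#' @param brain_mask 3D array, nonzero inside the brain.
#' @param basis a [make_kinetic_basis()] object on the same schedule.
#' @param fraction proportion (0, 1] of in-mask voxels to keep (default 0.1).
#' @param weight_threshold optional absolute weight cut; if given, voxels with
#'   a non-binding grey-matter weight above it are kept and `fraction` is
#'   ignored.
#' @param ref_class index or name of the class used for ranking (default the
#'   first class, grey matter without specific binding).
#' @return Object of class `reference_extraction`: list with `reference_tac`
#'   ([tac()]), `reference_mask` (3D 0/1 array), `class_weight_maps` (list of
#'   3D arrays, one per class) and `weights` (voxels x classes matrix).
#' @export
extract_reference_tac <- function(img, brain_mask, basis, fraction = 0.1,
                                  weight_threshold = NULL, ref_class = 1L) {
  if (!same_schedule(img$schedule, basis$schedule)) {
    stop("image and basis must share one frame schedule")
  }
  if (!is.null(weight_threshold)) {
    if (weight_threshold <= 0) stop("weight_threshold must be > 0")
  } else if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  A <- basis$class_tacs
  if (qr(A)$rank < ncol(A)) stop("singular basis: class TACs are collinear")
  A_norm <- apply(A, 2, function(v) v / tac_auc(v, basis$schedule))
  vt <- mask_tac_matrix(img, brain_mask)
  areas <- as.vector(vt$tacs %*% auc_weights(img$schedule))
  ok <- areas > 0
  if (!any(ok)) stop("no voxel with positive activity in mask")
  V_norm <- vt$tacs[ok, , drop = FALSE] / areas[ok]
  W <- t(nnls_multi(A_norm, t(V_norm)))  # voxels x classes
  if (is.character(ref_class)) ref_class <- match(ref_class, basis$class_names)
  w_ref <- W[, ref_class]
  if (!is.null(weight_threshold)) {
    keep <- which(w_ref >= weight_threshold)
    if (length(keep) == 0L) stop("no voxel passes the weight threshold")
  } else {
    n_keep <- max(1L, round(fraction * length(w_ref)))
    keep <- order(-w_ref, seq_along(w_ref))[seq_len(n_keep)]
  }
  dims <- dim(brain_mask)
  ref_mask <- array(0L, dims)
  idx_ok <- vt$idx[ok]
  ref_mask[idx_ok[keep]] <- 1L
  ref_values <- colMeans(vt$tacs[ok, , drop = FALSE][keep, , drop = FALSE])
  weight_maps <- lapply(seq_len(ncol(W)), function(k) {
    m <- array(NA_real_, dims)
    m[idx_ok] <- W[, k]
    m
  })
  names(weight_maps) <- basis$class_names
  structure(list(reference_tac = tac(ref_values, img$schedule),
                 reference_mask = ref_mask,
                 class_weight_maps = weight_maps,
                 weights = W, voxel_index = idx_ok),
            class = "reference_extraction")
}

# Trapezoid quadrature weights such that area = values %*% w, on
# (0, midpoints) with C(0) = 0; shared by TAC normalisation and Logan.
auc_weights <- function(schedule) {
  t <- c(0, frame_mid_min(schedule))
  nt <- length(t)
  w <- numeric(nt)
  dt <- diff(t)
  w[1:(nt - 1)] <- w[1:(nt - 1)] + dt / 2
  w[2:nt] <- w[2:nt] + dt / 2
  w[-1]
}

# Cumulative trapezoid integral of frame values on (0, midpoints), C(0) = 0.
# Works on a matrix (voxels x frames) or a vector.
cum_frame_integral <- function(values, schedule) {
  vec <- is.null(dim(values))
  if (vec) values <- matrix(values, nrow = 1)
  t <- frame_mid_min(schedule)
  out <- values
  out[, 1] <- t[1] * values[, 1] / 2
  for (j in 2:ncol(values)) {
    out[, j] <- out[, j - 1] +
      (t[j] - t[j - 1]) * (values[, j] + values[, j - 1]) / 2
  }
  if (vec) drop(out) else out
}

#' Logan reference-tissue graphical analysis of one TAC
#'
#' Regresses \eqn{y(T) = \int_0^T C_T \,dt / C_T(T)} on
#' \eqn{x(T) = \int_0^T C_{ref}\, dt / C_T(T)} over the frames whose midpoint
#' is at or after `t_star`; the slope of the late linear segment estimates the
#' distribution volume ratio (DVR). Cumulative integrals use frame-wise
#' trapezoids on the frame midpoints.
#'
#' @param target target-tissue [tac()].
#' @param reference reference-tissue [tac()] on the same schedule.
#' @param t_star start of the linear segment (minutes). At least 3 frame
#'   midpoints must lie at or after it.
#' @return list with `dvr` (slope), `intercept`, `r2` and `n_frames_used`.
#' @export
logan_dvr_tac <- function(target, reference, t_star = 20) {
  if (!same_schedule(target$schedule, reference$schedule)) {
    stop("target and reference must share one schedule")
  }
  sched <- target$schedule
  mid <- frame_mid_min(sched)
  sel <- mid >= t_star
  if (sum(sel) < 3L) stop("need at least 3 frames with midpoint >= t_star")
  if (any(target$values[sel] <= 0)) {
    stop("non-positive target activity in the fit window")
  }
  int_t <- cum_frame_integral(target$values, sched)
  int_r <- cum_frame_integral(reference$values, sched)
  x <- int_r[sel] / target$values[sel]
  y <- int_t[sel] / target$values[sel]
  if (stats::var(x) <= 1e-12 * (1 + mean(x)^2)) stop("degenerate x variance")
  fit <- stats::lsfit(x, y)
  res <- fit$residuals
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(dvr = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r2 = r2, n_frames_used = sum(sel))
}

#' Voxelwise Logan DVR image
#'
#' Applies the Logan reference graphical analysis to every in-mask voxel,
#' vectorised over voxels. Voxels with non-positive activity in the fit
#' window are flagged `NaN` and counted; voxels outside the mask are `NA`.
#'
#' @param img a [dynamic_pet_image()].
#' @param brain_mask 3D array, nonzero inside the brain.
#' @param reference reference-tissue [tac()].
#' @param t_star start of the Logan linear segment (minutes).
#' @return Object of class `dvr_image`: list with 3D arrays `data` (DVR),
#'   `intercept_map`, `fit_r2_map`, plus `t_star` and `n_failed`.
#' @export
logan_dvr_image <- function(img, brain_mask, reference, t_star = 20) {
  if (!same_schedule(img$schedule, reference$schedule)) {
    stop("image and reference must share one schedule")
  }
  mid <- frame_mid_min(img$schedule)
  sel <- mid >= t_star
  if (sum(sel) < 3L) stop("need at least 3 frames with midpoint >= t_star")
  vt <- mask_tac_matrix(img, brain_mask)
  V <- vt$tacs
  int_r <- cum_frame_integral(reference$values, img$schedule)
  INT_T <- cum_frame_integral(V, img$schedule)[, sel, drop = FALSE]
  Vs <- V[, sel, drop = FALSE]
  good <- rowSums(Vs <= 0) == 0
  X <- sweep(1 / Vs, 2, int_r[sel], `*`)
  Y <- INT_T / Vs
  mx <- rowMeans(X); my <- rowMeans(Y)
  sxx <- rowSums((X - mx)^2)
  sxy <- rowSums((X - mx) * (Y - my))
  syy <- rowSums((Y - my)^2)
  good <- good & sxx > 1e-12 * mx^2
  slope <- ifelse(good, sxy / sxx, NaN)
  icpt <- ifelse(good, my - slope * mx, NaN)
  r2 <- ifelse(good, slope * sxy / syy, NaN)
  dims <- dim(brain_mask)
  mk <- function(v) { a <- array(NA_real_, dims); a[vt$idx] <- v; a }
  structure(list(data = mk(slope), intercept_map = mk(icpt),
                 fit_r2_map = mk(r2), t_star = t_star,
                 n_failed = sum(!good)),
            class = "dvr_image")
}

#' @export
print.dvr_image <- function(x, ...) {
  v <- x$data[is.finite(x$data)]
  cat(sprintf("DVR image: t* = %g min, %d voxels fit (%d failed), mean DVR %.3f\n",
              x$t_star, length(v), x$n_failed, mean(v)))
  invisible(x)
}

#' Suggest a Logan linearization start time
#'
#' Scans candidate start times and returns the earliest one after which the
#' maximum relative deviation of the Logan points from the line fitted to the
#' final segment stays below `max_rel_dev`.
#'
#' @param target,reference [tac()]s on one schedule.
#' @param candidates candidate start times (minutes).
#' @param max_rel_dev maximum tolerated relative deviation (default 0.10).
#' @return the chosen t* in minutes (latest candidate if none qualifies).
#' @export
suggest_t_star <- function(target, reference,
                           candidates = c(5, 10, 15, 20, 25, 30),
                           max_rel_dev = 0.10) {
  sched <- target$schedule
  mid <- frame_mid_min(sched)
  candidates <- sort(candidates)
  last <- candidates[length(candidates)]
  ref_fit <- logan_dvr_tac(target, reference, t_star = last)
  int_t <- cum_frame_integral(target$values, sched)
  int_r <- cum_frame_integral(reference$values, sched)
  for (ts in candidates) {
    sel <- mid >= ts & target$values > 0
    x <- int_r[sel] / target$values[sel]
    y <- int_t[sel] / target$values[sel]
    pred <- ref_fit$intercept + ref_fit$dvr * x
    if (max(abs(y - pred) / pmax(abs(y), 1e-12)) < max_rel_dev) return(ts)
  }
  last
}

#' Region-of-interest means of a parametric image
#'
#' @param param_image 3D numeric array (e.g. the `data` slot of a
#'   [logan_dvr_image()] result) with `NA`/`NaN` marking unfit voxels.
#' @param atlas 3D integer array of ROI labels; 0 = unlabeled.
#' @param roi_names optional named integer vector mapping names to labels; by
#'   default all nonzero labels present in the atlas are reported.
#' @return data.frame with columns `roi`, `label`, `n_voxels`, `mean`, `sd`
#'   (mean and SD over finite in-ROI voxels).
#' @export
roi_means <- function(param_image, atlas, roi_names = NULL) {
  if (inherits(param_image, "dvr_image")) param_image <- param_image$data
  if (!all(dim(param_image) == dim(atlas))) {
    stop("atlas must be aligned with the image")
  }
  if (is.null(roi_names)) {
    labs <- sort(unique(atlas[atlas != 0]))
    roi_names <- stats::setNames(labs, paste0("roi_", labs))
  }
  rows <- lapply(names(roi_names), function(nm) {
    lab <- roi_names[[nm]]
    v <- param_image[atlas == lab]
    if (length(v) == 0L) stop("label absent from atlas: ", lab)
    v <- v[is.finite(v)]
    if (length(v) == 0L) stop("ROI has zero finite voxels: ", nm)
    data.frame(roi = nm, label = lab, n_voxels = length(v),
               mean = mean(v), sd = stats::sd(v))
  })
  do.call(rbind, rows)
}
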