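#' Sum late frames of a dynamic image
#'
#' Voxelwise sum of the frames whose intervals lie inside the requested
#' window (frame boundaries matched with 1 s tolerance). The default 40-60
#' minute window selects the last four 300 s frames of the standard protocol.
#'
#' @param img a [dynamic_pet_image()].
#' @param window_min numeric length-2, window start and end in minutes.
#' @return Object of class `summed_image`: list with `data` (3D array),
#'   `window_min` and `frames_used` (frame indices).
#' @export
sum_frames <- function(img, window_min = c(40, 60)) {
  w <- window_min * 60
  sched <- img$schedule
  if (w[1] < -1 || w[2] > total_duration_s(sched) + 1) {
    stop("window not covered by the frame schedule")
  }
  sel <- which(sched$start_s >= w[1] - 1 & frame_end_s(sched) <= w[2] + 1)
  if (length(sel) == 0L) stop("window selects zero frames")
  data <- img$data[, , , sel, drop = FALSE]
  structure(list(data = apply(data, 1:3, sum), window_min = window_min,
                 frames_used = sel),
            class = "summed_image")
}

#' Quantize a summed image to discrete gray levels
#'
#' Linear min-max scaling over in-mask voxels:
#' `level = floor((x - lo) / (hi - lo) * Ng)`, clamped to `[0, Ng - 1]`.
#' Optional percentile clipping bounds `lo`/`hi` before scaling for outlier
#' robustness.
#'
#' @param img a [sum_frames()] result or a 3D numeric array.
#' @param mask 3D array, nonzero inside the brain.
#' @param Ng number of gray levels (>= 2; default 64).
#' @param clip_quantiles optional length-2 probabilities, e.g. `c(0.005,
#'   0.995)`, used to clip intensities before scaling.
#' @return Object of class `quantized_volume`: list with `levels` (3D integer
#'   array, `NA` outside mask), `Ng` and `bounds`.
#' @export
quantize <- function(img, mask, Ng = 64, clip_quantiles = NULL) {
  if (inherits(img, "summed_image")) img <- img$data
  if (Ng < 2) stop("Ng must be >= 2")
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("mask is empty")
  x <- img[idx]
  if (!is.null(clip_quantiles)) {
    q <- stats::quantile(x, clip_quantiles, names = FALSE)
    x <- pmin(pmax(x, q[1]), q[2])
  }
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("constant image in mask: quantization undefined")
  lev <- pmin(floor((x - lo) / (hi - lo) * Ng), Ng - 1)
  levels <- array(NA_integer_, dim(img))
  levels[idx] <- as.integer(lev)
  structure(list(levels = levels, Ng = as.integer(Ng), bounds = c(lo, hi)),
            class = "quantized_volume")
}

#' Distance-1 3D displacement set
#'
#' The 13 unique direction vectors of the 26-neighbourhood (one per
#' antipodal pair). With symmetric accumulation, pooling these covers all 26
#' neighbours, which makes pooled-GLCM features invariant to axis permutation.
#'
#' @param distance integer displacement magnitude multiplier (default 1).
#' @return 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
glcm_offsets <- function(distance = 1L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(g, 1, function(v) {
    nz <- v[v != 0]
    length(nz) > 0 && nz[1] > 0  # lexicographically positive half
  })
  g[keep, , drop = FALSE] * as.integer(distance)
}

#' Accumulate a pooled 3D gray-level co-occurrence matrix
#'
#' Counts co-occurring level pairs over all offsets; a pair contributes only
#' if both voxels are inside the mask (no padding). Counts are pooled across
#' offsets, the transpose is added when `symmetric = TRUE`, and the pooled
#' counts are normalised to a joint probability matrix.
#'
#' @param q a [quantize()] result.
#' @param mask optional extra 3D mask; by default the non-`NA` support of `q`.
#' @param offsets integer matrix of displacement vectors (rows), as from
#'   [glcm_offsets()].
#' @param symmetric add the transpose before normalisation (default TRUE).
#' @return Object of class `glcm`: list with `p` (Ng x Ng probabilities),
#'   `offsets`, `pair_count` and `symmetric`.
#' @export
compute_glcm <- function(q, mask = NULL, offsets = glcm_offsets(),
                         symmetric = TRUE) {
  offsets <- matrix(as.integer(offsets), ncol = 3)
  if (nrow(offsets) == 0L) stop("offsets must be nonempty")
  lev <- q$levels
  if (!is.null(mask)) lev[mask == 0] <- NA_integer_
  Ng <- q$Ng
  d <- dim(lev)
  counts <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    lo <- pmax(1L, 1L - o)
    hi <- pmin(d, d - o)
    if (any(hi < lo)) next  # offset larger than the volume along some axis
    x1 <- lo[1]:hi[1]; y1 <- lo[2]:hi[2]; z1 <- lo[3]:hi[3]
    a <- lev[x1, y1, z1, drop = FALSE]
    b <- lev[x1 + o[1], y1 + o[2], z1 + o[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    code <- a[ok] * Ng + b[ok] + 1L
    tab <- tabulate(code, nbins = Ng * Ng)
    counts <- counts + matrix(tab, Ng, Ng, byrow = TRUE)
  }
  pair_count <- sum(counts)
  if (pair_count == 0) stop("no valid voxel pairs for any offset")
  if (symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), offsets = offsets,
                 pair_count = pair_count, symmetric = symmetric),
            class = "glcm")
}

#' The fourteen classical Haralick texture features
#'
#' Computes, from a normalised GLCM `p(i, j)` (levels indexed 1..Ng):
#' energy, contrast, correlation, variance, homogeneity (inverse difference
#' moment), sum average/variance/entropy over the diagonal-sum distribution
#' `p_{x+y}`, entropy, difference variance/entropy over `p_{|x-y|}`, the two
#' information measures of correlation and the maximal correlation
#' coefficient (square root of the second-largest eigenvalue of
#' `Q(i,j) = sum_k p(i,k) p(j,k) / (p_x(i) p_y(k))`). All entropies use log
#' base 2 with the convention `0 * log 0 = 0`; a small guard (1e-12) protects
#' the logs in the information-measure terms.
#'
#' If a marginal is degenerate (a single occupied level), correlation and the
#' maximal correlation coefficient are undefined and reported as `NaN` with a
#' warning.
#'
#' @param glcm a [compute_glcm()] result (or a bare normalised matrix).
#' @return Object of class `haralick_features`: named numeric vector of 14
#'   features.
#' @export
haralick_features <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) glcm$p else as.matrix(glcm)
  if (abs(sum(p) - 1) > 1e-6) stop("GLCM must be normalised")
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  eps <- 1e-12
  log2z <- function(x) ifelse(x > 0, log2(x), 0)

  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(seq_len(Ng) * px)
  mu_y <- sum(seq_len(Ng) * py)
  sd_x <- sqrt(sum((seq_len(Ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(Ng) - mu_y)^2 * py))

  # diagonal-sum / difference distributions
  sums <- as.vector(i + j)       # 2 .. 2 Ng
  diffs <- as.vector(abs(i - j)) # 0 .. Ng - 1
  p_sum <- vapply(2:(2 * Ng), function(k) sum(p[sums == k]), numeric(1))
  p_dif <- vapply(0:(Ng - 1), function(k) sum(p[diffs == k]), numeric(1))
  k_sum <- 2:(2 * Ng)
  k_dif <- 0:(Ng - 1)

  energy <- sum(p^2)
  contrast <- sum(k_dif^2 * p_dif)
  mu <- sum(i * p)  # grand level mean (= mu_x for symmetric p)
  variance <- sum((i - mu)^2 * p)
  homogeneity <- sum(p / (1 + (i - j)^2))
  sum_average <- sum(k_sum * p_sum)
  sum_variance <- sum((k_sum - sum_average)^2 * p_sum)
  sum_entropy <- -sum(p_sum * log2z(p_sum))
  entropy <- -sum(p * log2z(p))
  dif_average <- sum(k_dif * p_dif)
  difference_variance <- sum((k_dif - dif_average)^2 * p_dif)
  difference_entropy <- -sum(p_dif * log2z(p_dif))

  hx <- -sum(px * log2z(px))
  hy <- -sum(py * log2z(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * log2(pxy + eps))
  hxy2 <- -sum(pxy * log2(pxy + eps))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else NaN
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  degenerate <- sd_x < eps || sd_y < eps
  if (degenerate) {
    warning("degenerate GLCM marginal: correlation and MCC undefined")
    correlation <- NaN
    mcc <- NaN
  } else {
    correlation <- (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y)
    occ <- which(px > 0 & py > 0)
    pp <- p[occ, occ, drop = FALSE]
    Q <- sweep(pp, 1, px[occ], "/") %*% t(sweep(pp, 2, py[occ], "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- if (length(ev) >= 2) sqrt(max(0, ev[2])) else NaN
  }

  structure(c(energy = energy, contrast = contrast, correlation = correlation,
              variance = variance, homogeneity = homogeneity,
              sum_average = sum_average, sum_variance = sum_variance,
              sum_entropy = sum_entropy, entropy = entropy,
              difference_variance = difference_variance,
              difference_entropy = difference_entropy,
              imc1 = imc1, imc2 = imc2, max_corr_coeff = mcc),
            class = "haralick_features")
}

#' Names of the fourteen Haralick features, in report order
#' @return character vector of length 14.
#' @export
haralick_feature_names <- function() {
  c("energy", "contrast", "correlation", "variance", "homogeneity",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "difference_variance", "difference_entropy", "imc1", "imc2",
    "max_corr_coeff")
}

#' @export
print.haralick_features <- function(x, ...) {
  cat("Haralick features (14):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Whole-brain texture quantification of a dynamic image
#'
#' Composition of the textural branch: [sum_frames()] over the late window,
#' [quantize()] inside the whole-brain mask, pooled 3D [compute_glcm()] and
#' [haralick_features()]. With `per_direction = TRUE` the features are
#' instead computed per offset and averaged.
#'
#' @param img a [dynamic_pet_image()].
#' @param brain_mask 3D array, nonzero inside the brain.
#' @param window_min late summation window (minutes), default `c(40, 60)`.
#' @param Ng gray levels (default 64).
#' @param offsets displacement set, default the 13 distance-1 directions.
#' @param symmetric symmetric GLCM accumulation (default TRUE).
#' @param clip_quantiles optional quantile clipping for [quantize()].
#' @param per_direction average per-offset features instead of pooling
#'   matrices (default FALSE).
#' @return a [haralick_features()] vector.
#' @export
texture_pipeline <- function(img, brain_mask, window_min = c(40, 60), Ng = 64,
                             offsets = glcm_offsets(), symmetric = TRUE,
                             clip_quantiles = NULL, per_direction = FALSE) {
  s <- sum_frames(img, window_min)
  q <- quantize(s, brain_mask, Ng = Ng, clip_quantiles = clip_quantiles)
  if (per_direction) {
    offsets <- matrix(as.integer(offsets), ncol = 3)
    feats <- vapply(seq_len(nrow(offsets)), function(r) {
      g <- compute_glcm(q, offsets = offsets[r, , drop = FALSE],
                        symmetric = symmetric)
      as.numeric(haralick_features(g))
    }, numeric(14))
    structure(stats::setNames(rowMeans(feats), haralick_feature_names()),
              class = "haralick_features")
  } else {
    haralick_features(compute_glcm(q, offsets = offsets,
                                   symmetric = symmetric))
  }
}
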