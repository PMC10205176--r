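# Independent reference implementations used as oracles. These deliberately
# use naive loops and direct formulas, sharing no code with the package.

# --- brute-force pooled GLCM -------------------------------------------------
bf_glcm <- function(levels, offsets, Ng, symmetric = TRUE) {
  d <- dim(levels)
  counts <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      a <- levels[x, y, z]; b <- levels[x2, y2, z2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# --- brute-force Haralick features ------------------------------------------
# Direct double loops over the matrix; log base 2, 0 log 0 = 0, eps = 1e-12
# inside the information-measure logs (the package's stated convention).
bf_haralick <- function(p) {
  Ng <- nrow(p)
  eps <- 1e-12
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- numeric(Ng); py <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mu_x <- sum((1:Ng) * px); mu_y <- sum((1:Ng) * py)
  sd_x <- sqrt(sum(((1:Ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:Ng) - mu_y)^2 * py))
  p_sum <- numeric(2 * Ng - 1)  # index k-1 for k = 2..2Ng
  p_dif <- numeric(Ng)          # index k+1 for k = 0..Ng-1
  for (i in 1:Ng) for (j in 1:Ng) {
    p_sum[i + j - 1] <- p_sum[i + j - 1] + p[i, j]
    p_dif[abs(i - j) + 1] <- p_dif[abs(i - j) + 1] + p[i, j]
  }
  energy <- sum(p^2)
  contrast <- 0
  for (k in 0:(Ng - 1)) contrast <- contrast + k^2 * p_dif[k + 1]
  mu <- 0
  for (i in 1:Ng) for (j in 1:Ng) mu <- mu + i * p[i, j]
  variance <- 0
  for (i in 1:Ng) for (j in 1:Ng) variance <- variance + (i - mu)^2 * p[i, j]
  homog <- 0
  for (i in 1:Ng) for (j in 1:Ng) homog <- homog + p[i, j] / (1 + (i - j)^2)
  ks <- 2:(2 * Ng)
  sum_avg <- sum(ks * p_sum)
  sum_var <- sum((ks - sum_avg)^2 * p_sum)
  sum_ent <- -sum(vapply(p_sum, function(v) v * lg(v), numeric(1)))
  entropy <- -sum(apply(p, c(1, 2), function(v) v * lg(v)))
  kd <- 0:(Ng - 1)
  dif_avg <- sum(kd * p_dif)
  dif_var <- sum((kd - dif_avg)^2 * p_dif)
  dif_ent <- -sum(vapply(p_dif, function(v) v * lg(v), numeric(1)))
  hx <- -sum(vapply(px, function(v) v * lg(v), numeric(1)))
  hy <- -sum(vapply(py, function(v) v * lg(v), numeric(1)))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    hxy1 <- hxy1 - p[i, j] * log2(px[i] * py[j] + eps)
    hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j] + eps)
  }
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else NaN
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  if (sd_x < eps || sd_y < eps) {
    correlation <- NaN; mcc <- NaN
  } else {
    s <- 0
    for (i in 1:Ng) for (j in 1:Ng) s <- s + i * j * p[i, j]
    correlation <- (s - mu_x * mu_y) / (sd_x * sd_y)
    occ <- which(px > 0 & py > 0)
    n <- length(occ)
    Q <- matrix(0, n, n)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      i <- occ[a]; j <- occ[b]
      Q[a, b] <- sum(p[i, occ] * p[j, occ] / (px[i] * py[occ]))
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- if (n >= 2) sqrt(max(0, ev[2])) else NaN
  }
  c(energy = energy, contrast = contrast, correlation = correlation,
    variance = variance, homogeneity = homog, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_ent, entropy = entropy,
    difference_variance = dif_var, difference_entropy = dif_ent,
    imc1 = imc1, imc2 = imc2, max_corr_coeff = mcc)
}

# --- grid-search NNLS oracle -------------------------------------------------
# Exhaustive 0.05-step grid over [0, 1]^p followed by an exhaustive 0.01-step
# grid on the box around the coarse optimum. The least-squares objective is
# convex, so the refinement pass is exact at 0.01 resolution.
grid_nnls <- function(A, b, lo = 0, hi = 1) {
  p <- ncol(A)
  best <- function(levels_list) {
    W <- as.matrix(expand.grid(levels_list))
    res <- W %*% t(A)
    sse <- rowSums((res - matrix(b, nrow(W), length(b), byrow = TRUE))^2)
    W[which.min(sse), ]
  }
  coarse <- best(rep(list(seq(lo, hi, by = 0.05)), p))
  fine_levels <- lapply(coarse, function(w) {
    seq(max(lo, w - 0.05), min(hi, w + 0.05), by = 0.01)
  })
  unname(best(fine_levels))
}

# --- direct O(n^2) convolution oracle for the SRTM response ------------------
# C_T(t) = R1 Cref(t) + (k2 - R1 k2 / (1 + BP)) * int_0^t Cref(s) e^{-k2a (t-s)} ds
# on a fine uniform grid, trapezoid quadrature evaluated from scratch per t.
bf_srtm <- function(cref, t, R1, k2, BP) {
  k2a <- k2 / (1 + BP)
  conv <- vapply(seq_along(t), function(n) {
    if (n == 1) return(0)
    integrand <- cref[1:n] * exp(-k2a * (t[n] - t[1:n]))
    sum(diff(t[1:n]) * (integrand[-1] + integrand[-n]) / 2)
  }, numeric(1))
  R1 * cref + (k2 - R1 * k2 / (1 + BP)) * conv
}
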