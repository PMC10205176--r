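sched <- make_frame_schedule()

test_that("the 40-60 min window selects exactly the last four 300 s frames", {
  img <- dynamic_pet_image(array(1, c(2, 2, 2, 22)), sched)
  s <- sum_frames(img, c(40, 60))
  expect_equal(s$frames_used, 19:22)
  expect_equal(s$data, array(4, c(2, 2, 2)))
  # a window equal to one frame returns that frame
  one <- sum_frames(img, c(55, 60))
  expect_equal(one$frames_used, 22L)
  # all-zero image sums to zero
  z <- dynamic_pet_image(array(0, c(2, 2, 2, 22)), sched)
  expect_true(all(sum_frames(z, c(40, 60))$data == 0))
  expect_error(sum_frames(img, c(40, 70)), "not covered")
  expect_error(sum_frames(img, c(40.5, 41)), "zero frames")
})

test_that("quantization follows the linear min-max formula", {
  v <- array(c(0, 5, 10, 0, 5, 10, 0, 10), c(2, 2, 2))
  mask <- array(1L, c(2, 2, 2))
  q <- quantize(v, mask, Ng = 2)
  expect_equal(as.integer(q$levels), as.integer(c(0, 1, 1, 0, 1, 1, 0, 1)))
  # identity mapping on 0..63 at Ng = 64
  v2 <- array(0:63, c(4, 4, 4))
  q2 <- quantize(v2, array(1L, c(4, 4, 4)), Ng = 64)
  expect_equal(as.integer(q2$levels), 0:63)
  expect_equal(min(q2$levels), 0L)
  expect_equal(max(q2$levels), 63L)
  expect_error(quantize(array(1, c(2, 2, 2)), mask, Ng = 4), "constant")
  expect_error(quantize(v, array(0L, c(2, 2, 2)), 4), "empty")
})

test_that("GLCM counts match hand enumeration on a 2x2x1 slice", {
  lev <- array(c(0L, 0L, 1L, 1L), c(2, 2, 1))  # [[0,1],[0,1]] in (x, y)
  q <- structure(list(levels = lev, Ng = 2L, bounds = c(0, 1)),
                 class = "quantized_volume")
  g <- compute_glcm(q, offsets = matrix(c(0L, 1L, 0L), 1))
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(g$pair_count, 2)
  # constant volume: all mass at the single occupied level
  qc <- structure(list(levels = array(1L, c(3, 3, 1)), Ng = 4L,
                       bounds = c(0, 1)), class = "quantized_volume")
  gc <- compute_glcm(qc)
  expect_equal(gc$p[2, 2], 1)
  expect_equal(sum(gc$p), 1)
})

test_that("symmetric accumulation yields an exactly symmetric matrix", {
  set.seed(1)
  lev <- array(sample(0:3, 60, TRUE), c(5, 4, 3))
  q <- structure(list(levels = lev, Ng = 4L, bounds = c(0, 3)),
                 class = "quantized_volume")
  g <- compute_glcm(q)
  expect_identical(g$p, t(g$p))
  expect_equal(sum(g$p), 1, tolerance = 1e-12)
})

test_that("masked-out neighbours never contribute pairs", {
  lev <- array(0L, c(3, 1, 1)); lev[2] <- 1L; lev[3] <- 1L
  mask <- array(1L, c(3, 1, 1)); mask[3] <- 0L
  q <- quantize(array(c(0, 5, 9), c(3, 1, 1)), mask, Ng = 2)
  g <- compute_glcm(q, offsets = matrix(c(1L, 0L, 0L), 1))
  # only the (voxel1, voxel2) pair remains
  expect_equal(g$pair_count, 1)
})

test_that("closed forms hold for degenerate and uniform matrices", {
  # constant image -> single occupied level
  qc <- structure(list(levels = array(2L, c(4, 4, 2)), Ng = 4L,
                       bounds = c(0, 1)), class = "quantized_volume")
  expect_warning(h <- haralick_features(compute_glcm(qc)), "degenerate")
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["homogeneity"]], 1)
  expect_true(is.nan(h[["correlation"]]))
  expect_true(is.nan(h[["max_corr_coeff"]]))
  # uniform GLCM
  for (Ng in c(2, 4, 8)) {
    hu <- haralick_features(matrix(1 / Ng^2, Ng, Ng))
    expect_equal(hu[["energy"]], 1 / Ng^2)
    expect_equal(hu[["entropy"]], 2 * log2(Ng))
  }
})

test_that("a checkerboard volume has correlation -1 under axial offsets", {
  d <- c(6, 6, 4)
  parity <- array(0L, d)
  parity[] <- (slice.index(parity, 1) + slice.index(parity, 2) +
                 slice.index(parity, 3)) %% 2L
  q <- structure(list(levels = parity, Ng = 2L, bounds = c(0, 1)),
                 class = "quantized_volume")
  axial <- matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L), 3, byrow = TRUE)
  h <- haralick_features(compute_glcm(q, offsets = axial))
  expect_equal(h[["correlation"]], -1)
})

test_that("GLCM and all 14 features match the brute-force oracle", {
  set.seed(7)
  for (rep in 1:8) {
    Ng <- sample(2:4, 1)
    lev <- array(sample(0:(Ng - 1), 6 * 6 * 3, TRUE), c(6, 6, 3))
    if (rep %% 2 == 0) lev[sample(length(lev), 10)] <- NA  # masked voxels
    q <- structure(list(levels = lev, Ng = Ng, bounds = c(0, 1)),
                   class = "quantized_volume")
    offs <- glcm_offsets()
    g <- compute_glcm(q, offsets = offs)
    expect_equal(g$p, bf_glcm(lev, offs, Ng), tolerance = 1e-12)
    h <- suppressWarnings(haralick_features(g))
    o <- suppressWarnings(bf_haralick(g$p))
    expect_equal(unclass(h), o, tolerance = 1e-10)
  }
})

test_that("pooled distance-1 features are invariant to axis permutation", {
  set.seed(11)
  lev <- array(sample(0:3, 5 * 6 * 7, TRUE), c(5, 6, 7))
  q <- function(a) structure(list(levels = a, Ng = 4L, bounds = c(0, 1)),
                             class = "quantized_volume")
  h0 <- haralick_features(compute_glcm(q(lev)))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    hp <- haralick_features(compute_glcm(q(aperm(lev, perm))))
    expect_equal(unclass(hp), unclass(h0), tolerance = 1e-12)
  }
})

test_that("additive noise raises entropy and lowers energy on smooth fields", {
  cfg <- small_phantom(noise_scale = 0, texture_len_sd = 0)
  ent <- matrix(NA_real_, 5, 2)
  enr <- matrix(NA_real_, 5, 2)
  for (i in 1:5) {
    s <- generate_subject(cfg, "HC", seed = 100 + i)
    base <- sum_frames(s$dynamic_image, c(40, 60))
    set.seed(i)
    noisy <- base
    noisy$data <- base$data + array(rnorm(length(base$data), 0,
                                          0.05 * max(base$data)),
                                    dim(base$data))
    for (j in 1:2) {
      img <- if (j == 1) base else noisy
      h <- haralick_features(compute_glcm(quantize(img, s$brain_mask, 16)))
      ent[i, j] <- h[["entropy"]]; enr[i, j] <- h[["energy"]]
    }
  }
  expect_gt(mean(ent[, 2]), mean(ent[, 1]))
  expect_lt(mean(enr[, 2]), mean(enr[, 1]))
})

test_that("the texture pipeline is deterministic and supports both poolings", {
  cfg <- small_phantom()
  s <- generate_subject(cfg, "AD", seed = 21)
  h1 <- texture_pipeline(s$dynamic_image, s$brain_mask, Ng = 16)
  h2 <- texture_pipeline(s$dynamic_image, s$brain_mask, Ng = 16)
  expect_identical(unclass(h1), unclass(h2))
  expect_named(unclass(h1), haralick_feature_names())
  expect_length(unclass(h1), 14L)
  hd <- texture_pipeline(s$dynamic_image, s$brain_mask, Ng = 16,
                         per_direction = TRUE)
  expect_length(unclass(hd), 14L)
  expect_false(identical(unclass(h1), unclass(hd)))
  hc <- texture_pipeline(s$dynamic_image, s$brain_mask, Ng = 16,
                         clip_quantiles = c(0.005, 0.995))
  expect_length(unclass(hc), 14L)
})
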