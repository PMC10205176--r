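sched <- make_frame_schedule()
ref <- simulate_reference_tac(sched)

test_that("Logan analysis of identical TACs gives DVR 1 and intercept 0", {
  fit <- logan_dvr_tac(ref, ref, t_star = 20)
  expect_equal(fit$dvr, 1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("Logan slope scales with a pointwise-doubled target", {
  t2 <- tac(2 * ref$values, sched)
  expect_equal(logan_dvr_tac(t2, ref, 20)$dvr, 2, tolerance = 1e-10)
})

test_that("DVR is invariant to a common scale on target and reference", {
  tt <- simulate_target_tac(ref, 1, 0.15, 0.3)
  f1 <- logan_dvr_tac(tt, ref, 20)
  f2 <- logan_dvr_tac(tac(7.3 * tt$values, sched), tac(7.3 * ref$values, sched), 20)
  expect_equal(f1$dvr, f2$dvr, tolerance = 1e-12)
})

test_that("Logan recovers 1 + BP within 5% and monotonically on noiseless SRTM", {
  bps <- c(0, 0.1, 0.2, 0.5)
  dvrs <- vapply(bps, function(bp) {
    tt <- simulate_target_tac(ref, 1, 0.15, bp)
    logan_dvr_tac(tt, ref, t_star = 20)$dvr
  }, numeric(1))
  expect_true(all(abs(dvrs / (1 + bps) - 1) < 0.05))
  expect_true(all(diff(dvrs) > 0))
})

test_that("Logan preconditions are enforced", {
  expect_error(logan_dvr_tac(ref, ref, t_star = 55), "at least 3 frames")
  bad <- ref$values
  bad[21] <- -0.1
  expect_error(logan_dvr_tac(tac(bad, sched), ref, 20), "non-positive")
  flat <- tac(rep(1, 22), sched)
  expect_error(logan_dvr_tac(flat, tac(rep(0, 22), sched), 20), "degenerate")
})

test_that("voxelwise Logan agrees with the per-TAC fit and with lm", {
  cfg <- noiseless_phantom(bp_ad = 0.3)
  s <- generate_subject(cfg, "AD", seed = 1)
  refx <- tac(make_kinetic_basis(cfg$schedule)$class_tacs[, 1], cfg$schedule)
  dvr <- logan_dvr_image(s$dynamic_image, s$brain_mask, refx, t_star = 20)
  # pick one voxel per tissue class and re-fit with the scalar path and lm
  nf <- 22
  flat <- matrix(s$dynamic_image$data, ncol = nf)
  for (cls in c(1, 2, 4)) {
    i <- which(s$class_map == cls)[1]
    v <- tac(flat[i, ], cfg$schedule)
    scalar <- logan_dvr_tac(v, refx, 20)
    expect_equal(dvr$data[i], scalar$dvr, tolerance = 1e-10)
    mid <- frame_mid_min(cfg$schedule)
    sel <- mid >= 20
    it <- cumsum(c(mid[1] * v$values[1] / 2,
                   diff(mid) * (v$values[-1] + v$values[-22]) / 2))
    ir <- cumsum(c(mid[1] * refx$values[1] / 2,
                   diff(mid) * (refx$values[-1] + refx$values[-22]) / 2))
    lmfit <- lm(y ~ x, data.frame(x = ir[sel] / v$values[sel],
                                  y = it[sel] / v$values[sel]))
    expect_equal(scalar$dvr, unname(coef(lmfit)[2]), tolerance = 1e-9)
  }
  # voxels outside the mask are NA
  expect_true(all(is.na(dvr$data[s$brain_mask == 0])))
  expect_equal(dvr$n_failed, 0)
})

test_that("a uniform-binding phantom maps to DVR ~ 1 and an ROI effect shows", {
  cfg <- noiseless_phantom(bp_ad = 0.2)
  hc <- generate_subject(cfg, "HC", seed = 1)
  basis <- make_kinetic_basis(cfg$schedule)
  refx <- tac(basis$class_tacs[, 1], cfg$schedule)
  d_hc <- logan_dvr_image(hc$dynamic_image, hc$brain_mask, refx, 20)
  grey <- hc$class_map == 1
  expect_equal(mean(d_hc$data[grey]), 1, tolerance = 0.01)
  ad <- generate_subject(cfg, "AD", seed = 1)
  d_ad <- logan_dvr_image(ad$dynamic_image, ad$brain_mask, refx, 20)
  lab <- match(cfg$ad_roi, phantom_roi_names())
  expect_gt(mean(d_ad$data[ad$atlas == lab]),
            mean(d_ad$data[ad$atlas > 1 & ad$brain_mask == 1]))
})

test_that("supervised cluster weights are one-hot on pure class voxels", {
  cfg <- noiseless_phantom(bp_ad = 0.3)
  s <- generate_subject(cfg, "AD", seed = 3)
  basis <- make_kinetic_basis(cfg$schedule, amplitude = cfg$amplitude)
  ext <- extract_reference_tac(s$dynamic_image, s$brain_mask, basis,
                               fraction = 0.1)
  W <- ext$weights
  cls <- s$class_map[ext$voxel_index]
  for (k in 1:4) {
    rows <- W[cls == k, , drop = FALSE]
    # weight of the true class ~ its curve's area (normalised system), others 0
    expect_equal(max(abs(rows[, -k])), 0, tolerance = 1e-6)
    expect_equal(max(abs(rows[, k] - 1)), 0, tolerance = 1e-6)
  }
})

test_that("mixed voxels decompose into their mixing weights (NNLS oracles)", {
  basis <- make_kinetic_basis(sched)
  A <- apply(basis$class_tacs, 2,
             function(v) v / pettex:::tac_auc(v, sched))
  mix <- 0.5 * A[, 1] + 0.5 * A[, 2]
  w <- pettex:::nnls_single(A, mix)
  expect_equal(unname(w), c(0.5, 0.5, 0, 0), tolerance = 1e-8)
  # grid-search oracle on the same system
  w_grid <- grid_nnls(A, mix)
  expect_true(all(abs(w - w_grid) <= 0.02))
  # random mixtures against pracma::lsqnonneg
  set.seed(42)
  for (i in 1:10) {
    b <- A %*% pmax(rnorm(4, 0.3, 0.3), 0) + rnorm(22, 0, 0.001)
    w1 <- pettex:::nnls_single(A, b)
    w2 <- pracma::lsqnonneg(A, as.numeric(b))$x
    expect_equal(unname(w1), w2, tolerance = 1e-6)
  }
})

test_that("reference extraction recovers the true non-binding mask (Dice 1)", {
  cfg <- noiseless_phantom(bp_ad = 0.3)
  s <- generate_subject(cfg, "AD", seed = 4)
  basis <- make_kinetic_basis(cfg$schedule, amplitude = cfg$amplitude)
  prev <- mean(s$class_map[s$brain_mask == 1] == 1)
  ext <- extract_reference_tac(s$dynamic_image, s$brain_mask, basis,
                               fraction = prev)
  truth <- s$class_map == 1
  dice <- 2 * sum(ext$reference_mask == 1 & truth) /
    (sum(ext$reference_mask) + sum(truth))
  expect_equal(dice, 1)
  # reference TAC is the mean of the selected voxels' raw TACs = class curve
  expect_equal(ext$reference_tac$values, unname(basis$class_tacs[, 1]),
               tolerance = 1e-10)
})

test_that("reference extraction is equivariant to voxel reordering", {
  cfg <- noiseless_phantom()
  s <- generate_subject(cfg, "HC", seed = 5)
  basis <- make_kinetic_basis(cfg$schedule, amplitude = cfg$amplitude)
  flip <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  img_f <- dynamic_pet_image(s$dynamic_image$data[rev(seq_len(16)), , , ],
                             cfg$schedule)
  # ties in the ranking are only resolved order-independently when the whole
  # tied class is selected, so match the fraction to the true prevalence
  prev <- mean(s$class_map[s$brain_mask == 1] == 1)
  e1 <- extract_reference_tac(s$dynamic_image, s$brain_mask, basis, prev)
  e2 <- extract_reference_tac(img_f, flip(s$brain_mask), basis, prev)
  expect_equal(flip(e2$reference_mask), e1$reference_mask)
  expect_equal(e2$reference_tac$values, e1$reference_tac$values)
})

test_that("an absolute weight threshold can replace the fraction rule", {
  cfg <- noiseless_phantom()
  s <- generate_subject(cfg, "HC", seed = 6)
  basis <- make_kinetic_basis(cfg$schedule, amplitude = cfg$amplitude)
  ext <- extract_reference_tac(s$dynamic_image, s$brain_mask, basis,
                               weight_threshold = 0.9)
  truth <- s$class_map == 1
  expect_equal(sum(ext$reference_mask), sum(truth))
})

test_that("roi_means reduces parametric maps correctly", {
  img <- array(1.5, c(4, 4, 2))
  atlas <- array(0L, c(4, 4, 2))
  atlas[1:2, , ] <- 1L
  atlas[3:4, , ] <- 2L
  out <- roi_means(img, atlas)
  expect_equal(out$mean, c(1.5, 1.5))
  img[atlas == 2] <- 2
  out <- roi_means(img, atlas, c(low = 1, high = 2))
  expect_equal(out$mean, c(1.5, 2.0))
  expect_equal(out$roi, c("low", "high"))
  # hand-enumerated 3-voxel ROI
  img2 <- array(0, c(3, 1, 1))
  img2[] <- c(1, 2, 4)
  atl2 <- array(1L, c(3, 1, 1))
  expect_equal(roi_means(img2, atl2)$mean, (1 + 2 + 4) / 3)
  expect_error(roi_means(img2, atl2, c(missing = 7)), "absent")
  img2[] <- NaN
  expect_error(roi_means(img2, atl2), "zero finite")
})
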