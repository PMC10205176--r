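test_that("the sample-to-feature cap reproduces the cohort rule", {
  expect_equal(max_features(c(19, 21), 10), 4L)
  expect_equal(max_features(c(10, 10), 10), 2L)
  expect_equal(max_features(c(5, 5), 10), 1L)
  expect_equal(max_features(c(19, 21), 10, per_class = TRUE), 1L)
  expect_error(max_features(c(3, 4), 10), "too small")
})

test_that("the correlation filter removes one of each highly correlated pair", {
  set.seed(3)
  n <- 30
  a <- rnorm(n)
  df <- data.frame(subject_id = sprintf("s%02d", 1:n),
                   group = rep(c("AD", "HC"), 15),
                   alpha = a, beta = a,                         # r = 1
                   gamma = rnorm(n))                            # independent
  kept <- correlation_filter(df, 0.9)
  expect_length(kept, 2L)
  expect_true("gamma" %in% kept)
  expect_length(intersect(c("alpha", "beta"), kept), 1L)
  # A ~ B correlated at ~0.95, C independent: C always retained
  df$beta <- a + rnorm(n, 0, 0.25)
  while (abs(cor(df$alpha, df$beta)) < 0.9) df$beta <- a + rnorm(n, 0, 0.2)
  kept2 <- correlation_filter(df, 0.9)
  expect_length(kept2, 2L)
  expect_true("gamma" %in% kept2)
  # independent features below threshold are all retained
  df2 <- df
  df2$beta <- rnorm(n)
  expect_setequal(correlation_filter(df2, 0.9), c("alpha", "beta", "gamma"))
  # zero-variance feature dropped up front
  df$flat <- 1
  expect_false("flat" %in% suppressMessages(correlation_filter(df, 0.9)))
})

test_that("logistic ranking puts an informative feature first", {
  wins <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    g <- rep(c("AD", "HC"), each = n / 2)
    df <- data.frame(subject_id = sprintf("s%03d", 1:n), group = g,
                     signal = (g == "AD") * 2 + rnorm(n, 0, 0.5),
                     noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
    r <- rank_by_logistic(df)
    wins <- wins + (r$feature[1] == "signal")
  }
  expect_gte(wins, 9L)
})

test_that("ranking ties break alphabetically", {
  set.seed(4)
  n <- 60
  g <- rep(c("AD", "HC"), each = n / 2)
  x <- (g == "AD") + rnorm(n, 0, 0.6)
  df <- data.frame(subject_id = sprintf("s%02d", 1:n), group = g,
                   zeta = x, eta = x)  # identical columns -> equal |beta|
  r <- rank_by_logistic(df)
  expect_equal(abs(diff(r$importance[1:2])), 0, tolerance = 1e-10)
  expect_equal(r$feature[1:2], c("eta", "zeta"))
})

test_that("LOOCV predicts every subject exactly once, independent of order", {
  tab <- separable_table(n_ad = 6, n_hc = 7, seed = 2)
  cv <- loocv_svm(tab, c("f1", "f2"))
  expect_equal(attr(cv, "n_folds"), 13L)
  expect_equal(sort(cv$subject_id), sort(tab$subject_id))
  expect_equal(anyDuplicated(cv$subject_id), 0L)
  perm <- tab[sample(nrow(tab)), ]
  cv2 <- loocv_svm(perm, c("f1", "f2"))
  m <- merge(cv, cv2, by = "subject_id")
  expect_equal(m$predicted.x, m$predicted.y)
})

test_that("a separable cohort is classified perfectly", {
  tab <- separable_table(seed = 5)
  cv <- loocv_svm(tab, paste0("f", 1:4))
  expect_equal(unname(performance_metrics(cv)["accuracy"]), 1)
})

test_that("fold standardisation cannot leak the held-out subject", {
  # shifting one held-out subject by a huge constant changes only its own
  # prediction inputs; every other subject's prediction is unchanged
  tab <- separable_table(n_ad = 8, n_hc = 8, seed = 6, shift = 3)
  tab2 <- tab
  tab2$f2[1] <- tab2$f2[1] + 1e6
  cv1 <- loocv_svm(tab, c("f1", "f2"))
  cv2 <- loocv_svm(tab2, c("f1", "f2"))
  expect_equal(cv1$predicted[-1], cv2$predicted[-1])
})

test_that("performance metrics match direct counting", {
  r <- data.frame(truth = c("AD", "AD", "HC", "HC"),
                  predicted = c("AD", "HC", "HC", "HC"))
  m <- performance_metrics(r)
  expect_equal(unname(m), c(0.75, 0.5, 1.0, 0.75))
  r2 <- data.frame(truth = c("AD", "HC"), predicted = c("AD", "HC"))
  expect_true(all(performance_metrics(r2) == 1))
  r3 <- data.frame(truth = c("AD", "AD", "HC", "HC"),
                   predicted = rep("AD", 4))
  m3 <- performance_metrics(r3)
  expect_equal(unname(m3), c(0.5, 1, 0, 0.5))
  expect_equal(m3[["balanced_accuracy"]],
               (m3[["sensitivity"]] + m3[["specificity"]]) / 2)
})

test_that("Cochran's Q reproduces the McNemar reduction and conventions", {
  # 8 vs 5 discordant pairs: Q = (8-5)^2 / (8+5)
  resp <- rbind(matrix(c(1, 0), 8, 2, byrow = TRUE),
                matrix(c(0, 1), 5, 2, byrow = TRUE),
                matrix(1, 4, 2), matrix(0, 3, 2))
  q <- cochran_q(resp)
  expect_equal(q$Q, 9 / 13, tolerance = 1e-12)
  expect_equal(q$df, 1L)
  expect_false(q$reject_at_alpha)
  # identical columns: zero denominator convention
  same <- cbind(c(1, 0, 1, 1), c(1, 0, 1, 1))
  q0 <- cochran_q(same)
  expect_equal(q0$Q, 0)
  expect_equal(q0$p_value, 1)
  expect_error(cochran_q(cbind(c(1, 2), c(0, 1))), "binary")
  # k = 3 sanity: p from chi-square with 2 df
  set.seed(8)
  r3 <- matrix(rbinom(30, 1, 0.5), 10, 3)
  q3 <- cochran_q(r3)
  expect_equal(q3$df, 2L)
  expect_equal(q3$p_value, pchisq(q3$Q, 2, lower.tail = FALSE))
})

test_that("comparing a table against itself gives identical metrics and Q = 0", {
  tab <- separable_table(n_ad = 8, n_hc = 9, seed = 9, shift = 2)
  cc <- compare_classifiers(tab, tab)
  expect_equal(cc$metrics$kinetic, cc$metrics$texture)
  expect_equal(cc$cochran$Q, 0)
  expect_equal(cc$cochran$p_value, 1)
  expect_length(cc$metrics, 2L)
  expect_s3_class(cc$cochran, "cochran_q")
  expect_equal(nrow(cc$predictions), 17L)
  # correctness-based response convention also runs
  cc2 <- compare_classifiers(tab, tab, response = "correct")
  expect_equal(cc2$cochran$Q, 0)
})
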