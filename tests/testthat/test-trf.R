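test_that("forward prediction matches the convolution sum", {
  set.seed(21)
  ps <- rand_predictor_set(60, bands = 3, n_pred = 2, seed = 21)
  lags_ms <- seq(-30, 60, by = 10)
  kernels <- list(p1 = matrix(rnorm(30), 10, 3), p2 = matrix(rnorm(30), 10, 3))
  s <- strf(kernels, lags_ms, 100)
  y <- predict(s, ps)
  # brute-force double loop oracle
  lags <- round(lags_ms / 10)
  yo <- numeric(60)
  for (t in 1:60)
    for (nm in names(kernels))
      for (j in seq_along(lags))
        for (b in 1:3) {
          u <- t - lags[j]
          if (u >= 1 && u <= 60)
            yo[t] <- yo[t] + kernels[[nm]][j, b] * ps$predictors[[nm]]$values[u, b]
        }
  expect_equal(y, yo, tolerance = 1e-12)
})

test_that("prediction identities: zero kernels and unit impulses", {
  ps <- rand_predictor_set(40, bands = 1, seed = 22)
  z <- strf(list(p1 = matrix(0, 5, 1)), seq(0, 40, 10), 100)
  expect_equal(predict(z, ps), rep(0, 40))

  imp <- matrix(0, 6, 1); imp[4, 1] <- 1      # lag 3 samples
  s <- strf(list(p1 = imp), seq(0, 50, 10), 100)
  y <- predict(s, ps)
  x <- ps$predictors$p1$values[, 1]
  expect_equal(y[4:40], x[1:37])
  expect_equal(y[1:3], rep(0, 3))

  ps_bad <- ps; ps_bad$rate <- 50
  expect_error(predict(s, ps_bad), "rate")
})

test_that("boosting recovers a delayed predictor with an impulse basis", {
  set.seed(23)
  pst <- lapply(1:4, function(i) rand_predictor_set(800, bands = 1, seed = 23 + i))
  K <- matrix(0, 20, 1); K[4, 1] <- 1         # 30 ms delay
  gt <- strf(list(p1 = K), seq(0, 190, 10), 100)
  resp <- lapply(pst, function(ps) predict(gt, ps))
  cfg <- trf_basis_config(0, 200, basis_width = 10, rate = 100)
  est <- boost_channel(resp, pst, cfg, train_trials = 1:2,
                       validation_trials = 3, delta = 0.002)
  expect_gt(cor(predict(est, pst[[1]]), resp[[1]]), 0.99)
  mass <- rowSums(abs(est$kernels$p1))
  near <- which(abs(est$lags_ms - 30) <= 10)
  expect_gt(sum(mass[near]) / sum(mass), 0.95)
  # training error trace is monotone non-increasing
  expect_true(all(diff(attr(est, "history")) <= 1e-9))
})

test_that("kernel mass stays within a basis width of the true lag with the default basis", {
  set.seed(29)
  pst <- lapply(1:3, function(i) rand_predictor_set(800, bands = 1, seed = 33 + i))
  K <- matrix(0, 20, 1); K[4, 1] <- 1
  gt <- strf(list(p1 = K), seq(0, 190, 10), 100)
  resp <- lapply(pst, function(ps) predict(gt, ps))
  cfg <- trf_basis_config(0, 200, basis_width = 50, rate = 100)
  est <- boost_channel(resp, pst, cfg, 1:2, 3)
  mass <- rowSums(abs(est$kernels$p1))
  near <- which(abs(est$lags_ms - 30) <= 50)
  expect_gt(sum(mass[near]) / sum(mass), 0.9)
})

test_that("boosting handles a zero response and rescales equivariantly", {
  pst <- lapply(1:3, function(i) rand_predictor_set(200, bands = 1, seed = 40 + i))
  cfg <- trf_basis_config(0, 100, 50, 100)
  expect_warning(
    est0 <- boost_channel(lapply(1:3, function(i) rep(0, 200)), pst, cfg, 1:2, 3),
    "zero-variance")
  expect_equal(max(abs(est0$kernels$p1)), 0)

  K <- two_peak_trf(seq(0, 90, 10))
  gt <- strf(list(p1 = matrix(K, ncol = 1)), seq(0, 90, 10), 100)
  resp <- lapply(pst, function(ps) predict(gt, ps))
  e1 <- boost_channel(resp, pst, cfg, 1:2, 3)
  e2 <- boost_channel(lapply(resp, function(y) 7 * y), pst, cfg, 1:2, 3)
  expect_equal(e2$kernels$p1, 7 * e1$kernels$p1, tolerance = 1e-8)
})

test_that("nested cross-validation follows the round-robin fold rule", {
  expect_equal(fold_assignment(4, 4), 1:4)
  expect_equal(fold_assignment(8, 4), rep(1:4, 2))
  expect_error(fold_assignment(3, 4), "fewer")
})

test_that("nested cross-validation scores noiseless data near one and noise near zero", {
  set.seed(25)
  pst <- lapply(1:4, function(i) rand_predictor_set(600, bands = 2, seed = 50 + i))
  lags_ms <- seq(0, 190, 10)
  K <- outer(two_peak_trf(lags_ms), c(1, 0.6))
  gt <- strf(list(p1 = K), lags_ms, 100)
  resp <- lapply(pst, function(ps) {
    y <- predict(gt, ps)
    cbind(y, y)                                # two identical channels
  })
  cfg <- trf_basis_config(0, 200, 50, 100)
  res <- nested_crossval(resp, pst, cfg)
  expect_true(all(res$r > 0.99))
  expect_equal(res$fold_assignment, 1:4)

  # pure noise: cross-validated r scattered around zero
  set.seed(26)
  noise <- lapply(1:4, function(i) matrix(rnorm(600 * 4), 600, 4))
  resn <- nested_crossval(noise, pst, cfg)
  expect_lt(abs(mean(resn$r)), 2 * stats::sd(resn$r) / sqrt(4) + 0.05)
  expect_true(all(abs(resn$r) < 0.2))
})

test_that("averaging inner STRFs commutes with prediction", {
  set.seed(27)
  pst <- lapply(1:3, function(i) rand_predictor_set(300, bands = 2, seed = 60 + i))
  cfg <- trf_basis_config(0, 150, 50, 100)
  gt <- strf(list(p1 = outer(two_peak_trf(seq(0, 140, 10)), c(1, 0.5))),
             seq(0, 140, 10), 100)
  resp <- lapply(pst, function(ps) predict(gt, ps) + rnorm(300, sd = 0.1))
  e1 <- boost_channel(resp, pst, cfg, 1, 3)
  e2 <- boost_channel(resp, pst, cfg, 2, 3)
  avg <- strf_mean(list(e1, e2))
  p_avg <- predict(avg, pst[[1]])
  p_mean <- (predict(e1, pst[[1]]) + predict(e2, pst[[1]])) / 2
  expect_equal(p_avg, p_mean, tolerance = 1e-12)
})

test_that("baseline lags carry little mass for causal simulated responses", {
  set.seed(28)
  pst <- lapply(1:4, function(i) rand_predictor_set(800, bands = 1, seed = 70 + i))
  lags_ms <- seq(0, 190, 10)
  gt <- strf(list(p1 = matrix(two_peak_trf(lags_ms), ncol = 1)), lags_ms, 100)
  resp <- lapply(pst, function(ps) {
    y <- predict(gt, ps)
    y + rnorm(length(y), sd = stats::sd(y))    # SNR 0 dB
  })
  cfg <- trf_basis_config(-100, 300, 50, 100)
  res <- fit_strf(resp, pst, cfg)
  K <- res[[1]]$kernels$p1
  base <- res[[1]]$lags_ms < 0
  expect_lt(sum(abs(K[base, ])) / sum(abs(K)), 0.10)
})
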