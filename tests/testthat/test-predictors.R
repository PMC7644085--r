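test_that("masked/overt decomposition matches the defining formulas", {
  src <- predictor(spec_of(matrix(5, 1, 1), role = "onset"), "o_att")
  mix <- predictor(spec_of(matrix(3, 1, 1), role = "onset"), "o_mix")
  sp <- split_masked_overt(src, mix)
  expect_equal(sp$masked$values[1, 1], 2)
  expect_equal(sp$overt$values[1, 1], 3)
  expect_identical(sp$overt$name, "o_att_overt")
  expect_identical(sp$masked$name, "o_att_masked")

  # source == mixture: nothing is masked
  sp2 <- split_masked_overt(src, src)
  expect_equal(max(abs(sp2$masked$values)), 0)
  expect_equal(sp2$overt$values, src$values)

  bad <- predictor(spec_of(matrix(1, 2, 1), role = "onset"), "o_mix")
  expect_error(split_masked_overt(src, bad), "mismatch")
})

test_that("decomposition reconstructs the source exactly for random pairs", {
  set.seed(11)
  for (i in 1:50) {
    a <- matrix(rexp(60), 15, 4)
    b <- matrix(rexp(60), 15, 4)
    sp <- split_masked_overt(predictor(spec_of(a, role = "onset"), "o"),
                             predictor(spec_of(b, role = "onset"), "om"))
    expect_equal(sp$overt$values + sp$masked$values, a,
                 tolerance = 4 * .Machine$double.eps)
    expect_equal(sp$overt$values, pmin(a, b),
                 tolerance = 4 * .Machine$double.eps)
  }
})

test_that("overt fraction pools l1 norms and sums to one", {
  src <- predictor(spec_of(matrix(rexp(40, rate = 0.5), 10, 4),
                           role = "onset"), "o_att")
  mix <- predictor(spec_of(matrix(rexp(40, rate = 0.5), 10, 4),
                           role = "onset"), "o_mix")
  fr <- overt_fraction(list(src), mix)
  expect_equal(fr$overt + fr$masked, 1)
  expect_equal(fr$overt, sum(pmin(src$values, mix$values)) / sum(src$values))

  same <- overt_fraction(list(src), src)
  expect_equal(same$overt, 1)
  zero_mix <- predictor(spec_of(matrix(0, 10, 4), role = "onset"), "o_mix")
  fr0 <- overt_fraction(list(src), zero_mix)
  expect_equal(fr0$overt, 0)
  expect_equal(fr0$masked, 1)
  zero_src <- predictor(spec_of(matrix(0, 10, 4), role = "onset"), "o")
  expect_error(overt_fraction(list(zero_src), mix), "zero")
})

test_that("intensity tertiles assign whole events by per-band boundaries", {
  # nine events of intensities 1..9 in one band, separated by zeros
  n <- 9 * 20
  v <- matrix(0, n, 1)
  for (k in 1:9) v[(k - 1) * 20 + 1:2, 1] <- k / 2   # intensity k
  o <- predictor(spec_of(v, role = "onset"), "o_mix")
  lv <- split_intensity_levels(o)
  expect_identical(names(lv$predictors),
                   c("o_mix_low", "o_mix_mid", "o_mix_high"))
  ev_int <- function(p) {
    x <- p$values[, 1]
    sapply(1:9, function(k) sum(x[(k - 1) * 20 + 1:2]))
  }
  expect_equal(which(ev_int(lv$predictors$o_mix_low) > 0), 1:3)
  expect_equal(which(ev_int(lv$predictors$o_mix_mid) > 0), 4:6)
  expect_equal(which(ev_int(lv$predictors$o_mix_high) > 0), 7:9)
})

test_that("intensity levels partition the onset predictor exactly", {
  o <- rand_onset(300, bands = 4, seed = 12)
  lv <- split_intensity_levels(o)
  total <- Reduce(`+`, lapply(lv$predictors, function(p) p$values))
  expect_identical(total, o$values)
  # no event is split: each level's nonzero runs are whole runs of the input
  for (p in lv$predictors) {
    both <- (p$values > 0)
    expect_true(all(o$values[both] == p$values[both]))
  }
  # all-zero band gives three all-zero outputs
  z <- predictor(spec_of(matrix(0, 10, 2), role = "onset"), "o")
  lz <- split_intensity_levels(z)
  for (p in lz$predictors) expect_equal(max(abs(p$values)), 0)
})

test_that("model rosters match the model formulas", {
  set.seed(13)
  mk <- function(role) spec_of(matrix(rexp(40), 10, 4), role = role)
  env <- list(att = mk("envelope"), ign = mk("envelope"), mix = mk("envelope"))
  ons <- list(att = mk("onset"), ign = mk("onset"), mix = mk("onset"))

  expect_identical(names(build_model_set(env, ons, "clean")$predictors),
                   c("o", "e"))
  expect_identical(names(build_model_set(env, ons, "stream")$predictors),
                   c("o_mix", "o_att", "o_ign", "e_mix", "e_att", "e_ign"))
  masked <- build_model_set(env, ons, "masked")
  expect_identical(names(masked$predictors),
                   c("o_mix", "o_att_overt", "o_att_masked", "o_ign_overt",
                     "o_ign_masked", "e_mix", "e_att", "e_ign"))
  lvl <- build_model_set(env, ons, "level_control")
  expect_identical(names(lvl$predictors),
                   c("o_mix_low", "o_mix_mid", "o_mix_high", "o_att_overt",
                     "o_att_masked", "e_mix", "e_att", "e_ign"))
  expect_length(lvl$predictors, length(masked$predictors))

  expect_error(build_model_set(env[c("att", "ign")], ons, "stream"),
               "missing stream")
})

test_that("l1 normalization scales bands, records norms, flags zeros", {
  v <- matrix(c(1, 3, 0, 1,
                0, 0, 0, 0), ncol = 2)
  p <- predictor(spec_of(v, role = "onset"), "o")
  ps <- l1_normalize(predictor_set(list(p), "custom"))
  q <- ps$predictors$o
  expect_equal(q$values[, 1], c(0.2, 0.6, 0, 0.2))
  expect_equal(unname(q$l1_norms), c(5, 0))
  expect_identical(unname(q$zero_bands), c(FALSE, TRUE))
  expect_equal(q$values[, 2], rep(0, 4))
  # renormalizing a normalized predictor records unit norms
  q2 <- l1_normalize(q)
  expect_equal(unname(q2$l1_norms), c(1, 0))
  expect_equal(q2$values, q$values)
})

test_that("predictor construction is deterministic", {
  a <- rand_onset(100, seed = 99)
  b <- rand_onset(100, seed = 99)
  expect_identical(split_intensity_levels(a)$predictors$o_low$values,
                   split_intensity_levels(b)$predictors$o_low$values)
  expect_identical(l1_normalize(a)$values, l1_normalize(b)$values)
})
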