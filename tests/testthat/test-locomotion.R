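test_that("locomotion fluorescence is the interpolated window percentile", {
  rate <- 30
  const <- rep(2.5, 1200)
  expect_equal(locomotion_fluorescence(const, frame_rate = rate), 2.5)

  # 101 values 0..100 in the window: index (n-1)*0.75 = 75 -> 75.0
  tr <- rep(-99, 1200)
  idx <- (10 * rate + 1):(10 * rate + 101)
  tr[idx] <- sample(0:100)                   # order must not matter
  expect_equal(locomotion_fluorescence(tr, window = c(10, 10 + 101 / rate),
                                       frame_rate = rate), 75.0)

  # invariant to values outside the window
  tr2 <- tr; tr2[1:100] <- 1e6
  expect_equal(
    locomotion_fluorescence(tr2, window = c(10, 10 + 101 / rate),
                            frame_rate = rate),
    locomotion_fluorescence(tr, window = c(10, 10 + 101 / rate),
                            frame_rate = rate))

  # matches an independent sort-index oracle on random data
  set.seed(3)
  v <- rnorm(450)
  tr3 <- rep(0, 1200); tr3[301:750] <- v
  expect_equal(locomotion_fluorescence(tr3, frame_rate = rate),
               sort_index_percentile(v, 75))
})

test_that("exponential decay fit recovers exact parameters", {
  j <- 1:6
  l <- 0.2 + 1.0 * exp(-j / 3.0)
  fit <- fit_decay(l, j)
  expect_equal(fit$kind, "exp")
  expect_equal(fit$A, 0.2, tolerance = 1e-6)
  expect_equal(fit$B, 1.0, tolerance = 1e-6)
  expect_equal(fit$C, 3.0, tolerance = 1e-5)
  expect_lt(max(abs(predict(fit, j) - l)), 1e-6)

  # constant data: degenerate, any C accepted, flagged
  fc <- fit_decay(rep(0.7, 5))
  expect_equal(fc$flag, "degenerate_constant")
  expect_equal(predict(fc, 1:5), rep(0.7, 5))

  expect_error(fit_decay(0.5), "at least 2")
})

test_that("decay fit matches a profile grid-search oracle on noisy data", {
  set.seed(11)
  j <- 1:8
  l <- 0.3 + 0.8 * exp(-j / 2.5) + rnorm(8, 0, 0.01)
  fit <- fit_decay(l, j)
  oracle <- grid_decay_fit(l, j)
  expect_lt(max(abs(predict(fit, j) - oracle$fitted)), 1e-4)
})

test_that("detrending subtracts the pre-drug fit from every recording", {
  j <- 1:10
  f <- 0.15 + 0.9 * exp(-j / 3)
  fit <- fit_decay(f[1:6], 1:6)
  # data exactly on the curve -> zeros everywhere
  expect_equal(detrend_values(f, j, fit), rep(0, 10), tolerance = 1e-7)

  # post-drug step of -0.5 on an exact pre-drug curve
  l <- f; l[7:10] <- l[7:10] - 0.5
  expect_equal(detrend_values(l, j, fit)[7:10], rep(-0.5, 4),
               tolerance = 1e-7)

  # adding a constant shifts A and leaves detrended values unchanged
  fit2 <- fit_decay(f[1:6] + 2, 1:6)
  expect_equal(fit2$A, fit$A + 2, tolerance = 1e-5)
  expect_equal(detrend_values(l + 2, j, fit2), detrend_values(l, j, fit),
               tolerance = 1e-6)
})

test_that("drug-effect classification labels by p-value and direction", {
  prm <- drug_test_params()
  # identical constants: no change, p = 1 by convention, flagged
  same <- classify_drug_effect(rep(0.4, 6), rep(0.4, 9), prm)
  expect_equal(same$label, "none")
  expect_equal(same$p, 1)
  expect_equal(same$flag, "zero_variance")

  # clear separation: decrease
  set.seed(4)
  dec <- classify_drug_effect(rnorm(6, 0, 0.01), rnorm(11, -1, 0.01), prm)
  expect_equal(dec$label, "decrease")
  expect_lt(dec$p, 1e-6)

  # wash-in exclusion: first 3 post values ignored
  cls <- classify_drug_effect(rep(0, 6) + rnorm(6, 0, 1e-3),
                              c(5, 5, 5, rnorm(8, 0, 1e-3)), prm)
  expect_equal(cls$label, "none")

  # too few recordings -> skipped with flag
  skip <- classify_drug_effect(c(0.1, 0.2), c(1, 2, 3, 4), prm)
  expect_equal(skip$flag, "too_few_recordings")
  expect_true(is.na(skip$p))
})

test_that("change-vs-baseline regression matches closed-form r", {
  # exact negative-slope line
  x <- seq(0.5, 3, length.out = 12)
  exact <- regress_change_vs_baseline(data.frame(baseline = x,
                                                 change = 1 - 2 * x))
  expect_equal(exact$r, -1)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, -2)
  expect_equal(exact$n, 12)

  # independent draws: r near 0 at large n
  set.seed(6)
  ind <- regress_change_vs_baseline(data.frame(baseline = rnorm(4000),
                                               change = rnorm(4000)))
  expect_lt(abs(ind$r), 0.05)

  # direct-summation covariance oracle
  set.seed(7)
  tb <- data.frame(baseline = runif(40), change = rnorm(40))
  expect_equal(regress_change_vs_baseline(tb)$r,
               direct_pearson_r(tb$baseline, tb$change))

  expect_error(regress_change_vs_baseline(
    data.frame(baseline = rep(1, 5), change = rnorm(5))), "zero variance")
})

test_that("820/910 nm artifact ratios are per-ROI metric quotients", {
  m910 <- c(1, 2, 4)
  expect_equal(artifact_ratio(0.4 * m910, m910)$ratio, rep(0.4, 3))
  expect_equal(artifact_ratio(m910, m910)$mean, 1)
  expect_equal(artifact_ratio(rep(0, 3), m910)$ratio, rep(0, 3))
  expect_warning(ar <- artifact_ratio(c(1, 1), c(2, 0)), "undefined")
  expect_equal(ar$flagged, 2L)
  expect_equal(ar$n, 1)
})

test_that("end-to-end analysis recovers the planted drug-effect structure", {
  p <- loco_gen_params(n_rois = 80, seed = 21)
  g <- gen_locomotion_block(p)
  dffm <- normalize_to_rest(g$block, select_least_active(g$block))
  res <- analyze_locomotion(dffm)
  # fitted r close to this block's planted sample correlation
  expect_equal(res$regression$r, cor(g$truth$b, g$truth$d), tolerance = 0.02)
  # detrended post-drug change approximates the planted per-ROI change
  expect_gt(cor(res$effects$change, g$truth$d), 0.99)
  # pre-drug detrended values are ~0 by construction
  pre <- res$summary[res$summary$condition == "pre_drug", ]
  expect_lt(max(abs(tapply(pre$L_detrended, pre$roi, mean))), 0.02)
})
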