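test_that("Hill fit recovers noiseless parameters exactly", {
  td <- gen_titration(true_kd = 1, hill_n = 1, f_min = 0, f_max = 1,
                      n_replicates = 2, noise_sd = 0, seed = 1)
  fit <- fit_hill(td)
  expect_equal(fit$kd, 1, tolerance = 1e-6)
  expect_equal(fit$hill_n, 1, tolerance = 1e-4)
  # predicted fluorescence at the fitted Kd is the half-maximal change
  pred <- fit$f_min + (fit$f_max - fit$f_min) * fit$kd^fit$hill_n /
    (fit$kd^fit$hill_n + fit$kd^fit$hill_n)
  expect_equal(pred, (fit$f_min + fit$f_max) / 2, tolerance = 1e-9)
})

test_that("Hill fit honours a fixed Hill coefficient and replicate rules", {
  td <- gen_titration(true_kd = 2, hill_n = 1, noise_sd = 0, n_replicates = 1, seed = 1)
  fit <- fit_hill(td, fix_hill_n = 1)
  expect_equal(fit$hill_n, 1)
  expect_equal(fit$kd, 2, tolerance = 1e-5)
  expect_true(is.na(fit$kd_sem))       # a single replicate has no SEM

  bad <- data.frame(ca_uM = c(1, 2, 3), fluor = c(0.1, 0.4, 0.8), replicate = 1)
  expect_error(fit_hill(bad), class = "alternans_invalid_parameter")
})

test_that("Kd and koff are invariant to affine transforms of the fluorescence", {
  td <- gen_titration(true_kd = 1.5, hill_n = 2, noise_sd = 0.01, seed = 7)
  scaled <- td
  scaled$data$fluor <- 3.7 * td$data$fluor + 11
  f1 <- fit_hill(td); f2 <- fit_hill(scaled)
  expect_equal(f2$kd, f1$kd, tolerance = 1e-5)
  expect_equal(f2$hill_n, f1$hill_n, tolerance = 1e-4)

  sf <- gen_stopped_flow(150, noise_sd = 0.005, seed = 8)
  sf2 <- sf
  sf2$traces$fluor <- 2.5 * sf$traces$fluor + 4
  e1 <- fit_exp_decay(sf); e2 <- fit_exp_decay(sf2)
  expect_equal(e2$koff, e1$koff, tolerance = 1e-6)
  expect_equal(e2$amplitude, 2.5 * e1$amplitude, tolerance = 1e-4)
})

test_that("exponential fit recovers a noiseless rate and matches a log-linear oracle", {
  sf <- gen_stopped_flow(true_koff = 100, amplitude = 1, offset = 0.2,
                         noise_sd = 0, n_traces = 1, seed = 1)
  fit <- fit_exp_decay(sf)
  expect_equal(fit$koff, 100, tolerance = 1e-4)

  # independent oracle: linear regression on log(F - C) has slope -k
  tr <- sf$traces
  k_oracle <- -coef(lm(log(tr$fluor - 0.2) ~ tr$t_ms))[2] * 1000
  expect_equal(fit$koff, unname(k_oracle), tolerance = 1e-6)
})

test_that("exponential fit rejects non-decaying traces", {
  sf <- gen_stopped_flow(100, amplitude = 1, offset = 0, noise_sd = 0,
                         n_traces = 1, seed = 1)
  sf$traces$fluor <- rev(sf$traces$fluor)   # rising trace
  expect_error(fit_exp_decay(sf), class = "alternans_fit_failure")
})

test_that("trace averaging behaves as a pointwise mean", {
  sf <- gen_stopped_flow(100, noise_sd = 0, n_traces = 5, seed = 1)
  avg <- average_traces(sf)
  one <- sf$traces[sf$traces$trace_id == 1, ]
  expect_equal(avg$fluor, one$fluor, tolerance = 1e-12)

  two <- sf$traces[sf$traces$trace_id %in% 1:2, ]
  two$fluor[two$trace_id == 2] <- -two$fluor[two$trace_id == 1]
  d <- structure(list(traces = two), class = "stopped_flow_dataset")
  expect_warning(avg0 <- average_traces(d), "fewer than 5")
  expect_equal(avg0$fluor, rep(0, nrow(avg0)), tolerance = 1e-12)
})

test_that("averaging n noisy traces shrinks the residual noise like 1/sqrt(n)", {
  n <- 16; sigma <- 0.05
  sf <- gen_stopped_flow(100, noise_sd = sigma, n_traces = n, seed = 3)
  avg <- average_traces(sf)
  clean <- gen_stopped_flow(100, noise_sd = 0, n_traces = 1, seed = 3)
  resid_sd <- sd(avg$fluor - clean$traces$fluor)
  expect_equal(resid_sd, sigma / sqrt(n), tolerance = 0.25)
})

test_that("two-group comparison matches the pooled Student t", {
  cmp0 <- compare_parameters(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp0$t_stat, 0)
  expect_equal(cmp0$p_value, 1)
  expect_equal(cmp0$fold_ratio, 1)

  cmp <- compare_parameters(c(10, 12, 14), c(20, 22, 24))
  # pooled-variance t: sp = 2, se = 2 sqrt(2/3), t = -10/se
  expect_equal(cmp$t_stat, -10 / (2 * sqrt(2 / 3)), tolerance = 1e-9)
  expect_equal(cmp$t_stat, -6.1237, tolerance = 1e-4)
  expect_equal(cmp$df, 4)
  expect_true(cmp$significant)

  expect_error(compare_parameters(1, c(1, 2)), class = "alternans_invalid_parameter")
})

test_that("the comparison's type-I error rate is close to alpha under the null", {
  set.seed(314)
  rejections <- mean(replicate(2000, {
    compare_parameters(rnorm(5), rnorm(5))$p_value <= 0.05
  }))
  expect_gt(rejections, 0.03)
  expect_lt(rejections, 0.07)
})

test_that("parameter recovery holds across the physiological Kd and rate range", {
  for (kd in c(0.1, 1, 10)) {
    td <- gen_titration(true_kd = kd, hill_n = 1.5, noise_sd = 0.02,
                        n_replicates = 6, seed = round(kd * 100))
    expect_lt(abs(fit_hill(td)$kd / kd - 1), 0.1)
  }
  for (k in c(10, 100, 500)) {
    sf <- gen_stopped_flow(true_koff = k, noise_sd = 0.02, n_traces = 9, seed = k)
    expect_lt(abs(fit_exp_decay(sf)$koff / k - 1), 0.05)
  }
})
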