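test_that("dF/F0 normalisation zeroes the baseline and respects polarity", {
  tr <- gen_transient_train(rate = 60, duration = 5, noise_sd = 0)
  nd <- normalize_dff(tr, channel = "v")
  expect_lt(abs(mean(nd$y[tr$time < 0.4])), 1e-9)

  flat <- tr
  flat$v[] <- 100
  ndf <- normalize_dff(flat, channel = "v")
  expect_equal(ndf$y, rep(0, length(flat$v)))

  inv <- gen_transient_train(rate = 60, duration = 5, noise_sd = 0,
                             polarity = c(-1, 1))
  nd_inv <- normalize_dff(inv, channel = "v")
  expect_equal(nd_inv$y, nd$y, tolerance = 1e-9)
})

test_that("downstream metrics are invariant to affine intensity transforms", {
  tr <- gen_transient_train(rate = 60, duration = 8, noise_sd = 0.01, seed = 4)
  m1 <- analyze_trace(tr)
  tr2 <- tr
  tr2$v <- 1.8 * tr$v + 40
  tr2$ca <- 0.6 * tr$ca + 15
  m2 <- analyze_trace(tr2)
  expect_equal(m2$apd30, m1$apd30, tolerance = 1e-6)
  expect_equal(m2$apd80, m1$apd80, tolerance = 1e-6)
  expect_equal(m2$catd80, m1$catd80, tolerance = 1e-6)
})

test_that("beat segmentation finds each evoked transient and nothing else", {
  tr <- gen_transient_train(rate = 60, duration = 20, noise_sd = 0)
  expect_length(segment_beats(tr, channel = "v"), 20)

  flat <- tr
  flat$v[] <- 100
  expect_length(segment_beats(flat, channel = "v"), 0)
})

test_that("recovery durations follow linear interpolation on a constructed ramp", {
  # instantaneous rise then linear decay to baseline over 100 ms
  t <- seq(0, 0.3, by = 0.01)
  # exact node values: y falls from 1 at t[6] to 0 at t[16] in steps of 0.1
  y <- pmax(0, 1 - (seq_along(t) - 6) / 10) * (seq_along(t) >= 6)
  beat <- list(index = 1, t = t, y = y, activation_time = 0.05,
               baseline = 0, peak = 1, amplitude = 1)
  expect_equal(duration_at_recovery(beat, 0.30), 30, tolerance = 1e-6)
  expect_equal(duration_at_recovery(beat, 0.80), 80, tolerance = 1e-6)
  expect_equal(duration_at_recovery(beat, 1.00), 100, tolerance = 1e-6)

  # a signal that never recovers is reported as NA, not an error
  stuck <- beat
  stuck$y <- pmax(y, 0.5)
  expect_true(is.na(duration_at_recovery(stuck, 0.80)))
})

test_that("triangulation index follows its defining formula", {
  expect_equal(triangulation_index(210, 300), 0.3)
  expect_equal(triangulation_index(100, 250), 0.6)
  expect_equal(triangulation_index(200, 200), 0)
  expect_error(triangulation_index(300, 200), class = "alternans_invalid_parameter")
})

test_that("alternans metric matches a brute-force phase-enumeration oracle", {
  expect_equal(alternans_metric(c(1.2, 0.8, 1.2, 0.8))$ratio, 0.4)
  expect_true(alternans_metric(c(1.2, 0.8, 1.2, 0.8))$flag)
  expect_equal(alternans_metric(rep(1, 6))$ratio, 0)
  expect_false(alternans_metric(rep(1, 6))$flag)
  expect_error(alternans_metric(c(1, 2)), class = "alternans_insufficient_data")

  oracle <- function(p) {
    ph1 <- abs(mean(p[seq(1, length(p), 2)]) - mean(p[seq(2, length(p), 2)]))
    ph2 <- abs(mean(p[seq(2, length(p), 2)]) - mean(p[seq(1, length(p), 2)]))
    max(ph1, ph2) / mean(p)
  }
  set.seed(21)
  for (i in 1:25) {
    p <- abs(rnorm(sample(4:12, 1), mean = 1, sd = 0.3)) + 0.1
    expect_equal(alternans_metric(p)$ratio, oracle(p), tolerance = 1e-12)
  }
})

test_that("an injected alternans ratio is recovered from a noisy train", {
  tr <- gen_transient_train(rate = 60, duration = 20, alternans_ratio = 0.2,
                            noise_sd = 0.02, seed = 6)
  rep <- entrainment_check(tr)
  expect_equal(rep$alternans_ratio, 0.2, tolerance = 0.1)
  expect_lt(abs(rep$alternans_ratio - 0.2), 0.02)
  expect_true(rep$alternans_flag)
})

test_that("entrainment classification counts missed transients", {
  clean <- gen_transient_train(rate = 55, duration = 20, noise_sd = 0.01, seed = 2)
  r1 <- entrainment_check(clean)
  expect_true(r1$entrained)
  expect_equal(r1$n_irregular, 0)

  two_one <- gen_transient_train(rate = 60, duration = 20,
                                 skipped_beats = seq(2, 20, by = 2), noise_sd = 0)
  r2 <- entrainment_check(two_one)
  expect_equal(r2$n_transients, r2$n_stimuli / 2)
  expect_false(r2$entrained)
})

test_that("pacing rate conversions are exact inverses", {
  expect_equal(pcl_to_bpm(600), 100)
  expect_equal(pcl_to_bpm(1000), 60)
  expect_equal(bpm_to_pcl(pcl_to_bpm(437)), 437)
  for (pcl in c(300, 450, 700, 1090.9)) {
    expect_equal(bpm_to_pcl(pcl_to_bpm(pcl)), pcl, tolerance = 1e-12)
  }
  expect_error(pcl_to_bpm(0), class = "alternans_invalid_parameter")
})

test_that("accepted beats always satisfy the duration ordering", {
  for (s in 1:3) {
    tr <- gen_transient_train(rate = 75, duration = 12, noise_sd = 0.02, seed = s)
    m <- analyze_trace(tr)
    ok <- !is.na(m$apd30) & !is.na(m$apd80)
    expect_true(all(m$apd30[ok] <= m$apd80[ok]))
    ok2 <- !is.na(m$catd30) & !is.na(m$catd80)
    expect_true(all(m$catd30[ok2] <= m$catd80[ok2]))
  }
})

test_that("frequency summaries compare groups and rates correctly", {
  set.seed(10)
  mk <- function(group, rate, mu) data.frame(group = group, rate_bpm = rate,
                                             apd80 = rnorm(12, mu, 5))
  m <- rbind(mk("WT", 55, 300), mk("WT", 75, 260),
             mk("VAR", 55, 340), mk("VAR", 75, 262))
  out <- summarize_by_frequency(m, metric_cols = "apd80")
  b55 <- out$between_groups[out$between_groups$rate_bpm == 55, ]
  expect_true(b55$significant)          # 40 ms offset >> 5 ms noise
  expect_equal(nrow(out$summary), 4)
  expect_lt(out$across_rates$WT$apd80$anova_p, 0.01)

  same <- rbind(mk("WT", 55, 300), mk("VAR", 55, 300))
  same$apd80 <- rep(1, nrow(same))      # identical constant groups
  out2 <- summarize_by_frequency(same, metric_cols = "apd80")
  expect_equal(out2$between_groups$p, 1)
})

test_that("one-way ANOVA across rates holds its size under the null", {
  set.seed(77)
  pvals <- replicate(400, {
    d <- data.frame(group = "g", rate_bpm = rep(c(55, 65, 75), each = 6),
                    m = rnorm(18))
    summarize_by_frequency(d, metric_cols = "m")$across_rates$g$m$anova_p
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
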