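test_that("housekeeping normalisation removes per-sample scale", {
  cm <- gen_counts(n_genes = 30, fold_changes = c(GENEA = 2),
                   dispersion = 0, seed = 1)
  norm1 <- normalize_counts(cm)
  scaled <- cm
  scaled$counts[, 2] <- scaled$counts[, 2] * 3   # tripled library
  norm2 <- normalize_counts(scaled)
  # tripling one library triples its factor relative to the others; the
  # overall geometric-mean gauge absorbs a 3^(1/7) shift
  expect_equal(unname(norm2$factors[2] / norm1$factors[2]), 3 / 3^(1 / 7),
               tolerance = 1e-9)
  # normalised profiles agree up to that single global gauge constant
  ratio <- norm2$linear / norm1$linear
  expect_lt(diff(range(ratio[norm1$linear > 0])), 1e-9)

  # identical samples: all factors one, output log2(counts + 1)
  same <- cm
  same$counts <- matrix(rep(same$counts[, 1], ncol(same$counts)),
                        ncol = ncol(same$counts),
                        dimnames = dimnames(same$counts))
  ns <- normalize_counts(same)
  expect_equal(unname(ns$factors), rep(1, 7), tolerance = 1e-12)
  expect_equal(ns$log2[, 1], log2(same$counts[, 1] + 1), tolerance = 1e-12)
})

test_that("a zero housekeeping count is a hard normalisation error", {
  cm <- gen_counts(n_genes = 20, fold_changes = numeric(0), seed = 2)
  cm$counts[cm$housekeeping[1], 1] <- 0
  expect_error(normalize_counts(cm), class = "alternans_normalization_error")
})

test_that("Welch test matches its defining formula and symmetries", {
  w <- welch_test(c(10, 12, 14), c(20, 22, 24))
  expect_equal(w$t, -6.1237, tolerance = 1e-4)
  expect_equal(w$df, 4, tolerance = 1e-9)

  sw <- welch_test(c(20, 22, 24), c(10, 12, 14))
  expect_equal(sw$t, -w$t)
  expect_equal(sw$p, w$p)

  same <- welch_test(c(5, 5), c(5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Benjamini-Yekutieli adjustment matches the hand-computed step-up", {
  expect_equal(adjust_by(0.2), 0.2)                  # m = 1: unchanged
  expect_equal(adjust_by(c(0.01, 0.02, 0.9)), c(0.055, 0.055, 1),
               tolerance = 1e-12)
  expect_equal(adjust_by(rep(1, 5)), rep(1, 5))
  expect_error(adjust_by(c(0.5, 1.2)), class = "alternans_invalid_parameter")
})

test_that("BY is monotone, bounded, and at least as conservative as BH", {
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(5:60, 1))
    a <- adjust_by(p)
    expect_true(all(a >= p - 1e-12))
    expect_true(all(a <= 1))
    expect_true(all(a >= p.adjust(p, "BH") - 1e-12))
    ord <- order(p)
    expect_true(all(diff(a[ord]) >= -1e-12))
  }
})

test_that("a null count matrix yields essentially no significant calls", {
  n_sig <- vapply(1:20, function(s) {
    cm <- gen_counts(fold_changes = numeric(0), seed = 1000 + s)
    attr(call_degs(cm), "summary")$n_significant
  }, numeric(1))
  expect_lt(mean(n_sig > 0), 0.05 + 0.1)   # FDR control within MC error
})

test_that("differential calls are invariant to per-sample rescaling of raw counts", {
  cm <- gen_counts(seed = 4)
  d1 <- call_degs(cm)
  cm2 <- cm
  cm2$counts <- sweep(cm$counts, 2, c(2, 1, 3, 1, 0.5, 1, 4), "*")
  d2 <- call_degs(cm2)
  # per-sample scale is removed exactly up to the global gauge that the
  # log2(x + 1) pseudocount re-expresses; calls and statistics are stable
  expect_equal(d2$p, d1$p, tolerance = 1e-2)
  expect_equal(d2$log2fc, d1$log2fc, tolerance = 0.02)
  expect_identical(d2$significant, d1$significant)
})

test_that("group-mean expression ratios behave as ratios", {
  cm <- gen_counts(seed = 5)
  norm <- normalize_counts(cm)
  expect_equal(expression_ratio(norm, "PPIA", "PPIA", "WT"), 1)
  r <- expression_ratio(norm, "NPPA", "NPPB", "I79N")
  cm2 <- cm
  cm2$counts[c("NPPA", "NPPB"), ] <- cm2$counts[c("NPPA", "NPPB"), ] * 2
  expect_equal(expression_ratio(normalize_counts(cm2), "NPPA", "NPPB", "I79N"),
               r, tolerance = 1e-9)
  expect_error(expression_ratio(norm, "NOPE", "NPPB", "WT"),
               class = "alternans_invalid_parameter")
})

test_that("a synthetic maturation-index ratio is recovered from counts", {
  cm <- gen_counts(n_genes = 40,
                   fold_changes = c(TNNI3 = 1),
                   dispersion = 0.005, baseline_mean = 2000, seed = 6)
  # impose a 6.1:1 mean ratio by construction
  cm$counts <- rbind(cm$counts,
                     TNNI1 = pmax(1L, as.integer(round(cm$counts["TNNI3", ] / 6.1))))
  r <- expression_ratio(normalize_counts(cm), "TNNI3", "TNNI1", "I79N")
  expect_equal(r, 6.1, tolerance = 0.1)
})

test_that("delta-delta-Ct quantification inverts the fold-change formula", {
  ct <- expand.grid(gene = c("TGT", "ACTB", "GAPDH"),
                    sample = 1:3, group = c("ref", "cond"),
                    stringsAsFactors = FALSE)
  ct$ct <- 20
  expect_equal(ddct_fold(ct, "TGT", "cond", "ref"), 1)

  ct2 <- ct
  ct2$ct[ct2$gene == "TGT" & ct2$group == "cond"] <- 19   # ddCt = -1
  expect_equal(ddct_fold(ct2, "TGT", "cond", "ref"), 2)

  ct3 <- ct
  ct3$ct[ct3$gene == "TGT" & ct3$group == "cond"] <- 20 - log2(18.6)
  expect_equal(ddct_fold(ct3, "TGT", "cond", "ref"), 18.6, tolerance = 1e-9)

  missing <- ct[!(ct$gene == "GAPDH" & ct$sample == 2 & ct$group == "cond"), ]
  expect_error(ddct_fold(missing, "TGT", "cond", "ref"),
               class = "alternans_invalid_parameter")
})
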