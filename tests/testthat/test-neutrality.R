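test_that("Tajima's D matches direct evaluation of the 1989 constants", {
  # n=4, S=2, pi_total=4/3; independent arithmetic for the constants
  n <- 4; S <- 2
  a1 <- 1 + 1/2 + 1/3; a2 <- 1 + 1/4 + 1/9
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  d_expected <- (4/3 - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajima_d_counts(4, 2, 4/3), d_expected, tolerance = 1e-12)
  expect_equal(round(tajima_d_counts(4, 2, 4/3), 3), 1.893)
  expect_equal(tajima_d(two_snp_alignment(100L)), d_expected)
  expect_true(is.na(tajima_d_counts(10, 0, 0)))
  expect_error(tajima_d_counts(3, 2, 1), "n >= 4")

  # all-singleton excess on one sequence drives D negative
  haps <- matrix(0L, 10L, 6L)
  haps[1L, ] <- 1L
  st <- ivypopgen:::.seg_stats(haps)
  expect_lt(tajima_d_counts(st$n, st$S, st$pi_total), 0)
})

test_that("Ewens probabilities match exact enumeration and sum to one", {
  for (theta in c(0.3, 1, 4/3, 5)) {
    expect_equal(ewens_k_probabilities(4, theta), bf_ewens_n4(theta),
                 tolerance = 1e-12)
  }
  for (n in c(2L, 7L, 20L, 60L))
    expect_equal(sum(ewens_k_probabilities(n, 2.5)), 1, tolerance = 1e-10)
})

test_that("Fu's Fs matches the hand-computable Ewens cases", {
  expect_equal(fu_fs_counts(4, 2, 1), log(3), tolerance = 1e-12)
  # n=4, k=4, theta=4/3: S' = (4/3)^4 / ((4/3)(7/3)(10/3)(13/3)) = 256/3640
  sp <- 256 / 3640
  expect_equal(fu_fs_counts(4, 4, 4/3), log(sp / (1 - sp)), tolerance = 1e-12)
  expect_equal(round(fu_fs_counts(4, 4, 4/3), 2), -2.58)
  # all-identical sample: P(K >= 1) = 1 -> +Inf sentinel
  expect_identical(fu_fs_counts(6, 1, 2), Inf)
  expect_warning(fu_fs_counts(6, 2, 1e-12), NA) # small positive theta is fine
})

test_that("Fu's Fs is invariant to site and haplotype order", {
  set.seed(9)
  haps <- matrix(rbinom(8L * 12L, 1L, 0.3), nrow = 8L)
  f0 <- fu_fs(haps)
  expect_equal(fu_fs(haps[, sample(12L)]), f0)
  expect_equal(fu_fs(haps[sample(8L), ]), f0)
})

test_that("R2 matches hand evaluation and signals star genealogies", {
  aln <- two_snp_alignment(100L)
  expect_equal(r2_statistic(aln), 1/3, tolerance = 1e-12)
  # evenly spread singletons (star-like): R2 small
  star <- diag(1L, 8L)
  expect_lt(r2_statistic(star), r2_statistic(aln))
  expect_true(is.na(r2_counts(4, 0, 0, rep(0, 4))))
})

test_that("fixed-S nulls match the slightly negative neutral mean of D", {
  set.seed(17)
  null <- coalescent_null("tajima_d", 20, 17, reps = 3000)
  # D has a small negative expectation in finite samples; the reference
  # value -0.084 comes from an independent coalescent simulator under the
  # same conditioning (and matches the sign of published simulated-D columns)
  expect_lt(abs(mean(null) - (-0.084)), 0.05)

  med <- stats::median(null)
  pv <- coalescent_pvalue(med, "tajima_d", 20, 17, null_values = null)
  expect_equal(pv$p_low, 0.5, tolerance = 0.05)
  expect_equal(pv$p_high, 0.5, tolerance = 0.05)
  expect_gte(pv$p_low + pv$p_high, 1)  # ties counted in both tails

  pv1 <- coalescent_pvalue(0.5, "tajima_d", 10, 8, reps = 300, seed = 42)
  pv2 <- coalescent_pvalue(0.5, "tajima_d", 10, 8, reps = 300, seed = 42)
  expect_identical(pv1$null_values, pv2$null_values)
  expect_true(is.na(coalescent_pvalue(NA_real_, "tajima_d", 10, 8,
                                      null_values = null)$p_low))
})

test_that("growth data shift single-locus p-values into the lower tail", {
  # a single short locus has modest power against alpha = 10 (independent
  # coalescent-oracle power is ~0.15-0.25 at the 5% level; the pooled
  # multilocus test below is the powerful version), so the check here is the
  # tail shift, not near-certain rejection
  set.seed(23)
  model <- demography_model(growth_rate = 10)
  p_low <- replicate(40, {
    loc <- drop_mutations(simulate_tree(20, model), theta = 12)
    st <- ivypopgen:::.seg_stats(loc$haplotypes)
    if (st$S < 1) return(NA)
    d <- tajima_d_counts(st$n, st$S, st$pi_total)
    coalescent_pvalue(d, "tajima_d", 20, st$S, reps = 300)$p_low
  })
  expect_lt(stats::median(p_low, na.rm = TRUE), 0.3)
  expect_gte(mean(p_low <= 0.05, na.rm = TRUE), 0.10)
})

test_that("the multilocus D randomization flags growth but not symmetric data", {
  set.seed(29)
  model <- demography_model(growth_rate = 10)
  per_locus <- do.call(rbind, lapply(1:6, function(l) {
    loc <- drop_mutations(simulate_tree(30, model), theta = 10)
    st <- ivypopgen:::.seg_stats(loc$haplotypes)
    data.frame(d = tajima_d_counts(st$n, st$S, st$pi_total), n = 30, s = st$S)
  }))
  res <- multilocus_d_test(per_locus, reps = 600, seed = 3)
  expect_lt(res$observed, 0)
  expect_lt(res$p_low, 0.05)

  # per-locus D equal to each null's center: two-sided p near 0.5
  sym <- data.frame(d = c(0, 0, 0), n = 20, s = c(10, 12, 8))
  res0 <- multilocus_d_test(sym, reps = 600, seed = 4)
  expect_gt(res0$p_low, 0.2)
  expect_gt(res0$p_high, 0.2)
  expect_error(multilocus_d_test(data.frame(d = NA_real_, n = 20, s = 5)),
               ">= 2 loci")
})

test_that("the three expansion statistics agree in direction under growth", {
  set.seed(37)
  model <- demography_model(growth_rate = 10)
  stats3 <- replicate(30, {
    loc <- drop_mutations(simulate_tree(25, model), theta = 10)
    st <- ivypopgen:::.seg_stats(loc$haplotypes)
    c(d = tajima_d_counts(st$n, st$S, st$pi_total),
      fs = if (st$pi_total > 0)
        fu_fs_counts(st$n, st$k_hap, st$pi_total) else NA,
      r2 = r2_counts(st$n, st$S, st$pi_total, st$singletons))
  })
  null3 <- replicate(200, {
    loc <- drop_fixed_s(simulate_tree(25), 17)
    st <- ivypopgen:::.seg_stats(loc$haplotypes)
    c(d = tajima_d_counts(st$n, st$S, st$pi_total),
      fs = if (st$pi_total > 0)
        fu_fs_counts(st$n, st$k_hap, st$pi_total) else NA,
      r2 = r2_counts(st$n, st$S, st$pi_total, st$singletons))
  })
  # growth: D and Fs below their neutral means, R2 below its neutral mean
  expect_lt(mean(stats3["d", ], na.rm = TRUE), mean(null3["d", ], na.rm = TRUE))
  expect_lt(mean(stats3["fs", ][is.finite(stats3["fs", ])]),
            mean(null3["fs", ][is.finite(null3["fs", ])]))
  expect_lt(mean(stats3["r2", ], na.rm = TRUE),
            mean(null3["r2", ], na.rm = TRUE))
})
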