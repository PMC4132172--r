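test_that("Weir-Cockerham FST matches hand-computed cases", {
  # fixed difference between two populations
  G <- matrix(c(rep(0L, 10), rep(2L, 10)), ncol = 1L)
  snps <- toy_snps(G)
  meta <- toy_meta(rep(c("a", "b"), each = 10L))
  expect_equal(unname(weir_cockerham_fst(snps, meta)), 1)

  # both populations 25/50/25: theta-hat = -1/198 (no differentiation)
  G2 <- matrix(rep(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), 2L), ncol = 1L)
  snps2 <- toy_snps(G2)
  meta2 <- toy_meta(rep(c("a", "b"), each = 100L))
  expect_equal(unname(weir_cockerham_fst(snps2, meta2)), -1 / 198,
               tolerance = 1e-10)

  # monomorphic SNP: NA
  G3 <- cbind(G, 0L)
  expect_true(is.na(weir_cockerham_fst(toy_snps(G3), meta)[2L]))
})

test_that("random splits of one panmictic pool give FST near zero", {
  set.seed(19)
  fst <- replicate(400, {
    g <- rbinom(40L, 2L, 0.4)  # HWE pool
    G <- matrix(g, ncol = 1L)
    unname(weir_cockerham_fst(toy_snps(G), toy_meta(sample(rep(c("a", "b"),
                                                               each = 20L)))))
  })
  expect_equal(mean(fst, na.rm = TRUE), 0, tolerance = 0.01)
})

test_that("AMOVA recovers maximal-differentiation and full-selfing structure", {
  set.seed(4)
  # two clonal populations fixed for alternative alleles at all SNPs
  G <- rbind(matrix(0L, 6L, 8L), matrix(2L, 6L, 8L))
  res <- amova(toy_snps(G), toy_meta(rep(c("a", "b"), each = 6L)),
               permutations = 49)
  expect_equal(unname(res$percentages[1L]), 100)
  expect_equal(unname(res$f_statistics["FST"]), 1)

  # fully homozygous individuals, identical frequencies: FIS = 1, no
  # within-individual variance
  G2 <- rbind(matrix(rep(c(0L, 2L), each = 4L), 8L, 6L),
              matrix(rep(c(0L, 2L), each = 4L), 8L, 6L))
  res2 <- amova(toy_snps(G2), toy_meta(rep(c("a", "b"), each = 8L)),
                permutations = 49)
  expect_equal(unname(res2$f_statistics["FIS"]), 1)
  expect_equal(unname(res2$percentages[3L]), 0)

  # percentage and FIT identities
  set.seed(6)
  G3 <- matrix(rbinom(20L * 10L, 2L, 0.35), 20L, 10L)
  res3 <- amova(toy_snps(G3), toy_meta(rep(c("a", "b", "c", "d"), each = 5L)),
                permutations = 49)
  expect_equal(sum(res3$percentages), 100, tolerance = 1e-9)
  fst <- res3$f_statistics["FST"]; fis <- res3$f_statistics["FIS"]
  expect_equal(unname(res3$f_statistics["FIT"]),
               unname(fst + (1 - fst) * fis), tolerance = 1e-9)

  # singleton populations are excluded with a warning
  meta_bad <- toy_meta(c(rep("a", 9L), rep("b", 10L), "c"),
                       inds = rownames(G3))
  expect_warning(amova(toy_snps(G3), meta_bad, permutations = 9), "size 1")
})

test_that("Nei's distance matches hand evaluation and its sentinels", {
  # identical frequencies -> 0
  G <- matrix(rep(c(0L, 1L, 2L, 1L), 2L), ncol = 1L)
  d0 <- nei_distance(toy_snps(G), toy_meta(rep(c("a", "b"), each = 4L)))
  expect_equal(d0["a", "b"], 0, tolerance = 1e-12)

  # frequencies (0.5, 0.5) vs (0.9, 0.1): D = -ln(0.5/sqrt(0.5*0.82))
  G2 <- matrix(c(rep(1L, 10L), rep(2L, 8L), rep(1L, 2L)), ncol = 1L)
  d2 <- nei_distance(toy_snps(G2), toy_meta(rep(c("a", "b"), each = 10L)))
  expect_equal(d2["a", "b"], -log(0.5 / sqrt(0.5 * 0.82)), tolerance = 1e-12)
  expect_equal(round(d2["a", "b"], 3), 0.247)

  # non-overlapping fixed alleles -> +Inf sentinel
  G3 <- matrix(c(rep(0L, 4L), rep(2L, 4L)), ncol = 1L)
  d3 <- nei_distance(toy_snps(G3), toy_meta(rep(c("a", "b"), each = 4L)))
  expect_identical(d3["a", "b"], Inf)
})

test_that("Mantel test handles perfect relations, invariance and degenerate input", {
  set.seed(14)
  m1 <- as.matrix(stats::dist(stats::runif(9)))
  m2 <- 2 * m1 + 3
  res <- mantel_test(m1, m2, permutations = 999, seed = 1)
  expect_equal(res$r_xy, 1, tolerance = 1e-12)
  expect_lte(res$p, 2 / 1000)

  # affine transform of either matrix leaves r unchanged
  m3 <- as.matrix(stats::dist(stats::rnorm(9)))
  r_base <- mantel_test(m1, m3, permutations = 99, seed = 2)$r_xy
  expect_equal(mantel_test(5 * m1 + 1, m3, permutations = 99, seed = 2)$r_xy,
               r_base, tolerance = 1e-12)

  m_const <- matrix(1, 9, 9); diag(m_const) <- 0
  expect_error(mantel_test(m_const, m3), "constant")
})

test_that("great-circle distances use the 6371 km haversine", {
  meta <- data.frame(population_id = c("o", "anti", "same"),
                     individual_id = c("a", "b", "c"),
                     latitude = c(0, 0, 0), longitude = c(0, 180, 0))
  d <- geographic_distance(meta)
  expect_equal(d["o", "anti"], pi * 6371, tolerance = 1e-6)
  expect_equal(d["o", "same"], 0)
  expect_equal(d, t(d))
  meta$latitude[2L] <- NA
  expect_error(geographic_distance(meta), "anti")
})

test_that("the selfing-rate equation reproduces its anchors", {
  expect_equal(selfing_rate_from_fis(0.86), 200 * 0.86 / 1.86,
               tolerance = 1e-12)
  expect_equal(round(selfing_rate_from_fis(0.86)), 92)
  expect_equal(selfing_rate_from_fis(0), 0)
  expect_equal(selfing_rate_from_fis(1), 100)
  expect_warning(sr <- selfing_rate_from_fis(-0.1), "clamped")
  expect_equal(sr, 0)
})

test_that("LD r2 is the squared dosage correlation with a chi-square flag", {
  # identical dosage vectors -> r2 = 1
  g <- rbinom(60L, 2L, 0.5)
  snps <- toy_snps(cbind(g, g, 2L - g))
  ld <- ld_r2_matrix(snps)
  expect_equal(ld$r2[1L, 2L], 1)
  expect_equal(ld$r2[1L, 3L], 1)     # perfect repulsion is still r2 = 1
  expect_true(all(ld$ld_flags))

  # phased homozygote counts AB=40, ab=40, Ab=10, aB=10 -> r2 = 0.36
  G <- rbind(matrix(rep(c(2L, 2L), 40L), ncol = 2L, byrow = TRUE),
             matrix(rep(c(0L, 0L), 40L), ncol = 2L, byrow = TRUE),
             matrix(rep(c(2L, 0L), 10L), ncol = 2L, byrow = TRUE),
             matrix(rep(c(0L, 2L), 10L), ncol = 2L, byrow = TRUE))
  expect_equal(ld_r2_matrix(toy_snps(G))$r2[1L, 2L], 0.36, tolerance = 1e-12)

  # orthogonal-after-centering dosages -> r2 = 0
  x <- c(0L, 0L, 2L, 2L); y <- c(0L, 2L, 0L, 2L)
  expect_equal(ld_r2_matrix(toy_snps(cbind(x, y)))$r2[1L, 2L], 0,
               tolerance = 1e-12)
})

test_that("LD pruning removes linked SNPs and keeps unlinked sets intact", {
  set.seed(44)
  G <- matrix(rbinom(200L * 6L, 2L, 0.5), 200L, 6L)
  snps <- toy_snps(G)
  meta <- toy_meta(rep(c("a", "b"), each = 100L))
  dist <- snp_fst_distribution(snps, meta, permutations = 49, seed = 1)
  ld <- ld_r2_matrix(snps)
  pruned <- prune_ld_and_recompute(dist, ld$ld_flags)
  expect_lte(nrow(pruned), nrow(dist))

  # no significant LD anywhere: identical distribution
  pruned0 <- prune_ld_and_recompute(dist, rep(FALSE, 6L))
  expect_identical(pruned0$fst, dist$fst)

  # a duplicated SNP pair is removed entirely under the "any LD" rule
  Gdup <- cbind(G[, 1L], G[, 1L], G[, 2:3])
  ld2 <- ld_r2_matrix(toy_snps(Gdup))
  expect_true(all(ld2$ld_flags[1:2]))

  expect_error(prune_ld_and_recompute(dist, rep(TRUE, 6L)), "all SNPs pruned")
})

test_that("outlier percentiles place a focal FST within the background", {
  bg <- seq(0.01, 0.2, length.out = 20L)
  expect_equal(outlier_percentile(bg, 0.5), 100)
  expect_equal(outlier_percentile(bg, stats::median(bg)), 50)
  expect_error(outlier_percentile(bg[1:5], 0.5), ">= 10")
  expect_error(outlier_percentile(numeric(0), 0.5), "empty")
})

test_that("multilocus FST increases as island-model migration decreases", {
  set.seed(55)
  mean_fst <- vapply(c(20, 4, 0.5), function(m) {
    model <- demography_model(n_demes = 4L, migration_rate = m)
    mean(replicate(25, {
      loc <- drop_mutations(simulate_tree(48, model,
                                          leaf_deme = rep(1:4, each = 12L)),
                            theta = 6)
      G <- loc$haplotypes[seq(1, 47, 2), ] + loc$haplotypes[seq(2, 48, 2), ]
      rownames(G) <- sprintf("i%d", 1:24)
      comp <- ivypopgen:::.wc_components(G, rep(c("a", "b", "c", "d"),
                                                each = 6L))
      ivypopgen:::.f_from_components(comp)$fst
    }))
  }, numeric(1))
  expect_true(all(diff(mean_fst) > 0))
})

test_that("linearized FST is a strictly increasing transform", {
  f <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(f / (1 - f)) > 0))
  snps <- toy_snps(matrix(c(rep(0L, 6L), rep(2L, 6L), rep(c(0L, 2L), 6L)),
                          ncol = 2L))
  pf <- pairwise_fst(snps, toy_meta(rep(c("a", "b"), each = 6L)))
  expect_equal(pf$lin_fst["a", "b"],
               pf$fst["a", "b"] / (1 - pf$fst["a", "b"]))
})
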