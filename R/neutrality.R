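# Neutrality tests ------------------------------------------------------------
#
# Tajima's D, Fu's Fs and Ramos-Onsins & Rozas's R2, each with an empirical
# p-value from coalescent simulations conditioned on the observed number of
# segregating sites (the DnaSP convention), plus the multilocus
# randomization test for the mean of Tajima's D across loci.

#' Tajima's D from summary counts
#'
#' `D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the Tajima (1989)
#' constants derived from the sample size.
#'
#' @param n Number of haplotypes (>= 4).
#' @param s Number of segregating sites.
#' @param pi_total Mean pairwise difference count (un-normalized).
#' @return D, or `NA` when `s == 0` (undefined).
#' @export
tajima_d_counts <- function(n, s, pi_total) {
  if (n < 4L) stop("Tajima's D needs n >= 4")
  if (s == 0L) return(NA_real_)
  a1 <- harmonic_a1(n)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

#' Tajima's D on an alignment or simulated locus
#'
#' @param x A classified `hap_alignment`, a `sim_locus`, or a haplotype
#'   matrix.
#' @param site_filter `"silent"` (default) or `"all"` for alignments.
#' @return D, or `NA` when no segregating sites.
#' @export
tajima_d <- function(x, site_filter = "silent") {
  st <- .hap_stats(x, site_filter)
  tajima_d_counts(st$n, st$S, st$pi_total)
}

# log |Stirling numbers of the first kind| for row n, cached per sample size
.stirling_cache <- new.env(parent = emptyenv())

.log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  ls <- -Inf
  row <- 0           # row for n = 1: |s(1,1)| = 1
  for (m in seq_len(n - 1L)) {   # build row m+1 from row m
    prev <- c(-Inf, row, -Inf)   # pad k = 0 and k = m+1
    newrow <- numeric(m + 1L)
    for (k in seq_len(m + 1L)) {
      # |s(m+1,k)| = m*|s(m,k)| + |s(m,k-1)|
      x1 <- log(m) + prev[k + 1L]
      x2 <- prev[k]
      mx <- max(x1, x2)
      newrow[k] <- if (is.infinite(mx)) -Inf else
        mx + log(exp(x1 - mx) + exp(x2 - mx))
    }
    row <- newrow
  }
  .stirling_cache[[key]] <- row
  row
}

#' Ewens sampling-formula probabilities of the number of alleles
#'
#' `P(K = k | theta, n) = |s(n,k)| theta^k / theta^(n)` with the ascending
#' factorial `theta^(n) = theta (theta+1) ... (theta+n-1)`.
#'
#' @param n Sample size.
#' @param theta Scaled diversity parameter (> 0).
#' @return Numeric vector of probabilities for k = 1..n (sums to 1).
#' @export
ewens_k_probabilities <- function(n, theta) {
  stopifnot(n >= 1L, theta > 0)
  lsr <- .log_stirling_row(n)
  lognum <- lsr + seq_len(n) * log(theta)
  logden <- sum(log(theta + 0:(n - 1L)))
  exp(lognum - logden)
}

#' Fu's Fs from summary counts
#'
#' `S' = P(K >= k_obs | theta, n)` under the Ewens sampling formula with
#' `theta` estimated by the mean pairwise difference count (Fu 1997
#' convention); `Fs = ln(S'/(1-S'))`.
#'
#' @param n Number of haplotypes.
#' @param k_obs Observed number of distinct haplotypes.
#' @param theta Estimate of theta (mean pairwise differences; > 0).
#' @return Fs; `+Inf`/`-Inf` sentinel with a warning when `S'` hits 1 or 0
#'   within numerical precision.
#' @export
fu_fs_counts <- function(n, k_obs, theta) {
  stopifnot(n >= 2L, k_obs >= 1L, k_obs <= n)
  if (theta <= 0) {
    warning("Fu's Fs undefined: theta (pairwise differences) is zero")
    return(NA_real_)
  }
  if (k_obs == 1L) return(Inf)   # P(K >= 1) = 1 exactly
  pk <- ewens_k_probabilities(n, theta)
  s_prime <- sum(pk[k_obs:n])
  if (s_prime >= 1 - 1e-12) {
    warning("S' numerically 1; returning +Inf sentinel")
    return(Inf)
  }
  if (s_prime <= 1e-300) {
    warning("S' numerically 0; returning -Inf sentinel")
    return(-Inf)
  }
  log(s_prime / (1 - s_prime))
}

#' Fu's Fs on an alignment or simulated locus
#'
#' @inheritParams tajima_d
#' @export
fu_fs <- function(x, site_filter = "silent") {
  st <- .hap_stats(x, site_filter)
  fu_fs_counts(st$n, st$k_hap, st$pi_total)
}

#' Ramos-Onsins & Rozas's R2 from summary counts
#'
#' `R2 = sqrt(mean((U_i - pi_total/2)^2)) / S` where `U_i` counts the
#' singleton variants carried by haplotype `i` (minor-allele count 1, the
#' folded definition used without an outgroup).
#'
#' @param n Number of haplotypes.
#' @param s Number of segregating sites (>= 1).
#' @param pi_total Mean pairwise difference count.
#' @param singletons Integer vector: singletons carried per haplotype.
#' @export
r2_counts <- function(n, s, pi_total, singletons) {
  if (s < 1L) return(NA_real_)
  sqrt(mean((singletons - pi_total / 2)^2)) / s
}

#' Ramos-Onsins & Rozas's R2 on an alignment or simulated locus
#'
#' @inheritParams tajima_d
#' @export
r2_statistic <- function(x, site_filter = "silent") {
  st <- .hap_stats(x, site_filter)
  r2_counts(st$n, st$S, st$pi_total, st$singletons)
}

# internal: evaluate one named statistic on a sim_locus
.sim_statistic <- function(statistic, locus) {
  st <- .seg_stats(locus$haplotypes)
  switch(statistic,
         tajima_d = tajima_d_counts(st$n, st$S, st$pi_total),
         fu_fs = if (st$pi_total > 0)
           suppressWarnings(fu_fs_counts(st$n, st$k_hap, st$pi_total))
         else NA_real_,
         r2 = r2_counts(st$n, st$S, st$pi_total, st$singletons),
         stop("unknown statistic: ", statistic))
}

#' Simulate a fixed-S coalescent null distribution for a statistic
#'
#' @param statistic `"tajima_d"`, `"fu_fs"` or `"r2"`.
#' @param n Sample size (haplotypes).
#' @param s_obs Observed segregating sites to condition on.
#' @param reps Number of simulation replicates.
#' @param seed Optional RNG seed.
#' @param model Demography of the null (default: constant-size panmixia).
#' @return Numeric vector of simulated statistic values (NAs dropped).
#' @export
coalescent_null <- function(statistic, n, s_obs, reps, seed = NULL,
                            model = demography_model()) {
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(reps), function(i) {
    tr <- simulate_tree(n, model)
    .sim_statistic(statistic, drop_fixed_s(tr, s_obs))
  }, numeric(1))
  vals[is.finite(vals)]
}

#' Empirical coalescent p-value for a neutrality statistic
#'
#' Nulls are generated by fixed-S coalescent simulation; tail fractions use
#' the add-one Monte-Carlo correction `(r+1)/(reps+1)` and count ties in both
#' tails.
#'
#' @param observed Observed statistic value (`NA` yields an NA result).
#' @param statistic `"tajima_d"`, `"fu_fs"` or `"r2"`.
#' @param n Sample size.
#' @param s_obs Observed segregating-site count.
#' @param reps Replicates (>= 1000 recommended).
#' @param seed Optional RNG seed.
#' @param model Null demography.
#' @param null_values Optional precomputed null vector (skips simulation).
#' @return A `neutrality_result`: observed, sim_mean, p_low, p_high,
#'   null_values.
#' @export
coalescent_pvalue <- function(observed, statistic, n, s_obs, reps = 10000L,
                              seed = NULL, model = demography_model(),
                              null_values = NULL) {
  if (is.null(null_values))
    null_values <- coalescent_null(statistic, n, s_obs, reps, seed, model)
  res <- list(statistic = statistic, observed = observed,
              null_values = null_values,
              sim_mean = mean(null_values))
  if (is.na(observed)) {
    res$p_low <- NA_real_; res$p_high <- NA_real_
  } else {
    m <- length(null_values)
    res$p_low <- (sum(null_values <= observed) + 1) / (m + 1)
    res$p_high <- (sum(null_values >= observed) + 1) / (m + 1)
  }
  structure(res, class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("<neutrality_result> %s: obs=%.4g sim_mean=%.4g p_low=%.4g p_high=%.4g (%d nulls)\n",
              x$statistic, x$observed, x$sim_mean, x$p_low, x$p_high,
              length(x$null_values)))
  invisible(x)
}

#' Multilocus randomization test for mean Tajima's D
#'
#' The observed value is the mean D over loci with defined D.  Each null
#' replicate re-draws every locus's D from its own fixed-S coalescent null
#' and averages, following the coalescent randomization of the HKA program
#' (literally shuffling locus labels cannot change a mean across loci, so
#' the label-permutation wording in field descriptions is interpreted as
#' this scheme).
#'
#' @param per_locus data.frame with columns `d`, `n`, `s` (one row per
#'   locus); loci with `NA` D (zero segregating sites) are dropped.
#' @param reps Number of null mean-D replicates.
#' @param seed Optional RNG seed.
#' @param model Null demography.
#' @return A `neutrality_result` whose null values are null mean-D draws.
#' @export
multilocus_d_test <- function(per_locus, reps = 10000L, seed = NULL,
                              model = demography_model()) {
  keep <- !is.na(per_locus$d)
  per_locus <- per_locus[keep, , drop = FALSE]
  if (nrow(per_locus) < 2L) stop("need >= 2 loci with defined Tajima's D")
  if (!is.null(seed)) set.seed(seed)
  null_by_locus <- lapply(seq_len(nrow(per_locus)), function(i)
    coalescent_null("tajima_d", per_locus$n[i], per_locus$s[i], reps,
                    seed = NULL, model = model))
  m <- min(lengths(null_by_locus))
  null_means <- rowMeans(do.call(cbind, lapply(null_by_locus, `[`, seq_len(m))))
  coalescent_pvalue(mean(per_locus$d), "tajima_d_multilocus",
                    n = NA, s_obs = NA, null_values = null_means)
}
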