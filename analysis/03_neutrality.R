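#!/usr/bin/env Rscript
# Population-wide neutrality tests: the multilocus randomization test for
# mean Tajima's D, plus Fu's Fs and Ramos-Onsins & Rozas's R2 with
# coalescent p-values conditioned on the observed segregating sites.

suppressPackageStartupMessages(library(ivypopgen))
set.seed(3)

ds <- read_dataset("results/dataset")
alns <- ds$alignments

per_locus <- do.call(rbind, lapply(alns, function(a) {
  st <- ivypopgen:::.hap_stats(a, "silent")
  data.frame(locus = a$locus_id, n = st$n, s = st$S,
             d = tajima_d_counts(st$n, st$S, st$pi_total))
}))
print(per_locus, digits = 3, row.names = FALSE)

ml <- multilocus_d_test(per_locus, reps = 2000)
cat(sprintf("Multilocus mean D = %.3f (null mean %.3f); fraction of null below = %.4f, above = %.4f\n",
            ml$observed, ml$sim_mean, ml$p_low, ml$p_high))

st <- ivypopgen:::.pooled_counts(alns, unique(ds$meta$individual_id))
fs <- fu_fs_counts(st$n, st$k_hap, st$pi_total)
r2 <- r2_counts(st$n, st$S, st$pi_total, st$singletons)
fs_p <- coalescent_pvalue(fs, "fu_fs", st$n, st$S, reps = 2000)
r2_p <- coalescent_pvalue(r2, "r2", st$n, st$S, reps = 2000)
cat(sprintf("Fu's Fs = %.2f (sim mean %.2f, p_low %.4f)\n",
            fs, fs_p$sim_mean, fs_p$p_low))
cat(sprintf("R2 = %.3f (sim mean %.3f, p_low %.4f)\n",
            r2, r2_p$sim_mean, r2_p$p_low))

out <- data.frame(
  statistic = c("multilocus_mean_D", "fu_fs", "r2"),
  observed = c(ml$observed, fs, r2),
  sim_mean = c(ml$sim_mean, fs_p$sim_mean, r2_p$sim_mean),
  p_low = c(ml$p_low, fs_p$p_low, r2_p$p_low),
  p_high = c(ml$p_high, fs_p$p_high, r2_p$p_high))
utils::write.csv(out, "results/neutrality.csv", row.names = FALSE)
cat("Written to results/neutrality.csv\n")
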