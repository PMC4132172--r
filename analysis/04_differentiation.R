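#!/usr/bin/env Rscript
# Hierarchical F-statistics (AMOVA with permutation p-values), the implied
# selfing rate, and isolation-by-distance via Mantel tests of Nei's D,
# pairwise FST, and linearized FST against great-circle distance.

suppressPackageStartupMessages(library(ivypopgen))
set.seed(4)

ds <- read_dataset("results/dataset")
snps <- extract_snps(ds$alignments, ds$meta)

am <- amova(snps, ds$meta, permutations = 999)
print(am)
sr <- selfing_rate_from_fis(max(0, unname(am$f_statistics["FIS"])))
cat(sprintf("Implied equilibrium selfing rate: %.1f%%\n", sr))
utils::write.csv(
  data.frame(component = names(am$variance_components),
             variance = am$variance_components,
             percent = am$percentages),
  "results/amova.csv", row.names = FALSE)

geo <- geographic_distance(ds$meta)
nei <- nei_distance(snps, ds$meta)
pf <- pairwise_fst(snps, ds$meta)
ibd <- list(nei_d = mantel_test(nei, geo, permutations = 9999),
            fst = mantel_test(pf$fst, geo, permutations = 9999),
            lin_fst = mantel_test(pf$lin_fst, geo, permutations = 9999))
for (nm in names(ibd))
  cat(sprintf("IBD %-8s r_xy = %+.3f, p = %.4f\n", nm, ibd[[nm]]$r_xy,
              ibd[[nm]]$p))
utils::write.csv(
  data.frame(matrix_pair = names(ibd),
             r_xy = vapply(ibd, `[[`, numeric(1), "r_xy"),
             p = vapply(ibd, `[[`, numeric(1), "p")),
  "results/ibd_mantel.csv", row.names = FALSE)

write_mat <- function(m, f) utils::write.csv(round(m, 5), f)
write_mat(nei, "results/nei_distance.csv")
write_mat(pf$fst, "results/pairwise_fst.csv")
write_mat(pf$lin_fst, "results/pairwise_linfst.csv")
write_mat(geo, "results/geographic_km.csv")
cat("Distance matrices written under results/\n")
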