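# Pipeline orchestration ------------------------------------------------------
#
# Runs the full analysis over a dataset (real or synthetic) and assembles a
# report mirroring the original study's tables: a per-population summary
# (leaf allele frequencies, diversity, Tajima's D with its simulated null),
# global statistics, isolation-by-distance, the per-SNP FST block with the
# leaf-locus contrast, clustering, and the auxiliary group comparisons.

#' Kruskal-Wallis comparison of a statistic between groups
#'
#' @param values Numeric vector (e.g. per-population diversity).
#' @param groups Group labels, same length.
#' @return List: `H`, `df`, `p` (H = 0, p = 1 when all values are tied).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Regress per-population diversity on geographic location
#'
#' Ordinary least squares of a diversity index on latitude and (separately)
#' longitude, plus the latitude-longitude correlation, which explains why
#' the two predictors tend to agree.
#'
#' @param div Per-population data.frame with `population_id` and the
#'   response column.
#' @param meta Population table (coordinates per population).
#' @param response Column of `div` to regress (default `"theta_pi"`).
#' @return data.frame with one row per predictor: slope, r2, F, p; plus the
#'   lat-lon correlation r2 as an attribute.
#' @export
diversity_geography_regression <- function(div, meta, response = "theta_pi") {
  if (nrow(div) < 3L) stop("need >= 3 populations")
  coords <- unique(meta[, c("population_id", "latitude", "longitude")])
  d <- merge(div, coords, by = "population_id")
  out <- do.call(rbind, lapply(c("latitude", "longitude"), function(pred) {
    if (stats::sd(d[[pred]]) == 0) stop("constant predictor: ", pred)
    fit <- stats::lm(d[[response]] ~ d[[pred]])
    sm <- summary(fit)
    fstat <- sm$fstatistic
    data.frame(predictor = pred, slope = stats::coef(fit)[2L],
               r2 = sm$r.squared, F = unname(fstat[1L]),
               p = stats::pf(fstat[1L], fstat[2L], fstat[3L],
                             lower.tail = FALSE),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "latlon_r2") <- stats::cor(d$latitude, d$longitude)^2
  out
}

#' Run the full analysis pipeline
#'
#' Executes io -> diversity -> neutrality -> differentiation -> clustering
#' -> leaf shape in order; any block that fails is recorded in the error
#' manifest and the remaining blocks still run.
#'
#' @param dataset List with `alignments` (classified), `meta`, and optionally
#'   `progeny` — e.g. from [generate_dataset()] or [read_dataset()].
#' @param boundary_lat Clinal boundary latitude for north/south grouping;
#'   required (the boundary comes from prior work, never a silent default).
#' @param sim_reps Coalescent replicates for neutrality nulls.
#' @param permutations Permutations for F-statistic and Mantel p-values.
#' @param k_range Cluster counts to fit (`NULL` skips clustering).
#' @param cluster_iterations,cluster_burn_in MCMC settings per K.
#' @param seed RNG seed governing every stochastic step.
#' @return An `analysis_report` list of blocks (table1, global, ibd,
#'   snp_fst, leaf, clustering, group_tests, settings, errors).
#' @export
run_pipeline <- function(dataset, boundary_lat, sim_reps = 1000L,
                         permutations = 999L, k_range = NULL,
                         cluster_iterations = 2000L, cluster_burn_in = 500L,
                         seed = 1L) {
  set.seed(seed)
  alns <- dataset$alignments
  meta <- assign_region(dataset$meta, boundary_lat)
  report <- list(settings = list(boundary_lat = boundary_lat,
                                 sim_reps = sim_reps,
                                 permutations = permutations,
                                 k_range = k_range, seed = seed),
                 errors = list())
  run_block <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      report$errors[[name]] <<- conditionMessage(res)
      NULL
    } else res
  }

  snps <- run_block("io", extract_snps(alns, meta))

  report$table1 <- run_block("diversity", {
    div <- population_diversity(alns, meta)
    leaf <- leaf_allele_frequencies(meta)
    tab <- merge(leaf[, c("population_id", "freq_L", "freq_l")], div,
                 by = "population_id")
    # per-population Tajima's D with its fixed-S coalescent null
    dcols <- do.call(rbind, lapply(tab$population_id, function(p) {
      ids <- meta$individual_id[meta$population_id == p]
      st <- .pooled_counts(alns, ids)
      d <- tajima_d_counts(st$n, st$S, st$pi_total)
      if (is.na(d) || st$S == 0L)
        return(data.frame(tajima_d = d, sim_d = NA_real_,
                          pct_low = NA_real_, pct_high = NA_real_))
      pv <- coalescent_pvalue(d, "tajima_d", st$n, st$S, reps = sim_reps)
      data.frame(tajima_d = d, sim_d = pv$sim_mean,
                 pct_low = 100 * pv$p_low, pct_high = 100 * pv$p_high)
    }))
    cbind(tab, dcols)
  })

  report$global <- run_block("neutrality", {
    pool <- pooled_diversity(alns)
    st <- .pooled_counts(alns, unique(meta$individual_id))
    d_global <- tajima_d_counts(st$n, st$S, st$pi_total)
    per_locus <- do.call(rbind, lapply(alns, function(a) {
      s <- .hap_stats(a, "silent")
      data.frame(locus = a$locus_id, n = s$n, s = s$S,
                 d = tajima_d_counts(s$n, s$S, s$pi_total))
    }))
    ml <- multilocus_d_test(per_locus, reps = sim_reps)
    fs <- fu_fs_counts(st$n, st$k_hap, st$pi_total)
    r2 <- r2_counts(st$n, st$S, st$pi_total, st$singletons)
    fs_p <- coalescent_pvalue(fs, "fu_fs", st$n, st$S, reps = sim_reps)
    r2_p <- coalescent_pvalue(r2, "r2", st$n, st$S, reps = sim_reps)
    list(theta_w = pool$theta_w, theta_pi = pool$theta_pi,
         diffs_per_kb = per_kb_differences(pool$theta_pi),
         tajima_d_global = d_global, per_locus_d = per_locus,
         multilocus_d = ml, fu_fs = fs_p, r2 = r2_p)
  })

  report$fstats <- run_block("differentiation", {
    am <- amova(snps, meta, permutations = permutations)
    fis <- unname(am$f_statistics["FIS"])
    list(amova = am,
         selfing_rate_pct = selfing_rate_from_fis(max(fis, 0)))
  })

  report$ibd <- run_block("ibd", {
    geo <- geographic_distance(meta)
    nei <- nei_distance(snps, meta)
    pf <- pairwise_fst(snps, meta)
    list(nei = mantel_test(nei, geo, permutations = permutations),
         fst = mantel_test(pf$fst, geo, permutations = permutations),
         lin_fst = mantel_test(pf$lin_fst, geo, permutations = permutations))
  })

  report$snp_fst <- run_block("snp_fst", {
    dist <- snp_fst_distribution(snps, meta, permutations = permutations)
    ld <- ld_r2_matrix(snps)
    pruned <- if (all(ld$ld_flags)) NULL else
      prune_ld_and_recompute(dist, ld$ld_flags)
    list(distribution = dist, ld_flags = ld$ld_flags, pruned = pruned,
         prop_significant = mean(dist$p <= 0.05, na.rm = TRUE))
  })

  report$leaf <- run_block("leafshape", {
    leaf_locus_fst(meta, snp_fst = report$snp_fst$distribution$fst)
  })

  if (!is.null(k_range)) {
    report$clustering <- run_block("clustering", {
      models <- lapply(k_range, function(k)
        fit_clusters(snps, k, iterations = cluster_iterations,
                     burn_in = cluster_burn_in))
      sel <- if (length(models) >= 2L) choose_k(models) else NULL
      list(models = models, selection = sel,
           pcoa = pcoa(genotype_distance(snps)))
    })
  }

  report$group_tests <- run_block("group_tests", {
    div <- report$table1
    kw_region <- kruskal_wallis(div$theta_pi,
                                .pop_region(meta)[div$population_id])
    reg <- diversity_geography_regression(div, meta)
    list(kw_region = kw_region, regression = reg)
  })

  structure(report, class = "analysis_report")
}

# pooled silent-site counts for a set of individuals, concatenating the
# silent columns of all loci (within-individual phase across loci is
# arbitrary but consistent, which is all the haplotype-count statistics need)
.pooled_counts <- function(alns, individuals) {
  mats <- lapply(alns, function(a) {
    a2 <- subset_alignment(a, individuals)
    ord <- order(a2$hap_individual)
    .silent_matrix(a2)$mat[ord, , drop = FALSE]
  })
  .seg_stats(do.call(cbind, mats))
}

.pop_region <- function(meta) {
  r <- meta$region[!duplicated(meta$population_id)]
  stats::setNames(r, meta$population_id[!duplicated(meta$population_id)])
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  if (!is.null(x$global))
    cat(sprintf("  global: theta_w=%.5f theta_pi=%.5f (%.2f diffs/kb), multilocus D=%.2f\n",
                x$global$theta_w, x$global$theta_pi, x$global$diffs_per_kb,
                x$global$multilocus_d$observed))
  if (!is.null(x$fstats))
    cat(sprintf("  FST=%.3f FIS=%.3f SR=%.1f%%\n",
                x$fstats$amova$f_statistics["FST"],
                x$fstats$amova$f_statistics["FIS"],
                x$fstats$selfing_rate_pct))
  if (!is.null(x$leaf) && !is.null(x$leaf$percentile_in_background))
    cat(sprintf("  leaf locus FST=%.3f (%.0fth percentile of SNPs)\n",
                x$leaf$leaf_fst, x$leaf$percentile_in_background))
  if (length(x$errors))
    cat("  errors in blocks:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write the per-population summary table as CSV
#'
#' @param report An `analysis_report`.
#' @param path Output CSV.
#' @export
write_table1 <- function(report, path) {
  utils::write.csv(report$table1, path, row.names = FALSE)
  invisible(path)
}
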