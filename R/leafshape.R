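# Leaf-shape locus ------------------------------------------------------------
#
# Leaf shape is governed by one biallelic codominant locus: lobed (LL),
# heterozygote (Ll), entire (ll).  Maternal genotypes are inferred from the
# segregation of leaf shapes among selfed progeny arrays, and differentiation
# at the locus is contrasted with the per-SNP FST background.

.selfed_progeny_probs <- function(genotype, s = 1, pollen_L = 0.5) {
  # phenotype order: (lobed, het, entire)
  selfed <- switch(genotype,
                   LL = c(1, 0, 0),
                   Ll = c(0.25, 0.5, 0.25),
                   ll = c(0, 0, 1))
  if (s >= 1) return(selfed)
  outc <- switch(genotype,
                 LL = c(pollen_L, 1 - pollen_L, 0),
                 Ll = c(pollen_L / 2, 0.5, (1 - pollen_L) / 2),
                 ll = c(0, pollen_L, 1 - pollen_L))
  s * selfed + (1 - s) * outc
}

#' Infer a maternal leaf-shape genotype from a progeny array
#'
#' Maximum-likelihood genotype under multinomial segregation of selfed
#' progeny: LL -> all lobed, ll -> all entire, Ll -> (1/4, 1/2, 1/4).
#' Pure selfing is the default; with `selfing < 1` the outcross pollen pool
#' enters through a nuisance L-allele frequency.  Ties break toward Ll, the
#' only genotype compatible with mixed progeny classes.
#'
#' @param counts Integer vector `(n_lobed, n_het, n_entire)` with positive
#'   total.
#' @param selfing Assumed selfing rate of the maternal line (default 1).
#' @param pollen_L Outcross pollen L-allele frequency (used when
#'   `selfing < 1`).
#' @return List: `genotype` (`"LL"`, `"Ll"` or `"ll"`), `loglik` (named
#'   log-likelihood triple).
#' @export
infer_maternal_genotype <- function(counts, selfing = 1, pollen_L = 0.5) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0L))
  if (sum(counts) == 0L) stop("empty progeny array")
  gts <- c("LL", "Ll", "ll")
  ll <- vapply(gts, function(g) {
    pr <- .selfed_progeny_probs(g, selfing, pollen_L)
    if (any(pr == 0 & counts > 0)) -Inf else
      sum(counts[pr > 0] * log(pr[pr > 0]))
  }, numeric(1))
  best <- which(ll == max(ll))
  genotype <- if (length(best) > 1L && 2L %in% best) "Ll" else gts[best[1L]]
  list(genotype = genotype, loglik = ll)
}

#' Simulate a selfed progeny array for a maternal genotype
#'
#' @param genotype `"LL"`, `"Ll"` or `"ll"`.
#' @param n_progeny Scored family size (default 10).
#' @param seed Optional RNG seed.
#' @return Integer triple `(n_lobed, n_het, n_entire)`.
#' @export
simulate_progeny_array <- function(genotype, n_progeny = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.integer(stats::rmultinom(1L, n_progeny,
                              .selfed_progeny_probs(genotype))[, 1L])
}

#' Per-population leaf-shape allele frequencies
#'
#' Frequency of L is `(2*n_LL + n_Ll) / (2*n_genotyped)`; individuals with
#' unknown genotype are excluded.
#'
#' @param meta Population table with a `leaf_genotype` column.
#' @return data.frame: population_id, n_genotyped, freq_L, freq_l (`NA` rows
#'   for populations with no genotyped individuals).
#' @export
leaf_allele_frequencies <- function(meta) {
  pops <- unique(meta$population_id)
  do.call(rbind, lapply(pops, function(p) {
    g <- meta$leaf_genotype[meta$population_id == p]
    g <- g[g %in% c("LL", "Ll", "ll")]
    n <- length(g)
    fL <- if (n == 0L) NA_real_ else
      (2 * sum(g == "LL") + sum(g == "Ll")) / (2 * n)
    data.frame(population_id = p, n_genotyped = n,
               freq_L = fL, freq_l = if (n == 0L) NA_real_ else 1 - fL,
               stringsAsFactors = FALSE)
  }))
}

# leaf genotypes as an L-allele dosage snp_matrix (one pseudo-SNP)
.leaf_snp_matrix <- function(meta) {
  dos <- c(LL = 2L, Ll = 1L, ll = 0L)[meta$leaf_genotype]
  geno <- matrix(unname(dos), ncol = 1L,
                 dimnames = list(meta$individual_id, "leaf_shape"))
  structure(list(genotypes = geno,
                 snp_info = data.frame(snp_id = "leaf_shape",
                                       locus_id = "leaf_shape", column = 0L,
                                       minor = "l", major = "L",
                                       stringsAsFactors = FALSE),
                 individuals = meta$individual_id),
            class = "snp_matrix")
}

#' Differentiation at the leaf-shape locus
#'
#' Applies the same Weir-Cockerham estimator used for sequence SNPs to an
#' L-allele dosage recoding of the leaf genotypes, and (optionally)
#' positions the locus within a per-SNP FST background.
#'
#' @param meta Population table with leaf genotypes (>= 2 populations
#'   genotyped).
#' @param snp_fst Optional numeric vector of background per-SNP FST values.
#' @return A `leaf_locus_summary`: `allele_freqs` (per population),
#'   `leaf_fst`, `variance_percentages` (among populations / among
#'   individuals / within individuals), and — when a background is supplied —
#'   `fold_vs_background` and `percentile_in_background`.
#' @export
leaf_locus_fst <- function(meta, snp_fst = NULL) {
  known <- meta[meta$leaf_genotype %in% c("LL", "Ll", "ll"), , drop = FALSE]
  if (length(unique(known$population_id)) < 2L)
    stop("need >= 2 populations with leaf genotypes")
  snps <- .leaf_snp_matrix(known)
  comp <- .wc_components(snps$genotypes, known$population_id)
  if (comp$monomorphic)
    return(structure(list(allele_freqs = leaf_allele_frequencies(meta),
                          leaf_fst = NA_real_), class = "leaf_locus_summary"))
  f <- .f_from_components(comp)
  vt <- pmax(c(f$A, f$B, f$C), 0)
  out <- list(allele_freqs = leaf_allele_frequencies(meta),
              leaf_fst = f$fst,
              f_statistics = c(FST = f$fst, FIS = f$fis, FIT = f$fit),
              variance_percentages = stats::setNames(
                100 * vt / sum(vt),
                c("among_populations", "among_individuals_within",
                  "within_individuals")))
  if (!is.null(snp_fst)) {
    bg <- snp_fst[!is.na(snp_fst)]
    out$fold_vs_background <- f$fst / mean(bg)
    out$percentile_in_background <- outlier_percentile(bg, f$fst)
  }
  structure(out, class = "leaf_locus_summary")
}

#' @export
print.leaf_locus_summary <- function(x, ...) {
  cat(sprintf("<leaf_locus_summary> FST=%.3f", x$leaf_fst))
  if (!is.null(x$percentile_in_background))
    cat(sprintf(" (%.0fth percentile of SNP background, %.1fx mean)",
                x$percentile_in_background, x$fold_vs_background))
  cat("\n")
  invisible(x)
}

#' Read progeny-array counts from CSV
#'
#' Columns: `maternal_id, n_lobed, n_het, n_entire`.
#' @param path CSV file.
#' @export
read_progeny_arrays <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("maternal_id", "n_lobed", "n_het", "n_entire")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("progeny table missing columns: ",
                         paste(miss, collapse = ", "))
  tab
}
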