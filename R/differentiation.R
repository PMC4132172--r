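# Hierarchical F-statistics and differentiation ------------------------------
#
# Weir & Cockerham (1984) variance components (a: among populations, b:
# among individuals within populations, c: within individuals) are used for
# the global AMOVA-style partition, the per-SNP FST distribution, and the
# pairwise population FST entering isolation-by-distance tests, so a single
# estimator family backs every differentiation number in the pipeline.

# per-SNP W&C components: genotypes = ind x SNP dosage matrix (0/1/2, NA ok)
.wc_components <- function(genotypes, pop) {
  pop <- factor(pop)
  G <- as.matrix(genotypes)
  notna <- !is.na(G)
  G0 <- ifelse(notna, G, 0)
  n_mat <- rowsum(notna + 0, pop)                  # pops x S sample sizes
  sum_g <- rowsum(G0, pop)
  het <- rowsum(ifelse(notna, (G == 1) + 0, 0), pop)
  p_mat <- sum_g / (2 * n_mat)
  p_mat[n_mat == 0] <- 0
  r <- colSums(n_mat > 0)
  n_tot <- colSums(n_mat)
  nbar <- n_tot / r
  nc <- (n_tot - colSums(n_mat^2) / n_tot) / (r - 1)
  pbar <- colSums(n_mat * p_mat) / n_tot
  s2 <- colSums(n_mat * sweep(p_mat, 2L, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(het) / n_tot
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  mono <- pbar <= 0 | pbar >= 1
  list(a = a, b = b, c = cc, monomorphic = mono)
}

#' Per-SNP Weir & Cockerham FST
#'
#' @param snps A `snp_matrix`.
#' @param meta Population table (row order defines individuals).
#' @return Numeric vector of theta-hat per SNP (`NA` for SNPs monomorphic in
#'   the pooled sample).
#' @export
weir_cockerham_fst <- function(snps, meta) {
  comp <- .wc_components(snps$genotypes[meta$individual_id, , drop = FALSE],
                         meta$population_id)
  denom <- comp$a + comp$b + comp$c
  fst <- comp$a / denom
  fst[comp$monomorphic | denom == 0] <- NA_real_
  stats::setNames(fst, colnames(snps$genotypes))
}

# multilocus F statistics from summed components
.f_from_components <- function(comp) {
  keep <- !comp$monomorphic
  A <- sum(comp$a[keep]); B <- sum(comp$b[keep]); C <- sum(comp$c[keep])
  list(A = A, B = B, C = C,
       fst = A / (A + B + C),
       fis = 1 - C / (B + C),
       fit = 1 - C / (A + B + C))
}

# permute allele pairing within individuals within populations (FIS null)
.permute_alleles_within <- function(G, pop) {
  a1 <- pmin(G, 1L); a2 <- pmax(G - 1L, 0L)
  out <- G
  for (p in unique(pop)) {
    rows <- which(pop == p)
    A <- rbind(a1[rows, , drop = FALSE], a2[rows, , drop = FALSE])
    perm <- sample.int(nrow(A))
    half <- length(rows)
    out[rows, ] <- A[perm[seq_len(half)], , drop = FALSE] +
      A[perm[half + seq_len(half)], , drop = FALSE]
  }
  out
}

#' Three-level AMOVA with permutation significance
#'
#' Partitions molecular variance among populations, among individuals within
#' populations, and within individuals, using summed Weir-Cockerham
#' components across SNPs.  Negative variance components are truncated to
#' zero before percentages are computed (Excoffier convention).  FST
#' significance permutes individuals among populations; FIS significance
#' permutes allele pairing within individuals within populations.
#'
#' @param snps A `snp_matrix`.
#' @param meta Population table (>= 2 populations with >= 2 individuals;
#'   singleton populations are excluded with a warning).
#' @param permutations Number of permutations for each p-value.
#' @param seed Optional RNG seed.
#' @return An `amova_result`: `variance_components`, `percentages` (sum to
#'   100), `f_statistics` (FST, FIS, FIT), `p_values`.
#' @export
amova <- function(snps, meta, permutations = 999L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- table(meta$population_id)
  if (any(sizes < 2L)) {
    warning("excluding population(s) of size 1: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
    meta <- meta[meta$population_id %in% names(sizes)[sizes >= 2L], ,
                 drop = FALSE]
  }
  if (length(unique(meta$population_id)) < 2L)
    stop("need >= 2 populations with >= 2 individuals")
  G <- snps$genotypes[meta$individual_id, , drop = FALSE]
  pop <- meta$population_id

  obs <- .f_from_components(.wc_components(G, pop))
  vc <- c(among_populations = obs$A,
          among_individuals_within = obs$B,
          within_individuals = obs$C)
  vt <- pmax(vc, 0)
  pct <- 100 * vt / sum(vt)

  fst_null <- fis_null <- numeric(permutations)
  for (i in seq_len(permutations)) {
    f1 <- .f_from_components(.wc_components(G, sample(pop)))
    fst_null[i] <- f1$fst
    f2 <- .f_from_components(.wc_components(.permute_alleles_within(G, pop),
                                            pop))
    fis_null[i] <- f2$fis
  }
  p_fst <- (sum(fst_null >= obs$fst, na.rm = TRUE) + 1) / (permutations + 1)
  p_fis <- (sum(fis_null >= obs$fis, na.rm = TRUE) + 1) / (permutations + 1)

  structure(list(
    variance_components = vc,
    percentages = pct,
    f_statistics = c(FST = obs$fst, FIS = obs$fis, FIT = obs$fit),
    p_values = c(FST = p_fst, FIS = p_fis)),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  cat(sprintf("  among populations:            %5.1f%%\n", x$percentages[1L]))
  cat(sprintf("  among individuals within:     %5.1f%%\n", x$percentages[2L]))
  cat(sprintf("  within individuals:           %5.1f%%\n", x$percentages[3L]))
  cat(sprintf("  FST=%.3f (p=%.4g)  FIS=%.3f (p=%.4g)  FIT=%.3f\n",
              x$f_statistics["FST"], x$p_values["FST"],
              x$f_statistics["FIS"], x$p_values["FIS"],
              x$f_statistics["FIT"]))
  invisible(x)
}

# per-population allele frequency matrix (pops x SNPs), minor-allele freq
.pop_allele_freqs <- function(snps, meta) {
  G <- snps$genotypes[meta$individual_id, , drop = FALSE]
  pop <- factor(meta$population_id)
  notna <- !is.na(G)
  n_mat <- rowsum(notna + 0, pop)
  p <- rowsum(ifelse(notna, G, 0), pop) / (2 * n_mat)
  p
}

#' Nei's (1972) standard genetic distance between populations
#'
#' `D = -ln(Jxy / sqrt(Jx * Jy))` with identities averaged over loci.
#'
#' @param snps A `snp_matrix`.
#' @param meta Population table.
#' @return Symmetric population matrix (`Inf` sentinel when two populations
#'   share no alleles anywhere).
#' @export
nei_distance <- function(snps, meta) {
  p <- .pop_allele_freqs(snps, meta)
  q <- 1 - p
  pops <- rownames(p)
  k <- length(pops)
  D <- matrix(0, k, k, dimnames = list(pops, pops))
  J_self <- rowMeans(p^2 + q^2)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    Jxy <- mean(p[i, ] * p[j, ] + q[i, ] * q[j, ])
    D[i, j] <- D[j, i] <- if (Jxy <= 0) Inf else
      -log(Jxy / sqrt(J_self[i] * J_self[j]))
  }
  D
}

#' Pairwise population FST and its linearization
#'
#' Multilocus Weir-Cockerham FST for every population pair, plus the
#' linearized transform `FST/(1-FST)` expected to scale with distance under
#' isolation-by-distance.
#'
#' @param snps A `snp_matrix`.
#' @param meta Population table.
#' @return List of two symmetric matrices: `fst` and `lin_fst`.  Negative
#'   pairwise estimates are kept in `fst` (they are informative about
#'   sampling noise) but floored at 0 in `lin_fst`.
#' @export
pairwise_fst <- function(snps, meta) {
  pops <- unique(meta$population_id)
  k <- length(pops)
  M <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sub <- meta[meta$population_id %in% pops[c(i, j)], , drop = FALSE]
    f <- .f_from_components(
      .wc_components(snps$genotypes[sub$individual_id, , drop = FALSE],
                     sub$population_id))$fst
    M[i, j] <- M[j, i] <- if (is.finite(f)) f else 0
  }
  list(fst = M, lin_fst = pmax(M, 0) / (1 - pmax(M, 0)))
}

#' Great-circle distances between populations
#'
#' Haversine distance on raw latitude/longitude with Earth radius 6371 km.
#'
#' @param meta Population table with one coordinate pair per population.
#' @return Symmetric matrix of distances in kilometers.
#' @export
geographic_distance <- function(meta) {
  pops <- unique(meta$population_id)
  coords <- t(vapply(pops, function(p) {
    rows <- meta[meta$population_id == p, , drop = FALSE]
    c(rows$longitude[1L], rows$latitude[1L])
  }, numeric(2)))
  if (anyNA(coords)) {
    bad <- pops[apply(is.na(coords), 1L, any)]
    stop("missing coordinates for population(s): ", paste(bad, collapse = ", "))
  }
  d <- geosphere::distm(coords,
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(d) <- list(pops, pops)
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over corresponding off-diagonal entries, with
#' significance from joint row/column permutations of one matrix (one-tailed
#' upper by default, as in GenAlEx).
#'
#' @param mat_a,mat_b Symmetric matrices of the same dimension.
#' @param permutations Number of permutations (paper default 9999).
#' @param seed Optional RNG seed.
#' @param tail `"upper"` (default) or `"two"`.
#' @return List with `r_xy` and `p`.
#' @export
mantel_test <- function(mat_a, mat_b, permutations = 9999L, seed = NULL,
                        tail = c("upper", "two")) {
  tail <- match.arg(tail)
  stopifnot(all(dim(mat_a) == dim(mat_b)))
  if (stats::sd(mat_a[lower.tri(mat_a)]) == 0 ||
      stats::sd(mat_b[lower.tri(mat_b)]) == 0)
    stop("undefined correlation: constant distance matrix")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(mat_a), stats::as.dist(mat_b),
                       method = "pearson", permutations = permutations)
  p <- fit$signif
  if (tail == "two") {
    lo <- (sum(fit$perm <= fit$statistic) + 1) / (length(fit$perm) + 1)
    p <- min(1, 2 * min(p, lo))
  }
  list(r_xy = unname(fit$statistic), p = p)
}

#' Equilibrium selfing rate from the inbreeding coefficient
#'
#' `SR = 2*FIS/(1+FIS) * 100`, the percent selfing implied by FIS at
#' inbreeding equilibrium.
#'
#' @param fis Inbreeding coefficient in `[0,1]`; negative values (outbreeding
#'   excess) are clamped to 0 with a warning.
#' @return Selfing rate in percent.
#' @export
selfing_rate_from_fis <- function(fis) {
  if (any(fis < 0)) {
    warning("negative FIS implies outbreeding excess; clamped to 0")
    fis <- pmax(fis, 0)
  }
  if (any(fis > 1)) stop("FIS cannot exceed 1")
  200 * fis / (1 + fis)
}

#' Pairwise LD between SNPs as squared dosage correlation
#'
#' Composite-genotype r^2 (squared Pearson correlation of 0/1/2 dosage
#' vectors), which needs no phase assumption and converges to gametic r^2
#' under strong inbreeding.  Significance uses the chi-square approximation
#' `n * r^2 ~ chi2(1)`.
#'
#' @param snps A `snp_matrix` with >= 2 SNPs.
#' @param alpha Significance level for flagging (default 0.05).
#' @return List: `r2` matrix, `significant` logical matrix, and per-SNP
#'   `ld_flags` (`TRUE` if the SNP is in significant LD with any other).
#' @export
ld_r2_matrix <- function(snps, alpha = 0.05) {
  G <- snps$genotypes
  if (ncol(G) < 2L) stop("need >= 2 SNPs")
  r <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))
  r2 <- r^2
  n_pair <- crossprod(!is.na(G))
  chi <- n_pair * r2
  sig <- chi > stats::qchisq(1 - alpha, df = 1)
  sig[is.na(sig)] <- FALSE
  diag(sig) <- FALSE
  diag(r2) <- NA_real_
  list(r2 = r2, significant = sig, ld_flags = apply(sig, 1L, any))
}

#' Per-SNP FST distribution with permutation p-values
#'
#' @param snps A `snp_matrix`.
#' @param meta Population table.
#' @param permutations Permutations of individuals among populations.
#' @param seed Optional RNG seed.
#' @return A `snp_fst_distribution`: data.frame (snp_id, fst, p) plus the
#'   underlying matrix attributes.
#' @export
snp_fst_distribution <- function(snps, meta, permutations = 999L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- weir_cockerham_fst(snps, meta)
  ge <- rep(0L, length(obs))
  G <- snps$genotypes[meta$individual_id, , drop = FALSE]
  for (i in seq_len(permutations)) {
    comp <- .wc_components(G, sample(meta$population_id))
    f <- comp$a / (comp$a + comp$b + comp$c)
    ge <- ge + (!is.na(f) & !is.na(obs) & f >= obs)
  }
  p <- (ge + 1) / (permutations + 1)
  p[is.na(obs)] <- NA_real_
  structure(data.frame(snp_id = names(obs), fst = unname(obs), p = unname(p),
                       stringsAsFactors = FALSE),
            class = c("snp_fst_distribution", "data.frame"))
}

#' Restrict an FST distribution to SNPs free of significant LD
#'
#' Removes every SNP flagged as being in significant LD with any other SNP
#' and returns the restricted distribution; the input is left intact.
#'
#' @param dist A `snp_fst_distribution`.
#' @param ld_flags Logical vector (per SNP) from [ld_r2_matrix()].
#' @export
prune_ld_and_recompute <- function(dist, ld_flags) {
  stopifnot(length(ld_flags) == nrow(dist))
  if (all(ld_flags)) stop("all SNPs pruned: every SNP is in significant LD")
  out <- dist[!ld_flags, , drop = FALSE]
  class(out) <- class(dist)
  out
}

#' Percentile of a focal FST within a SNP background distribution
#'
#' @param per_snp_fst Numeric vector of background per-SNP FST values
#'   (>= 10 non-missing values required).
#' @param focal_fst Focal value (e.g. the leaf-shape locus FST).
#' @return Percent of background values strictly below the focal value.
#' @export
outlier_percentile <- function(per_snp_fst, focal_fst) {
  v <- per_snp_fst[!is.na(per_snp_fst)]
  if (length(v) == 0L) stop("empty FST distribution")
  if (length(v) < 10L) stop("need >= 10 background FST values")
  100 * mean(v < focal_fst)
}
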