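# Silent-site nucleotide diversity ------------------------------------------
#
# All diversity statistics are computed on silent sites only (synonymous +
# noncoding), matching the convention of the original analysis.  Per-site
# values divide by an effective silent length: noncoding columns count 1 and
# CDS columns count their fractional Nei-Gojobori degeneracy, so monomorphic
# coding positions still contribute to the denominator.

# internal: matrix of usable silent columns + their silent length
.silent_matrix <- function(aln, site_filter = c("silent", "all")) {
  site_filter <- match.arg(site_filter)
  keep <- if (site_filter == "silent")
    aln$site_class %in% c("silent_noncoding", "synonymous")
  else aln$site_class != "excluded"
  list(mat = aln$seqs[, keep, drop = FALSE],
       length = sum(aln$silent_weight[keep]))
}

# internal: segregating-site summaries on a column matrix.
# Multiallelic columns are excluded everywhere (default policy; the source
# chromatographs were hand-edited to clean biallelic calls).
# Works for character alignments and for 0/1 simulated haplotypes.
.seg_stats <- function(mat) {
  n <- nrow(mat)
  if (ncol(mat) == 0L)
    return(list(n = n, S = 0L, pi_total = 0,
                singletons = rep(0L, n), k_hap = 1L))
  n_states <- apply(mat, 2L, function(col) length(unique(col)))
  usable <- n_states <= 2L
  mat <- mat[, usable, drop = FALSE]
  seg <- apply(mat, 2L, function(col) length(unique(col)) == 2L)
  segmat <- mat[, seg, drop = FALSE]
  S <- ncol(segmat)
  if (S == 0L)
    return(list(n = n, S = 0L, pi_total = 0,
                singletons = rep(0L, n), k_hap = .count_haplotypes(mat)))
  # minor-allele counts per segregating column
  minor_count <- integer(S)
  is_minor <- matrix(FALSE, n, S)
  for (j in seq_len(S)) {
    col <- segmat[, j]
    tab <- sort(table(col))
    minor_state <- names(tab)[1L]          # ties resolve alphabetically
    minor_count[j] <- tab[[1L]]
    is_minor[, j] <- col == minor_state
  }
  pi_total <- sum(minor_count * (n - minor_count)) / choose(n, 2)
  singles <- minor_count == 1L
  singletons <- if (any(singles))
    rowSums(is_minor[, singles, drop = FALSE]) else rep(0L, n)
  list(n = n, S = S, pi_total = pi_total,
       singletons = as.integer(singletons), k_hap = .count_haplotypes(mat))
}

.count_haplotypes <- function(mat) {
  if (ncol(mat) == 0L) return(1L)
  length(unique(apply(mat, 1L, paste, collapse = "")))
}

# internal: dispatch alignment / sim_locus / bare matrix to .seg_stats
.hap_stats <- function(x, site_filter = "silent") {
  if (inherits(x, "hap_alignment")) {
    sm <- .silent_matrix(x, site_filter)
    st <- .seg_stats(sm$mat)
    st$silent_length <- sm$length
    st
  } else if (inherits(x, "sim_locus")) {
    st <- .seg_stats(x$haplotypes)
    st$silent_length <- NA_real_
    st
  } else if (is.matrix(x)) {
    st <- .seg_stats(x)
    st$silent_length <- NA_real_
    st
  } else stop("unsupported input of class ", paste(class(x), collapse = "/"))
}

#' Restrict an alignment to a subset of individuals
#' @param aln A `hap_alignment`.
#' @param individuals Character vector of individual IDs to keep.
#' @export
subset_alignment <- function(aln, individuals) {
  keep <- aln$hap_individual %in% individuals
  if (!any(keep)) stop("no haplotypes left after subsetting")
  hap_alignment(aln$locus_id, aln$seqs[keep, , drop = FALSE],
                aln$hap_individual[keep], aln$site_class, aln$silent_weight)
}

#' Watterson's theta per silent site
#'
#' `theta_W = S / (a1 * L_silent)` with `a1 = sum_{i=1}^{n-1} 1/i`, `S` the
#' number of segregating silent sites and `L_silent` the effective silent
#' length.
#'
#' @param aln A classified `hap_alignment` (>= 2 haplotypes).
#' @param site_filter `"silent"` (default) or `"all"` usable sites.
#' @return Per-site estimate (0 when monomorphic; `NA` with a warning when
#'   the silent length is zero).
#' @export
watterson_theta <- function(aln, site_filter = "silent") {
  st <- .hap_stats(aln, site_filter)
  if (st$n < 2L) stop("need at least 2 haplotypes")
  if (is.na(st$silent_length) || st$silent_length <= 0) {
    warning("undefined estimate: zero silent length")
    return(NA_real_)
  }
  st$S / (harmonic_a1(st$n) * st$silent_length)
}

#' Pairwise nucleotide diversity per silent site
#'
#' Mean count of silent differences over all haplotype pairs, divided by the
#' effective silent length.
#'
#' @inheritParams watterson_theta
#' @export
pairwise_theta <- function(aln, site_filter = "silent") {
  st <- .hap_stats(aln, site_filter)
  if (st$n < 2L) stop("need at least 2 haplotypes")
  if (is.na(st$silent_length) || st$silent_length <= 0) {
    warning("undefined estimate: zero silent length")
    return(NA_real_)
  }
  st$pi_total / st$silent_length
}

#' Per-locus diversity summary
#'
#' @param aln A classified `hap_alignment`.
#' @param individuals Optional subset of individual IDs (e.g. one population).
#' @return One-row data.frame: locus, n_haplotypes, s_silent, theta_w,
#'   theta_pi, silent_length.
#' @export
diversity_estimate <- function(aln, individuals = NULL) {
  if (!is.null(individuals)) aln <- subset_alignment(aln, individuals)
  st <- .hap_stats(aln, "silent")
  tw <- if (st$silent_length > 0) st$S / (harmonic_a1(st$n) * st$silent_length)
        else NA_real_
  tp <- if (st$silent_length > 0) st$pi_total / st$silent_length else NA_real_
  data.frame(locus = aln$locus_id, n_haplotypes = st$n, s_silent = st$S,
             theta_w = tw, theta_pi = tp, silent_length = st$silent_length,
             stringsAsFactors = FALSE)
}

#' Length-weighted multilocus average of diversity estimates
#'
#' @param estimates data.frame as returned by rbinding [diversity_estimate()]
#'   rows (one per locus).
#' @return One-row data.frame with summed S, length-weighted theta_w and
#'   theta_pi, and total silent length.
#' @export
multilocus_average <- function(estimates) {
  if (nrow(estimates) == 0L) stop("no estimates supplied")
  w <- estimates$silent_length
  data.frame(n_loci = nrow(estimates),
             s_silent = sum(estimates$s_silent),
             theta_w = sum(estimates$theta_w * w, na.rm = TRUE) / sum(w),
             theta_pi = sum(estimates$theta_pi * w, na.rm = TRUE) / sum(w),
             silent_length = sum(w))
}

#' Pooled (population-wide) multilocus diversity
#'
#' Pools all haplotypes (optionally a subset of individuals) before computing
#' each locus's statistics, then length-weights across loci.  This matches a
#' "total" row computed on the full sample, which is not the arithmetic mean
#' of per-population values (the pooled Watterson estimate in particular
#' exceeds every per-population value whenever most variants are local).
#'
#' @param alns List of classified `hap_alignment` objects.
#' @param individuals Optional subset of individual IDs.
#' @return One-row data.frame as [multilocus_average()].
#' @export
pooled_diversity <- function(alns, individuals = NULL) {
  est <- do.call(rbind, lapply(alns, diversity_estimate,
                               individuals = individuals))
  multilocus_average(est)
}

#' Per-population diversity table
#'
#' @param alns List of classified alignments.
#' @param meta Population table.
#' @return data.frame with one row per population: multilocus s_silent,
#'   theta_w, theta_pi.
#' @export
population_diversity <- function(alns, meta) {
  pops <- unique(meta$population_id)
  do.call(rbind, lapply(pops, function(p) {
    ids <- meta$individual_id[meta$population_id == p]
    out <- pooled_diversity(alns, ids)
    cbind(data.frame(population_id = p, stringsAsFactors = FALSE), out)
  }))
}

#' Express per-site diversity as differences per kilobase
#'
#' @param theta_pi Per-site pairwise diversity (>= 0).
#' @return `1000 * theta_pi`, the average number of nucleotide differences
#'   per 1000 bp between two randomly chosen haplotypes.
#' @export
per_kb_differences <- function(theta_pi) {
  stopifnot(all(theta_pi >= 0, na.rm = TRUE))
  1000 * theta_pi
}
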