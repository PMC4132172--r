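# Fixtures built in code: small alignments, genotype matrices, and
# brute-force oracles kept deliberately independent of the package's own
# computation paths.

# alignment whose two segregating (noncoding) columns give haplotypes
# {AA, AT, TA, TT}, padded with monomorphic columns to total length L
two_snp_alignment <- function(L = 100L) {
  seqs <- matrix("C", nrow = 4L, ncol = L)
  seqs[, 1L] <- c("A", "A", "T", "T")
  seqs[, 2L] <- c("A", "T", "A", "T")
  aln <- hap_alignment("toy", seqs, c("i1", "i1", "i2", "i2"))
  classify_sites(aln, NULL)
}

# snp_matrix from a bare dosage matrix
toy_snps <- function(G, loci = NULL) {
  if (is.null(rownames(G))) rownames(G) <- sprintf("i%d", seq_len(nrow(G)))
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(ncol(G)))
  colnames(G) <- sprintf("s%d", seq_len(ncol(G)))
  structure(list(genotypes = G,
                 snp_info = data.frame(snp_id = colnames(G), locus_id = loci,
                                       column = seq_len(ncol(G)) - 1L,
                                       minor = "A", major = "G",
                                       stringsAsFactors = FALSE),
                 individuals = rownames(G)),
            class = "snp_matrix")
}

toy_meta <- function(pops, inds = NULL, lat = NULL, lon = NULL) {
  n <- length(pops)
  if (is.null(inds)) inds <- sprintf("i%d", seq_len(n))
  data.frame(individual_id = inds, population_id = pops,
             latitude = if (is.null(lat)) rep(1, n) else lat,
             longitude = if (is.null(lon)) rep(1, n) else lon,
             leaf_genotype = "unknown", stringsAsFactors = FALSE)
}

# brute-force mean pairwise difference count over all haplotype pairs
bf_pi_total <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2)
}

# brute-force Ewens P(K = k) for n = 4 via enumerated |s(4,k)| = (6,11,6,1)
bf_ewens_n4 <- function(theta) {
  num <- c(6, 11, 6, 1) * theta^(1:4)
  num / (theta * (theta + 1) * (theta + 2) * (theta + 3))
}

# write a FASTA with given header/sequence pairs
write_fasta_lines <- function(path, headers, seqs) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
}
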