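test_that("haplotype FASTA parsing follows the two-haplotypes-per-individual contract", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_lines(f, c("a|hap1", "a|hap2", "b|hap1", "b|hap2"),
                    c("ACGTACGTAA", "ACGTACGTAT", "ACGAACGTAA", "ACGTACGTAA"))
  aln <- read_haplotype_fasta(f, locus_id = "loc1")
  expect_s3_class(aln, "hap_alignment")
  expect_equal(nrow(aln$seqs), 4L)
  expect_equal(alignment_length(aln), 10L)
  expect_setequal(unique(aln$hap_individual), c("a", "b"))
  expect_true(all(aln$site_class == "excluded"))

  # three haplotypes for one individual is malformed, and names the culprit
  write_fasta_lines(f, c("a|hap1", "a|hap2", "a|hap1", "b|hap1", "b|hap2"),
                    rep("ACGT", 5L))
  expect_error(read_haplotype_fasta(f), "a")

  # ragged alignments are rejected
  write_fasta_lines(f, c("a|hap1", "a|hap2"), c("ACGT", "ACGTT"))
  expect_error(read_haplotype_fasta(f), "length mismatch")
})

test_that("FASTA round-trip is byte-stable for sequence content", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_lines(f1, c("a|hap1", "a|hap2", "b|hap1", "b|hap2"),
                    c("ACGTACGTAA", "ACGTACGTAT", "ACGAACGTAA", "ACGTACGTAA"))
  aln <- read_haplotype_fasta(f1, locus_id = "x")
  write_haplotype_fasta(aln, f2)
  aln2 <- read_haplotype_fasta(f2, locus_id = "x")
  expect_identical(unname(aln$seqs), unname(aln2$seqs))
  expect_identical(aln$hap_individual, aln2$hap_individual)
})

test_that("site classification separates silent, synonymous and nonsynonymous columns", {
  # no CDS: everything silent noncoding with weight 1
  aln <- two_snp_alignment(10L)
  expect_true(all(aln$site_class == "silent_noncoding"))
  expect_equal(sum(aln$silent_weight), 10)

  # third position of a GGN glycine codon, polymorphic G/A: synonymous
  seqs <- rbind(c("G", "G", "A", "C"), c("G", "G", "G", "C"),
                c("G", "G", "A", "C"), c("G", "G", "G", "C"))
  cl <- classify_sites(hap_alignment("l", seqs, c("i1", "i1", "i2", "i2")),
                       coding_annotation("l", cbind(0L, 3L), 0L))
  expect_equal(cl$site_class[3L], "synonymous")
  expect_equal(cl$silent_weight[3L], 1)        # fourfold degenerate
  expect_equal(cl$site_class[4L], "silent_noncoding")

  # ATG vs TTG at position 1 (Met -> Leu): nonsynonymous
  seqs2 <- rbind(c("A", "T", "G"), c("T", "T", "G"),
                 c("A", "T", "G"), c("T", "T", "G"))
  cl2 <- classify_sites(hap_alignment("l2", seqs2, c("i1", "i1", "i2", "i2")),
                        coding_annotation("l2", cbind(0L, 3L), 0L))
  expect_equal(cl2$site_class[1L], "nonsynonymous")

  # CDS interval past the end is an annotation error
  expect_error(classify_sites(two_snp_alignment(10L),
                              coding_annotation("toy", cbind(0L, 12L), 0L)),
               "past alignment end")

  # gap and ambiguity columns are excluded with zero weight
  seqs3 <- rbind(c("A", "-", "N"), c("A", "C", "A"),
                 c("A", "C", "A"), c("A", "C", "A"))
  cl3 <- classify_sites(hap_alignment("l3", seqs3, c("i1", "i1", "i2", "i2")),
                        NULL)
  expect_equal(cl3$site_class, c("silent_noncoding", "excluded", "excluded"))
  expect_equal(cl3$silent_weight, c(1, 0, 0))
})

test_that("SNP extraction yields biallelic dosage genotypes", {
  aln <- two_snp_alignment(10L)
  meta <- toy_meta(c("a", "a"), inds = c("i1", "i2"))
  snps <- extract_snps(list(aln), meta)
  expect_equal(dim(snps$genotypes), c(2L, 2L))
  # dosages equal haplotype counts of the minor allele
  expect_true(all(snps$genotypes %in% 0:2))

  # monomorphic locus contributes nothing
  mono <- classify_sites(hap_alignment("m", matrix("A", 4L, 6L),
                                       c("i1", "i1", "i2", "i2")), NULL)
  expect_equal(ncol(extract_snps(list(mono), meta)$genotypes), 0L)

  # triallelic columns are dropped
  seqs <- matrix("C", 4L, 3L)
  seqs[, 1L] <- c("A", "C", "G", "A")
  tri <- classify_sites(hap_alignment("t", seqs, c("i1", "i1", "i2", "i2")),
                        NULL)
  expect_equal(ncol(extract_snps(list(tri), meta)$genotypes), 0L)

  expect_error(extract_snps(list(), meta), "empty")
})

test_that("dosage consistency holds on random synthetic alignments", {
  set.seed(11)
  for (rep in 1:5) {
    n_ind <- 6L; L <- 40L
    seqs <- matrix(sample(c("A", "C", "G", "T"), 2L * n_ind * L, replace = TRUE,
                          prob = c(0.7, 0.1, 0.1, 0.1)), nrow = 2L * n_ind)
    ids <- rep(sprintf("i%d", seq_len(n_ind)), each = 2L)
    aln <- classify_sites(hap_alignment("r", seqs, ids), NULL)
    meta <- toy_meta(rep("p", n_ind), inds = sprintf("i%d", seq_len(n_ind)))
    snps <- extract_snps(list(aln), meta)
    for (j in seq_len(ncol(snps$genotypes))) {
      col <- snps$snp_info$column[j] + 1L
      minor <- snps$snp_info$minor[j]
      manual <- tapply(seqs[, col] == minor, ids, sum)
      expect_equal(unname(snps$genotypes[names(manual), j]),
                   unname(as.integer(manual)))
    }
  }
})

test_that("silent-site counts are invariant to haplotype row order", {
  aln <- two_snp_alignment(50L)
  set.seed(2)
  perm <- sample(4L)
  shuf <- classify_sites(
    hap_alignment("toy", aln$seqs[perm, ], aln$hap_individual[perm]), NULL)
  expect_equal(watterson_theta(shuf), watterson_theta(aln))
  expect_equal(pairwise_theta(shuf), pairwise_theta(aln))
})

test_that("population table reader validates columns and assigns regions", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,population_id,latitude,longitude,leaf_genotype",
               "a,P1,38.5,-77.0,LL", "b,P1,38.5,-77.0,Ll",
               "c,P2,33.1,-82.5,ll", ""), f)
  meta <- read_population_table(f, boundary_lat = 36)
  expect_equal(nrow(meta), 3L)
  expect_equal(meta$region, c("north", "north", "south"))
  writeLines(c("individual_id,population_id,latitude,longitude",
               "a,P1,38.5,-77.0", "a,P1,38.5,-77.0"), f)
  expect_error(read_population_table(f), "duplicate")
})
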