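#' @keywords internal
"_PACKAGE"

# Core data model ------------------------------------------------------------
#
# A `hap_alignment` is the unit every statistic consumes: a matrix of phased
# haplotype sequences (rows) for one sequenced locus, two rows per diploid
# individual, with a per-column site classification used to restrict
# statistics to silent sites (synonymous + noncoding).  Coordinates are
# 0-based, half-open everywhere.

SITE_CLASSES <- c("silent_noncoding", "synonymous", "nonsynonymous", "excluded")

#' Construct a phased haplotype alignment
#'
#' @param locus_id Single string naming the locus.
#' @param seqs Character matrix of single IUPAC nucleotide characters, one row
#'   per haplotype (uppercased internally).
#' @param hap_individual Character vector mapping each haplotype row to its
#'   diploid individual; every individual must appear exactly twice.
#' @param site_class Optional character vector (one per column) in
#'   `c("silent_noncoding", "synonymous", "nonsynonymous", "excluded")`.
#'   Defaults to `"excluded"` until [classify_sites()] is run.
#' @param silent_weight Optional numeric vector of per-column contributions to
#'   the effective silent length (noncoding columns count 1, coding columns
#'   count their fractional degeneracy, excluded columns 0).
#'
#' @return An object of class `hap_alignment`.
#' @export
hap_alignment <- function(locus_id, seqs, hap_individual,
                          site_class = NULL, silent_weight = NULL) {
  if (!is.matrix(seqs)) seqs <- as.matrix(seqs)
  mode(seqs) <- "character"
  seqs[] <- toupper(seqs)
  if (nrow(seqs) < 1L || ncol(seqs) < 1L)
    stop("alignment must have at least one haplotype and one column")
  tab <- table(hap_individual)
  bad <- names(tab)[tab != 2L]
  if (length(hap_individual) != nrow(seqs))
    stop("hap_individual must name one individual per haplotype row")
  if (length(bad))
    stop("malformed input: individual(s) without exactly 2 haplotypes: ",
         paste(bad, collapse = ", "))
  if (is.null(site_class)) site_class <- rep("excluded", ncol(seqs))
  if (length(site_class) != ncol(seqs))
    stop("site_class length must equal alignment length")
  if (!all(site_class %in% SITE_CLASSES))
    stop("invalid site classes: ",
         paste(setdiff(unique(site_class), SITE_CLASSES), collapse = ", "))
  if (is.null(silent_weight))
    silent_weight <- as.numeric(site_class == "silent_noncoding")
  structure(
    list(locus_id = as.character(locus_id), seqs = seqs,
         hap_individual = as.character(hap_individual),
         site_class = site_class, silent_weight = as.numeric(silent_weight)),
    class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> locus %s: %d haplotypes (%d individuals) x %d bp\n",
              x$locus_id, nrow(x$seqs), length(unique(x$hap_individual)),
              ncol(x$seqs)))
  cat("  site classes:",
      paste(sprintf("%s=%d", names(table(x$site_class)), table(x$site_class)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Length in bp of an alignment
#' @param aln A `hap_alignment`.
#' @export
alignment_length <- function(aln) ncol(aln$seqs)

#' Construct a coding annotation for one locus
#'
#' Intervals are 0-based, half-open, must be sorted and non-overlapping.
#' The concatenated CDS need not be a multiple of 3 (partial fragments are
#' expected for short sequenced amplicons); `frame` gives the offset in
#' `{0,1,2}` of the first complete codon within the concatenated CDS.
#'
#' @param locus_id Locus label.
#' @param cds_intervals Two-column matrix (start, end) or list of pairs.
#' @param frame Integer offset in 0..2.
#' @return A `coding_annotation` object.
#' @export
coding_annotation <- function(locus_id, cds_intervals = NULL, frame = 0L) {
  if (is.null(cds_intervals) || length(cds_intervals) == 0L) {
    iv <- matrix(integer(0), ncol = 2L)
  } else {
    iv <- if (is.list(cds_intervals)) do.call(rbind, cds_intervals) else cds_intervals
    iv <- matrix(as.integer(iv), ncol = 2L)
    if (any(iv[, 2L] <= iv[, 1L])) stop("empty or inverted CDS interval")
    if (is.unsorted(iv[, 1L])) stop("CDS intervals must be sorted")
    if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      stop("CDS intervals must not overlap")
    if (any(iv[, 1L] < 0L)) stop("CDS interval before origin")
  }
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  structure(list(locus_id = as.character(locus_id), cds_intervals = iv,
                 frame = frame),
            class = "coding_annotation")
}

# FASTA / CSV / interval readers --------------------------------------------

#' Read a per-locus phased haplotype FASTA
#'
#' Header convention: `>IND_ID|hap1` and `>IND_ID|hap2` for the two phased
#' haplotypes of each diploid individual.  All records must share one length.
#'
#' @param path FASTA file.
#' @param locus_id Locus label; defaults to the file name minus extension.
#' @param metadata Optional population table; if given, every individual in
#'   the FASTA must appear in it.
#' @return A [hap_alignment()] with all site classes `"excluded"` until
#'   [classify_sites()] assigns them.
#' @export
read_haplotype_fasta <- function(path, locus_id = NULL, metadata = NULL) {
  if (is.null(locus_id))
    locus_id <- sub("\\.(fa|fasta|fas)$", "", basename(path), ignore.case = TRUE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) != 1L)
    stop("length mismatch: ragged alignment in ", path,
         " (widths ", paste(unique(lens), collapse = ", "), ")")
  ids <- sub("\\|hap[12]$", "", names(ss))
  seqs <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  rownames(seqs) <- names(ss)
  if (!is.null(metadata)) {
    missing_ind <- setdiff(ids, metadata$individual_id)
    if (length(missing_ind))
      stop("individuals absent from metadata: ",
           paste(missing_ind, collapse = ", "))
  }
  hap_alignment(locus_id, seqs, ids)
}

#' Write a haplotype alignment as FASTA
#'
#' Inverse of [read_haplotype_fasta()]; round-trips byte-stably for sequence
#' content.
#' @param aln A `hap_alignment`.
#' @param path Output file.
#' @export
write_haplotype_fasta <- function(aln, path) {
  idx <- stats::ave(seq_along(aln$hap_individual), aln$hap_individual,
                    FUN = seq_along)
  headers <- sprintf("%s|hap%d", aln$hap_individual, idx)
  ss <- Biostrings::BStringSet(apply(aln$seqs, 1L, paste, collapse = ""))
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read the population metadata table
#'
#' Expects CSV columns `individual_id`, `population_id`, `latitude`,
#' `longitude` and optionally `leaf_genotype` (`LL`/`Ll`/`ll`/`unknown`).
#' A `region` column (`north`/`south`) is derived from latitude relative to
#' `boundary_lat`, the clinal boundary separating northern from southern
#' populations (taken from prior work, so it is a required input whenever
#' regions are used, never a silent default).
#'
#' @param path CSV file (CRLF and trailing blank lines tolerated).
#' @param boundary_lat Optional clinal boundary latitude in decimal degrees.
#' @return A data.frame (`pop_table`).
#' @export
read_population_table <- function(path, boundary_lat = NULL) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  meta <- meta[rowSums(!is.na(meta) & meta != "") > 0L, , drop = FALSE]
  need <- c("individual_id", "population_id", "latitude", "longitude")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("population table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$individual_id))
    stop("duplicate individual_id in population table")
  if (!"leaf_genotype" %in% names(meta)) meta$leaf_genotype <- "unknown"
  meta$leaf_genotype[is.na(meta$leaf_genotype) | meta$leaf_genotype == ""] <-
    "unknown"
  bad <- setdiff(unique(meta$leaf_genotype), c("LL", "Ll", "ll", "unknown"))
  if (length(bad)) stop("invalid leaf genotypes: ", paste(bad, collapse = ", "))
  if (!is.null(boundary_lat)) meta <- assign_region(meta, boundary_lat)
  class(meta) <- c("pop_table", "data.frame")
  meta
}

#' Assign north/south regions from a clinal boundary latitude
#' @param meta Population table.
#' @param boundary_lat Boundary latitude (decimal degrees).
#' @export
assign_region <- function(meta, boundary_lat) {
  meta$region <- ifelse(meta$latitude >= boundary_lat, "north", "south")
  meta
}

#' Write a population table as CSV
#' @param meta Population table.
#' @param path Output CSV.
#' @export
write_population_table <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED-like coding annotation file
#'
#' Tab- or whitespace-separated columns: locus, start, end, frame; 0-based
#' half-open intervals, one row per CDS interval.  Only the first interval's
#' frame is used per locus.
#'
#' @param path Interval file.
#' @return Named list of [coding_annotation()] objects, one per locus.
#' @export
read_coding_annotation <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("locus", "start", "end", "frame"))
  out <- lapply(split(tab, tab$locus), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    coding_annotation(d$locus[1L], cbind(d$start, d$end), d$frame[1L])
  })
  out[unique(tab$locus)]
}

#' Write coding annotations in the BED-like format
#' @param anns List of `coding_annotation` objects.
#' @param path Output file.
#' @export
write_coding_annotation <- function(anns, path) {
  rows <- do.call(rbind, lapply(anns, function(a) {
    if (nrow(a$cds_intervals) == 0L) return(NULL)
    data.frame(locus = a$locus_id, start = a$cds_intervals[, 1L],
               end = a$cds_intervals[, 2L], frame = a$frame)
  }))
  if (is.null(rows)) rows <- data.frame(locus = character(0), start = integer(0),
                                        end = integer(0), frame = integer(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Site classification --------------------------------------------------------

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# cached codon lookups: amino acid after substituting base b at codon
# position k, and the per-position fraction of synonymous changes
.codon_env <- new.env(parent = emptyenv())

.codon_lookups <- function() {
  if (!is.null(.codon_env$aa_sub)) return(.codon_env)
  code <- .codon_table()
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  aa_sub <- array(NA_character_, dim = c(64L, 3L, 4L),
                  dimnames = list(codons, NULL, bases))
  degeneracy <- matrix(NA_real_, 64L, 3L, dimnames = list(codons, NULL))
  for (cd in codons) {
    for (k in 1:3) {
      syn <- logical(4L)
      for (b in seq_along(bases)) {
        cd2 <- cd
        substr(cd2, k, k) <- bases[b]
        aa_sub[cd, k, b] <- code[[cd2]]
        syn[b] <- identical(code[[cd2]], code[[cd]])
      }
      degeneracy[cd, k] <- mean(syn[bases != substr(cd, k, k)])
    }
  }
  .codon_env$aa_sub <- aa_sub
  .codon_env$degeneracy <- degeneracy
  .codon_env$aa <- stats::setNames(as.character(code), codons)
  .codon_env
}

#' Classify alignment columns as silent, synonymous, nonsynonymous or excluded
#'
#' Columns containing gaps or ambiguity codes are `excluded` from all
#' statistics.  Columns outside every CDS interval are `silent_noncoding`.
#' A polymorphic CDS column is `synonymous` only if every observed change at
#' that column preserves the encoded amino acid in every observed haplotype
#' codon context, else `nonsynonymous`.  Monomorphic CDS columns are labelled
#' `synonymous` when fourfold degenerate, otherwise `nonsynonymous`.
#'
#' Every CDS column additionally receives a fractional silent weight (the
#' Nei–Gojobori fraction of the three possible point mutations that are
#' synonymous, averaged over observed haplotype codons), so per-site
#' statistics have a well-defined effective silent length even at monomorphic
#' positions.  CDS positions whose codon is truncated by the fragment edge
#' cannot be evaluated and are `excluded`.
#'
#' @param aln A `hap_alignment`.
#' @param ann A [coding_annotation()] for the same locus (or `NULL` /
#'   zero intervals for a fully noncoding fragment).
#' @return The alignment with `site_class` and `silent_weight` filled in.
#' @export
classify_sites <- function(aln, ann = NULL) {
  L <- ncol(aln$seqs)
  if (is.null(ann)) ann <- coding_annotation(aln$locus_id, NULL, 0L)
  if (!is.null(ann$locus_id) && ann$locus_id != aln$locus_id)
    stop("annotation locus (", ann$locus_id, ") does not match alignment (",
         aln$locus_id, ")")
  if (nrow(ann$cds_intervals) && max(ann$cds_intervals[, 2L]) > L)
    stop("annotation error: CDS interval extends past alignment end")

  cls <- rep("silent_noncoding", L)
  wt <- rep(1, L)

  clean <- apply(aln$seqs, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  # CDS positions, in reading order
  cds_cols <- integer(0)
  for (i in seq_len(nrow(ann$cds_intervals)))
    cds_cols <- c(cds_cols, seq.int(ann$cds_intervals[i, 1L],
                                    ann$cds_intervals[i, 2L] - 1L))
  if (length(cds_cols)) {
    usable <- seq_along(cds_cols) > ann$frame
    n_cod <- (sum(usable)) %/% 3L
    in_codon <- rep(FALSE, length(cds_cols))
    if (n_cod > 0L)
      in_codon[ann$frame + seq_len(3L * n_cod)] <- TRUE
    # truncated codon positions cannot be evaluated
    cls[cds_cols[!in_codon] + 1L] <- "excluded"
    wt[cds_cols[!in_codon] + 1L] <- 0
    if (n_cod > 0L) {
      lk <- .codon_lookups()
      codon_cols <- matrix(cds_cols[ann$frame + seq_len(3L * n_cod)],
                           nrow = 3L)  # one column per codon
      for (ci in seq_len(n_cod)) {
        pos3 <- codon_cols[, ci] + 1L        # 1-based alignment columns
        if (!all(clean[pos3])) {
          # codon containing a dirty column: dirty columns excluded below;
          # clean positions of that codon lack a reliable context
          cls[pos3] <- "excluded"; wt[pos3] <- 0
          next
        }
        codons <- paste0(aln$seqs[, pos3[1L]], aln$seqs[, pos3[2L]],
                         aln$seqs[, pos3[3L]])
        ucod <- unique(codons)
        for (k in 1:3) {
          col1 <- pos3[k]
          obs <- unique(aln$seqs[, col1])
          # fractional silent weight: mean over haplotype codons of the
          # fraction of the 3 alternative bases that leave the AA unchanged
          wt[col1] <- mean(lk$degeneracy[codons, k])
          if (length(obs) > 1L) {
            # polymorphic: synonymous iff every observed state change is
            # synonymous in every observed codon context
            syn <- all(vapply(ucod, function(cd)
              all(lk$aa_sub[cd, k, obs] == lk$aa[[cd]]), logical(1)))
            cls[col1] <- if (syn) "synonymous" else "nonsynonymous"
          } else {
            cls[col1] <- if (wt[col1] >= 1) "synonymous" else "nonsynonymous"
          }
        }
      }
    }
  }
  cls[!clean] <- "excluded"
  wt[!clean] <- 0
  aln$site_class <- cls
  aln$silent_weight <- wt
  aln
}

# SNP extraction -------------------------------------------------------------

#' Extract biallelic SNPs from a set of alignments
#'
#' Every clean biallelic segregating column across the supplied loci becomes
#' one SNP; genotypes are minor-allele dosages (0/1/2) summed over each
#' individual's two haplotype rows.  Columns with gaps/ambiguity codes or
#' more than two states are dropped (the paper's chromatographs were edited
#' to clean biallelic calls; no gap model is described).
#'
#' @param alns List of `hap_alignment` objects sharing one individual set.
#' @param meta Population table fixing individual order.
#' @return A `snp_matrix`: list with `genotypes` (individuals x SNPs integer
#'   matrix), `snp_info` (data.frame: snp_id, locus_id, column, minor, major),
#'   and `individuals`.
#' @export
extract_snps <- function(alns, meta) {
  if (length(alns) == 0L) stop("empty alignment list")
  inds <- meta$individual_id
  geno <- list(); info <- list()
  for (aln in alns) {
    sq <- aln$seqs
    ind_rows <- split(seq_len(nrow(sq)), aln$hap_individual)
    if (!setequal(names(ind_rows), inds))
      stop("alignment ", aln$locus_id, " individuals differ from metadata")
    r1 <- vapply(ind_rows[inds], `[`, integer(1), 1L)
    r2 <- vapply(ind_rows[inds], `[`, integer(1), 2L)
    for (j in seq_len(ncol(sq))) {
      col <- sq[, j]
      if (!all(col %in% c("A", "C", "G", "T"))) next
      states <- sort(unique(col))
      if (length(states) != 2L) next
      cnt <- table(factor(col, levels = states))
      minor <- states[which.min(cnt)]  # ties resolve alphabetically
      major <- setdiff(states, minor)
      dos <- (col[r1] == minor) + (col[r2] == minor)
      geno[[length(geno) + 1L]] <- as.integer(dos)
      info[[length(info) + 1L]] <-
        data.frame(snp_id = sprintf("%s_%d", aln$locus_id, j - 1L),
                   locus_id = aln$locus_id, column = j - 1L,
                   minor = minor, major = major,
                   stringsAsFactors = FALSE)
    }
  }
  genotypes <- if (length(geno)) do.call(cbind, geno) else
    matrix(integer(0), nrow = length(inds), ncol = 0L)
  snp_info <- if (length(info)) do.call(rbind, info) else
    data.frame(snp_id = character(0), locus_id = character(0),
               column = integer(0), minor = character(0), major = character(0))
  rownames(genotypes) <- inds
  colnames(genotypes) <- snp_info$snp_id
  structure(list(genotypes = genotypes, snp_info = snp_info,
                 individuals = inds),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d individuals x %d biallelic SNPs (%d loci)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$snp_info$locus_id))))
  invisible(x)
}

#' Subset a snp_matrix by SNP index
#' @param snps A `snp_matrix`.
#' @param keep Logical or integer index over SNP columns.
#' @export
subset_snps <- function(snps, keep) {
  structure(list(genotypes = snps$genotypes[, keep, drop = FALSE],
                 snp_info = snps$snp_info[keep, , drop = FALSE],
                 individuals = snps$individuals),
            class = "snp_matrix")
}
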