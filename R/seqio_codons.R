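# Reading and validating coding sequences, codon counting, and per-position
# nucleotide composition. Sequences are taken as given in frame 1: the input
# is CDS FASTA, never genomic coordinates.

#' Read and validate coding sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA of coding sequences and
#' applies the package's CDS validation policy: the length must be a positive
#' multiple of 3, the sequence must contain no ambiguity characters (only
#' A/C/G/T after upper-casing), and no internal stop codon (TAA/TAG/TGA
#' before the final codon). A terminal stop codon is allowed and kept in the
#' record; stop codons are excluded later from all composition and usage
#' tallies. When several records share a gene id, the longest surviving
#' record is kept.
#'
#' @param path path to a FASTA file
#' @param quiet suppress the per-record rejection log (default FALSE)
#' @return a named character vector of sequences (names are gene ids), with
#'   attribute `rejected`: a data.frame of gene_id and reason
#'   (`"length"`, `"ambiguity"`, `"internal stop"`) for every dropped record
#' @export
read_cds_fasta <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  validate_cds(seqs, ids, quiet = quiet)
}

#' Validate in-memory coding sequences
#'
#' The validation core behind [read_cds_fasta()]; useful when sequences are
#' already in memory (e.g. from the synthetic generator).
#'
#' @param seqs character vector of nucleotide sequences
#' @param ids gene ids, same length as `seqs`
#' @param quiet suppress the rejection log
#' @return as [read_cds_fasta()]
#' @export
validate_cds <- function(seqs, ids = names(seqs), quiet = FALSE) {
  stopifnot(length(seqs) == length(ids))
  seqs <- toupper(seqs)
  reason <- rep(NA_character_, length(seqs))

  bad_len <- nchar(seqs) == 0L | nchar(seqs) %% 3L != 0L
  reason[bad_len] <- "length"

  ok <- is.na(reason)
  bad_amb <- ok & grepl("[^ACGT]", seqs)
  reason[bad_amb] <- "ambiguity"

  ok <- is.na(reason)
  has_internal_stop <- function(s) {
    cod <- codon_split(s)
    any(cod[-length(cod)] %in% STOP_CODONS)
  }
  bad_stop <- ok & vapply(seqs, has_internal_stop, logical(1), USE.NAMES = FALSE)
  reason[bad_stop] <- "internal stop"

  rejected <- data.frame(gene_id = ids[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  if (!quiet && nrow(rejected) > 0L) {
    message(nrow(rejected), " record(s) rejected: ",
            paste(sprintf("%s (%s)", rejected$gene_id, rejected$reason),
                  collapse = ", "))
  }

  keep <- is.na(reason)
  seqs <- seqs[keep]; ids <- ids[keep]
  # longest record per gene id; ties resolved by first occurrence
  if (anyDuplicated(ids)) {
    ord <- order(ids, -nchar(seqs))
    seqs <- seqs[ord]; ids <- ids[ord]
    first <- !duplicated(ids)
    seqs <- seqs[first]; ids <- ids[first]
  }
  if (length(seqs) == 0L) stop("no valid coding sequences after filtering")
  out <- stats::setNames(seqs, ids)
  attr(out, "rejected") <- rejected
  out
}

#' Write coding sequences to FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line-wrap width (default 70)
#' @return `path`, invisibly
#' @export
write_cds_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Count codons in a coding sequence
#'
#' Tallies consecutive non-overlapping triplets from position 1 (the reading
#' frame is never re-estimated). All 64 codons are always present in the
#' result, with zero counts where unobserved.
#'
#' @param seq a single valid CDS string
#' @return integer vector of length 64 named by codon; attribute `n_codons`
#'   is the total (= nchar/3)
#' @export
count_codons <- function(seq) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) > 0L, nchar(seq) %% 3L == 0L)
  cod <- codon_split(seq)
  counts <- table(factor(cod, levels = ALL_CODONS))
  out <- stats::setNames(as.integer(counts), ALL_CODONS)
  attr(out, "n_codons") <- length(cod)
  out
}

#' Count codons for many sequences at once
#'
#' @param seqs named character vector of CDS
#' @return integer matrix, genes in rows, 64 codon columns
#' @export
count_codons_matrix <- function(seqs) {
  m <- t(vapply(seqs, function(s) {
    cc <- count_codons(s)
    as.integer(cc)
  }, integer(64L)))
  colnames(m) <- ALL_CODONS
  rownames(m) <- names(seqs)
  m
}

#' Positional GC and purine composition of a gene's codons
#'
#' Computes, for each of the three codon positions, the fraction of G+C and
#' of A+G among the bases occupying that position, weighted by codon counts.
#' Stop codons are excluded by default (they have no synonymous competition
#' and never enter bias or usage tallies).
#'
#' @param counts codon count vector from [count_codons()] (names = codons)
#' @param exclude_stops drop TAA/TAG/TGA from the tally (default TRUE)
#' @return list with numeric vectors `gc` and `purine`, each of length 3,
#'   and `n_codons`, the number of codons tallied
#' @export
positional_composition <- function(counts, exclude_stops = TRUE) {
  codons <- names(counts)
  if (is.null(codons)) stop("counts must be named by codon")
  if (exclude_stops) {
    keep <- !(codons %in% STOP_CODONS)
    counts <- counts[keep]; codons <- codons[keep]
  }
  n <- sum(counts)
  if (n == 0L) stop("no usable codons: positional composition undefined")
  bases <- matrix(unlist(strsplit(codons, "")), ncol = 3L, byrow = TRUE)
  gc <- numeric(3L); purine <- numeric(3L)
  for (k in 1:3) {
    gc[k] <- sum(counts[bases[, k] %in% c("G", "C")]) / n
    purine[k] <- sum(counts[bases[, k] %in% c("A", "G")]) / n
  }
  list(gc = gc, purine = purine, n_codons = as.integer(n))
}

#' Per-gene positional composition table
#'
#' @param counts_matrix genes x 64 codon count matrix
#' @param exclude_stops see [positional_composition()]
#' @return data.frame with gene_id, n_codons, gc1..gc3, purine1..purine3
#' @export
composition_table <- function(counts_matrix, exclude_stops = TRUE) {
  rows <- lapply(rownames(counts_matrix), function(g) {
    cc <- stats::setNames(counts_matrix[g, ], colnames(counts_matrix))
    pc <- positional_composition(cc, exclude_stops = exclude_stops)
    data.frame(gene_id = g, n_codons = pc$n_codons,
               gc1 = pc$gc[1], gc2 = pc$gc[2], gc3 = pc$gc[3],
               purine1 = pc$purine[1], purine2 = pc$purine[2],
               purine3 = pc$purine[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
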