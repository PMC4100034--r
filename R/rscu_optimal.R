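# Relative synonymous codon usage (RSCU), optimal-codon identification from
# tRNA gene copy numbers, and group comparisons of optimal-codon usage.

#' Relative synonymous codon usage of pooled codon counts
#'
#' For codon j of amino acid i with family size n_i and count x_ij,
#' RSCU_ij = x_ij * n_i / sum_j x_ij, so values within a family average to 1.
#' Counts are pooled across genes before RSCU (never averaged per gene),
#' which makes the family-sum identity exact. Families with zero total
#' observations are returned as NA (undefined), not 0.
#'
#' @param pooled codon counts named by codon, pooled over a gene group
#'   (a vector, or a genes x codons matrix which is column-summed first)
#' @param multi_only restrict to multi-codon families (default TRUE; Met and
#'   Trp carry no synonymous information)
#' @return data.frame: amino_acid (one-letter), codon, count, rscu
#' @export
compute_rscu <- function(pooled, multi_only = TRUE) {
  if (is.matrix(pooled)) pooled <- colSums(pooled)
  x <- pooled[SENSE_CODONS]
  x[is.na(x)] <- 0
  aa <- SENSE_AA
  fam_tot <- tapply(x, aa, sum)
  fam_n <- as.integer(FAMILY_SIZE[aa])
  rscu <- ifelse(fam_tot[aa] > 0, x * fam_n / fam_tot[aa], NA_real_)
  out <- data.frame(amino_acid = unname(aa), codon = SENSE_CODONS,
                    count = unname(as.numeric(x)), rscu = unname(rscu),
                    stringsAsFactors = FALSE)
  if (multi_only) out <- out[FAMILY_SIZE[out$amino_acid] > 1L, ]
  rownames(out) <- NULL
  out
}

#' Read a tRNA copy-number table
#'
#' Expects a TSV with header columns `codon`, `anticodon`, `copies`, `adat`
#' (0/1), one row per codon, structured like a GtRNAdb per-codon summary.
#' Validates that anticodons are the reverse complements of their codons and
#' that the `adat` flag only marks tRNAs with A at the wobble (first
#' anticodon) position of ADAT-substrate amino acids.
#'
#' @param path TSV path
#' @return validated data.frame with columns codon, anticodon, copies, adat
#' @export
read_trna_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_trna_table(tab)
}

#' Validate a tRNA copy-number table
#' @param tab data.frame with codon, anticodon, copies, adat
#' @return the table, checked and with adat coerced to logical
#' @export
validate_trna_table <- function(tab) {
  need <- c("codon", "anticodon", "copies", "adat")
  if (!all(need %in% names(tab)))
    stop("tRNA table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$codon)) stop("duplicate codons in tRNA table")
  if (any(tab$copies < 0)) stop("negative tRNA copy number")
  bad <- tab$anticodon != revcomp_codon(tab$codon)
  if (any(bad))
    stop("anticodon is not the reverse complement of its codon: ",
         paste(tab$codon[bad], collapse = ", "))
  tab$adat <- as.logical(tab$adat)
  wobble_a <- substr(tab$anticodon, 1, 1) == "A"
  aa <- CODON_TO_AA[tab$codon]
  if (any(tab$adat & !(wobble_a & aa %in% ADAT_AMINO_ACIDS)))
    stop("adat flag set on a tRNA without A34 or outside the ADAT amino acids")
  tab
}

#' Identify optimal codons from tRNA gene copy numbers
#'
#' Within each multi-codon family the optimal codon is the one matched to the
#' largest decoding tRNA pool. Each codon's decoding weight is the gene copy
#' number of its Watson-Crick cognate tRNA (anticodon = reverse complement).
#' When `adat = TRUE` (default), tRNAs flagged as ADAT substrates (A34
#' deaminated to inosine) have their copies credited to the C-ending codon of
#' their family instead of the T-ending Watson-Crick cognate, reflecting that
#' the modified wobble base reads C. Families whose maximal weight is tied
#' are excluded, as are the single-codon families Met and Trp.
#'
#' @param trna tRNA table from [read_trna_table()] / [trna_fixture()]
#' @param adat apply the ADAT reassignment rule (default TRUE)
#' @return list with `optimal`: data.frame (amino_acid, amino_acid_3,
#'   codon, weight) of one optimal codon per included amino acid, and
#'   `excluded`: data.frame (amino_acid, reason) with reasons
#'   `"single-codon"` or `"tied tRNA counts"`
#' @export
identify_optimal_codons <- function(trna, adat = TRUE) {
  trna <- validate_trna_table(trna)
  missing_codons <- setdiff(SENSE_CODONS, trna$codon)
  if (length(missing_codons) > 0L)
    stop("tRNA table missing sense codons: ",
         paste(missing_codons, collapse = ", "))
  w <- stats::setNames(as.numeric(trna$copies), trna$codon)[SENSE_CODONS]
  if (adat) {
    flag <- stats::setNames(trna$adat, trna$codon)[SENSE_CODONS]
    for (codon in SENSE_CODONS[flag]) {
      # A34 tRNA: WC cognate is the T-ending codon; reassign to the C-ending
      target <- sub("T$", "C", codon)
      w[target] <- w[target] + w[codon]
      w[codon] <- 0
    }
  }
  aas <- sort(unique(SENSE_AA))
  opt <- list(); exc <- list()
  for (a in aas) {
    fam <- SENSE_CODONS[SENSE_AA == a]
    if (length(fam) == 1L) {
      exc[[a]] <- data.frame(amino_acid = a, reason = "single-codon",
                             stringsAsFactors = FALSE)
      next
    }
    fw <- w[fam]
    top <- fw[fw == max(fw)]
    if (length(top) > 1L) {
      exc[[a]] <- data.frame(amino_acid = a, reason = "tied tRNA counts",
                             stringsAsFactors = FALSE)
      next
    }
    opt[[a]] <- data.frame(amino_acid = a, amino_acid_3 = unname(AA_THREE[a]),
                           codon = names(top), weight = unname(top),
                           stringsAsFactors = FALSE)
  }
  list(optimal = do.call(rbind, c(opt, list(make.row.names = FALSE))),
       excluded = do.call(rbind, c(exc, list(make.row.names = FALSE))))
}

#' Count GC-ending codons
#'
#' @param codons character vector of codon triplets
#' @return number of codons whose third base is G or C
#' @export
count_gc_ending <- function(codons) {
  stopifnot(all(nchar(codons) == 3L))
  sum(substr(codons, 3, 3) %in% c("G", "C"))
}

#' Compare optimal-codon usage between gene groups
#'
#' Given per-group RSCU tables and an optimal-codon set, reports (a) for each
#' ordered pair of groups, the amino acids in which the first group's
#' optimal-codon RSCU exceeds the second group's (ties count as
#' non-exceeding), and (b) for each group, the amino acids in which the
#' optimal codon attains the strictly maximal RSCU within its family
#' ("preferential use"; ties are non-preferential). Amino acids whose RSCU
#' is undefined (zero family count) in any group of a pairwise comparison
#' are dropped from that comparison and listed.
#'
#' @param groups named list of RSCU tables from [compute_rscu()]
#' @param optimal result of [identify_optimal_codons()]
#' @return list with `exceedance` (data.frame group_a, group_b, n_exceed,
#'   amino_acids, n_compared, dropped), and `preferential` (data.frame
#'   group, n_preferential, amino_acids)
#' @export
compare_optimal_usage <- function(groups, optimal) {
  stopifnot(length(groups) >= 2L, !is.null(names(groups)))
  opt <- optimal$optimal
  get_opt_rscu <- function(tab) {
    stats::setNames(tab$rscu[match(opt$codon, tab$codon)], opt$amino_acid)
  }
  opt_rscu <- lapply(groups, get_opt_rscu)

  pref <- lapply(names(groups), function(g) {
    tab <- groups[[g]]
    is_pref <- vapply(seq_len(nrow(opt)), function(i) {
      fam <- tab[tab$amino_acid == opt$amino_acid[i], ]
      v <- fam$rscu[fam$codon == opt$codon[i]]
      if (any(is.na(fam$rscu)) || length(v) != 1L) return(NA)
      sum(fam$rscu >= v) == 1L  # strict max: nothing else ties or exceeds
    }, logical(1))
    aa3 <- opt$amino_acid_3[which(is_pref %in% TRUE)]
    data.frame(group = g, n_preferential = sum(is_pref, na.rm = TRUE),
               amino_acids = paste(aa3, collapse = ","),
               stringsAsFactors = FALSE)
  })

  pairs <- expand.grid(a = names(groups), b = names(groups),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  exceed <- lapply(seq_len(nrow(pairs)), function(i) {
    ra <- opt_rscu[[pairs$a[i]]]; rb <- opt_rscu[[pairs$b[i]]]
    usable <- !is.na(ra) & !is.na(rb)
    wins <- usable & ra > rb
    data.frame(group_a = pairs$a[i], group_b = pairs$b[i],
               n_exceed = sum(wins),
               amino_acids = paste(opt$amino_acid_3[wins], collapse = ","),
               n_compared = sum(usable),
               dropped = paste(opt$amino_acid_3[!usable], collapse = ","),
               stringsAsFactors = FALSE)
  })
  list(exceedance = do.call(rbind, exceed),
       preferential = do.call(rbind, pref))
}
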