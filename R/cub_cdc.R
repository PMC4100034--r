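# The Codon Deviation Coefficient (CDC): a codon usage bias statistic that
# measures how far a gene's observed codon usage deviates from an expectation
# built only from the gene's own positional nucleotide composition. Because
# the background is composition-aware it needs no reference gene set, which
# matters in genomes with heterogeneous isochores. Significance comes from a
# parametric bootstrap against the same background.

#' Expected codon usage from positional composition
#'
#' Builds the null codon usage of a gene from its positional GC and purine
#' fractions. Per codon position k, nucleotide probabilities factorise as
#' P(G) = gc\[k\]*purine\[k\], P(C) = gc\[k\]*(1-purine\[k\]),
#' P(A) = (1-gc\[k\])*purine\[k\], P(T) = (1-gc\[k\])*(1-purine\[k\]);
#' a codon's probability is the product over its three positions. Stop codons
#' are removed and the vector renormalised over the 61 sense codons.
#'
#' @param comp list with `gc` and `purine`, each length 3 in \[0,1\]
#'   (as returned by [positional_composition()])
#' @return named numeric vector of probabilities over the 61 sense codons,
#'   summing to 1
#' @export
expected_codon_usage <- function(comp) {
  gc <- comp$gc; pur <- comp$purine
  stopifnot(length(gc) == 3L, length(pur) == 3L,
            all(gc >= 0 & gc <= 1), all(pur >= 0 & pur <= 1))
  # base probabilities per position: rows A,C,G,T
  p <- vapply(1:3, function(k) {
    c(A = (1 - gc[k]) * pur[k],
      C = gc[k] * (1 - pur[k]),
      G = gc[k] * pur[k],
      T = (1 - gc[k]) * (1 - pur[k]))
  }, numeric(4L))
  bases <- matrix(unlist(strsplit(SENSE_CODONS, "")), ncol = 3L, byrow = TRUE)
  prob <- p[bases[, 1], 1] * p[bases[, 2], 2] * p[bases[, 3], 3]
  names(prob) <- SENSE_CODONS
  s <- sum(prob)
  if (s <= 0) {
    # composition forces every sense codon to probability zero only if the
    # forced codon is a stop; fall back to mass on the forced codon's family
    stop("expected usage degenerate: composition forces a stop codon")
  }
  prob / s
}

#' Codon Deviation Coefficient of observed counts against an expectation
#'
#' CDC = 1 - cosine similarity between the observed sense-codon frequency
#' vector and the expected probability vector. 0 means observed usage is
#' exactly proportional to the background expectation; values near 1 mean
#' extreme deviation. Scale-invariant in the observed counts.
#'
#' @param counts codon counts named by codon (64 or 61 entries; stops ignored)
#' @param expected expected sense-codon probabilities from
#'   [expected_codon_usage()]
#' @return CDC value in \[0,1\]
#' @export
cdc_statistic <- function(counts, expected) {
  obs <- counts[SENSE_CODONS]
  obs[is.na(obs)] <- 0
  e <- expected[SENSE_CODONS]
  no <- sqrt(sum(obs^2))
  if (no == 0) stop("observed vector has no sense codons")
  1 - sum(obs * e) / (no * sqrt(sum(e^2)))
}

#' Bootstrap P-value for a gene's CDC
#'
#' Simulates `n_boot` pseudo-genes of the same codon count drawn i.i.d. from
#' the expected usage, recomputes CDC for each, and returns the add-one
#' Monte-Carlo P-value P = (1 + #\{CDC_sim >= CDC_obs\}) / (n_boot + 1), so P
#' is never exactly 0. Reproducible given `seed`.
#'
#' @param counts observed codon counts (named)
#' @param expected expected sense-codon probabilities
#' @param n_boot number of bootstrap replicates (>= 100; default 1000)
#' @param seed integer seed for the replicate draws (required)
#' @return P-value in (0, 1\]
#' @export
cdc_pvalue <- function(counts, expected, n_boot = 1000L, seed) {
  stopifnot(n_boot >= 100L)
  if (missing(seed)) stop("a seed is required for the bootstrap")
  obs <- counts[SENSE_CODONS]
  obs[is.na(obs)] <- 0
  n <- sum(obs)
  e <- expected[SENSE_CODONS]
  observed_cdc <- cdc_statistic(obs, e)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sims <- stats::rmultinom(n_boot, size = n, prob = e) # 61 x n_boot
  sim_cdc <- 1 - (crossprod(sims, e) /
                    (sqrt(colSums(sims^2)) * sqrt(sum(e^2))))[, 1]
  (1 + sum(sim_cdc >= observed_cdc)) / (n_boot + 1)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Classify a CDC value into the five bias ranks
#'
#' Thresholds: low (< 0.10), medium-low (0.10-0.13), medium (0.13-0.16),
#' medium-high (0.16-0.19), high (> 0.19). Intervals are treated as
#' left-closed / right-open, so a value of exactly 0.19 is `high`.
#'
#' @param cdc numeric vector of CDC values in \[0,1\]
#' @return factor with levels low, medium-low, medium, medium-high, high
#' @export
assign_cub_rank <- function(cdc) {
  if (any(cdc < 0 | cdc > 1, na.rm = TRUE)) stop("cdc values must lie in [0,1]")
  labs <- c("low", "medium-low", "medium", "medium-high", "high")
  cut(cdc, breaks = c(-Inf, 0.10, 0.13, 0.16, 0.19, Inf),
      labels = labs, right = FALSE)
}

#' Score codon usage bias for a set of coding sequences
#'
#' The per-gene CUB table: CDC, bootstrap P-value, positional GC, and bias
#' rank. Each gene's background expectation is built from its own positional
#' composition, so no reference gene set is involved. Per-gene bootstrap
#' seeds are derived deterministically from `seed`.
#'
#' @param seqs named character vector of valid CDS (see [read_cds_fasta()])
#' @param n_boot bootstrap replicates per gene (default 1000)
#' @param seed integer master seed
#' @param exclude_stops exclude stop codons from composition (default TRUE)
#' @return data.frame: gene_id, n_codons, cdc, p_value, gc1..gc3, cub_rank
#' @export
cub_score <- function(seqs, n_boot = 1000L, seed, exclude_stops = TRUE) {
  if (missing(seed)) stop("a seed is required")
  cm <- count_codons_matrix(seqs)
  gene_seeds <- derive_seeds(seed, nrow(cm))
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    cc <- stats::setNames(cm[i, ], colnames(cm))
    comp <- positional_composition(cc, exclude_stops = exclude_stops)
    e <- expected_codon_usage(comp)
    cdc <- cdc_statistic(cc, e)
    p <- cdc_pvalue(cc, e, n_boot = n_boot, seed = gene_seeds[i])
    data.frame(gene_id = rownames(cm)[i], n_codons = comp$n_codons,
               cdc = cdc, p_value = p,
               gc1 = comp$gc[1], gc2 = comp$gc[2], gc3 = comp$gc[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$cub_rank <- assign_cub_rank(out$cdc)
  out
}

#' Derive a stream of per-unit seeds from one master seed
#'
#' @param seed master integer seed
#' @param n how many seeds
#' @return integer vector of n seeds, all below 2^31
#' @export
derive_seeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
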