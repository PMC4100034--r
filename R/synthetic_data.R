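# Synthetic data with the statistical structure the analysis assumes: coding
# sequences with a tunable bias toward a designated optimal-codon set, an
# RPKM matrix with EIG / EVG / TS / intermediate-breadth blocks, and an
# hg19-like tRNA copy-number fixture. Every generator is deterministic given
# its seed and exports per-gene ground truth for recovery tests.

# Average human-like amino-acid composition (percent), shipped as a constant
# so synthetic family sample sizes are realistic without external data.
AA_COMPOSITION <- c(
  A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1, G = 6.6,
  H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7, P = 6.3, S = 8.3,
  T = 5.4, W = 1.2, Y = 2.7, V = 6.0
) / 100

#' Generator configuration
#'
#' Defaults define the package's reference synthetic scenario: a 10-tissue
#' panel with 200 EIG, 800 EVG, 30 TS genes per tissue and 200
#' intermediate-breadth genes; EIG expression high and consistent
#' (lognormal, across-tissue sigma 0.2 on the log scale, median RPKM ~145),
#' EVG expression variable (sigma 1.2, median ~20); gene lengths lognormal
#' around ~400 codons; codon bias beta coupled to expression level in EIGs
#' only (the translational-selection signal under study), constant
#' elsewhere.
#'
#' @param n_eig,n_evg,n_ts_per_tissue,n_other class sizes
#' @param tissues tissue names (default: the 10-tissue human panel)
#' @param len_meanlog,len_sdlog,len_min gene length in codons (lognormal)
#' @param eig_median,eig_spread median RPKM and between-gene log-sd for EIG
#' @param evg_median,evg_spread same for EVG
#' @param ts_median,ts_spread same for TS and intermediate genes
#' @param sigma_eig,sigma_evg across-tissue log-sd (EIG consistent, EVG
#'   variable; must satisfy sigma_eig < sigma_evg)
#' @param beta_rule function(class, mean_level) -> beta in \[0,1\]; the
#'   default couples beta to log10 expression in EIGs only
#' @param expressed_threshold RPKM threshold for an expressed call
#' @param seed integer seed (mandatory)
#' @return config list
#' @export
generator_config <- function(n_eig = 200L, n_evg = 800L,
                             n_ts_per_tissue = 30L, n_other = 200L,
                             tissues = c("testis", "brain", "adipose",
                                         "colon", "heart", "breast",
                                         "kidney", "liver", "lymph_node",
                                         "skeletal_muscle"),
                             len_meanlog = log(400), len_sdlog = 0.35,
                             len_min = 100L,
                             eig_median = 145, eig_spread = 0.8,
                             evg_median = 20, evg_spread = 1.2,
                             ts_median = 10, ts_spread = 1.0,
                             sigma_eig = 0.2, sigma_evg = 1.2,
                             beta_rule = default_beta_rule,
                             expressed_threshold = 0, seed) {
  if (missing(seed)) stop("the generator requires a seed")
  stopifnot(sigma_eig < sigma_evg, length(tissues) >= 2L)
  as.list(environment())
}

#' Default bias-to-expression coupling
#'
#' Beta (the probability mass shifted toward the optimal codon within each
#' synonymous family) increases log-linearly with mean expression in EIGs
#' only. EVG, TS and intermediate genes get expression-independent beta with
#' gene-to-gene scatter spanning the bias-rank range, so every class
#' populates all CUB ranks while only EIGs carry a CUB-expression
#' correlation. The rule is called inside the generator's seeded RNG stream,
#' so the scatter is reproducible.
#'
#' @param class gene class label
#' @param mean_level per-gene mean RPKM
#' @return beta in \[0,1\]
#' @export
default_beta_rule <- function(class, mean_level) {
  b <- 0.10 + 0.25 * (log10(pmax(mean_level, 1)) - 1)
  other <- class != "EIG"
  b[other] <- stats::runif(sum(other), 0.05, 0.55)
  pmin(pmax(b, 0), 1)
}

#' Synthetic hg19-like tRNA copy-number fixture
#'
#' A per-codon tRNA gene copy-number table shaped like a GtRNAdb codon
#' summary. Copy numbers are synthetic but hg19-like, chosen so the
#' optimal-codon rule produces the reference outcomes used throughout the
#' package: a two-way tie in the Glu family (excluded), a unique GC-ending
#' optimal codon for each of the other 17 analyzed amino acids, and ADAT
#' (inosine-34) credit deciding Ile/Thr/Ser/Arg/Ala/Pro. The `adat` flag
#' marks every A34 tRNA of the eight ADAT-substrate amino acids.
#'
#' @return data.frame: codon, anticodon, copies, adat
#' @export
trna_fixture <- function() {
  copies_by_anticodon <- c(
    # Ala            Arg
    AGC = 25, CGC = 4, TGC = 9, GGC = 0,
    ACG = 7, CCG = 4, GCG = 0, TCG = 6, CCT = 5, TCT = 6,
    # Asn        Asp        Cys
    GTT = 32, ATT = 0, GTC = 19, ATC = 0, GCA = 30, ACA = 0,
    # Gln        Glu (tied)
    CTG = 20, TTG = 11, CTC = 8, TTC = 8,
    # Gly
    GCC = 15, CCC = 7, TCC = 9, ACC = 0,
    # His        Ile
    GTG = 11, ATG = 0, AAT = 14, GAT = 3, TAT = 5,
    # Leu
    AAG = 9, CAG = 11, GAG = 0, TAG = 3, CAA = 7, TAA = 4,
    # Lys        Met      Phe
    CTT = 17, TTT = 16, CAT = 20, GAA = 12, AAA = 0,
    # Pro
    AGG = 10, CGG = 4, GGG = 0, TGG = 7,
    # Ser
    AGA = 11, GGA = 0, TGA = 5, CGA = 4, GCT = 8, ACT = 0,
    # Thr
    AGT = 10, CGT = 6, GGT = 0, TGT = 6,
    # Trp      Tyr
    CCA = 9, GTA = 14, ATA = 1,
    # Val
    AAC = 11, CAC = 16, GAC = 0, TAC = 7
  )
  anticodon <- revcomp_codon(SENSE_CODONS)
  tab <- data.frame(
    codon = SENSE_CODONS,
    anticodon = anticodon,
    copies = as.integer(copies_by_anticodon[anticodon]),
    adat = substr(anticodon, 1, 1) == "A" &
      SENSE_AA %in% ADAT_AMINO_ACIDS,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  validate_trna_table(tab)
}

#' Write a tRNA table to TSV
#' @param tab tRNA table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trna_table <- function(tab, path) {
  tab$adat <- as.integer(tab$adat)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic RPKM matrix with class structure
#'
#' EIG rows: lognormal around a high per-gene mean with small across-tissue
#' sigma; EVG rows: lognormal with large sigma; TS rows: positive in exactly
#' one tissue; intermediate rows: positive in 2..(n_tissues-1) tissues. Class
#' mean levels are ordered EIG >= EVG >= TS by default.
#'
#' @param config from [generator_config()]
#' @return list: `rpkm` (matrix genes x tissues) and `truth` (data.frame
#'   gene_id, class, ts_tissue, breadth, mean_level, beta)
#' @export
generate_expression <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  tissues <- config$tissues
  nt <- length(tissues)
  n_ts <- config$n_ts_per_tissue * nt
  n <- config$n_eig + config$n_evg + n_ts + config$n_other
  gene_id <- sprintf("g%05d", seq_len(n))
  class <- rep(c("EIG", "EVG", "TS", "other"),
               c(config$n_eig, config$n_evg, n_ts, config$n_other))
  ts_tissue <- rep(NA_character_, n)
  ts_tissue[class == "TS"] <- rep(tissues, each = config$n_ts_per_tissue)

  mean_level <- numeric(n)
  mean_level[class == "EIG"] <- stats::rlnorm(config$n_eig,
                                              log(config$eig_median),
                                              config$eig_spread)
  mean_level[class == "EVG"] <- stats::rlnorm(config$n_evg,
                                              log(config$evg_median),
                                              config$evg_spread)
  mean_level[class %in% c("TS", "other")] <-
    stats::rlnorm(n_ts + config$n_other, log(config$ts_median),
                  config$ts_spread)

  rpkm <- matrix(0, n, nt, dimnames = list(gene_id, tissues))
  for (i in seq_len(n)) {
    sig <- switch(class[i], EIG = config$sigma_eig, EVG = config$sigma_evg,
                  config$ts_spread)
    vals <- mean_level[i] * stats::rlnorm(nt, 0, sig)
    if (class[i] == "TS") {
      keep <- match(ts_tissue[i], tissues)
      rpkm[i, keep] <- vals[keep]
    } else if (class[i] == "other") {
      breadth <- sample(2:(nt - 1L), 1L)
      keep <- sample(nt, breadth)
      rpkm[i, keep] <- vals[keep]
    } else {
      rpkm[i, ] <- vals
    }
  }
  beta <- config$beta_rule(class, mean_level)
  truth <- data.frame(gene_id = gene_id, class = class, ts_tissue = ts_tissue,
                      breadth = as.integer(
                        rowSums(rpkm > config$expressed_threshold)),
                      mean_level = mean_level, beta = beta,
                      stringsAsFactors = FALSE)
  list(rpkm = rpkm, truth = truth)
}

#' Generate synthetic coding sequences with optimal-codon bias
#'
#' Per gene, an amino-acid sequence is drawn from a fixed average
#' composition; each residue's codon is the family's optimal codon with
#' probability beta and uniform within the family otherwise (families without
#' a defined optimal codon are always uniform). A terminal TAA stop is
#' appended, so every sequence satisfies the CDS invariants by construction.
#'
#' @param beta per-gene bias in \[0,1\], named by gene id
#' @param config from [generator_config()] (lengths and seed)
#' @param optimal optimal-codon set (default: from [trna_fixture()])
#' @return named character vector of CDS
#' @export
generate_cds <- function(beta, config, optimal = NULL) {
  stopifnot(all(beta >= 0 & beta <= 1), !is.null(names(beta)))
  if (is.null(optimal)) optimal <- identify_optimal_codons(trna_fixture())
  opt_map <- stats::setNames(optimal$optimal$codon,
                             optimal$optimal$amino_acid)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  n <- length(beta)
  lens <- pmax(config$len_min,
               round(stats::rlnorm(n, config$len_meanlog, config$len_sdlog)))
  fam_codons <- split(SENSE_CODONS, SENSE_AA)
  seqs <- character(n)
  for (i in seq_len(n)) {
    aa <- sample(names(AA_COMPOSITION), lens[i], replace = TRUE,
                 prob = AA_COMPOSITION)
    codons <- character(lens[i])
    for (a in unique(aa)) {
      idx <- which(aa == a)
      fam <- fam_codons[[a]]
      picked <- fam[sample.int(length(fam), length(idx), replace = TRUE)]
      if (!is.na(opt_map[a]) && beta[i] > 0) {
        use_opt <- stats::runif(length(idx)) < beta[i]
        picked[use_opt] <- opt_map[a]
      }
      codons[idx] <- picked
    }
    seqs[i] <- paste0(paste(codons, collapse = ""), "TAA")
  }
  stats::setNames(seqs, names(beta))
}

#' Generate the full synthetic dataset
#'
#' Expression matrix, coupled coding sequences, tRNA fixture and ground
#' truth, all deterministic under the config seed.
#'
#' @param config from [generator_config()]
#' @return list: seqs, rpkm, trna, truth
#' @export
generate_dataset <- function(config) {
  expr <- generate_expression(config)
  beta <- stats::setNames(expr$truth$beta, expr$truth$gene_id)
  trna <- trna_fixture()
  seqs <- generate_cds(beta, config,
                       optimal = identify_optimal_codons(trna))
  list(seqs = seqs, rpkm = expr$rpkm, trna = trna, truth = expr$truth)
}
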