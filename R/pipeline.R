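# End-to-end orchestration: score CUB from FASTA, classify expression
# patterns from the RPKM matrix, compute group RSCU against the optimal-codon
# set, and run the association statistics — all on the intersection of gene
# ids, with the CUB significance filter applied exactly once.

#' Build a pipeline configuration
#'
#' @param fasta path to the CDS FASTA
#' @param rpkm path to the genes x tissues RPKM TSV
#' @param trna path to the tRNA copy-number TSV
#' @param out_dir output directory for the TSV reports
#' @param p_cut CUB bootstrap P-value filter (default 0.05)
#' @param expressed_threshold RPKM expressed-call threshold (default 0)
#' @param n_boot bootstrap replicates per gene (default 1000)
#' @param n_bins,k,cv_cut EIG/EVG clustering parameters
#' @param seed master seed (mandatory)
#' @return config list
#' @export
pipeline_config <- function(fasta, rpkm, trna, out_dir,
                            p_cut = 0.05, expressed_threshold = 0,
                            n_boot = 1000L, n_bins = 1001L, k = 10L,
                            cv_cut = 0.25, seed) {
  if (missing(seed)) stop("a seed is required")
  as.list(environment())
}

#' Validate a pipeline configuration
#'
#' Checks input files, thresholds, and seed presence without mutating any
#' state.
#'
#' @param config from [pipeline_config()]
#' @return character vector of problems (empty when the config is valid)
#' @export
validate_config <- function(config) {
  problems <- character(0)
  for (f in c("fasta", "rpkm", "trna")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      problems <- c(problems, paste0("missing input file: ", f))
  }
  if (is.null(config$seed)) problems <- c(problems, "seed is required")
  if (!is.null(config$p_cut) && (config$p_cut <= 0 || config$p_cut > 1))
    problems <- c(problems, "p_cut must be in (0, 1]")
  if (!is.null(config$n_boot) && config$n_boot < 100)
    problems <- c(problems, "n_boot must be >= 100")
  if (!is.null(config$expressed_threshold) && config$expressed_threshold < 0)
    problems <- c(problems, "expressed_threshold must be >= 0")
  problems
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Scores CUB for every valid CDS, classifies expression patterns, restricts
#' downstream analyses to the id intersection of FASTA and matrix with the
#' CUB P-value filter applied exactly once (before/after counts logged),
#' computes per-class high-CUB RSCU against the optimal-codon set, and runs
#' the class / breadth correlations, rank trend and GC3 analyses. Writes
#' cub.tsv, classes.tsv, rscu.tsv, optimal_codons.tsv, correlations.tsv,
#' breadth_correlations.tsv, contrasts.tsv and summary.txt to `out_dir`
#' (when set), and returns everything invisibly as a list.
#'
#' @param config from [pipeline_config()]
#' @param quiet suppress progress messages
#' @return list: cub, classes, optimal, rscu (long data.frame), comparison,
#'   correlations, breadth_correlations, rank_trend, gc3, filtered_genes,
#'   counts
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  problems <- validate_config(config)
  if (length(problems) > 0L)
    stop("invalid config:\n", paste(" -", problems, collapse = "\n"))
  say <- function(...) if (!quiet) message(...)

  seqs <- read_cds_fasta(config$fasta, quiet = quiet)
  m <- read_expression_matrix(config$rpkm)
  trna <- read_trna_table(config$trna)

  shared <- intersect(names(seqs), rownames(m))
  if (length(shared) == 0L)
    stop("no gene ids shared between FASTA and expression matrix")
  say(length(shared), " genes shared between FASTA (", length(seqs),
      ") and matrix (", nrow(m), ")")
  seqs <- seqs[shared]
  m <- m[shared, , drop = FALSE]

  cub <- cub_score(seqs, n_boot = config$n_boot, seed = config$seed)
  n_before <- nrow(cub)
  keep <- cub$p_value < config$p_cut
  say("CUB P < ", config$p_cut, " filter: ", sum(keep), " of ", n_before,
      " genes retained")
  cub_f <- cub[keep, ]

  classes <- classify_expression(m, threshold = config$expressed_threshold,
                                 n_bins = config$n_bins, k = config$k,
                                 cv_cut = config$cv_cut)
  classes_f <- classes[classes$gene_id %in% cub_f$gene_id, ]

  optimal <- identify_optimal_codons(trna)
  counts_m <- count_codons_matrix(seqs)
  high <- cub_f$gene_id[cub_f$cub_rank == "high"]
  groups <- list()
  for (lab in c("EIG", "EVG", "TS")) {
    g <- intersect(high, classes_f$gene_id[classes_f$label == lab])
    if (length(g) > 0L)
      groups[[lab]] <- compute_rscu(counts_m[g, , drop = FALSE])
  }
  comparison <- if (length(groups) >= 2L)
    compare_optimal_usage(groups, optimal) else NULL

  correlations <- class_correlations(cub_f, m, classes_f)
  breadth_cors <- breadth_stratified_correlations(cub_f, m, classes_f)
  trend <- rank_trend(cub_f, m, colnames(m)[1])
  gc3 <- gc3_analyses(cub_f, m, colnames(m)[1],
                      genes = classes_f$gene_id[classes_f$label == "EIG"])

  result <- list(
    cub = cub, classes = classes, optimal = optimal, rscu_groups = groups,
    comparison = comparison, correlations = correlations,
    breadth_correlations = breadth_cors, rank_trend = trend, gc3 = gc3,
    filtered_genes = cub_f$gene_id,
    counts = c(shared = length(shared), cub_scored = n_before,
               cub_pass = sum(keep))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    o <- function(f) file.path(config$out_dir, f)
    write_tsv(cub, o("cub.tsv"))
    write_tsv(classes, o("classes.tsv"))
    write_tsv(optimal$optimal, o("optimal_codons.tsv"))
    rscu_long <- do.call(rbind, lapply(names(groups), function(g) {
      tab <- groups[[g]]
      tab$is_optimal <- tab$codon %in% optimal$optimal$codon
      cbind(group_id = g, tab)
    }))
    if (!is.null(rscu_long)) write_tsv(rscu_long, o("rscu.tsv"))
    write_tsv(correlations, o("correlations.tsv"))
    write_tsv(breadth_cors, o("breadth_correlations.tsv"))
    if (!is.null(comparison)) {
      write_tsv(comparison$exceedance, o("contrasts.tsv"))
      write_tsv(comparison$preferential, o("preferential.tsv"))
    }
    writeLines(pipeline_summary(result), o("summary.txt"))
  }
  invisible(result)
}

pipeline_summary <- function(result) {
  cls <- table(result$classes$label)
  cors <- result$correlations
  med_r <- tapply(cors$r, cors$class, stats::median, na.rm = TRUE)
  c(sprintf("genes shared: %d; CUB scored: %d; CUB P-filter pass: %d",
            result$counts["shared"], result$counts["cub_scored"],
            result$counts["cub_pass"]),
    sprintf("classes: %s",
            paste(names(cls), as.integer(cls), sep = "=", collapse = ", ")),
    sprintf("median CUB-expression r by class: %s",
            paste(names(med_r), round(med_r, 3), sep = "=", collapse = ", ")),
    sprintf("optimal codons: %d amino acids included, %d excluded (%s)",
            nrow(result$optimal$optimal), nrow(result$optimal$excluded),
            paste(result$optimal$excluded$amino_acid, collapse = ",")))
}
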