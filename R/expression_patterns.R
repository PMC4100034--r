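# Classification of genes by expression pattern from a genes x tissues RPKM
# matrix: tissue-specific (TS) genes are expressed in exactly one tissue;
# ubiquitously expressed genes are split into expression-invariable (EIG, the
# strict housekeeping definition) and expression-variable (EVG) by clustering
# their per-tissue relative-expression rank profiles.

#' Read a genes x tissues RPKM matrix from TSV
#'
#' First column must be the gene id; remaining columns are tissue RPKM.
#'
#' @param path TSV path
#' @return numeric matrix, rownames = gene ids, colnames = tissues
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  validate_expression_matrix(m)
}

validate_expression_matrix <- function(m) {
  if (ncol(m) < 2L) stop("expression matrix needs at least 2 tissues")
  if (any(m < 0)) stop("negative RPKM values")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  storage.mode(m) <- "double"
  m
}

#' Expression breadth per gene
#'
#' Number of tissues in which a gene is expressed, i.e. RPKM strictly above
#' the threshold. The strict reading of "expressed" is RPKM > 0 (default).
#'
#' @param m RPKM matrix (genes x tissues)
#' @param threshold expressed-call threshold (default 0)
#' @return named integer vector of breadths
#' @export
expression_breadth <- function(m, threshold = 0) {
  stopifnot(threshold >= 0)
  rowSums(m > threshold)
}

#' Relative-expression rank profiles
#'
#' Per tissue, maps each gene's RPKM to a quantile-bin rank in 1..n_bins
#' (default 1001 bins), giving a relative-expression profile that is
#' comparable across tissues with different RPKM scales.
#'
#' @param m RPKM matrix restricted to the genes of interest
#' @param n_bins number of quantile bins (default 1001)
#' @return integer matrix of ranks, same shape as `m`
#' @keywords internal
rank_profiles <- function(m, n_bins = 1001L) {
  apply(m, 2, function(x) {
    r <- rank(x, ties.method = "average")
    as.integer(ceiling(r / length(x) * n_bins))
  })
}

#' Classify ubiquitously expressed genes into EIG and EVG
#'
#' Genes expressed in all tissues are assigned a per-gene across-tissue
#' dispersion, hierarchically clustered on it (Euclidean distance, average
#' linkage), and the tree is cut into `k` clusters. Clusters whose median
#' dispersion falls below `cv_cut` are labelled EIG (expression-invariable);
#' the rest are EVG. Deterministic; identical expression rows always share a
#' label.
#'
#' Two dispersion measures are available. The default, `"log_sd"`, is the
#' standard deviation of log10 RPKM across tissues: it estimates the
#' multiplicative across-tissue variability directly and does not saturate
#' for genes at extreme expression levels. `"rank_cv"` is the coefficient of
#' variation of the gene's per-tissue quantile-bin ranks (relative expression
#' binned into `n_bins` levels per tissue); note that rank profiles compress
#' at the top and bottom of the expression range, so consistently extreme
#' but variable genes can look invariable under this measure.
#'
#' @param m RPKM matrix restricted to ubiquitously expressed genes (all
#'   entries above the expressed threshold, hence strictly positive)
#' @param n_bins quantile bins for relative expression (default 1001; used
#'   by the `"rank_cv"` measure)
#' @param k clusters to cut the tree into (default 10)
#' @param cv_cut dispersion below which a cluster is EIG (default 0.25, in
#'   the units of the chosen measure)
#' @param dispersion `"log_sd"` (default) or `"rank_cv"`
#' @return character vector ("EIG"/"EVG") named by gene id
#' @export
classify_eig_evg <- function(m, n_bins = 1001L, k = 10L, cv_cut = 0.25,
                             dispersion = c("log_sd", "rank_cv")) {
  dispersion <- match.arg(dispersion)
  if (nrow(m) < 2L) stop("need at least 2 ubiquitously expressed genes")
  if (nrow(m) < k) stop("fewer genes than clusters requested")
  d <- if (dispersion == "log_sd") {
    if (any(m <= 0)) stop("log_sd dispersion requires strictly positive RPKM")
    apply(log10(m), 1, stats::sd)
  } else {
    rk <- rank_profiles(m, n_bins = n_bins)
    apply(rk, 1, function(x) stats::sd(x) / mean(x))
  }
  hc <- stats::hclust(stats::dist(d), method = "average")
  cl <- stats::cutree(hc, k = k)
  cluster_d <- tapply(d, cl, stats::median)
  lab <- ifelse(cluster_d[as.character(cl)] < cv_cut, "EIG", "EVG")
  stats::setNames(unname(lab), rownames(m))
}

#' Classify genes by expression pattern
#'
#' Full classification of an RPKM matrix: breadth-1 genes are TS (with the
#' expressing tissue recorded), genes expressed in all tissues are split into
#' EIG/EVG by [classify_eig_evg()], genes of intermediate breadth (and
#' breadth 0) are labelled `other` and retained with their breadth for
#' breadth-stratified analyses.
#'
#' @param m RPKM matrix (genes x tissues)
#' @param threshold expressed-call threshold (default 0)
#' @param n_bins,k,cv_cut,dispersion passed to [classify_eig_evg()]
#' @return data.frame: gene_id, breadth, label (EIG/EVG/TS/other), ts_tissue
#' @export
classify_expression <- function(m, threshold = 0, n_bins = 1001L, k = 10L,
                                cv_cut = 0.25, dispersion = "log_sd") {
  m <- validate_expression_matrix(m)
  br <- expression_breadth(m, threshold)
  nt <- ncol(m)
  label <- rep("other", nrow(m))
  ts_tissue <- rep(NA_character_, nrow(m))

  is_ts <- br == 1L
  label[is_ts] <- "TS"
  ts_tissue[is_ts] <- colnames(m)[apply(m[is_ts, , drop = FALSE], 1,
                                        function(x) which(x > threshold))]

  ubiq <- br == nt
  if (sum(ubiq) >= 2L) {
    ee <- classify_eig_evg(m[ubiq, , drop = FALSE], n_bins = n_bins,
                           k = min(k, sum(ubiq)), cv_cut = cv_cut,
                           dispersion = dispersion)
    label[ubiq] <- ee[rownames(m)[ubiq]]
  }
  data.frame(gene_id = rownames(m), breadth = as.integer(br), label = label,
             ts_tissue = ts_tissue, stringsAsFactors = FALSE)
}

#' Top-n genes of a class by maximum RPKM across tissues
#'
#' Implements the "highest RPKM among the tissues" ranking used to select the
#' most highly expressed genes of a class. Ties at the boundary are broken by
#' lexicographic gene id, so the selection is deterministic.
#'
#' @param m RPKM matrix
#' @param genes gene ids of the class to rank
#' @param n how many genes to keep
#' @return character vector of n gene ids
#' @export
top_n_by_max_rpkm <- function(m, genes, n) {
  genes <- intersect(genes, rownames(m))
  if (n > length(genes)) stop("n exceeds the class size")
  mx <- apply(m[genes, , drop = FALSE], 1, max)
  ord <- order(-mx, genes)
  genes[ord][seq_len(n)]
}
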