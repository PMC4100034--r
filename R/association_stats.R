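# The statistical comparison suite: CUB-expression correlations per class /
# tissue / breadth, bias-rank trends, Wilcoxon group contrasts, and the GC3
# analyses. Raw P-values are reported with the conventional star annotation
# ('*' < 0.05, '**' < 1e-3, '***' < 1e-10); no multiple-testing correction.

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 1e-10, "***", ifelse(p < 1e-3, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

#' Correlate codon usage bias with expression level
#'
#' Pearson (default) or Spearman correlation between per-gene CDC and log10
#' RPKM in one tissue, over a given gene subset. Genes with RPKM = 0 in the
#' tissue are excluded from that tissue's correlation (no pseudo-counts).
#' For Pearson, the P-value is the regression F-test of the linear fit
#' (equivalent to the two-sided t-test on r).
#'
#' @param cub CUB table from [cub_score()] (gene_id, cdc, ...)
#' @param m RPKM matrix
#' @param tissue tissue (column) name
#' @param genes gene ids defining the subset (default: all genes in `cub`)
#' @param method "pearson" or "spearman"
#' @return one-row data.frame: tissue, method, n, r, p, stars (r/p are NA
#'   with n recorded when fewer than 3 usable genes)
#' @export
correlate_cub_expression <- function(cub, m, tissue, genes = cub$gene_id,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  genes <- intersect(intersect(genes, cub$gene_id), rownames(m))
  expr <- m[genes, tissue]
  keep <- expr > 0
  genes <- genes[keep]
  x <- cub$cdc[match(genes, cub$gene_id)]
  y <- log10(expr[keep])
  n <- length(genes)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(tissue = tissue, method = method, n = n,
                      r = NA_real_, p = NA_real_, stars = "",
                      stringsAsFactors = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  data.frame(tissue = tissue, method = method, n = n,
             r = unname(ct$estimate), p = ct$p.value,
             stars = p_stars(ct$p.value), stringsAsFactors = FALSE)
}

#' Per-class, per-tissue correlation table
#'
#' One CUB-expression correlation per (class, tissue) pair, mirroring the
#' per-panel layout of a class x tissue correlation figure. Only genes whose
#' CUB passes the significance filter should be passed in.
#'
#' @param cub CUB table
#' @param m RPKM matrix
#' @param classes classification from [classify_expression()]
#' @param labels which labels to report (default EIG, EVG, TS)
#' @param method correlation method
#' @return data.frame: class, tissue, method, n, r, p, stars. TS genes are
#'   correlated only within their own tissue.
#' @export
class_correlations <- function(cub, m, classes,
                               labels = c("EIG", "EVG", "TS"),
                               method = "pearson") {
  rows <- list()
  for (lab in labels) {
    if (lab == "TS") {
      for (tis in colnames(m)) {
        g <- classes$gene_id[classes$label == "TS" &
                               classes$ts_tissue == tis]
        r <- correlate_cub_expression(cub, m, tis, g, method)
        rows[[length(rows) + 1L]] <- cbind(class = paste0("TS(", tis, ")"), r)
      }
    } else {
      g <- classes$gene_id[classes$label == lab]
      for (tis in colnames(m)) {
        r <- correlate_cub_expression(cub, m, tis, g, method)
        rows[[length(rows) + 1L]] <- cbind(class = lab, r)
      }
    }
  }
  do.call(rbind, rows)
}

#' Breadth-stratified CUB-expression correlations
#'
#' One correlation per (tissue, breadth) over the genes of that breadth that
#' are expressed in that tissue. Strata with fewer than 3 usable genes are
#' reported with NA.
#'
#' @param cub CUB table
#' @param m RPKM matrix
#' @param classes classification table (provides breadth)
#' @param method correlation method
#' @return data.frame: breadth, tissue, method, n, r, p, stars
#' @export
breadth_stratified_correlations <- function(cub, m, classes,
                                            method = "pearson") {
  rows <- list()
  for (b in sort(unique(classes$breadth))) {
    if (b == 0L) next
    g <- classes$gene_id[classes$breadth == b]
    for (tis in colnames(m)) {
      r <- correlate_cub_expression(cub, m, tis, g, method)
      rows[[length(rows) + 1L]] <- cbind(breadth = b, r)
    }
  }
  do.call(rbind, rows)
}

#' Expression-level trend across bias ranks
#'
#' Median log10 RPKM per CUB rank plus a two-sided rank-sum test between each
#' adjacent pair of ranks. Genes with zero RPKM in the tissue are excluded.
#'
#' @param cub CUB table (must contain cub_rank)
#' @param m RPKM matrix
#' @param tissue tissue used for the expression level
#' @return list with `summary` (rank, n, median_log10_rpkm) and
#'   `adjacent` (rank_a, rank_b, p, stars); empty ranks are skipped
#' @export
rank_trend <- function(cub, m, tissue) {
  genes <- intersect(cub$gene_id, rownames(m))
  expr <- m[genes, tissue]
  keep <- expr > 0
  genes <- genes[keep]
  y <- log10(expr[keep])
  # coerce to the canonical rank order; tables reloaded from TSV arrive as
  # plain character
  levs <- c("low", "medium-low", "medium", "medium-high", "high")
  rk <- factor(as.character(cub$cub_rank[match(genes, cub$gene_id)]),
               levels = levs)
  if (anyNA(rk)) stop("cub_rank contains values outside the five ranks")
  summ <- data.frame(rank = levs,
                     n = as.integer(table(rk)[levs]),
                     median_log10_rpkm = as.numeric(
                       tapply(y, rk, stats::median)[levs]),
                     stringsAsFactors = FALSE)
  present <- levs[summ$n > 0]
  adj <- list()
  if (length(present) >= 2L) {
    for (i in seq_len(length(present) - 1L)) {
      a <- present[i]; b <- present[i + 1L]
      gc <- group_contrast(y[rk == a], y[rk == b])
      adj[[i]] <- data.frame(rank_a = a, rank_b = b, p = gc$p,
                             stars = p_stars(gc$p), stringsAsFactors = FALSE)
    }
  }
  list(summary = summ, adjacent = do.call(rbind, adj))
}

#' Two-sided rank-sum contrast between two groups
#'
#' Mann-Whitney / Wilcoxon rank-sum test: exact enumeration over all
#' combinations (ties handled by mid-ranks) when both groups have at most 8
#' observations, normal approximation with tie correction otherwise. Also
#' reports which group has the larger median. If all pooled values are tied
#' the result is P = 1 with no direction.
#'
#' @param a,b numeric vectors (both non-empty)
#' @param exact_max exact enumeration when max(n_a, n_b) <= this (default 8)
#' @return list: p, larger ("a", "b" or NA), median_a, median_b, n_a, n_b
#' @export
group_contrast <- function(a, b, exact_max = 8L) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  ma <- stats::median(a); mb <- stats::median(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(p = 1, larger = NA_character_, median_a = ma, median_b = mb,
                n_a = length(a), n_b = length(b)))
  }
  if (max(length(a), length(b)) <= exact_max) {
    p <- ranksum_exact_p(a, b)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
  larger <- if (ma > mb) "a" else if (mb > ma) "b" else NA_character_
  list(p = p, larger = larger, median_a = ma, median_b = mb,
       n_a = length(a), n_b = length(b))
}

#' Exact two-sided rank-sum P by enumeration
#'
#' Enumerates every assignment of the pooled mid-ranks to group A (all
#' choose(n_a + n_b, n_a) combinations) and returns the two-sided P-value of
#' the observed rank sum: the probability of a rank sum at least as far from
#' its mean as observed. Handles ties exactly via mid-ranks. Intended for
#' small samples only.
#'
#' @param a,b numeric vectors
#' @return exact two-sided P-value
#' @export
ranksum_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(na + nb, na)
  w_all <- colSums(matrix(r[combos], nrow = na))
  mu <- na * (na + nb + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

#' GC-composition analyses
#'
#' (i) Pearson correlations of GC3 with CDC and of GC3 with expression level
#' (log10 RPKM in `tissue`, zero-RPKM genes excluded) over a gene subset;
#' (ii) rank-sum comparison of GC1/GC2/GC3 between the high-CUB and low-CUB
#' rank groups of the subset.
#'
#' @param cub CUB table (needs cdc, gc1..gc3, cub_rank)
#' @param m RPKM matrix
#' @param tissue tissue for the expression correlation
#' @param genes gene subset (default all)
#' @return list with `correlations` (data.frame pair, n, r, p, stars) and
#'   `gc_contrast` (data.frame position, p, stars, larger, n_high, n_low)
#' @export
gc3_analyses <- function(cub, m, tissue, genes = cub$gene_id) {
  sub <- cub[cub$gene_id %in% genes, ]
  cor_row <- function(x, y, label) {
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(pair = label, n = length(x), r = NA_real_,
                        p = NA_real_, stars = "", stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, y)
    data.frame(pair = label, n = length(x), r = unname(ct$estimate),
               p = ct$p.value, stars = p_stars(ct$p.value),
               stringsAsFactors = FALSE)
  }
  cors <- cor_row(sub$gc3, sub$cdc, "gc3_vs_cdc")
  g2 <- intersect(sub$gene_id, rownames(m))
  expr <- m[g2, tissue]
  keep <- expr > 0
  cors <- rbind(cors, cor_row(sub$gc3[match(g2[keep], sub$gene_id)],
                              log10(expr[keep]), "gc3_vs_expression"))
  hi <- sub[sub$cub_rank == "high", ]
  lo <- sub[sub$cub_rank == "low", ]
  contr <- NULL
  if (nrow(hi) > 0L && nrow(lo) > 0L) {
    contr <- do.call(rbind, lapply(c("gc1", "gc2", "gc3"), function(col) {
      gc <- group_contrast(hi[[col]], lo[[col]])
      dir <- if (is.na(gc$larger)) NA_character_ else
        c(a = "high", b = "low")[[gc$larger]]
      data.frame(position = col, p = gc$p, stars = p_stars(gc$p),
                 larger = dir,
                 n_high = gc$n_a, n_low = gc$n_b, stringsAsFactors = FALSE)
    }))
  }
  list(correlations = cors, gc_contrast = contr)
}
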