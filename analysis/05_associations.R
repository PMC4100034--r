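#!/usr/bin/env Rscript
# Step 5: association statistics.
#
# For the genes whose CUB is significant: per-class and breadth-stratified
# correlations between CDC and log expression, the expression trend across
# CUB ranks, and GC-content analyses by codon position.
#
# Run after steps 1-4: Rscript analysis/05_associations.R

suppressPackageStartupMessages(library(codonsel))

m <- read_expression_matrix("results/data/rpkm.tsv")
cub <- read.delim("results/cub.tsv", stringsAsFactors = FALSE)
cl <- read.delim("results/classes.tsv", stringsAsFactors = FALSE)

cub_f <- cub[cub$p_value < 0.05, ]
cl_f <- cl[cl$gene_id %in% cub_f$gene_id, ]

cors <- class_correlations(cub_f, m, cl_f)
write.table(cors, "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
med_r <- tapply(cors$r, sub("\\(.*", "", cors$class), median, na.rm = TRUE)
cat("median CDC-expression r by class:\n")
print(round(med_r, 3))

bc <- breadth_stratified_correlations(cub_f, m, cl_f)
write.table(bc, "results/breadth_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tissue <- colnames(m)[1]
trend <- rank_trend(cub_f, m, tissue)
write.table(trend$summary, "results/rank_trend.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(trend$adjacent))
  write.table(trend$adjacent, "results/rank_trend_adjacent.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
cat(sprintf("\nexpression by CUB rank (%s):\n", tissue))
print(trend$summary)
print(trend$adjacent)

gc3 <- gc3_analyses(cub_f, m, tissue,
                    genes = cl_f$gene_id[cl_f$label == "EIG"])
write.table(gc3$correlations, "results/gc3_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(gc3$gc_contrast))
  write.table(gc3$gc_contrast, "results/gc3_contrast.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
cat("\nwrote results/correlations.tsv and companion tables\n")
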