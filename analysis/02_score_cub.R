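#!/usr/bin/env Rscript
# Step 2: score per-gene codon usage bias.
#
# Computes the codon deviation coefficient (CDC) for every valid coding
# sequence against its own positional GC/purine expectation, with a
# parametric bootstrap P-value, and assigns the five-level CUB rank.
#
# Run after 01_simulate.R: Rscript analysis/02_score_cub.R

suppressPackageStartupMessages(library(codonsel))

dir.create("results", showWarnings = FALSE)
seqs <- read_cds_fasta("results/data/cds.fa")

cub <- cub_score(seqs, n_boot = 1000L, seed = 20140602)
write.table(cub, "results/cub.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("scored %d genes; median CDC %.3f; %.1f%% significant at P<0.05\n",
            nrow(cub), median(cub$cdc), 100 * mean(cub$p_value < 0.05)))
print(table(cub$cub_rank))
cat("wrote results/cub.tsv\n")
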