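#!/usr/bin/env Rscript
# Step 4: optimal codons and group RSCU.
#
# Identifies the optimal codon of each amino acid from tRNA gene copy
# numbers (with the inosine-modification credit for the eight ADAT-target
# amino acids), then pools codon counts of the significant high-CUB genes by
# expression class and compares each class's relative synonymous codon usage
# (RSCU) of the optimal codons.
#
# Run after steps 1-3: Rscript analysis/04_rscu_optimal.R

suppressPackageStartupMessages(library(codonsel))

trna <- read_trna_table("results/data/trna.tsv")
seqs <- read_cds_fasta("results/data/cds.fa")
cub <- read.delim("results/cub.tsv", stringsAsFactors = FALSE)
cl <- read.delim("results/classes.tsv", stringsAsFactors = FALSE)

optimal <- identify_optimal_codons(trna)
write.table(optimal$optimal, "results/optimal_codons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d optimal codons, %d GC-ending; excluded: %s\n",
            nrow(optimal$optimal), count_gc_ending(optimal$optimal$codon),
            paste(optimal$excluded$amino_acid, optimal$excluded$reason,
                  sep = ":", collapse = ", ")))

# pooled RSCU of significant high-CUB genes, by expression class
high <- cub$gene_id[cub$p_value < 0.05 & cub$cub_rank == "high"]
cm <- count_codons_matrix(seqs)
groups <- list()
for (lab in c("EIG", "EVG", "TS")) {
  g <- intersect(high, cl$gene_id[cl$label == lab])
  if (length(g) > 0L) groups[[lab]] <- compute_rscu(cm[g, , drop = FALSE])
}
rscu_long <- do.call(rbind, lapply(names(groups), function(g) {
  tab <- groups[[g]]
  tab$is_optimal <- tab$codon %in% optimal$optimal$codon
  cbind(group_id = g, tab)
}))
write.table(rscu_long, "results/rscu.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

if (length(groups) >= 2L) {
  cmp <- compare_optimal_usage(groups, optimal)
  write.table(cmp$exceedance, "results/contrasts.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cmp$preferential, "results/preferential.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  print(cmp$preferential)
}
cat("wrote results/optimal_codons.tsv, results/rscu.tsv\n")
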