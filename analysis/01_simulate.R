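#!/usr/bin/env Rscript
# Step 1: simulate the benchmark dataset.
#
# Generates coding sequences whose codon bias is coupled to expression level
# in the expression-invariant class only, a genes x tissues RPKM matrix with
# known expression-pattern labels, and the tRNA copy-number table. All later
# steps work from the files written here; the ground-truth table is kept for
# evaluation only.
#
# Run from the repository root: Rscript analysis/01_simulate.R

suppressPackageStartupMessages(library(codonsel))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = 20140601)
ds <- generate_dataset(cfg)

write_cds_fasta(ds$seqs, file.path(out, "cds.fa"))
write.table(data.frame(gene_id = rownames(ds$rpkm), ds$rpkm,
                       check.names = FALSE),
            file.path(out, "rpkm.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_trna_table(ds$trna, file.path(out, "trna.tsv"))
write.table(ds$truth, file.path(out, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d genes, %d tissues\n", nrow(ds$rpkm), ncol(ds$rpkm)))
print(table(ds$truth$class))
cat("wrote", out, "\n")
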