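#!/usr/bin/env Rscript
# Step 3: classify expression patterns.
#
# Labels every gene from the RPKM matrix: tissue-specific (expressed in
# exactly one tissue), expression-invariant or expression-variable (the two
# ubiquitous classes, split by clustering the dispersion of log expression),
# or "other". Compares the labels against the simulation ground truth.
#
# Run after 01_simulate.R: Rscript analysis/03_classify_expression.R

suppressPackageStartupMessages(library(codonsel))

dir.create("results", showWarnings = FALSE)
m <- read_expression_matrix("results/data/rpkm.tsv")
truth <- read.delim("results/data/truth.tsv", stringsAsFactors = FALSE)

cl <- classify_expression(m)
write.table(cl, "results/classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth_class <- truth$class[match(cl$gene_id, truth$gene_id)]
cat(sprintf("label recovery vs ground truth: %.1f%%\n",
            100 * mean(cl$label == truth_class)))
print(table(truth = truth_class, called = cl$label))
cat("wrote results/classes.tsv\n")
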