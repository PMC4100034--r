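test_that("RSCU matches the direct formula and marks empty families NA", {
  counts <- setNames(integer(64), names(Biostrings::GENETIC_CODE))
  counts[c("GCA", "GCC", "GCG", "GCT")] <- c(2L, 6L, 0L, 0L)
  tab <- compute_rscu(counts)
  ala <- tab[tab$amino_acid == "A", ]
  expect_equal(ala$rscu[ala$codon == "GCC"], 3.0)
  expect_equal(ala$rscu[ala$codon == "GCA"], 1.0)
  expect_equal(ala$rscu[ala$codon %in% c("GCG", "GCT")], c(0, 0))
  # unobserved families are NA, not 0
  expect_true(all(is.na(tab$rscu[tab$amino_acid == "L"])))
})

test_that("uniform usage within a family gives RSCU 1 everywhere", {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  counts <- setNames(rep(3L, length(sense)), sense)
  tab <- compute_rscu(counts)
  expect_equal(tab$rscu, rep(1, nrow(tab)))
})

test_that("RSCU family sums equal family size on random observed families", {
  set.seed(31)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  for (i in 1:25) {
    counts <- setNames(rpois(length(sense), 4), sense)
    tab <- compute_rscu(counts)
    sums <- tapply(tab$rscu, tab$amino_acid, sum)
    fam <- table(tab$amino_acid)
    observed <- names(sums)[!is.na(sums)]
    expect_equal(as.numeric(sums[observed]), as.numeric(fam[observed]),
                 tolerance = 1e-12)
  }
})

test_that("RSCU is invariant to pooling order and group splitting", {
  set.seed(32)
  seqs <- setNames(vapply(1:8, function(i) random_cds(120), ""),
                   paste0("g", 1:8))
  cm <- count_codons_matrix(seqs)
  whole <- compute_rscu(cm)
  split_sum <- compute_rscu(colSums(cm[1:3, ]) + colSums(cm[4:8, ]))
  shuffled <- compute_rscu(cm[sample(nrow(cm)), ])
  expect_equal(whole, split_sum)
  expect_equal(whole, shuffled)
})

test_that("optimal codons: argmax rule, tie exclusion, single-codon exclusion", {
  trna <- trna_fixture()
  # Phe: cognate of TTC has 12 copies, of TTT has 0 -> TTC optimal
  oc <- identify_optimal_codons(trna)
  expect_equal(oc$optimal$codon[oc$optimal$amino_acid == "F"], "TTC")
  # Glu tied, Met/Trp single-codon
  expect_setequal(oc$excluded$amino_acid, c("E", "M", "W"))
  expect_equal(oc$excluded$reason[oc$excluded$amino_acid == "E"],
               "tied tRNA counts")
  expect_equal(sort(oc$excluded$reason), c("single-codon", "single-codon",
                                           "tied tRNA counts"))
  expect_equal(nrow(oc$optimal), 17L)
  # permutation invariance over row order
  oc2 <- identify_optimal_codons(trna[rev(seq_len(nrow(trna))), ])
  expect_equal(oc$optimal, oc2$optimal)
  # missing codon errors
  expect_error(identify_optimal_codons(trna[-5, ]), "missing")
})

test_that("ADAT reassignment decides the inosine-decoded families", {
  trna <- trna_fixture()
  with_adat <- identify_optimal_codons(trna, adat = TRUE)$optimal
  without <- identify_optimal_codons(trna, adat = FALSE)$optimal
  # Ile: ATC wins only through the A34 (inosine) credit
  expect_equal(with_adat$codon[with_adat$amino_acid == "I"], "ATC")
  expect_equal(without$codon[without$amino_acid == "I"], "ATT")
  # Phe (non-ADAT family) unaffected
  expect_equal(with_adat$codon[with_adat$amino_acid == "F"],
               without$codon[without$amino_acid == "F"])
})

test_that("tRNA table validation catches structural errors", {
  trna <- trna_fixture()
  bad <- trna; bad$anticodon[1] <- "GGG"
  expect_error(validate_trna_table(bad), "reverse complement")
  bad2 <- trna; bad2$copies[2] <- -1
  expect_error(validate_trna_table(bad2), "negative")
  bad3 <- trna; bad3$adat[bad3$codon == "TTT"] <- TRUE # Phe is not ADAT
  expect_error(validate_trna_table(bad3), "adat")
  # round trip through TSV
  path <- tempfile(fileext = ".tsv")
  write_trna_table(trna, path)
  expect_equal(read_trna_table(path), trna)
})

test_that("packaged fixture file matches the in-code table", {
  path <- system.file("extdata", "trna_hg19like_synthetic.tsv",
                      package = "codonsel")
  expect_true(nzchar(path))
  expect_equal(read_trna_table(path), trna_fixture())
})

test_that("GC-ending counts", {
  expect_equal(count_gc_ending(c("AAA", "AAT")), 0L)
  expect_equal(count_gc_ending("GGC"), 1L)
  expect_equal(count_gc_ending(c("GGC", "TTG", "CAA", "ACC")), 3L)
})

test_that("optimal-usage comparison: symmetry and generator ground truth", {
  trna <- trna_fixture()
  optimal <- identify_optimal_codons(trna)
  set.seed(33)
  seqs <- setNames(vapply(1:6, function(i) random_cds(150), ""),
                   paste0("g", 1:6))
  tab <- compute_rscu(count_codons_matrix(seqs))
  # identical tables: no exceedance in either direction
  cmp <- compare_optimal_usage(list(a = tab, b = tab), optimal)
  expect_equal(cmp$exceedance$n_exceed, c(0L, 0L))

  # biased vs unbiased group: the biased group exceeds in every amino acid
  # that carries an optimal codon (17), and prefers all 17 optimal codons
  cfg <- generator_config(n_eig = 0L, n_evg = 0L, n_ts_per_tissue = 0L,
                          n_other = 0L, len_meanlog = log(300), seed = 34)
  beta_hi <- setNames(rep(0.5, 60), sprintf("hi%02d", 1:60))
  beta_lo <- setNames(rep(0.0, 60), sprintf("lo%02d", 1:60))
  hi <- compute_rscu(count_codons_matrix(generate_cds(beta_hi, cfg, optimal)))
  cfg$seed <- 35
  lo <- compute_rscu(count_codons_matrix(generate_cds(beta_lo, cfg, optimal)))
  cmp2 <- compare_optimal_usage(list(hi = hi, lo = lo), optimal)
  ex <- cmp2$exceedance
  expect_equal(ex$n_exceed[ex$group_a == "hi"], 17L)
  expect_equal(ex$n_exceed[ex$group_a == "lo"], 0L)
  pref <- cmp2$preferential
  expect_equal(pref$n_preferential[pref$group == "hi"], 17L)
})
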