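# Shared helpers: tiny in-code fixtures and independent oracles.

# random valid CDS of n_codons sense codons (+ optional terminal stop)
random_cds <- function(n_codons, stop = TRUE) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  body <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  if (stop) paste0(body, "TAA") else body
}

# independent per-triplet tally oracle (loop, no factor/table machinery)
tally_codons_oracle <- function(seq) {
  out <- integer(0)
  for (i in seq(1, nchar(seq), by = 3)) {
    cod <- substr(seq, i, i + 2)
    out[cod] <- if (is.na(out[cod])) 1L else out[cod] + 1L
  }
  out
}

# brute-force positional composition over an explicit codon expansion
composition_oracle <- function(counts) {
  codons <- rep(names(counts), counts)
  gc <- purine <- numeric(3)
  for (k in 1:3) {
    b <- substr(codons, k, k)
    gc[k] <- mean(b %in% c("G", "C"))
    purine[k] <- mean(b %in% c("A", "G"))
  }
  list(gc = gc, purine = purine)
}

# write a temporary FASTA from a named character vector, with line wrapping
write_tmp_fasta <- function(seqs, width = 60) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  for (j in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[j]), con)
    s <- seqs[[j]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  close(con)
  path
}

# exact two-sided rank-sum oracle: enumerate group assignments by bitmask,
# an implementation independent of the package's combn-based enumeration
ranksum_bitmask_oracle <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != na) next
    total <- total + 1L
    w <- sum(r[bits == 1L])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# small default generator scenario for quick tests
small_config <- function(seed, ...) {
  generator_config(n_eig = 40L, n_evg = 120L, n_ts_per_tissue = 4L,
                   n_other = 40L, len_meanlog = log(200), seed = seed, ...)
}
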