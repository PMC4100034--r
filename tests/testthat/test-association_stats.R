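fake_cub <- function(cdc, ids = sprintf("g%03d", seq_along(cdc))) {
  data.frame(gene_id = ids, n_codons = 200L, cdc = cdc, p_value = 0.001,
             gc1 = 0.5, gc2 = 0.5, gc3 = 0.5,
             cub_rank = assign_cub_rank(cdc), stringsAsFactors = FALSE)
}

one_tissue_matrix <- function(rpkm, ids) {
  m <- cbind(t1 = rpkm, t2 = rpkm)
  rownames(m) <- ids
  m
}

test_that("correlation: perfect linearity, anti-monotone, small-sample oracle", {
  cdc <- seq(0.05, 0.23, length.out = 10)
  cub <- fake_cub(cdc)
  m <- one_tissue_matrix(10^(2 * cdc), cub$gene_id)  # log10 rpkm = 2*cdc
  r <- correlate_cub_expression(cub, m, "t1")
  expect_equal(r$r, 1.0, tolerance = 1e-12)
  expect_equal(r$n, 10L)

  anti <- correlate_cub_expression(cub, one_tissue_matrix(
    10^(-cdc), cub$gene_id), "t1", method = "spearman")
  expect_equal(anti$r, -1.0)

  # closed-form covariance oracle on random vectors
  set.seed(51)
  for (i in 1:10) {
    x <- runif(8); y <- runif(8)
    cub2 <- fake_cub(x)
    m2 <- one_tissue_matrix(10^y, cub2$gene_id)
    got <- correlate_cub_expression(cub2, m2, "t1")
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$r, oracle, tolerance = 1e-12)
    # pearson P equals the regression F-test of the linear fit
    f <- summary(lm(y ~ x))$fstatistic
    expect_equal(got$p, pf(f[1], f[2], f[3], lower.tail = FALSE),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("zero-RPKM genes are excluded and tiny strata are undefined", {
  cub <- fake_cub(c(0.05, 0.1, 0.15, 0.2, 0.25))
  rpkm <- c(10, 0, 20, 0, 30)
  m <- one_tissue_matrix(rpkm, cub$gene_id)
  r <- correlate_cub_expression(cub, m, "t1")
  expect_equal(r$n, 3L)
  r2 <- correlate_cub_expression(cub, m, "t1",
                                 genes = cub$gene_id[c(1, 2, 3)])
  expect_equal(r2$n, 2L)          # one of the three has rpkm 0
  expect_true(is.na(r2$r))
})

test_that("pearson r is invariant under positive affine transforms,
           spearman under monotone transforms", {
  set.seed(52)
  x <- runif(30); y <- x + rnorm(30, 0, 0.3)
  cub <- fake_cub(x)
  base <- correlate_cub_expression(cub, one_tissue_matrix(10^y, cub$gene_id),
                                   "t1")
  aff <- correlate_cub_expression(cub, one_tissue_matrix(10^(2 * y + 1),
                                                         cub$gene_id), "t1")
  expect_equal(base$r, aff$r, tolerance = 1e-12)
  sp1 <- correlate_cub_expression(cub, one_tissue_matrix(10^y, cub$gene_id),
                                  "t1", method = "spearman")
  sp2 <- correlate_cub_expression(cub, one_tissue_matrix(10^exp(y),
                                                         cub$gene_id),
                                  "t1", method = "spearman")
  expect_equal(sp1$r, sp2$r, tolerance = 1e-12)
})

test_that("permuted CUB values give correlations centred at zero", {
  set.seed(53)
  x <- runif(200); y <- runif(200)
  rs <- replicate(50, {
    cub <- fake_cub(sample(x))
    correlate_cub_expression(cub, one_tissue_matrix(10^y, cub$gene_id),
                             "t1")$r
  })
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("breadth-stratified correlations recover coupling only at full breadth", {
  set.seed(54)
  nt <- 10; n <- 600
  ids <- sprintf("g%03d", 1:n)
  breadth <- sample(c(3, 6, nt), n, replace = TRUE)
  level <- rlnorm(n, log(50), 1)
  m <- matrix(0, n, nt, dimnames = list(ids, paste0("t", 1:nt)))
  for (i in 1:n) {
    on <- sample(nt, breadth[i])
    m[i, on] <- level[i] * rlnorm(breadth[i], 0, 0.2)
  }
  # CDC coupled to level only for breadth-10 genes
  cdc <- ifelse(breadth == nt,
                0.08 + 0.04 * (log10(level) - mean(log10(level))),
                runif(n, 0.05, 0.15))
  cdc <- pmin(pmax(cdc, 0), 1)
  cub <- fake_cub(cdc, ids)
  classes <- data.frame(gene_id = ids, breadth = breadth,
                        label = "other", ts_tissue = NA_character_,
                        stringsAsFactors = FALSE)
  out <- breadth_stratified_correlations(cub, m, classes)
  r10 <- out$r[out$breadth == nt]
  r_low <- out$r[out$breadth < nt]
  expect_true(all(r10 > 0.5))
  expect_lt(median(abs(r_low), na.rm = TRUE), 0.2)
  # a stratum with fewer than 3 usable genes is undefined
  small <- breadth_stratified_correlations(
    cub[1:2, ], m[1:2, , drop = FALSE],
    classes[1:2, ])
  expect_true(all(is.na(small$r)))
})

test_that("rank trend: monotone coupling gives increasing medians;
           exchangeable ranks give equal medians", {
  set.seed(55)
  cdc <- runif(400, 0.02, 0.3)
  cub <- fake_cub(cdc)
  level <- 10^(1 + 5 * cdc)          # strictly increasing in cdc
  m <- one_tissue_matrix(level, cub$gene_id)
  tr <- rank_trend(cub, m, "t1")
  meds <- tr$summary$median_log10_rpkm[tr$summary$n > 0]
  expect_true(all(diff(meds) > 0))
  expect_true(all(tr$adjacent$p < 0.05))

  flat <- one_tissue_matrix(rep(100, 400), cub$gene_id)
  tr2 <- rank_trend(cub, flat, "t1")
  expect_true(all(tr2$adjacent$p == 1))
  expect_equal(var(tr2$summary$median_log10_rpkm[tr2$summary$n > 0]), 0)
})

test_that("group contrast: identical samples, direction, and extreme shift", {
  same <- group_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_true(is.na(same$larger))
  tied <- group_contrast(rep(2, 5), rep(2, 7))
  expect_equal(tied$p, 1)

  set.seed(56)
  a <- rnorm(200, 2); b <- rnorm(200, 0)
  gc <- group_contrast(a, b)
  expect_lt(gc$p, 1e-3)
  expect_equal(gc$larger, "a")
})

test_that("exact rank-sum P agrees with the bitmask enumeration oracle
           and with wilcox.test on tie-free cases", {
  set.seed(57)
  for (i in 1:12) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- round(runif(na, 0, 10), 2); b <- round(runif(nb, 0, 10), 2)
    expect_equal(ranksum_exact_p(a, b), ranksum_bitmask_oracle(a, b))
    if (!anyDuplicated(c(a, b))) {
      expect_equal(ranksum_exact_p(a, b),
                   wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
  # tied cases against the oracle
  a <- c(1, 1, 2); b <- c(1, 2, 2, 3)
  expect_equal(ranksum_exact_p(a, b), ranksum_bitmask_oracle(a, b))
  # 3-vs-3 toy case, hand enumeration: all of a below all of b is the most
  # extreme split, two-sided P = 2/choose(6,3)
  expect_equal(ranksum_exact_p(c(1, 2, 3), c(4, 5, 6)), 2 / 20)
})

test_that("GC3 analyses: correlations, degenerate input, rank contrast", {
  set.seed(58)
  n <- 120
  gc3 <- runif(n, 0.3, 0.9)
  cdc <- pmin(pmax(0.05 + 0.4 * (gc3 - 0.3) + rnorm(n, 0, 0.02), 0), 1)
  cub <- fake_cub(cdc)
  cub$gc3 <- gc3
  cub$gc1 <- 0.5 + 0.2 * (cub$cub_rank == "high")
  m <- one_tissue_matrix(10^(1 + 2 * gc3 + rnorm(n, 0, 0.2)), cub$gene_id)
  out <- gc3_analyses(cub, m, "t1")
  cors <- out$correlations
  expect_gt(cors$r[cors$pair == "gc3_vs_cdc"], 0.5)
  expect_gt(cors$r[cors$pair == "gc3_vs_expression"], 0.5)
  expect_true(all(c("gc1", "gc2", "gc3") %in% out$gc_contrast$position))
  hi_gc1 <- out$gc_contrast[out$gc_contrast$position == "gc1", ]
  expect_equal(hi_gc1$larger, "high", ignore_attr = TRUE)

  # constant GC3: undefined correlation with n still reported
  cub2 <- fake_cub(runif(10, 0.02, 0.3))
  m2 <- one_tissue_matrix(rep(10, 10), cub2$gene_id)
  out2 <- gc3_analyses(cub2, m2, "t1")
  expect_true(is.na(out2$correlations$r[1]))
  expect_equal(out2$correlations$n[1], 10L)
})
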