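test_that("|iHS| outliers use a strict threshold and drop NA", {
  track <- data.frame(chrom = "X", pos = 1:5 * 100,
                      snp_id = letters[1:5],
                      ihs = c(-2.5, 1.9, 2.0, 3.1, NA))
  out <- ihs_outliers(track)
  expect_equal(out$snp_id, c("a", "d"))
  expect_equal(nrow(ihs_outliers(track[0, ])), 0)
})

test_that("boxplot fences match the hand-worked quartile interpolation", {
  v <- c(1:11, 100)
  bx <- boxplot_outliers(v)
  expect_equal(bx$thresholds$f_l, 3.75)
  expect_equal(bx$thresholds$f_u, 9.25)
  expect_equal(bx$thresholds$q, 5.5)
  expect_equal(bx$thresholds$ul, 17.5)
  expect_equal(bx$thresholds$ll, -4.5)
  expect_equal(bx$upper, 12L)
  expect_length(bx$lower, 0)

  # all equal: zero IQR, strict inequality -> no outliers
  be <- boxplot_outliers(rep(0.3, 10))
  expect_equal(be$thresholds$ul, be$thresholds$ll)
  expect_length(be$upper, 0); expect_length(be$lower, 0)

  # symmetric sample: symmetric fences
  bs <- boxplot_outliers(c(-5, -2, -1, 0, 1, 2, 5))
  expect_equal(bs$thresholds$ul - bs$thresholds$f_u,
               bs$thresholds$f_l - bs$thresholds$ll)

  expect_error(boxplot_outliers(c(1, 2, 3)), "at least 4")
})

test_that("boxplot thresholds agree with the sort/interpolate oracle", {
  set.seed(77)
  for (i in 1:50) {
    x <- runif(sample(4:1000, 1))
    bx <- boxplot_outliers(x)
    f_l <- oracle_quartile(x, 0.25); f_u <- oracle_quartile(x, 0.75)
    expect_equal(bx$thresholds$f_l, f_l, tolerance = 1e-12)
    expect_equal(bx$thresholds$f_u, f_u, tolerance = 1e-12)
    expect_equal(bx$thresholds$ul, f_u + 1.5 * (f_u - f_l), tolerance = 1e-12)
    expect_equal(bx$thresholds$ll, f_l - 1.5 * (f_u - f_l), tolerance = 1e-12)
  }
})

test_that("BH q-values: worked example, monotonicity, permutation invariance", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(88)
  p <- runif(200)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(200)
  expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
})

test_that("empirical upper-tail p-values rank the statistic", {
  v <- c(0.1, 0.5, NA, 0.5, 0.9)
  p <- empirical_upper_p(v)
  expect_equal(p[5], (1 + 1) / 5)   # largest of 4 non-missing
  expect_equal(p[1], (1 + 4) / 5)
  expect_equal(p[2], p[4])
  expect_true(is.na(p[3]))
})

test_that("regions are windows around outliers, merged when touching", {
  out <- data.frame(pos = c(122360000), snp_id = "peak", ihs = -5.85)
  reg <- build_regions(out, chrom = "X", chrom_length = 135180000)
  expect_equal(reg$start_bp / 1e6, 122.16)
  expect_equal(reg$end_bp / 1e6, 122.56)
  expect_equal((reg$end_bp - reg$start_bp) / 1e6, 0.40)

  # two outliers 300 kb apart -> one region of 0.7 Mb
  out2 <- data.frame(pos = c(1e6, 1.3e6), snp_id = c("a", "b"),
                     ihs = c(2.5, -3.5))
  reg2 <- build_regions(out2, chrom = "X")
  expect_equal(nrow(reg2), 1)
  expect_equal((reg2$end_bp - reg2$start_bp) / 1e6, 0.7)
  expect_equal(reg2$peak_snp, "b")
  expect_equal(reg2$n_snps, 2L)

  # clamping at the chromosome start
  reg3 <- build_regions(data.frame(pos = 50000, snp_id = "edge", ihs = 3),
                        chrom = "X")
  expect_equal(reg3$start_bp, 1)

  expect_equal(nrow(build_regions(data.frame(pos = numeric(),
                                             snp_id = character(),
                                             ihs = numeric()), "X")), 0)
})

test_that("region merging is idempotent and order-independent", {
  set.seed(9)
  pos <- sample.int(5e6, 40)
  regs <- do.call(rbind, lapply(pos, function(p)
    small_region_df(max(1, p - 2e5), p + 2e5, value = runif(1))))
  m1 <- merge_regions(regs)
  expect_equal(merge_regions(m1), m1)
  m2 <- merge_regions(regs[sample(nrow(regs)), ])
  expect_equal(m2$start_bp, m1$start_bp)
  expect_equal(m2$end_bp, m1$end_bp)
  expect_true(all(m1$start_bp[-1] > head(m1$end_bp, -1)))
})

test_that("candidate combination implements both decision modes", {
  ihs_r <- small_region_df(1e6, 1.4e6, method = "ihs", value = 3)
  fst_r <- small_region_df(1.3e6, 1.7e6, method = "fst", value = 0.6)
  # threshold mode: union, merged
  comb <- combine_candidates(ihs_r, fst_r, label = "b1")
  expect_equal(nrow(comb), 1)
  expect_equal(comb$start_bp, 1e6); expect_equal(comb$end_bp, 1.7e6)
  expect_equal(comb$method, "combined")

  # fdr mode on three disjoint regions
  r1 <- small_region_df(1e6, 1.4e6, method = "ihs")      # q_ihs 0.03 only
  r2 <- small_region_df(3e6, 3.4e6, method = "ihs")      # both q = 0.08
  r3 <- small_region_df(5e6, 5.4e6, method = "ihs")      # q_ihs 0.2 only
  ihs_q <- data.frame(pos = c(1.2e6, 3.2e6, 5.2e6), q = c(0.03, 0.08, 0.2))
  fst_q <- data.frame(pos = c(3.2e6), q = c(0.08))
  cand <- combine_candidates(rbind(r1, r2, r3), r1[0, ], ihs_q = ihs_q,
                             fst_q = fst_q, mode = "fdr")
  expect_equal(cand$start_bp, c(1e6, 3e6))
  expect_error(combine_candidates(r1, r1, mode = "nope"))
})

test_that("summaries count regions and lengths like the study tables", {
  regs <- rbind(small_region_df(1e6, 1.4e6, method = "ihs", label = "b"),
                small_region_df(2e6, 2.4e6, method = "ihs", label = "b"),
                small_region_df(4e6, 4.5e6, method = "ihs", label = "b"))
  s <- summarize_regions(regs)
  expect_equal(s$n_regions, 3)
  expect_equal(s$avg_length_mb, 0.43)
  expect_equal(s$total_length_mb, 1.3)
  expect_equal(s$n_outlier_snps, 3)
  expect_equal(nrow(summarize_regions(regs[0, ])), 0)
})

test_that("overlap accounting is symmetric, bounded and exact", {
  a <- rbind(small_region_df(0, 0.4e6), small_region_df(1.0e6, 1.4e6))
  b <- small_region_df(0.2e6, 0.6e6)
  expect_equal(overlap_length(a, b), 0.2)
  expect_equal(overlap_length(b, a), 0.2)
  expect_equal(overlap_length(a, a), sum(a$end_bp - a$start_bp) / 1e6)
  expect_lte(overlap_length(a, b), min(sum(a$end_bp - a$start_bp),
                                       sum(b$end_bp - b$start_bp)) / 1e6)
  expect_equal(overlap_length(a, a[0, ]), 0)
})
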