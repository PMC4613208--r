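make_geno <- function(mat, samples = paste0("s", seq_len(nrow(mat)))) {
  rownames(mat) <- samples
  colnames(mat) <- paste0("snp", seq_len(ncol(mat)))
  mat
}

test_that("sample filters: strict call-rate boundary and duplicate removal", {
  set.seed(1)
  G <- make_geno(matrix(sample(0:2, 50, replace = TRUE), nrow = 5, ncol = 10))
  G[1, 1:2] <- NA          # call rate 0.8 -> removed
  G[2, 1] <- NA            # call rate 0.9 -> boundary, retained
  G[4, ] <- G[3, ]         # duplicate of s3 -> s4 (later) removed
  res <- filter_samples(G)
  expect_setequal(res$report$samples_removed$sample, c("s1", "s4"))
  expect_equal(res$report$samples_removed$reason[
    res$report$samples_removed$sample == "s1"], "low_call_rate")
  expect_equal(res$report$samples_removed$reason[
    res$report$samples_removed$sample == "s4"], "duplicate")
  expect_setequal(rownames(res$genotypes), c("s2", "s3", "s5"))
  allNA <- matrix(NA_real_, 2, 5,
                  dimnames = list(c("a", "b"), paste0("m", 1:5)))
  expect_error(filter_samples(allNA), "no samples survive")
})

test_that("SNP filters apply call rate, MAF and HWE in order", {
  G <- make_geno(rbind(c(NA, 0, 0, 0),
                       c(0,  0, 0, 1),
                       c(0,  0, 2, 0),
                       c(0,  0, 2, 0)))
  # snp1: call rate 3/4 -> call_rate
  # snp2: monomorphic, MAF 0 -> maf
  # snp3: all homozygotes (2 AA, 2 aa): exact HWE p = 6/70
  # snp4: MAF 1/8 = 0.125 -> retained
  res <- filter_snps(G, snp_map(paste0("snp", 1:4), "X", c(10, 20, 30, 40),
                                rep("A", 4), rep("G", 4)),
                     hwe_p_min = 0.1)
  rem <- res$report$snps_removed
  expect_equal(rem$reason[rem$snp_id == "snp1"], "call_rate")
  expect_equal(rem$reason[rem$snp_id == "snp2"], "maf")
  expect_equal(rem$reason[rem$snp_id == "snp3"], "hwe")
  expect_equal(hwe_exact_p(2, 0, 2), 6 / 70, tolerance = 1e-12)
  expect_equal(res$map$snp_id, "snp4")
})

test_that("strong heterozygote deficit fails HWE below 1e-6", {
  set.seed(3)
  # 10 AA + 10 aa, no heterozygotes: enumeration gives 1.3403e-6
  expect_equal(hwe_exact_p(10, 0, 10), 1.34030215763543e-6, tolerance = 1e-9)
  # 15 AA + 15 aa crosses the QC threshold
  expect_lt(hwe_exact_p(15, 0, 15), 1e-6)
  G <- make_geno(matrix(rep(c(0, 2), each = 15), ncol = 1),
                 samples = paste0("s", 1:30))
  G <- cbind(G, G[, 1], sample(0:2, 30, replace = TRUE))
  colnames(G) <- paste0("snp", 1:3)
  res <- filter_snps(G, snp_map(paste0("snp", 1:3), "X", c(10, 20, 30),
                                rep("A", 3), rep("G", 3)))
  expect_true(all(c("snp1", "snp2") %in%
                    res$report$snps_removed$snp_id[
                      res$report$snps_removed$reason == "hwe"]))
})

test_that("HWE exact p matches the enumeration oracle and its edge cases", {
  expect_equal(hwe_exact_p(0, 2, 0), 1.0)
  expect_equal(hwe_exact_p(5, 0, 0), 1.0)   # monomorphic
  expect_error(hwe_exact_p(0, 0, 0), "zero")
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    nA <- sample(0:(2 * n), 1)
    het_max <- min(nA, 2 * n - nA)
    het <- if (het_max == 0) 0 else sample(seq(nA %% 2, het_max, by = 2), 1)
    nAA <- (nA - het) / 2
    naa <- n - nAA - het
    expect_equal(hwe_exact_p(nAA, het, naa), oracle_hwe(nAA, het, naa),
                 tolerance = 1e-12)
  }
})

test_that("HWE false-positive rate is nominal on HWE-true simulated data", {
  set.seed(99)
  n <- 200; p <- 0.3
  ps <- replicate(1000, {
    g <- rbinom(n, 2, p)
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
})

test_that("residual imputation fills the population-modal genotype", {
  G <- make_geno(rbind(0, 0, 2, NA), samples = paste0("s", 1:4))
  pops <- setNames(rep("p1", 4), paste0("s", 1:4))
  expect_equal(unname(impute_residual_missing(G, pops)[4, 1]), 0)
  # tie {0, 2} -> smaller code
  G2 <- make_geno(rbind(0, 2, NA), samples = paste0("s", 1:3))
  expect_equal(unname(impute_residual_missing(G2)[3, 1]), 0)
  # no missing -> identity
  G3 <- make_geno(matrix(c(0, 1, 2, 1), 2))
  expect_identical(impute_residual_missing(G3), G3)
})

test_that("PCA separates simulated populations and respects duplicates", {
  cfg <- sim_config(seed = 5, n_samples = c(30, 30), n_snps = 400,
                    chrom_length_bp = 4e7, fst_background = 0.3,
                    n_diff_loci = 0, sweep = NULL)
  pan <- simulate_panel(cfg)
  pc <- pca_coordinates(pan$G)
  s <- sign(pc[1, 1])
  lab <- unname(pan$pops[rownames(pc)])
  expect_true(all(sign(pc[lab == lab[1], 1]) == s))
  expect_true(all(sign(pc[lab != lab[1], 1]) == -s))

  G <- pan$G[c(1:10, 1), ]
  rownames(G) <- c(rownames(pan$G)[1:10], "dup")
  pc2 <- pca_coordinates(G)
  expect_equal(unname(pc2[11, ]), unname(pc2[1, ]), tolerance = 1e-8)

  Gc <- matrix(0, nrow = 4, ncol = 5,
               dimnames = list(paste0("s", 1:4), paste0("m", 1:5)))
  expect_error(pca_coordinates(Gc), "polymorphic")
  # identical heterozygous samples: polymorphic pooled frequency, zero
  # variance -> every coordinate 0
  G1 <- Gc + 1
  expect_equal(max(abs(pca_coordinates(G1))), 0)
})

test_that("QC is idempotent: a second pass removes nothing", {
  set.seed(21)
  cfg <- sim_config(seed = 21, n_samples = c(25, 25), n_snps = 300,
                    chrom_length_bp = 3e7, n_diff_loci = 2, sweep = NULL,
                    missing_rate = 0.02)
  pan <- simulate_panel(cfg)
  G <- pan$G
  G[3, sample(300, 60)] <- NA  # plant one low-call-rate sample
  f1 <- filter_samples(G)
  s1 <- filter_snps(f1$genotypes, pan$map, pops = pan$pops)
  f2 <- filter_samples(s1$genotypes)
  s2 <- filter_snps(f2$genotypes, s1$map, pops = pan$pops)
  expect_equal(nrow(f2$report$samples_removed), 0)
  expect_equal(nrow(s2$report$snps_removed), 0)
  expect_identical(dim(s2$genotypes), dim(s1$genotypes))
})
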