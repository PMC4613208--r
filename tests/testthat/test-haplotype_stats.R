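test_that("EHH matches hand-worked group counts at the core's flank", {
  # 6 carriers of allele 1 at the core (column 2); over columns 2..4 they
  # split into identical groups of sizes {3, 2, 1}:
  # EHH = (C(3,2) + C(2,2) + C(1,2)) / C(6,2) = 4/15
  H <- hap_matrix(c("0100", "0100", "0100",   # group of 3
                    "0110", "0110",           # group of 2
                    "0111",                   # singleton
                    "0000", "0011"))          # non-carriers
  pos <- c(100, 200, 300, 400)
  right <- ehh_at(H, pos, core = 2, allele = 1, side = "right")
  expect_equal(right$ehh[2], 4 / 15)
  expect_equal(right$distance[2], 200)
  expect_equal(right$ehh[1], 6 / 15)  # {3,3} split one SNP out

  # all carriers identical over the flank -> EHH 1 everywhere
  H1 <- hap_matrix(rep("0110", 6))
  r1 <- ehh_at(H1, pos, core = 2, allele = 1, side = "right")
  expect_equal(r1$ehh, c(1, 1))

  # all carriers pairwise distinct at the first flanking SNP -> EHH 0
  H0 <- hap_matrix(c("010", "011"))
  r0 <- ehh_at(H0, c(1, 2, 3), core = 2, allele = 1, side = "right")
  expect_equal(r0$ehh[1], 0)

  # < 2 carriers: unavailable
  u <- ehh_at(hap_matrix(c("01", "00")), c(1, 2), core = 1, allele = 1,
              side = "right")
  expect_false(attr(u, "available"))
})

test_that("EHH equals the pair-enumeration oracle on random panels", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(4:12, 1); m <- sample(5:20, 1)
    H <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n, m)
    rownames(H) <- rep(paste0("s", seq_len(ceiling(n / 2))), each = 2)[1:n]
    pos <- sort(sample.int(1e6, m))
    core <- sample(m, 1); allele <- sample(0:1, 1)
    if (sum(H[, core] == allele) < 2) next
    for (side in c("left", "right")) {
      df <- ehh_at(H, pos, core, allele, side)
      for (k in seq_len(nrow(df)))
        expect_equal(df$ehh[k], oracle_ehh(H, core, allele, df$snp[k]),
                     tolerance = 1e-12)
    }
  }
})

test_that("EHH curves are non-increasing in |distance|", {
  set.seed(202)
  for (i in 1:20) {
    n <- 20; m <- 30
    H <- matrix(rbinom(n * m, 1, 0.5), n, m)
    rownames(H) <- rep(paste0("s", 1:10), each = 2)
    pos <- sort(sample.int(3e6, m))
    core <- sample(2:(m - 1), 1)
    for (allele in 0:1) {
      if (sum(H[, core] == allele) < 2) next
      cur <- ehh_curve(H, pos, core, allele)
      expect_true(all(diff(cur$right$ehh) <= 1e-12))
      expect_true(all(diff(cur$left$ehh) <= 1e-12))
    }
  }
})

test_that("iHH integration: trapezoid, cutoff, gap truncation, edge cases", {
  mk_curve <- function(right_d, right_e, left_d = numeric(), left_e = numeric()) {
    structure(list(core = 1, allele = 1, available = TRUE,
                   left = data.frame(snp = seq_along(left_d),
                                     distance = -left_d, ehh = left_e),
                   right = data.frame(snp = seq_along(right_d),
                                      distance = right_d, ehh = right_e)),
              class = "ehh_curve")
  }
  # hand trapezoid: 10000*(1+.5)/2 + 10000*(.5+.05)/2 = 10250
  cv <- mk_curve(c(10000, 20000), c(0.5, 0.05))
  expect_equal(integrate_ehh(cv, ehh_cutoff = 0.04)$ihh, 10250)
  # the 0.05 point is excluded at the default cutoff boundary? 0.05 >= 0.05
  expect_equal(integrate_ehh(cv, ehh_cutoff = 0.05)$ihh, 10250)
  expect_equal(integrate_ehh(cv, ehh_cutoff = 0.051)$ihh, 7500)

  # constant EHH 1 over 100 kb -> rectangle
  cv2 <- mk_curve(c(50000, 100000), c(1, 1))
  expect_equal(integrate_ehh(cv2)$ihh, 100000)

  # first flanking point below cutoff -> zero
  cv3 <- mk_curve(c(10000), c(0.01))
  expect_equal(integrate_ehh(cv3)$ihh, 0)

  # gap > max_gap truncates and flags
  cv4 <- mk_curve(c(10000, 700000), c(0.8, 0.7))
  r4 <- integrate_ehh(cv4, max_gap_bp = 500000)
  expect_equal(r4$ihh, 10000 * (1 + 0.8) / 2)
  expect_true("truncated_by_gap" %in% r4$flags)

  # empty curve
  cv5 <- mk_curve(numeric(), numeric())
  r5 <- integrate_ehh(cv5)
  expect_equal(r5$ihh, 0)
  expect_true("no_flank" %in% r5$flags)
})

test_that("raw iHS is the log integral ratio with NA on zero integrals", {
  expect_equal(raw_ihs(12345, 12345), 0)
  expect_equal(raw_ihs(2 * 777, 777), log(2))
  expect_true(is.na(raw_ihs(100, 0)))
  expect_true(is.na(raw_ihs(0, 100)))
})

test_that("standardization yields mean 0 / sd 1 per bin and Gaussian p", {
  set.seed(7)
  raw <- rnorm(500, mean = 0.3, sd = 0.8)
  freq <- runif(500, 0.05, 0.95)
  std <- standardize_ihs(raw, freq)
  for (b in unique(std$bin[!is.na(std$ihs)])) {
    v <- std$ihs[std$bin == b & !is.na(std$ihs)]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sd(v) - 1), 1e-6)
  }
  # p_ihs anchors: z = 0 -> 0; z = 1.96 -> -log10(0.04999...) ~ 1.301
  i0 <- which.min(abs(std$ihs))
  expect_equal(std$p_ihs[i0], -log10(2 * pnorm(-abs(std$ihs[i0]))))
  expect_equal(-log10(2 * pnorm(-1.96)), 1.301, tolerance = 1e-3)
  expect_equal(-log10(2 * pnorm(0)), 0)

  # zero-variance bin -> NA with warning
  expect_warning(s2 <- standardize_ihs(c(1, 1, 1), c(0.2, 0.21, 0.22)),
                 "starved|zero")
  expect_true(all(is.na(s2$ihs)))
  # bin_width = 1 recovers one global standardization
  sg <- standardize_ihs(raw, freq, bin_width = 1)
  expect_equal(sg$ihs, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
})

test_that("allele-swap antisymmetry and translation invariance hold", {
  set.seed(11)
  cfg <- sim_config(seed = 11, n_samples = c(25), n_snps = 80,
                    chrom_length_bp = 8e6, fst_background = 0,
                    n_diff_loci = 0, sweep = NULL)
  pan <- simulate_panel(cfg)
  map_flip <- pan$map
  map_flip$ancestral <- ifelse(pan$map$ancestral == "ref", "alt", "ref")
  tr <- suppressWarnings(ihs_scan(pan$H, pan$map, pops = pan$pops,
                                  population = "pop1"))
  trf <- suppressWarnings(ihs_scan(pan$H, map_flip, pops = pan$pops,
                                   population = "pop1"))
  ok <- !is.na(tr$raw_ihs) & !is.na(trf$raw_ihs)
  expect_gt(sum(ok), 10)
  expect_equal(tr$raw_ihs[ok], -trf$raw_ihs[ok], tolerance = 1e-12)
  expect_equal(trf$derived_freq, 1 - tr$derived_freq, tolerance = 1e-12)

  map_shift <- pan$map
  map_shift$pos <- map_shift$pos + 12345L
  trs <- suppressWarnings(ihs_scan(pan$H, map_shift, pops = pan$pops,
                                   population = "pop1"))
  expect_equal(trs$ihh_a, tr$ihh_a, tolerance = 1e-12)
  expect_equal(trs$ihh_d, tr$ihh_d, tolerance = 1e-12)
})

test_that("the scan flags ineligible SNPs and rejects degenerate panels", {
  cfg <- sim_config(seed = 13, n_samples = c(20), n_snps = 60,
                    chrom_length_bp = 6e6, fst_background = 0,
                    n_diff_loci = 0, sweep = NULL)
  pan <- simulate_panel(cfg)
  map <- pan$map
  map$ancestral[1] <- "unknown"
  tr <- suppressWarnings(ihs_scan(pan$H, map, pops = pan$pops,
                                  population = "pop1"))
  expect_true(is.na(tr$ihs[1]))
  expect_equal(tr$flags[1], "no_ancestral")
  out <- abs(tr$derived_freq) < 0.05 | tr$derived_freq > 0.95
  expect_true(all(is.na(tr$ihs[out])))

  H1 <- pan$H[1:2, , drop = FALSE]  # single sample
  expect_error(ihs_scan(H1, map), "at least 2 samples")
})

test_that("an injected sweep stands out in the standardized scan", {
  cfg <- sim_config(seed = 1)
  pan <- simulate_panel(cfg)
  tr <- suppressWarnings(ihs_scan(pan$H, pan$map, pops = pan$pops,
                                  population = "pop1"))
  core <- pan$truth$sweep$core_snp
  v <- tr$ihs[tr$snp_id == core]
  expect_false(is.na(v))
  # the focal SNP is an |iHS| > 2 outlier ...
  expect_gt(abs(v), 2)
  # ... ranks in the top 1% of non-NA SNPs ...
  expect_lte(mean(abs(tr$ihs) >= abs(v), na.rm = TRUE), 0.01)
  # ... and the derived allele carries the long haplotype (iHH_D >> iHH_A
  # on the swept background), so the score is negative
  expect_lt(v, 0)
})

test_that("neutral scans have modest tails after standardization", {
  cfg <- sim_config(seed = 29, n_samples = c(60), n_snps = 500,
                    chrom_length_bp = 5.5e7, fst_background = 0,
                    n_diff_loci = 0, sweep = NULL)
  pan <- simulate_panel(cfg)
  tr <- suppressWarnings(ihs_scan(pan$H, pan$map, pops = pan$pops,
                                  population = "pop1"))
  expect_lte(mean(abs(tr$ihs) > 2, na.rm = TRUE), 0.10)
})
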