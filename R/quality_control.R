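# PLINK-style panel quality control: sample call rate and duplicate removal,
# SNP call rate / MAF / Hardy-Weinberg filters, residual imputation, and a
# diagnostic PCA of population structure. Removal rules use strict "less
# than" boundaries throughout.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact p-value for a biallelic genotype sample: the sum of the
#' conditional probabilities (given the allele counts) of every heterozygote
#' configuration no more probable than the observed one. Computed from the
#' closed-form conditional distribution via log-factorials.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)  # monomorphic: single configuration
  hets <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  logp <- lfactorial(n) -
    (lfactorial((nA - hets) / 2) + lfactorial(hets) + lfactorial((na - hets) / 2)) +
    hets * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Sample-level quality control
#'
#' Removes samples with genotype call rate strictly below `min_call_rate`,
#' then removes the later-listed member of every remaining pair whose
#' identity-by-state over co-called SNPs is at least `duplicate_ibs`.
#'
#' @param G genotype matrix (samples x SNPs, 0/1/2/NA), rownames = samples.
#' @param min_call_rate minimum fraction of called SNPs per sample.
#' @param duplicate_ibs IBS threshold declaring two samples duplicates.
#' @return list with `genotypes` (filtered) and `report` (a `qc_report`).
#' @export
filter_samples <- function(G, min_call_rate = 0.90, duplicate_ibs = 0.99) {
  stopifnot(nrow(G) > 0)
  samples <- rownames(G)
  cr <- rowMeans(!is.na(G))
  low <- cr < min_call_rate
  removed <- data.frame(sample = samples[low],
                        reason = rep("low_call_rate", sum(low)),
                        stringsAsFactors = FALSE)
  X <- G[!low, , drop = FALSE]
  if (nrow(X) >= 2) {
    ibs <- .ibs_matrix(X)
    flag <- which(upper.tri(ibs) & !is.na(ibs) & ibs >= duplicate_ibs,
                  arr.ind = TRUE)
    if (nrow(flag)) {
      dup <- sort(unique(pmax(flag[, 1], flag[, 2])))  # later sample of each pair
      removed <- rbind(removed,
                       data.frame(sample = rownames(X)[dup],
                                  reason = "duplicate",
                                  stringsAsFactors = FALSE))
      X <- X[-dup, , drop = FALSE]
    }
  }
  if (nrow(X) == 0) stop("no samples survive QC")
  report <- list(samples_removed = removed,
                 snps_removed = data.frame(snp_id = character(),
                                           reason = character(),
                                           stringsAsFactors = FALSE),
                 thresholds = list(min_call_rate = min_call_rate,
                                   duplicate_ibs = duplicate_ibs))
  class(report) <- "qc_report"
  list(genotypes = X, report = report)
}

# mean proportion of shared alleles over co-called SNPs, via indicator
# cross-products (pairs with no co-called SNPs get NA)
.ibs_matrix <- function(X) {
  C <- (!is.na(X)) + 0
  I <- lapply(0:2, function(g) (!is.na(X) & X == g) + 0)
  co <- tcrossprod(C)
  same <- tcrossprod(I[[1]]) + tcrossprod(I[[2]]) + tcrossprod(I[[3]])
  half <- tcrossprod(I[[1]], I[[2]]) + tcrossprod(I[[2]], I[[1]]) +
    tcrossprod(I[[2]], I[[3]]) + tcrossprod(I[[3]], I[[2]])
  ibs <- (same + 0.5 * half) / co
  ibs[co == 0] <- NA
  ibs
}

#' SNP-level quality control
#'
#' Removes SNPs failing, in order: call rate < `min_call_rate`; pooled minor
#' allele frequency < `min_maf`; Hardy-Weinberg exact p < `hwe_p_min`. HWE is
#' tested within each population (when `pops` is given) and the minimum p
#' across populations is compared with the threshold, so between-population
#' differentiation (Wahlund effect) does not trigger removals.
#'
#' @param G genotype matrix after sample QC.
#' @param map matching [snp_map].
#' @param pops optional named vector sample -> population label.
#' @param min_call_rate,min_maf,hwe_p_min thresholds (strict `<` removal).
#' @return list with `genotypes`, `map` and `report`.
#' @export
filter_snps <- function(G, map, pops = NULL, min_call_rate = 0.90,
                        min_maf = 0.05, hwe_p_min = 1e-6) {
  stopifnot(ncol(G) == nrow(map))
  cr <- colMeans(!is.na(G))
  p_alt <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.nan(maf)] <- 0

  groups <- if (is.null(pops)) rep("all", nrow(G)) else unname(pops[rownames(G)])
  hwe_min_p <- rep(1, ncol(G))
  candidate <- which(cr >= min_call_rate & maf >= min_maf)
  for (j in candidate) {
    pj <- 1
    for (g in unique(groups)) {
      gj <- G[groups == g, j]
      n0 <- sum(gj == 0, na.rm = TRUE)
      n1 <- sum(gj == 1, na.rm = TRUE)
      n2 <- sum(gj == 2, na.rm = TRUE)
      if (n0 + n1 + n2 >= 1)
        pj <- min(pj, hwe_exact_p(n0, n1, n2))
    }
    hwe_min_p[j] <- pj
  }

  reason <- rep(NA_character_, ncol(G))
  reason[hwe_min_p < hwe_p_min] <- "hwe"
  reason[maf < min_maf] <- "maf"
  reason[cr < min_call_rate] <- "call_rate"  # first rule wins
  drop <- !is.na(reason)
  if (all(drop)) stop("no SNPs survive QC")
  report <- list(samples_removed = data.frame(sample = character(),
                                              reason = character(),
                                              stringsAsFactors = FALSE),
                 snps_removed = data.frame(snp_id = map$snp_id[drop],
                                           reason = reason[drop],
                                           stringsAsFactors = FALSE),
                 thresholds = list(min_call_rate = min_call_rate,
                                   min_maf = min_maf, hwe_p_min = hwe_p_min))
  class(report) <- "qc_report"
  list(genotypes = G[, !drop, drop = FALSE], map = map[!drop, ],
       report = report)
}

#' Fill residual missing genotypes by the population-modal genotype
#'
#' Each missing entry is replaced by the most frequent called genotype for
#' that SNP within the sample's population (ties broken toward the smaller
#' genotype code); a population with no calls falls back to the pooled mode.
#'
#' @param G genotype matrix after QC.
#' @param pops optional named vector sample -> population.
#' @return the completed genotype matrix.
#' @export
impute_residual_missing <- function(G, pops = NULL) {
  if (!anyNA(G)) return(G)
  groups <- if (is.null(pops)) rep("all", nrow(G)) else unname(pops[rownames(G)])
  modal <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tab <- tabulate(v + 1L, nbins = 3L)
    which.max(tab) - 1L  # which.max takes the first (smaller) on ties
  }
  for (j in which(colSums(is.na(G)) > 0)) {
    pooled <- modal(G[, j])
    for (g in unique(groups)) {
      rows <- which(groups == g & is.na(G[, j]))
      if (!length(rows)) next
      fill <- modal(G[groups == g, j])
      if (is.na(fill)) fill <- pooled
      G[rows, j] <- fill
    }
  }
  G
}

#' PCA of the genotype matrix for population-structure inspection
#'
#' Columns are centered at twice the pooled alt frequency and scaled by
#' `sqrt(2 p (1 - p))`; monomorphic SNPs are skipped and residual missing
#' entries contribute zero after centering. Coordinates are projections onto
#' the top right-singular directions; component signs are unconstrained.
#'
#' @param G genotype matrix (samples x SNPs).
#' @param n_components number of components to return.
#' @return matrix samples x `n_components` with columns `PC1..PCk`.
#' @export
pca_coordinates <- function(G, n_components = 2) {
  stopifnot(nrow(G) >= 2, ncol(G) >= 2)
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < n_components)
    stop("fewer polymorphic SNPs than requested components")
  X <- sweep(G[, poly, drop = FALSE], 2, 2 * p[poly])
  X <- sweep(X, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  X[is.na(X)] <- 0
  sv <- svd(X, nu = 0, nv = n_components)
  coords <- X %*% sv$v
  dimnames(coords) <- list(rownames(G), paste0("PC", seq_len(n_components)))
  coords
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", nrow(x$samples_removed), "samples removed,",
      nrow(x$snps_removed), "SNPs removed\n")
  if (nrow(x$samples_removed)) print(table(x$samples_removed$reason))
  if (nrow(x$snps_removed)) print(table(x$snps_removed$reason))
  invisible(x)
}

#' Write a QC report as TSV files plus a JSON summary
#'
#' @param report a `qc_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$samples_removed, file.path(dir, "qc_samples_removed.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$snps_removed, file.path(dir, "qc_snps_removed.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  smry <- list(thresholds = report$thresholds,
               n_samples_removed = nrow(report$samples_removed),
               n_snps_removed = nrow(report$snps_removed),
               samples_by_reason = as.list(table(report$samples_removed$reason)),
               snps_by_reason = as.list(table(report$snps_removed$reason)))
  jsonlite::write_json(smry, file.path(dir, "qc_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
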