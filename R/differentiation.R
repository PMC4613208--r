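# Per-SNP FST from expected heterozygosities: FST = (H_T - H_S) / H_T with
# H_T = 1 - (p^2 + q^2) = 2pq computed from the pooled allele frequency and
# H_S the sample-size-weighted mean of the subpopulation expected
# heterozygosities 2 p_i q_i. This is the plain H_T/H_S estimator, with no
# Nei or Weir-Cockerham small-sample correction.

#' Per-population allele frequencies
#'
#' Works on either a genotype matrix (samples x SNPs, 0/1/2/NA) or a
#' haplotype matrix (2n x SNPs, 0/1, sample rownames duplicated). The alt
#' allele frequency per population is the alt allele count over the called
#' allele count; a population with no calls at a SNP yields `NA`.
#'
#' @param x genotype or haplotype matrix, rownames = sample ids.
#' @param pops named vector sample -> population label.
#' @param input matrix type; `"auto"` detects haplotype input by duplicated
#'   rownames with no value above 1.
#' @return list with `freq` (populations x SNPs), `n_called` (called allele
#'   counts, populations x SNPs) and `n_samples` (samples per population).
#' @export
allele_frequencies <- function(x, pops, input = c("auto", "genotype", "haplotype")) {
  input <- match.arg(input)
  if (input == "auto") {
    hap <- anyDuplicated(rownames(x)) > 0 && all(x %in% c(0L, 1L, NA))
    input <- if (hap) "haplotype" else "genotype"
  }
  labs <- unname(pops[rownames(x)])
  if (anyNA(labs))
    stop("samples without a population label: ",
         paste(unique(rownames(x)[is.na(labs)]), collapse = ", "))
  per_allele <- if (input == "genotype") 2L else 1L
  groups <- sort(unique(labs))
  freq <- n_called <- matrix(NA_real_, nrow = length(groups), ncol = ncol(x),
                             dimnames = list(groups, colnames(x)))
  for (g in groups) {
    xg <- x[labs == g, , drop = FALSE]
    called <- colSums(!is.na(xg)) * per_allele
    alt <- colSums(xg, na.rm = TRUE)
    freq[g, ] <- ifelse(called > 0, alt / called, NA)
    n_called[g, ] <- called
  }
  n_samples <- vapply(groups, function(g) length(unique(rownames(x)[labs == g])),
                      integer(1))
  list(freq = freq, n_called = n_called, n_samples = n_samples)
}

#' Per-SNP FST from subpopulation allele frequencies
#'
#' Pooled frequency is the weight-averaged subpopulation frequency
#' (weights = called allele counts; `weighted = FALSE` uses a plain mean);
#' `H_T = 2 p q`, `H_S = sum_i w_i 2 p_i q_i`, `FST = (H_T - H_S) / H_T`,
#' `NA` when `H_T = 0` (monomorphic across populations). Negative rounding
#' artifacts are clamped at 0.
#'
#' @param freq matrix populations x SNPs of alt frequencies (`NA` allowed).
#' @param n matrix (populations x SNPs) or vector of weights, typically the
#'   called allele counts from [allele_frequencies()].
#' @param weighted use weighted pooling (default) or unweighted means.
#' @return data.frame with `p_pool`, `h_t`, `h_s`, `fst` per SNP.
#' @export
fst_per_snp <- function(freq, n, weighted = TRUE) {
  freq <- as.matrix(freq)
  if (nrow(freq) < 2) stop("FST needs at least two populations")
  if (is.null(dim(n))) n <- matrix(n, nrow = nrow(freq), ncol = ncol(freq))
  w <- ifelse(is.na(freq), 0, n)
  if (!weighted) w <- ifelse(is.na(freq), 0, 1)
  n_pop <- colSums(!is.na(freq))
  wsum <- colSums(w)
  f0 <- ifelse(is.na(freq), 0, freq)
  p_pool <- colSums(w * f0) / wsum
  h_t <- 2 * p_pool * (1 - p_pool)
  h_s <- colSums(w * 2 * f0 * (1 - f0)) / wsum
  fst <- ifelse(h_t > 0, pmin(1, pmax(0, (h_t - h_s) / h_t)), NA)
  bad <- n_pop < 2
  p_pool[bad] <- h_t[bad] <- h_s[bad] <- fst[bad] <- NA
  data.frame(p_pool = p_pool, h_t = h_t, h_s = h_s, fst = fst)
}

#' Between-population FST scan
#'
#' Runs the per-SNP FST over a subset of population labels (all labels by
#' default); the study design of three breeds yields four standard runs:
#' the three-way joint scan plus the three pairwise scans.
#'
#' @param x genotype or haplotype matrix.
#' @param map matching [snp_map].
#' @param pops named vector sample -> population.
#' @param subset population labels to include (default: all).
#' @param label scan label for the output track (default: labels joined
#'   with `-`).
#' @param weighted see [fst_per_snp()].
#' @return a score-track data.frame: `chrom`, `pos`, `snp_id`, one
#'   `p_<population>` column per population, `h_t`, `h_s`, `fst`, `label`.
#' @export
fst_scan <- function(x, map, pops, subset = NULL, label = NULL,
                     weighted = TRUE) {
  stopifnot(ncol(x) == nrow(map))
  all_labs <- unique(unname(pops))
  if (is.null(subset)) subset <- sort(all_labs)
  if (!all(subset %in% all_labs))
    stop("unknown population label(s): ",
         paste(setdiff(subset, all_labs), collapse = ", "))
  if (length(subset) < 2) stop("FST scan needs at least two populations")
  keep <- rownames(x) %in% names(pops)[unname(pops) %in% subset]
  af <- allele_frequencies(x[keep, , drop = FALSE], pops)
  res <- fst_per_snp(af$freq, af$n_called, weighted = weighted)
  if (is.null(label)) label <- paste(subset, collapse = "-")
  track <- data.frame(chrom = map$chrom, pos = map$pos, snp_id = map$snp_id,
                      stringsAsFactors = FALSE)
  for (g in rownames(af$freq)) track[[paste0("p_", g)]] <- af$freq[g, ]
  track$h_t <- res$h_t
  track$h_s <- res$h_s
  track$fst <- res$fst
  track$label <- label
  track
}
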