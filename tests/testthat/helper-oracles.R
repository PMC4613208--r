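# Independent brute-force oracles for the core statistics, deliberately
# written by a different route than the implementations they check.

# EHH by explicit pair enumeration: fraction of carrier pairs identical at
# every SNP between the core and s, inclusive.
oracle_ehh <- function(H, core, allele, s) {
  carriers <- which(H[, core] == allele)
  n <- length(carriers)
  if (n < 2) return(NA_real_)
  cols <- seq(min(core, s), max(core, s))
  hits <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (all(H[carriers[i], cols] == H[carriers[j], cols])) hits <- hits + 1L
  }
  hits / (n * (n - 1) / 2)
}

# FST by direct evaluation of the heterozygosity formulas from raw counts.
oracle_fst <- function(alt_counts, allele_totals) {
  p_i <- alt_counts / allele_totals
  p <- sum(alt_counts) / sum(allele_totals)
  q <- 1 - p
  h_t <- 1 - (p^2 + q^2)
  h_exp <- 2 * p_i * (1 - p_i)
  h_s <- sum(h_exp * allele_totals) / sum(allele_totals)
  if (h_t == 0) return(NA_real_)
  max(0, (h_t - h_s) / h_t)
}

# HWE exact p by the heterozygote-count recurrence (Wigginton-style),
# starting from an arbitrary reachable configuration.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  if (length(hets) > 1) for (k in 2:length(hets)) {
    h <- hets[k]  # from h-2 to h: ratio of conditional probabilities
    aa_prev <- (nA - (h - 2)) / 2
    bb_prev <- (na - (h - 2)) / 2
    pr[k] <- pr[k - 1] * 4 * aa_prev * bb_prev / (h * (h - 1))
  }
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# Quartiles by hand: linear interpolation at rank q * (n - 1) on the
# sorted sample (0-based ranks).
oracle_quartile <- function(x, q) {
  s <- sort(x)
  r <- q * (length(s) - 1)
  lo <- floor(r); hi <- ceiling(r)
  s[lo + 1] + (r - lo) * (s[hi + 1] - s[lo + 1])
}

# All-pairs interval intersection (1-based inclusive intervals).
oracle_gene_overlap <- function(regions, genes) {
  out <- matrix(FALSE, nrow(regions), nrow(genes))
  for (i in seq_len(nrow(regions))) for (j in seq_len(nrow(genes))) {
    out[i, j] <- regions$start_bp[i] <= genes$end_bp[j] &&
      genes$start_bp[j] <= regions$end_bp[i]
  }
  out
}

# A tiny deterministic haplotype matrix builder for hand examples.
hap_matrix <- function(rows, sample_ids = NULL) {
  H <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(H) / 2))
  rownames(H) <- rep(sample_ids, each = 2)
  H
}

# Small VCF fixture written to a temp file; gts is a variants x samples
# character matrix of GT strings.
write_test_vcf <- function(pos, ref, alt, gts, samples, aa = NULL,
                           chrom = "X", id = NULL) {
  if (is.null(id)) id <- paste0("snp", seq_along(pos))
  info <- if (is.null(aa)) rep(".", length(pos)) else
    ifelse(is.na(aa), ".", paste0("AA=", aa))
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chrom),
           "##INFO=<ID=AA,Number=1,Type=Character,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(chrom, pos, id, ref, alt, ".", "PASS", info, "GT",
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  path
}

small_region_df <- function(start, end, chrom = "X", method = "ihs",
                            label = "", value = 1, snp = "s") {
  data.frame(chrom = chrom, start_bp = start, end_bp = end,
             peak_snp = snp, peak_pos = (start + end) / 2,
             peak_value = value, n_snps = 1L, method = method,
             label = label, stringsAsFactors = FALSE)
}
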