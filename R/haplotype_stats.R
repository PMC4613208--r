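# Extended haplotype homozygosity (EHH), its physical-distance integral
# (iHH), and the integrated haplotype score iHS = standardized
# ln(iHH_A / iHH_D), the within-population sweep statistic. EHH at a flanking
# SNP s is the probability that two random haplotypes carrying the core
# allele are identical at every SNP from the core to s inclusive:
#   EHH(s) = sum_g C(k_g, 2) / C(n_c, 2)
# over the groups g of carriers with identical flanking haplotypes.

# Walk outward from the core over carrier haplotypes, refining the identity
# partition one SNP at a time. Early stopping (for scans): once EHH drops
# below `stop_below`, or a inter-SNP gap exceeds `max_gap_bp` (the point past
# the gap is still emitted so the integrator can flag the truncation).
.ehh_side <- function(H, carriers, core, side, pos, flank_end = NULL,
                      stop_below = -Inf, max_gap_bp = Inf) {
  m <- ncol(H)
  empty <- data.frame(snp = integer(), distance = numeric(), ehh = numeric())
  if (side == "right") {
    last <- if (is.null(flank_end)) m else flank_end
    if (last <= core) return(empty)
    cols <- seq.int(core + 1L, last)
  } else {
    last <- if (is.null(flank_end)) 1L else flank_end
    if (last >= core) return(empty)
    cols <- seq.int(core - 1L, last)
  }
  n <- length(carriers)
  denom <- n * (n - 1) / 2
  g <- rep(1L, n)
  out_snp <- integer(length(cols)); out_ehh <- numeric(length(cols))
  k <- 0L
  prev <- pos[core]
  for (s in cols) {
    key <- g * 2L + H[carriers, s]
    g <- match(key, unique(key))
    cnt <- tabulate(g, nbins = n)
    e <- sum(cnt * (cnt - 1L)) / 2 / denom
    k <- k + 1L
    out_snp[k] <- s; out_ehh[k] <- e
    gap <- abs(pos[s] - prev) > max_gap_bp
    prev <- pos[s]
    if (e < stop_below || gap) break
  }
  data.frame(snp = out_snp[seq_len(k)],
             distance = pos[out_snp[seq_len(k)]] - pos[core],
             ehh = out_ehh[seq_len(k)])
}

#' EHH values on one side of a core SNP
#'
#' @param H haplotype matrix for one population (rows = haplotypes,
#'   columns = SNPs, values 0/1 alt indicator), complete and phased.
#' @param pos physical positions (bp) of the SNP columns.
#' @param core core SNP column index.
#' @param allele core allele value (0 or 1) defining the carrier set.
#' @param side `"left"` or `"right"` of the core.
#' @param flank_end last SNP index to evaluate (defaults to the chromosome
#'   end on that side).
#' @return data.frame with `snp`, `distance` (signed bp from the core) and
#'   `ehh`; carries attribute `available = FALSE` (and zero rows) when
#'   fewer than 2 haplotypes carry the core allele.
#' @export
ehh_at <- function(H, pos, core, allele, side = c("left", "right"),
                   flank_end = NULL) {
  side <- match.arg(side)
  carriers <- which(H[, core] == allele)
  if (length(carriers) < 2L) {
    out <- data.frame(snp = integer(), distance = numeric(), ehh = numeric())
    attr(out, "available") <- FALSE
    return(out)
  }
  out <- .ehh_side(H, carriers, core, side, pos, flank_end = flank_end)
  attr(out, "available") <- TRUE
  out
}

#' Full EHH curve (both sides) around a core allele
#'
#' @inheritParams ehh_at
#' @param stop_below,max_gap_bp optional early-stopping controls used by the
#'   scan; the defaults compute the complete curve.
#' @return object of class `ehh_curve`: list with `core`, `allele`,
#'   `left`/`right` point tables and `available`.
#' @export
ehh_curve <- function(H, pos, core, allele, stop_below = -Inf,
                      max_gap_bp = Inf) {
  carriers <- which(H[, core] == allele)
  available <- length(carriers) >= 2L
  empty <- data.frame(snp = integer(), distance = numeric(), ehh = numeric())
  out <- list(core = core, allele = allele, available = available,
              left = empty, right = empty)
  if (available) {
    out$left <- .ehh_side(H, carriers, core, "left", pos,
                          stop_below = stop_below, max_gap_bp = max_gap_bp)
    out$right <- .ehh_side(H, carriers, core, "right", pos,
                           stop_below = stop_below, max_gap_bp = max_gap_bp)
  }
  class(out) <- "ehh_curve"
  out
}

#' Integrate an EHH curve over physical distance
#'
#' Trapezoidal integral of EHH against bp, summed over the two sides; each
#' side starts from the implicit core point (distance 0, EHH 1). On each
#' side integration stops at the first point with EHH below `ehh_cutoff`
#' (that point excluded), and a gap larger than `max_gap_bp` between
#' consecutive SNPs truncates the side at the last SNP before the gap
#' (flag `truncated_by_gap`).
#'
#' @param curve an `ehh_curve`.
#' @param ehh_cutoff stop integrating once EHH drops below this value.
#' @param max_gap_bp largest tolerated gap between consecutive SNPs.
#' @return list with `ihh` (bp x EHH units) and `flags` (character vector,
#'   possibly empty; `no_flank` when the curve has no points at all).
#' @export
integrate_ehh <- function(curve, ehh_cutoff = 0.05, max_gap_bp = 500000) {
  stopifnot(inherits(curve, "ehh_curve"))
  if (!curve$available) return(list(ihh = NA_real_, flags = "unavailable"))
  side_int <- function(df) {
    if (!nrow(df)) return(list(v = 0, gap = FALSE))
    d <- c(0, abs(df$distance))
    e <- c(1, df$ehh)
    gap <- FALSE
    big <- which(diff(d) > max_gap_bp)
    if (length(big)) {
      keep <- seq_len(big[1])
      d <- d[keep]; e <- e[keep]
      gap <- TRUE
    }
    below <- which(e < ehh_cutoff)
    if (length(below)) {
      keep <- seq_len(below[1] - 1L)
      d <- d[keep]; e <- e[keep]
    }
    if (length(d) < 2L) return(list(v = 0, gap = gap))
    list(v = sum(diff(d) * (head(e, -1) + tail(e, -1)) / 2), gap = gap)
  }
  L <- side_int(curve$left)
  R <- side_int(curve$right)
  flags <- character()
  if (L$gap || R$gap) flags <- c(flags, "truncated_by_gap")
  if (!nrow(curve$left) && !nrow(curve$right)) flags <- c(flags, "no_flank")
  list(ihh = L$v + R$v, flags = flags)
}

#' Unstandardized iHS
#'
#' `ln(iHH_A / iHH_D)`; `NA` when either integral is zero or missing.
#'
#' @param ihh_a,ihh_d integrated EHH for the ancestral and derived core
#'   allele.
#' @return the log ratio, or `NA`.
#' @export
raw_ihs <- function(ihh_a, ihh_d) {
  out <- rep(NA_real_, length(ihh_a))
  ok <- !is.na(ihh_a) & !is.na(ihh_d) & ihh_a > 0 & ihh_d > 0
  out[ok] <- log(ihh_a[ok] / ihh_d[ok])
  out
}

#' Standardize raw iHS within derived-allele-frequency bins
#'
#' The raw log ratio depends strongly on the derived allele frequency, so
#' standardization (subtract mean, divide by sample sd, denominator n - 1)
#' is performed within frequency bins of width `bin_width` spanning
#' `freq_range` (the rightmost bin is closed). `bin_width = 1` recovers a
#' single global standardization. Bins with fewer than two non-missing raw
#' values, or zero spread, yield `NA` with a warning.
#'
#' @param raw raw iHS values (`NA` allowed).
#' @param derived_freq derived-allele frequencies matching `raw`.
#' @param bin_width frequency bin width.
#' @param freq_range eligible derived-frequency range.
#' @return data.frame with `bin`, `ihs` and `p_ihs`
#'   (`-log10` of the two-sided Gaussian tail probability).
#' @export
standardize_ihs <- function(raw, derived_freq, bin_width = 0.05,
                            freq_range = c(0.05, 0.95)) {
  stopifnot(length(raw) == length(derived_freq))
  breaks <- seq(freq_range[1], freq_range[2], by = bin_width)
  if (tail(breaks, 1) < freq_range[2]) breaks <- c(breaks, freq_range[2])
  bin <- rep(NA_integer_, length(raw))
  inr <- !is.na(derived_freq) & derived_freq >= freq_range[1] &
    derived_freq <= freq_range[2]
  bin[inr] <- findInterval(derived_freq[inr], breaks, rightmost.closed = TRUE)
  ihs <- rep(NA_real_, length(raw))
  starved <- 0L
  for (b in sort(unique(bin[!is.na(bin)]))) {
    idx <- which(bin == b & !is.na(raw))
    if (length(idx) < 2L) { starved <- starved + length(idx); next }
    s <- sd(raw[idx])
    if (!is.finite(s) || s == 0) { starved <- starved + length(idx); next }
    ihs[idx] <- (raw[idx] - mean(raw[idx])) / s
  }
  if (starved > 0L)
    warning(sprintf("%d raw iHS values in starved or zero-variance bins set to NA",
                    starved))
  p_ihs <- -log10(2 * pnorm(-abs(ihs)))
  data.frame(bin = bin, ihs = ihs, p_ihs = p_ihs)
}

#' Within-population iHS scan
#'
#' For every SNP with known ancestral allele and derived frequency inside
#' `[min_maf, 1 - min_maf]`, integrates EHH separately over the haplotypes
#' carrying the ancestral and the derived core allele, forms
#' `ln(iHH_A / iHH_D)`, and standardizes within derived-frequency bins.
#'
#' @param H phased, complete haplotype matrix (alt indicator), rownames =
#'   sample ids (each twice).
#' @param map matching [snp_map]; SNPs with `ancestral == "unknown"` are
#'   skipped.
#' @param pops optional named vector sample -> population; with
#'   `population`, restricts the scan to that population's haplotypes.
#' @param population population label to scan.
#' @param min_maf eligibility floor on the derived allele frequency.
#' @param ehh_cutoff,max_gap_bp passed to [integrate_ehh()].
#' @param bin_width standardization bin width.
#' @param min_carriers minimum haplotypes per core allele (else `NA`).
#' @return a score-track data.frame: `chrom`, `pos`, `snp_id`,
#'   `derived_freq`, `ihh_a`, `ihh_d`, `raw_ihs`, `ihs`, `p_ihs`, `flags`,
#'   `label`.
#' @export
ihs_scan <- function(H, map, pops = NULL, population = NULL, min_maf = 0.05,
                     ehh_cutoff = 0.05, max_gap_bp = 500000,
                     bin_width = 0.05, min_carriers = 2) {
  stopifnot(ncol(H) == nrow(map))
  if (!is.null(population)) {
    if (is.null(pops)) stop("population given without a population map")
    keep <- unname(pops[rownames(H)]) == population
    if (!any(keep, na.rm = TRUE)) stop("unknown population: ", population)
    H <- H[which(keep), , drop = FALSE]
  }
  if (nrow(H) < 4L)
    stop("iHS scan needs at least 2 samples (4 haplotypes)")
  if (anyNA(H)) stop("haplotypes must be complete (no missing alleles)")
  m <- ncol(H)
  pos <- map$pos
  derived_val <- ifelse(map$ancestral == "ref", 1L,
                        ifelse(map$ancestral == "alt", 0L, NA_integer_))
  dfreq <- ihh_a <- ihh_d <- rep(NA_real_, m)
  flags <- character(m)
  for (j in seq_len(m)) {
    dv <- derived_val[j]
    if (is.na(dv)) { flags[j] <- "no_ancestral"; next }
    fd <- mean(H[, j] == dv)
    dfreq[j] <- fd
    if (fd < min_maf || fd > 1 - min_maf) { flags[j] <- "freq_out_of_range"; next }
    car_d <- which(H[, j] == dv)
    car_a <- which(H[, j] != dv)
    if (length(car_d) < min_carriers || length(car_a) < min_carriers) {
      flags[j] <- "too_few_carriers"; next
    }
    fl <- character()
    for (al in c("a", "d")) {
      carriers <- if (al == "a") car_a else car_d
      cur <- ehh_curve(H, pos, j, H[carriers[1], j],
                       stop_below = ehh_cutoff, max_gap_bp = max_gap_bp)
      res <- integrate_ehh(cur, ehh_cutoff = ehh_cutoff,
                           max_gap_bp = max_gap_bp)
      if (al == "a") ihh_a[j] <- res$ihh else ihh_d[j] <- res$ihh
      fl <- union(fl, res$flags)
    }
    flags[j] <- paste(fl, collapse = ",")
  }
  raw <- raw_ihs(ihh_a, ihh_d)
  eligible <- !is.na(dfreq) & dfreq >= min_maf & dfreq <= 1 - min_maf
  if (!any(eligible)) stop("no eligible SNPs for the iHS scan")
  std <- standardize_ihs(raw, dfreq, bin_width = bin_width,
                         freq_range = c(min_maf, 1 - min_maf))
  data.frame(chrom = map$chrom, pos = pos, snp_id = map$snp_id,
             derived_freq = dfreq, ihh_a = ihh_a, ihh_d = ihh_d,
             raw_ihs = raw, ihs = std$ihs, p_ihs = std$p_ihs,
             flags = flags,
             label = if (is.null(population)) "" else population,
             stringsAsFactors = FALSE)
}
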