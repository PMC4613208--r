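# Seeded generator of phased multi-population haplotype panels with known
# ground truth: Balding-Nichols differentiation around uniform ancestral
# frequencies, founder-mosaic haplotypes so linkage decays with physical
# distance, strongly differentiated loci, and injected hard sweeps (one
# high-frequency derived allele on a long shared haplotype). The defaults
# mimic the study geometry this pipeline targets: three ewe populations of
# 89/47/12 samples and ~1,200 SNPs spanning ~135 Mb of chromosome X
# (~110 kb average spacing).

#' Simulation configuration
#'
#' @param seed RNG seed (every downstream draw flows from it).
#' @param n_samples samples per population (its length sets the number of
#'   populations; populations are labelled `pop1`, `pop2`, ...).
#' @param n_snps number of SNPs (>= 10).
#' @param chrom chromosome name.
#' @param chrom_length_bp chromosome span in bp.
#' @param fst_background Balding-Nichols differentiation F of the neutral
#'   background, in `[0, 1)`.
#' @param n_diff_loci number of strongly differentiated loci.
#' @param diff_fst Balding-Nichols F used for the differentiated loci.
#' @param diff_min_fst minimum parametric FST a differentiated draw must
#'   reach (draws are repeated until it does): the ground-truth list must
#'   contain loci that are actually differentiated, and 0.25 is the classic
#'   "very great differentiation" band of Wright's scale.
#' @param sweep `NULL`, or a list with `population`, `target_freq`,
#'   `span_bp` and optionally `core_snp` (snp_id).
#' @param missing_rate genotype missingness applied by [degrade()] in
#'   [simulate_panel()].
#' @param n_founders founder haplotypes per population (haplotype
#'   diversity of the mosaic background).
#' @param recomb_rate_per_bp founder-mosaic breakpoint rate; the default
#'   1e-6/bp (mean segment 1 Mb) makes EHH decay over a few hundred kb at
#'   chip spacing.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_samples = c(89, 47, 12), n_snps = 1200,
                       chrom = "X", chrom_length_bp = 135180000,
                       fst_background = 0.05, n_diff_loci = 5,
                       diff_fst = 0.5, diff_min_fst = 0.25,
                       sweep = list(population = "pop1", target_freq = 0.8,
                                    span_bp = 1e6),
                       missing_rate = 0, n_founders = 20,
                       recomb_rate_per_bp = 1e-6) {
  stopifnot(n_snps >= 10, fst_background >= 0, fst_background < 1,
            missing_rate >= 0, missing_rate < 1, n_founders >= 2)
  cfg <- list(seed = seed, n_samples = n_samples,
              n_populations = length(n_samples), n_snps = n_snps,
              chrom = chrom, chrom_length_bp = chrom_length_bp,
              fst_background = fst_background, n_diff_loci = n_diff_loci,
              diff_fst = diff_fst, diff_min_fst = diff_min_fst,
              sweep = sweep, missing_rate = missing_rate,
              n_founders = n_founders,
              recomb_rate_per_bp = recomb_rate_per_bp)
  class(cfg) <- "sim_config"
  cfg
}

.bn_draw <- function(p, f) {
  # Balding-Nichols: Beta(p (1-F)/F, (1-p)(1-F)/F); F = 0 degenerates to p
  if (f <= 0) return(rep(p, length.out = length(p)))
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

.param_fst <- function(p_i, w) {
  # parametric FST of fixed subpopulation frequencies, weighted pooling
  p <- sum(w * p_i) / sum(w)
  h_t <- 2 * p * (1 - p)
  h_s <- sum(w * 2 * p_i * (1 - p_i)) / sum(w)
  if (h_t <= 0) 0 else (h_t - h_s) / h_t
}

#' Simulate a neutral multi-population haplotype panel
#'
#' Per-SNP derived-allele frequencies are drawn uniformly on (0.05, 0.95);
#' population frequencies follow the Balding-Nichols Beta around them.
#' Haplotypes are recombinant mosaics of per-population founder haplotypes
#' (Poisson crossovers along the chromosome), so haplotype identity decays
#' with distance. Differentiated loci are redrawn at `diff_fst` until their
#' parametric FST reaches `diff_min_fst`. Ref/alt orientation is
#' randomized; the true ancestral allele is recorded in the map.
#'
#' @param cfg a [sim_config()].
#' @return list with `map` ([snp_map], truth ancestral filled in), `H`
#'   (2n x SNPs alt-indicator matrix, rownames = sample ids), `pops`
#'   (named vector sample -> population) and `truth` (generating
#'   frequencies, differentiated-locus table).
#' @export
simulate_neutral <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$fst_background == 0 && cfg$n_diff_loci > 0)
    stop("differentiated loci require a nonzero background F")
  set.seed(cfg$seed)
  k <- cfg$n_populations
  m <- cfg$n_snps
  pos <- sort(sample.int(cfg$chrom_length_bp, m))
  p_derived <- runif(m, 0.05, 0.95)

  pop_labels <- paste0("pop", seq_len(k))
  pfreq <- matrix(0, nrow = k, ncol = m, dimnames = list(pop_labels, NULL))
  for (i in seq_len(k)) pfreq[i, ] <- .bn_draw(p_derived, cfg$fst_background)

  diff_loci <- integer(0)
  w <- 2 * cfg$n_samples
  if (cfg$n_diff_loci > 0) {
    diff_loci <- sort(sample.int(m, cfg$n_diff_loci))
    for (j in diff_loci) {
      for (try in 1:200) {
        cand <- .bn_draw(rep(p_derived[j], k), cfg$diff_fst)
        if (.param_fst(cand, w) >= cfg$diff_min_fst) break
      }
      pfreq[, j] <- cand
    }
  }

  # founder haplotypes and sample mosaics, per population
  n_hap <- 2L * sum(cfg$n_samples)
  D <- matrix(0L, nrow = n_hap, ncol = m)  # derived-allele indicator
  sample_ids <- unlist(lapply(seq_len(k), function(i)
    sprintf("%s_s%03d", pop_labels[i], seq_len(cfg$n_samples[i]))))
  rownames(D) <- rep(sample_ids, each = 2L)
  pops <- setNames(rep(pop_labels, cfg$n_samples), sample_ids)

  row0 <- 0L
  for (i in seq_len(k)) {
    founders <- matrix(rbinom(cfg$n_founders * m, 1L, rep(pfreq[i, ], each = cfg$n_founders)),
                       nrow = cfg$n_founders, ncol = m)
    for (h in seq_len(2L * cfg$n_samples[i])) {
      nbp <- rpois(1, cfg$recomb_rate_per_bp * cfg$chrom_length_bp)
      breaks <- sort(runif(nbp, 1, cfg$chrom_length_bp))
      seg <- findInterval(pos, breaks) + 1L
      choice <- sample.int(cfg$n_founders, nbp + 1L, replace = TRUE)
      D[row0 + h, ] <- founders[cbind(choice[seg], seq_len(m))]
    }
    row0 <- row0 + 2L * cfg$n_samples[i]
  }

  # randomize ref/alt orientation; record the true ancestral allele
  anc_is_ref <- runif(m) < 0.5
  H <- D
  H[, !anc_is_ref] <- 1L - H[, !anc_is_ref, drop = FALSE]
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(alleles, b), 1), character(1))
  map <- snp_map(sprintf("snp%04d", seq_len(m)), cfg$chrom, pos, ref, alt,
                 ancestral = ifelse(anc_is_ref, "ref", "alt"))
  colnames(H) <- map$snp_id

  truth <- list(p_derived = p_derived, pop_freq_derived = pfreq,
                diff_loci = if (length(diff_loci))
                  data.frame(snp_id = map$snp_id[diff_loci],
                             pos = pos[diff_loci],
                             fst_param = vapply(diff_loci, function(j)
                               .param_fst(pfreq[, j], w), numeric(1)),
                             stringsAsFactors = FALSE)
                else data.frame())
  list(map = map, H = H, pops = pops, truth = truth)
}

#' Inject a hard sweep into a haplotype panel
#'
#' Randomly chosen haplotypes of the sweep population are overwritten,
#' across a window centred on the core SNP, with copies of one donor
#' haplotype carrying the derived core allele, until the derived frequency
#' at the core reaches the target. Haplotypes outside the window are
#' untouched, so the injected signal is exactly the long shared haplotype
#' a recent hard sweep leaves behind.
#'
#' @param H haplotype matrix (alt indicator, rownames = sample ids).
#' @param map matching [snp_map] with resolved ancestral alleles.
#' @param pops named vector sample -> population.
#' @param population sweep population label.
#' @param target_freq target derived frequency at the core.
#' @param span_bp sweep window width (clamped to the chromosome with a
#'   warning when it sticks out).
#' @param core_snp `snp_id` of the core; by default a random SNP with
#'   derived frequency in [0.1, 0.4] in the sweep population, near the
#'   middle 80% of the chromosome.
#' @return list with `H` (modified) and `truth` (focal SNP, achieved
#'   frequency, donor count).
#' @export
inject_sweep <- function(H, map, pops, population, target_freq = 0.8,
                         span_bp = 1e6, core_snp = NULL) {
  rows <- which(unname(pops[rownames(H)]) == population)
  if (!length(rows)) stop("unknown sweep population: ", population)
  derived_val <- ifelse(map$ancestral == "ref", 1L, 0L)
  dfreq <- vapply(seq_len(ncol(H)), function(j)
    mean(H[rows, j] == derived_val[j]), numeric(1))
  if (is.null(core_snp)) {
    span_lo <- 0.1 * max(map$pos); span_hi <- 0.9 * max(map$pos)
    cand <- which(dfreq >= 0.1 & dfreq <= 0.4 &
                    map$pos >= span_lo & map$pos <= span_hi)
    if (!length(cand)) cand <- which(dfreq >= 0.05 & dfreq <= 0.5)
    if (!length(cand)) stop("no suitable core SNP for the sweep")
    core <- sample(cand, 1)
  } else {
    core <- match(core_snp, map$snp_id)
    if (is.na(core)) stop("core SNP not found: ", core_snp)
  }
  if (target_freq <= dfreq[core])
    stop("target frequency must exceed the current derived frequency")
  half <- span_bp / 2
  if (map$pos[core] - half < 1 || map$pos[core] + half > max(map$pos))
    warning("sweep span clamped to the chromosome")
  win <- which(map$pos >= map$pos[core] - half & map$pos <= map$pos[core] + half)

  dv <- derived_val[core]
  carriers <- rows[H[rows, core] == dv]
  if (!length(carriers)) {
    donor <- sample(rows, 1)
    H[donor, core] <- dv
    carriers <- donor
  }
  donor <- if (length(carriers) == 1) carriers else sample(carriers, 1)
  n_target <- round(target_freq * length(rows))
  need <- n_target - length(carriers)
  non <- setdiff(rows, carriers)
  converts <- if (need <= 0) integer(0) else
    if (length(non) == 1) non else sample(non, need)
  # a hard sweep has a single origin: every carrier shares the donor's
  # background across the window, pre-existing carriers included
  recip <- union(setdiff(carriers, donor), converts)
  for (r in recip) H[r, win] <- H[donor, win]
  achieved <- mean(H[rows, core] == dv)
  truth <- list(core_snp = map$snp_id[core], core_pos = map$pos[core],
                population = population, target_freq = target_freq,
                achieved_freq = achieved, span_bp = span_bp,
                window_snps = map$snp_id[win])
  list(H = H, truth = truth)
}

#' Mask genotypes and/or collapse haplotypes to genotypes
#'
#' @param x haplotype matrix (2n x SNPs) or genotype matrix.
#' @param missing_rate independent per-entry missingness probability.
#' @param unphase collapse a haplotype matrix to 0/1/2 genotypes first.
#' @return the degraded matrix.
#' @export
degrade <- function(x, missing_rate = 0, unphase = FALSE) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (unphase) {
    n <- nrow(x) / 2L
    g <- x[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      x[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    rownames(g) <- rownames(x)[seq(1L, 2L * n, by = 2L)]
    x <- g
  }
  if (missing_rate > 0) {
    mask <- runif(length(x)) < missing_rate
    x[mask] <- NA
  }
  x
}

#' Simulate a complete study panel (neutral background + sweep + QC noise)
#'
#' Convenience wrapper: [simulate_neutral()], then [inject_sweep()] (when
#' configured), then a genotype view via [degrade()].
#'
#' @param cfg a [sim_config()].
#' @return list with `map`, `H` (phased, complete), `G` (genotype view,
#'   with missingness when `missing_rate > 0`), `pops` and `truth`
#'   (including `sweep` when injected).
#' @export
simulate_panel <- function(cfg) {
  base <- simulate_neutral(cfg)
  truth <- base$truth
  H <- base$H
  if (!is.null(cfg$sweep)) {
    sw <- inject_sweep(H, base$map, base$pops,
                       population = cfg$sweep$population,
                       target_freq = cfg$sweep$target_freq,
                       span_bp = cfg$sweep$span_bp,
                       core_snp = cfg$sweep$core_snp)
    H <- sw$H
    truth$sweep <- sw$truth
  }
  G <- degrade(H, missing_rate = cfg$missing_rate, unphase = TRUE)
  list(map = base$map, H = H, G = G, pops = base$pops, truth = truth)
}

#' Write a simulated panel to disk (VCF + population TSV + truth JSON)
#'
#' @param panel output of [simulate_panel()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(panel$map, panel$H, file.path(dir, "panel.vcf"))
  write.table(data.frame(sample = names(panel$pops),
                         population = unname(panel$pops)),
              file.path(dir, "populations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(panel$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
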