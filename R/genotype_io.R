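# Readers and writers for the formats the pipeline touches: VCF (phased GT),
# PLINK PED/MAP text, TSV score tracks and BED region exports. Only biallelic
# SNPs on a single chromosome are supported; anything else errors loudly.

.valid_bases <- c("A", "C", "G", "T")

#' Construct a SNP map table
#'
#' A SNP map is a plain `data.frame` with one row per biallelic SNP and
#' columns `snp_id`, `chrom`, `pos` (1-based bp), `ref`, `alt` and
#' `ancestral` (one of `"ref"`, `"alt"`, `"unknown"`). Positions must be
#' strictly increasing.
#'
#' @param snp_id character vector of SNP identifiers.
#' @param chrom chromosome name (recycled).
#' @param pos integer positions, 1-based, strictly increasing.
#' @param ref,alt single-base alleles; `ref[i] != alt[i]`.
#' @param ancestral ancestral-allele call per SNP.
#' @return a `data.frame` of class `snp_map`.
#' @export
snp_map <- function(snp_id, chrom, pos, ref, alt,
                    ancestral = rep("unknown", length(snp_id))) {
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("positions must be >= 1 (1-based)")
  if (is.unsorted(pos, strictly = TRUE))
    stop("SNP positions must be strictly increasing (unsorted input)")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  if (!all(ancestral %in% c("ref", "alt", "unknown")))
    stop("ancestral must be one of 'ref', 'alt', 'unknown'")
  out <- data.frame(snp_id = as.character(snp_id),
                    chrom = as.character(chrom),
                    pos = pos, ref = as.character(ref),
                    alt = as.character(alt),
                    ancestral = as.character(ancestral),
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_map", "data.frame")
  out
}

.parse_gt <- function(gt) {
  # gt: character matrix variants x samples; returns list(a1, a2, sep)
  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  a1[a1 == "."] <- NA_character_
  a2[a2 == "."] <- NA_character_
  list(a1 = suppressWarnings(array(as.integer(a1), dim = dim(gt))),
       a2 = suppressWarnings(array(as.integer(a2), dim = dim(gt))),
       sep = sep)
}

#' Read a single-chromosome VCF of biallelic SNPs
#'
#' Parses GT fields into a genotype matrix (samples x SNPs, alt-allele
#' counts 0/1/2, `NA` for missing). When every genotype is phased (`|`) and
#' complete, a haplotype matrix (2n x SNPs, alt-allele indicator) is
#' returned as well; otherwise `haplotypes` is `NULL`. Ancestral alleles are
#' taken from the `AA` INFO tag when present.
#'
#' @param path path to a VCF (plain text or bgzipped).
#' @param require_phased error if any called genotype is unphased.
#' @return list with `map` ([snp_map]), `genotypes`, and `haplotypes`
#'   (matrix with rownames = sample ids repeated twice, or `NULL`).
#' @export
read_vcf <- function(path, require_phased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  id <- fix[, "ID"]
  bad <- is.na(alt) | grepl(",", alt) | nchar(ref) != 1L | nchar(alt) != 1L
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("multiallelic or non-SNP record at %s:%d (REF=%s ALT=%s)",
                 chrom[k], pos[k], ref[k], alt[k]))
  }
  if (length(unique(chrom)) > 1L)
    stop("VCF must contain exactly one chromosome")
  if (is.unsorted(pos, strictly = TRUE))
    stop("unsorted (or duplicated) positions in VCF")
  id[is.na(id) | id == "."] <- paste0(chrom, "_", pos)[is.na(id) | id == "."]

  aa <- tryCatch(vcfR::extract.info(v, element = "AA"),
                 error = function(e) NULL)
  ancestral <- rep("unknown", length(pos))
  if (!is.null(aa)) {
    ancestral[!is.na(aa) & aa == ref] <- "ref"
    ancestral[!is.na(aa) & aa == alt] <- "alt"
  }
  map <- snp_map(id, chrom[1], pos, ref, alt, ancestral)

  gt <- vcfR::extract.gt(v, element = "GT")  # variants x samples
  samples <- colnames(gt)
  pg <- .parse_gt(gt)
  called <- !is.na(pg$a1) & !is.na(pg$a2)
  if (require_phased && any(pg$sep == "/" & called))
    stop("require_phased: unphased genotypes present")
  G <- t(pg$a1 + pg$a2)  # samples x variants; NA where missing
  dimnames(G) <- list(samples, id)

  H <- NULL
  if (all(called) && all(pg$sep == "|")) {
    n <- length(samples)
    H <- matrix(0L, nrow = 2L * n, ncol = length(id))
    H[seq(1L, 2L * n, by = 2L), ] <- t(pg$a1)
    H[seq(2L, 2L * n, by = 2L), ] <- t(pg$a2)
    rownames(H) <- rep(samples, each = 2L)
    colnames(H) <- id
  }
  list(map = map, genotypes = G, haplotypes = H)
}

#' Write a phased haplotype panel as VCF
#'
#' @param map a [snp_map].
#' @param H haplotype matrix (2n x SNPs, alt indicator), rownames = sample
#'   ids repeated twice, consecutive rows per sample.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(map, H, path) {
  samples <- unique(rownames(H))
  n <- length(samples)
  stopifnot(nrow(H) == 2L * n, ncol(H) == nrow(map))
  aa_base <- ifelse(map$ancestral == "ref", map$ref,
                    ifelse(map$ancestral == "alt", map$alt, NA))
  info <- ifelse(is.na(aa_base), ".", paste0("AA=", aa_base))
  h1 <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = nrow(map))  # variants x samples
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", map$chrom[1]),
           "##INFO=<ID=AA,Number=1,Type=Character,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$snp_id, map$ref, map$alt, ".", "PASS",
                info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read PLINK text PED/MAP files
#'
#' Alleles are recoded to alt-allele counts 0/1/2; a `0 0` pair is missing.
#' The reference allele per SNP is taken from `ref` when given, otherwise
#' the first allele observed in file order.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param ref optional character vector of reference alleles, one per SNP.
#' @return list with `map` ([snp_map], ancestral all `"unknown"`) and
#'   `genotypes` (samples x SNPs).
#' @export
read_ped_map <- function(ped_path, map_path, ref = NULL) {
  mp <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) != 4L) stop("MAP file must have 4 columns (chrom, id, cM, bp)")
  names(mp) <- c("chrom", "snp_id", "cm", "pos")
  m <- nrow(mp)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  nc <- lengths(toks)
  if (any(nc != want)) {
    k <- which(nc != want)[1]
    stop(sprintf("PED line %d has %d fields; expected %d (6 + 2 x %d SNPs)",
                 k, nc[k], want, m))
  }
  tk <- do.call(rbind, toks)
  samples <- tk[, 2L]
  a1 <- tk[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tk[, 6L + 2L * seq_len(m), drop = FALSE]
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA

  refs <- character(m); alts <- character(m)
  G <- matrix(NA_integer_, nrow = length(samples), ncol = m)
  for (j in seq_len(m)) {
    obs <- c(rbind(a1[, j], a2[, j]))  # file order: sample by sample
    seen <- unique(obs[!is.na(obs)])
    if (length(seen) > 2L)
      stop(sprintf("SNP %s has >2 alleles in PED", mp$snp_id[j]))
    rj <- if (!is.null(ref)) ref[j] else seen[1]
    if (is.na(rj)) rj <- "A"
    aj <- setdiff(seen, rj)
    if (length(aj) == 0L) aj <- setdiff(.valid_bases, rj)[1]
    refs[j] <- rj; alts[j] <- aj[1]
    G[, j] <- (a1[, j] != rj) + (a2[, j] != rj)
  }
  ord <- order(mp$pos)
  mp <- mp[ord, ]; G <- G[, ord, drop = FALSE]
  refs <- refs[ord]; alts <- alts[ord]
  map <- snp_map(mp$snp_id, mp$chrom, mp$pos, refs, alts)
  dimnames(G) <- list(samples, map$snp_id)
  list(map = map, genotypes = G)
}

#' Resolve ancestral alleles
#'
#' Applies a user table of ancestral bases where available; remaining
#' unknowns are either set to the major allele across all samples
#' (`fallback = "major_allele"`, the default, with a warning since major
#' alleles are an imperfect proxy) or left unknown and later excluded from
#' the iHS scan (`fallback = "skip"`).
#'
#' @param map a [snp_map].
#' @param table optional named character vector, `snp_id -> base`.
#' @param genotypes genotype matrix, required for the major-allele fallback.
#' @param fallback `"major_allele"` or `"skip"`.
#' @return the updated [snp_map].
#' @export
set_ancestral <- function(map, table = NULL, genotypes = NULL,
                          fallback = c("major_allele", "skip")) {
  fallback <- match.arg(fallback)
  if (!is.null(table)) {
    idx <- match(names(table), map$snp_id)
    keep <- !is.na(idx)
    idx <- idx[keep]; base <- unname(table[keep])
    is_ref <- base == map$ref[idx]
    is_alt <- base == map$alt[idx]
    if (any(!is_ref & !is_alt)) {
      bad <- map$snp_id[idx[!is_ref & !is_alt]]
      stop("ancestral table base matches neither allele for: ",
           paste(bad, collapse = ", "))
    }
    map$ancestral[idx] <- ifelse(is_ref, "ref", "alt")
  }
  unk <- map$ancestral == "unknown"
  if (any(unk) && fallback == "major_allele") {
    if (is.null(genotypes))
      stop("major_allele fallback needs the genotype matrix")
    p_alt <- colMeans(genotypes[, unk, drop = FALSE], na.rm = TRUE) / 2
    map$ancestral[unk] <- ifelse(!is.na(p_alt) & p_alt > 0.5, "alt", "ref")
    warning(sprintf("ancestral allele unknown for %d SNPs; set to the major allele",
                    sum(unk)))
  }
  map
}

#' Write / read a per-SNP score track as TSV
#'
#' Missing values are written as literal `NA`; numeric values keep full
#' double precision so a write/read round trip is lossless to 1e-9.
#'
#' @param track a data.frame with at least `chrom`, `pos`, `snp_id`.
#' @param path file path.
#' @return `path` invisibly ([write_score_track]); a data.frame
#'   ([read_score_track]).
#' @export
write_score_track <- function(track, path) {
  stopifnot(all(c("chrom", "pos", "snp_id") %in% names(track)))
  num <- vapply(track, is.numeric, logical(1))
  out <- track
  for (j in which(num)) {
    v <- out[[j]]
    if (is.double(v)) out[[j]] <- ifelse(is.na(v), NA, sprintf("%.15g", v))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_score_track
#' @export
read_score_track <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Write selection regions as BED (0-based half-open)
#'
#' Internal coordinates are 1-based inclusive; on export the start is
#' shifted by one so every written interval is `[start - 1, end)`.
#'
#' @param regions a data.frame of regions (see [build_regions()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- "#chrom\tstart\tend\tname\tscore"
  if (nrow(regions)) {
    name <- if ("label" %in% names(regions) && any(nzchar(regions$label)))
      paste(regions$method, regions$label, sep = ":") else regions$method
    lines <- c(lines, paste(regions$chrom,
                            format(regions$start_bp - 1L, scientific = FALSE, trim = TRUE),
                            format(regions$end_bp, scientific = FALSE, trim = TRUE),
                            name,
                            sprintf("%.6g", regions$peak_value), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column sample-to-population table
#'
#' @param path TSV with columns `sample` and `population` (header optional).
#' @return named character vector, sample id -> population label.
#' @export
read_population_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, header = TRUE)
  if (!all(c("sample", "population") %in% names(d))) {
    d <- read.delim(path, stringsAsFactors = FALSE, header = FALSE)
    names(d)[1:2] <- c("sample", "population")
  }
  setNames(as.character(d$population), as.character(d$sample))
}
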