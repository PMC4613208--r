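# End-to-end orchestration: QC -> per-population iHS scans -> joint and
# pairwise FST scans -> outliers -> regions -> candidate combination ->
# summaries -> optional gene annotation, with every intermediate artifact
# written under one run directory. Reruns with the same config are
# byte-identical (no timestamps in any output).

#' Build a pipeline run configuration
#'
#' Defaults mirror the stage functions: QC call rate 0.90, MAF 0.05, HWE
#' p 1e-6; EHH cutoff 0.05, max gap 500 kb, bin width 0.05; `|iHS| > 2`;
#' region half-width 200 kb; annotation pad 100 kb; threshold combination.
#'
#' @param vcf phased single-chromosome VCF.
#' @param pops_file sample -> population TSV.
#' @param out_dir run directory (created).
#' @param genes_file optional gene models (GFF3/BED); annotation is
#'   skipped with a log message when absent.
#' @param ancestral_file optional TSV `snp_id`, `base` of ancestral calls.
#' @param ancestral_fallback `"major_allele"` or `"skip"`.
#' @param seed RNG seed recorded in the provenance (the pipeline itself is
#'   deterministic given its inputs).
#' @param chrom_length chromosome length for window clamping (defaults to
#'   the last SNP position).
#' @param min_call_rate,min_maf,hwe_p_min,duplicate_ibs QC thresholds.
#' @param ehh_cutoff,max_gap_bp,bin_width,ihs_threshold iHS parameters.
#' @param half_width_bp,pad_bp region construction / annotation widths.
#' @param combine_mode `"threshold"` or `"fdr"` (see
#'   [combine_candidates()]).
#' @return a `run_config` list.
#' @export
run_config <- function(vcf, pops_file, out_dir, genes_file = NULL,
                       ancestral_file = NULL,
                       ancestral_fallback = "major_allele", seed = 1,
                       chrom_length = NULL, min_call_rate = 0.90,
                       min_maf = 0.05, hwe_p_min = 1e-6,
                       duplicate_ibs = 0.99, ehh_cutoff = 0.05,
                       max_gap_bp = 500000, bin_width = 0.05,
                       ihs_threshold = 2.0, half_width_bp = 200000,
                       pad_bp = 100000, combine_mode = "threshold") {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full selection-signature pipeline
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with the run directory and the in-memory
#'   main results (`summary`, `candidates`, `overlaps`, tracks, regions).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  inp <- stage("input", {
    v <- read_vcf(cfg$vcf, require_phased = TRUE)
    if (is.null(v$haplotypes))
      stop("pipeline input must be fully phased and complete")
    v$pops <- read_population_table(cfg$pops_file)
    v
  })
  map <- inp$map
  if (is.null(cfg$chrom_length)) cfg$chrom_length <- max(map$pos)

  map <- stage("ancestral", {
    tab <- NULL
    if (!is.null(cfg$ancestral_file)) {
      a <- read.delim(cfg$ancestral_file, stringsAsFactors = FALSE)
      tab <- setNames(a[[2]], a[[1]])
    }
    suppressWarnings(set_ancestral(map, table = tab,
                                   genotypes = inp$genotypes,
                                   fallback = cfg$ancestral_fallback))
  })

  qc <- stage("qc", {
    fs <- filter_samples(inp$genotypes, min_call_rate = cfg$min_call_rate,
                         duplicate_ibs = cfg$duplicate_ibs)
    fv <- filter_snps(fs$genotypes, map, pops = inp$pops,
                      min_call_rate = cfg$min_call_rate,
                      min_maf = cfg$min_maf, hwe_p_min = cfg$hwe_p_min)
    report <- fv$report
    report$samples_removed <- fs$report$samples_removed
    list(G = fv$genotypes, map = fv$map, report = report)
  })
  write_qc_report(qc$report, cfg$out_dir)
  keep_samples <- rownames(qc$G)
  H <- inp$haplotypes[rownames(inp$haplotypes) %in% keep_samples,
                      qc$map$snp_id, drop = FALSE]
  map <- qc$map
  pops <- inp$pops[keep_samples]
  breeds <- sort(unique(unname(pops)))

  pca <- stage("pca", pca_coordinates(qc$G))
  write.table(data.frame(sample = rownames(pca),
                         population = unname(pops[rownames(pca)]),
                         round(pca, 6)),
              file.path(cfg$out_dir, "pca_coordinates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ihs_tracks <- list(); ihs_regions <- list()
  for (b in breeds) {
    tr <- stage(paste0("ihs_", b),
                suppressWarnings(ihs_scan(H, map, pops = pops, population = b,
                                          min_maf = cfg$min_maf,
                                          ehh_cutoff = cfg$ehh_cutoff,
                                          max_gap_bp = cfg$max_gap_bp,
                                          bin_width = cfg$bin_width)))
    write_score_track(tr, file.path(cfg$out_dir, paste0("ihs_", b, ".tsv")))
    out <- ihs_outliers(tr, threshold = cfg$ihs_threshold)
    ihs_tracks[[b]] <- tr
    ihs_regions[[b]] <- build_regions(out, chrom = map$chrom[1],
                                      half_width_bp = cfg$half_width_bp,
                                      chrom_length = cfg$chrom_length,
                                      method = "ihs", label = b,
                                      value_col = "ihs")
  }

  fst_tracks <- list(); fst_regions <- list()
  scan_sets <- c(list(breeds),
                 if (length(breeds) > 2) utils::combn(breeds, 2, simplify = FALSE))
  for (s in scan_sets) {
    lab <- paste(s, collapse = "-")
    tr <- stage(paste0("fst_", lab),
                fst_scan(H, map, pops, subset = s, label = lab))
    write_score_track(tr, file.path(cfg$out_dir, paste0("fst_", lab, ".tsv")))
    bx <- boxplot_outliers(tr$fst)
    out <- tr[bx$is_upper, , drop = FALSE]  # upper tail only: selection
    fst_tracks[[lab]] <- tr
    fst_regions[[lab]] <- build_regions(out, chrom = map$chrom[1],
                                        half_width_bp = cfg$half_width_bp,
                                        chrom_length = cfg$chrom_length,
                                        method = "fst", label = lab,
                                        value_col = "fst")
  }

  candidates <- list()
  for (b in breeds) {
    involves_b <- vapply(strsplit(names(fst_regions), "-", fixed = TRUE),
                         function(parts) b %in% parts, logical(1))
    fr <- do.call(rbind, fst_regions[involves_b])
    iq <- fq <- NULL
    if (cfg$combine_mode == "fdr") {
      tr <- ihs_tracks[[b]]
      iq <- data.frame(pos = tr$pos,
                       q = bh_fdr(2 * pnorm(-abs(tr$ihs))))
      joint <- fst_tracks[[paste(breeds, collapse = "-")]]
      fq <- data.frame(pos = joint$pos,
                       q = bh_fdr(empirical_upper_p(joint$fst)))
    }
    candidates[[b]] <- combine_candidates(ihs_regions[[b]], fr,
                                          ihs_q = iq, fst_q = fq,
                                          mode = cfg$combine_mode, label = b)
  }

  all_regions <- rbind(do.call(rbind, ihs_regions),
                       do.call(rbind, fst_regions))
  cand_regions <- do.call(rbind, candidates)
  summary_tab <- rbind(summarize_regions(all_regions),
                       summarize_regions(cand_regions))
  write.table(summary_tab, file.path(cfg$out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cand_regions, file.path(cfg$out_dir, "candidate_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_regions_bed(cand_regions, file.path(cfg$out_dir, "candidate_regions.bed"))

  overlaps <- NULL
  if (length(breeds) >= 2) {
    prs <- utils::combn(breeds, 2, simplify = FALSE)
    overlaps <- do.call(rbind, lapply(prs, function(p)
      data.frame(label_a = p[1], label_b = p[2],
                 overlap_mb = round(overlap_length(candidates[[p[1]]],
                                                   candidates[[p[2]]]), 2),
                 stringsAsFactors = FALSE)))
    write.table(overlaps, file.path(cfg$out_dir, "candidate_overlaps.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  gene_hits <- NULL
  if (!is.null(cfg$genes_file) && file.exists(cfg$genes_file)) {
    gene_hits <- stage("annotation", {
      genes <- read_gene_models(cfg$genes_file)
      padded <- extend_region(cand_regions, pad_bp = cfg$pad_bp,
                              chrom_length = cfg$chrom_length)
      genes_in_regions(padded, genes)
    })
    write.table(gene_hits, file.path(cfg$out_dir, "candidate_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    message("annotation skipped: no gene-model file")
  }

  prov <- cfg
  class(prov) <- NULL
  prov$package_version <- as.character(packageVersion("xsweep"))
  jsonlite::write_json(prov[order(names(prov))],
                       file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  jsonlite::write_json(summary_tab, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(out_dir = cfg$out_dir, summary = summary_tab,
                 candidates = cand_regions, overlaps = overlaps,
                 ihs_tracks = ihs_tracks, fst_tracks = fst_tracks,
                 ihs_regions = ihs_regions, fst_regions = fst_regions,
                 gene_hits = gene_hits, qc_report = qc$report, pca = pca))
}
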