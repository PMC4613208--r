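#!/usr/bin/env Rscript
# Stage 4: between-population FST scans.
#
# Per-SNP FST = (H_T - H_S)/H_T over the three-breed joint scan and the
# three pairwise scans. Outliers are called by the boxplot rule on each
# scan's empirical FST distribution (UL = F_U + 1.5 IQR); upper outliers
# only are promoted to regions, since selection inflates differentiation.

library(xsweep)

dat <- "results/data"
out <- "results/fst"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

v <- read_vcf(file.path(dat, "panel_qc.vcf"), require_phased = TRUE)
pops <- read_population_table(file.path(dat, "populations.tsv"))
pops <- pops[names(pops) %in% rownames(v$genotypes)]
chrom_len <- 135180000

truth <- jsonlite::read_json(file.path(dat, "truth.json"))
diff_ids <- vapply(truth$diff_loci, function(r) r$snp_id, character(1))

breeds <- sort(unique(unname(pops)))
scan_sets <- c(list(breeds), utils::combn(breeds, 2, simplify = FALSE))
for (s in scan_sets) {
  lab <- paste(s, collapse = "-")
  tr <- fst_scan(v$haplotypes, v$map, pops, subset = s, label = lab)
  write_score_track(tr, file.path(out, paste0("fst_", lab, ".tsv")))
  bx <- boxplot_outliers(tr$fst)
  outl <- tr[bx$is_upper, , drop = FALSE]
  regs <- build_regions(outl, chrom = v$map$chrom[1],
                        chrom_length = chrom_len, method = "fst",
                        label = lab, value_col = "fst")
  write.table(regs, file.path(out, paste0("fst_regions_", lab, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  recovered <- sum(diff_ids %in% outl$snp_id)
  cat(sprintf("%s: UL %.3f, %d upper outliers (max FST %.3f), %d regions; %d/%d truth loci recovered\n",
              lab, bx$thresholds$ul, nrow(outl),
              max(tr$fst, na.rm = TRUE), nrow(regs),
              recovered, length(diff_ids)))
}
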