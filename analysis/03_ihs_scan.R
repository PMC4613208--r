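#!/usr/bin/env Rscript
# Stage 3: within-population iHS scans.
#
# For every breed, integrates EHH around each SNP for the ancestral and the
# derived core allele, forms ln(iHH_A/iHH_D), standardizes within
# derived-frequency bins, and calls outliers at |iHS| > 2. Outlier SNPs are
# expanded into +/-200 kb windows and merged into candidate regions.

library(xsweep)

dat <- "results/data"
out <- "results/ihs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

v <- read_vcf(file.path(dat, "panel_qc.vcf"), require_phased = TRUE)
pops <- read_population_table(file.path(dat, "populations.tsv"))
pops <- pops[names(pops) %in% rownames(v$genotypes)]
chrom_len <- 135180000

truth <- jsonlite::read_json(file.path(dat, "truth.json"))
core_pos <- truth$sweep$core_pos

for (b in sort(unique(unname(pops)))) {
  tr <- suppressWarnings(ihs_scan(v$haplotypes, v$map, pops = pops,
                                  population = b))
  write_score_track(tr, file.path(out, paste0("ihs_", b, ".tsv")))
  outl <- ihs_outliers(tr)
  regs <- build_regions(outl, chrom = v$map$chrom[1],
                        chrom_length = chrom_len, method = "ihs", label = b,
                        value_col = "ihs")
  write.table(regs, file.path(out, paste0("ihs_regions_", b, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_regions_bed(regs, file.path(out, paste0("ihs_regions_", b, ".bed")))
  hit <- any(regs$start_bp <= core_pos & regs$end_bp >= core_pos)
  cat(sprintf("%s: %d scored SNPs, %d outliers (|iHS|>2), %d regions, top |iHS| %.2f%s\n",
              b, sum(!is.na(tr$ihs)), nrow(outl), nrow(regs),
              max(abs(tr$ihs), na.rm = TRUE),
              if (b == truth$sweep$population)
                sprintf("; sweep core %s region", if (hit) "INSIDE a" else "missed by every")
              else ""))
}
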