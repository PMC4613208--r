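#!/usr/bin/env Rscript
# Stage 2: quality control and population-structure inspection.
#
# PLINK-style filters on the genotype view of the phased panel: samples with
# call rate < 90% or duplicated (IBS >= 0.99), SNPs with call rate < 90%,
# MAF < 0.05 or per-population Hardy-Weinberg exact p < 1e-6. The PCA
# coordinates are a diagnostic: no samples are excluded from PCA clusters
# automatically. The QC-surviving phased panel is re-written for the scans.

library(xsweep)

dat <- "results/data"
out <- "results/qc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

v <- read_vcf(file.path(dat, "panel.vcf"), require_phased = TRUE)
pops <- read_population_table(file.path(dat, "populations.tsv"))

fs <- filter_samples(v$genotypes)
fv <- filter_snps(fs$genotypes, v$map, pops = pops)
report <- fv$report
report$samples_removed <- fs$report$samples_removed
write_qc_report(report, out)

keep <- rownames(fv$genotypes)
H <- v$haplotypes[rownames(v$haplotypes) %in% keep, fv$map$snp_id]
write_vcf(fv$map, H, file.path(dat, "panel_qc.vcf"))

pca <- pca_coordinates(fv$genotypes)
write.table(data.frame(sample = rownames(pca),
                       population = unname(pops[rownames(pca)]),
                       round(pca, 6)),
            file.path(out, "pca_coordinates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("samples: %d -> %d (%d removed)\n", nrow(v$genotypes),
            nrow(fv$genotypes), nrow(report$samples_removed)))
cat(sprintf("SNPs: %d -> %d (%s)\n", nrow(v$map), nrow(fv$map),
            if (nrow(report$snps_removed))
              paste(names(table(report$snps_removed$reason)),
                    table(report$snps_removed$reason), collapse = ", ")
            else "none removed"))
# PC1 separation by population, the analogue of the study's PCA screen
sep <- tapply(pca[, 1], unname(pops[rownames(pca)]), mean)
cat("population means on PC1:",
    paste(sprintf("%s=%.2f", names(sep), sep), collapse = "  "), "\n")
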