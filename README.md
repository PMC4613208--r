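# xsweep

Selection-signature scans on a single chromosome from phased SNP-chip
genotypes, for population geneticists and animal-breeding researchers who
want to locate genomic regions shaped by recent positive selection — for
example an X-chromosome scan across livestock breeds, where a handful of
populations of female samples are genotyped on a medium-density chip
(~1,000–1,500 SNPs per chromosome, ~100 kb spacing) and no genetic map is
available.

Two complementary statistics drive the scan:

- **iHS (integrated haplotype score)**, within each population. For each
  SNP, extended haplotype homozygosity
  `EHH(s) = Σ_g C(k_g,2) / C(n_c,2)` is integrated over physical distance
  separately for the haplotypes carrying the ancestral and the derived
  core allele, and

  `iHS = ( ln(iHH_A/iHH_D) − E[ln(iHH_A/iHH_D)] ) / SD[ln(iHH_A/iHH_D)]`,

  standardized within derived-allele-frequency bins. A recent sweep puts
  one allele on an unusually long shared haplotype, so `|iHS| > 2` flags
  it.
- **F_ST**, between populations, per SNP:
  `F_ST = (H_T − H_S)/H_T` with `H_T = 2pq` from the pooled frequency and
  `H_S` the size-weighted mean subpopulation expected heterozygosity.
  Outliers come from the boxplot rule on the scan's empirical
  distribution (`UL = F_U + 1.5·IQR`, `LL = F_L − 1.5·IQR`).

Around these sit PLINK-style quality control (call rate, MAF,
per-population Hardy–Weinberg exact test, duplicate detection by IBS),
PCA for structure inspection, candidate-region construction (±200 kb
windows merged), candidate combination across methods, overlap accounting
between populations, and gene annotation against a user-supplied
GFF3/BED with a ±100 kb extension. A seeded simulator (Balding–Nichols
differentiation over founder-mosaic haplotypes, plus injected hard
sweeps) provides ground truth for every stage; see
`vignettes/selection-scan-methods.Rmd` for the model and design choices.

## Worked example

Simulate the default study geometry — three populations of 89/47/12
samples, 1,200 SNPs over 135.18 Mb, background F = 0.05, five
differentiated loci (F = 0.5), one hard sweep driven to derived frequency
0.8 in `pop1` — then scan `pop1` with iHS and all populations with F_ST:

```r
library(xsweep)

panel <- simulate_panel(sim_config(seed = 101))
tr  <- ihs_scan(panel$H, panel$map, pops = panel$pops, population = "pop1")
out <- ihs_outliers(tr)                      # |iHS| > 2
regions <- build_regions(out, chrom = "X", chrom_length = 135180000,
                         method = "ihs", label = "pop1")
cat(nrow(out), "outlier SNPs ->", nrow(regions), "regions\n")
head(regions[order(-abs(regions$peak_value)), ], 3)
panel$truth$sweep[c("core_snp", "core_pos", "achieved_freq")]

ft <- fst_scan(panel$H, panel$map, panel$pops)
bx <- boxplot_outliers(ft$fst)
cat("FST fences: UL =", round(bx$thresholds$ul, 3),
    "; upper outliers:", length(bx$upper), "\n")
summarize_regions(regions)
```

Output:

```
46 outlier SNPs -> 35 regions
    start_bp    end_bp peak_snp peak_value n_snps
26 109595216 110411081  snp0988  -5.239901      6
27 110442345 110842345  snp0993  -3.273010      1
15  72386994  72786994  snp0634  -3.266306      1
$core_snp  "snp0988"
$core_pos  110162093
$achieved_freq  0.7977528

FST fences: UL = 0.2 ; upper outliers: 59
  method label n_outlier_snps n_regions avg_length_mb total_length_mb
1    ihs  pop1             46        35          0.44           15.29
```

The strongest iHS region is the one containing the injected sweep: its
peak is the focal SNP itself (`snp0988` at 110.16 Mb), the score is
negative because the *derived* allele rides the long haplotype, and six
outlier SNPs merged into one ~0.8 Mb region around it. The remaining
regions are the scan's empirical tail — exactly what a real scan
reports, which is why candidate calling combines two methods.

`run_pipeline(run_config(...))` chains every stage (QC → per-population
iHS → joint and pairwise F_ST → outliers → regions → combination →
summary → annotation) from a phased VCF plus a sample–population table,
writing every intermediate artifact, a machine-readable summary and a
provenance file into one run directory; reruns with the same
configuration are byte-identical.

## The analysis, step by step

The `analysis/` scripts run the full study on a simulated panel with
fixed seed, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # panel + ground truth + synthetic gene models
Rscript analysis/02_qc.R          # sample/SNP filters, PCA coordinates
Rscript analysis/03_ihs_scan.R    # per-breed iHS tracks, outliers, regions
Rscript analysis/04_fst_scan.R    # joint + pairwise FST, boxplot outliers, regions
Rscript analysis/05_regions.R     # combined candidates, summary table, overlaps
Rscript analysis/06_annotate.R    # genes in ±100 kb-padded candidate regions
```

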