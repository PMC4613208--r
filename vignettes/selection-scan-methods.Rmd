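---
title: "Methods: iHS and FST selection-signature scans on a single chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iHS and FST selection-signature scans on a single chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xsweep)
```

## What the package computes

`xsweep` scans one chromosome of phased SNP-chip genotypes for footprints
of recent positive selection, combining a within-population statistic (the
integrated haplotype score, iHS) with a between-population statistic
(per-SNP F~ST~ from expected heterozygosities). It was designed for the
setting of an X-chromosome scan in livestock breeds: a few populations of
female samples, ~1,000–1,500 biallelic SNPs at ~100 kb spacing, and no
genetic map, so all distances are physical (bp).

Because a chromosome-wide scan has many moving parts, every stage is a
separately exported and separately tested function, and a seeded simulator
(`sim_config()`, `simulate_panel()`) generates panels with known ground
truth — known ancestral alleles, known population frequencies, known
differentiated loci, and an injected hard sweep — so that each stage and
the whole pipeline can be validated against truth rather than against
another implementation.

## The statistics

**EHH and iHS.** For a core SNP and a core allele, the extended haplotype
homozygosity at a flanking SNP $s$ is the probability that two random
carrier haplotypes are identical at every SNP between the core and $s$
inclusive:

$$\mathrm{EHH}(s) = \frac{\sum_g \binom{k_g}{2}}{\binom{n_c}{2}},$$

where the $k_g$ are the sizes of the identity groups among the $n_c$
carriers. EHH starts at 1 at the core and is non-increasing outward.
Integrating EHH over physical distance on both sides (trapezoid rule)
gives iHH, computed separately for the ancestral ($iHH_A$) and derived
($iHH_D$) core allele, and

$$iHS = \frac{\ln(iHH_A/iHH_D) - \mathbf{E}[\ln(iHH_A/iHH_D)]}
             {\mathbf{SD}[\ln(iHH_A/iHH_D)]}.$$

A sweep drives one allele onto a long shared haplotype, so its iHH
dominates and $|iHS|$ grows; with the derived allele swept the score is
negative. The mean and SD are taken within derived-allele-frequency bins
(below). `p_ihs` is $-\log_{10}$ of the two-sided Gaussian tail
probability of the standardized score, which is justified by the
approximate standard normality of standardized iHS.

**Per-SNP F~ST~.** With pooled allele frequencies $p, q$ and
subpopulation frequencies $p_i$,

$$H_T = 1 - (p^2 + q^2), \qquad
  H_S = \sum_i \frac{n_i}{N}\, 2 p_i (1 - p_i), \qquad
  F_{ST} = \frac{H_T - H_S}{H_T},$$

the plain heterozygosity-ratio estimator with no small-sample (Nei or
Weir–Cockerham) correction. The pooled frequency is the
allele-count-weighted mean of the $p_i$, consistent with the weighting of
$H_S$; unweighted pooling is available via `weighted = FALSE`. Monomorphic
SNPs ($H_T = 0$) yield `NA`, and tiny negative values from rounding are
clamped to 0.

**Outlier rules.** iHS outliers are $|iHS| > 2$ (strict). F~ST~ outliers
use the boxplot rule on the empirical scan distribution: with quartiles
$F^L, F^U$ and $Q = F^U - F^L$, the fences are $UL = F^U + 1.5\,Q$ and
$LL = F^L - 1.5\,Q$; values strictly outside are outliers. Lower-tail
F~ST~ outliers are reported but never promoted to candidate regions —
selection inflates differentiation, so only the upper tail is a
selection signal.

**Regions.** Every outlier SNP spawns a window of ±200 kb (configurable);
overlapping or book-ended windows merge, the peak being the member SNP
with the largest absolute statistic. Candidate regions per population
combine the iHS regions with the F~ST~ regions of every scan involving
that population. Two combination modes exist: `threshold` (default), the
merged union of both methods' outlier regions — the operational rule of
the scan — and `fdr`, which keeps a region when the minimum
Benjamini–Hochberg q among its member SNPs is < 0.1 in both method tracks
or < 0.05 in at least one (iHS p-values from the Gaussian tail, F~ST~
p-values as empirical upper-tail ranks). The source material states the
FDR rule without an operational definition, so both readings are
provided rather than guessing a single intent.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_call_rate` | 0.90 | sample and SNP call-rate floor (strict `<` removes) |
| `duplicate_ibs` | 0.99 | IBS at or above which the later sample is a duplicate |
| `min_maf` | 0.05 | pooled MAF floor; also the iHS eligibility window on derived frequency |
| `hwe_p_min` | 1e-6 | HWE exact-test floor, per population |
| `ehh_cutoff` | 0.05 | EHH level at which integration stops (point excluded) |
| `max_gap_bp` | 500 kb | largest tolerated inter-SNP gap; larger gaps truncate the curve with a flag |
| `bin_width` | 0.05 | derived-frequency bin width for standardization; 1.0 gives one global bin |
| `ihs_threshold` | 2.0 | outlier threshold on \|iHS\| |
| `half_width_bp` | 200 kb | region half-width around an outlier SNP |
| `pad_bp` | 100 kb | annotation-time extension on each side of a candidate region |

The EHH cutoff and gap guard are standard practice for chip data: without
a cutoff, the long homozygosity tail accumulates noise, and a > 500 kb
gap means the curve in between is unobserved, so the side is truncated at
the last SNP before the gap and the SNP is flagged `truncated_by_gap`
rather than dropped. Binned standardization is used because the raw log
ratio depends strongly on the derived allele frequency; a single global
bin is the literal unconditional reading and remains available.

## Design choices where the design was genuinely open

- **HWE per population.** The QC removes a SNP only when the minimum
  HWE p across populations falls below the floor. Testing pooled
  genotypes would remove strongly differentiated SNPs via the Wahlund
  effect — exactly the SNPs the F~ST~ scan needs.
- **Exact test, two computational routes.** The HWE test is the exact
  conditional test over heterozygote configurations (the PLINK-style
  choice), implemented by the direct log-factorial formula; the test
  suite checks it against an independent recurrence-based enumeration.
- **Boundary semantics.** Removal thresholds use strict `<` exactly as
  stated for the QC rules; outlier calls use strict `>` so that a value
  equal to a fence or equal to 2.0 is not an outlier.
- **Quartiles.** Linear interpolation at ranks $0.25(n-1)$ and
  $0.75(n-1)$ on the sorted sample (R's type 7), cross-checked against a
  hand sort/interpolate oracle.
- **Duplicate rule.** "Duplicate" is operationalized as IBS ≥ 0.99 over
  co-called SNPs, dropping the later-listed sample (deterministic
  tie-break).
- **Ancestral alleles.** iHS needs ancestral/derived polarity, which chip
  annotations provide only partially. A user table takes precedence; the
  remaining SNPs either fall back to the major allele (default, with a
  warning) or stay unknown and are skipped by the scan (`fallback =
  "skip"`).
- **Coordinates.** 1-based inclusive internally (VCF convention); BED
  export is the single 0-based half-open conversion point. Region lengths
  are reported as `end - start` in Mb, matching the convention of
  reporting a ±200 kb window as 0.40 Mb.
- **Ploidy.** Only female samples are modeled; every sample is diploid on
  X. Hemizygous males are out of scope.

## What the simulator emulates — and what it does not

`simulate_neutral()` draws per-SNP derived frequencies uniformly on
(0.05, 0.95) and population frequencies from the Balding–Nichols Beta
distribution with differentiation parameter $F$. Haplotypes are
recombinant mosaics of per-population founder haplotypes: breakpoints are
Poisson along the chromosome and each segment copies a random founder.
This gives genuine LD that decays with physical distance — the property
EHH integration needs — at a tiny fraction of the cost of a coalescent
simulation.

Three generator constants were fixed from the study geometry and standard
population-genetic scales, and are not tuned per analysis:

- **Founder count 20 per population**: haplotype diversity typical of a
  bottlenecked livestock breed; it also contributes the drift component
  that makes small-sample F~ST~ estimates realistically noisy.
- **Breakpoint rate 1e-6/bp** (mean segment 1 Mb): makes EHH decay over a
  few hundred kb at ~110 kb SNP spacing, the regime chip-based EHH scans
  operate in.
- **Differentiated loci** are Balding–Nichols draws at $F = 0.5$,
  redrawn until the parametric F~ST~ of the drawn frequencies reaches
  0.25 — Wright's "very great differentiation" band — because the
  ground-truth list must contain loci that actually differentiated;
  an unconditioned $F=0.5$ draw can fix the same allele everywhere.

`inject_sweep()` creates a single-origin hard sweep: one donor haplotype
carrying the derived core allele is copied, across a window centred on the
core, onto every other carrier and onto enough non-carriers to reach the
target frequency. Immediately after injection, EHH among derived carriers
is exactly 1 across the window — the idealized signature iHS targets.

The simulator does **not** model demographic history, recombination
hotspots, genotyping error beyond uniform missingness, soft sweeps
(multiple sweep origins), or background selection. Passing tests
therefore show that the statistics and the pipeline recover the signals
they are defined to detect under clean conditions with realistic marker
geometry; they do not certify power on real data, where ancestral-allele
misassignment, uneven SNP ascertainment and demography all erode the
contrast.

## Numerical details

- iHH integrates EHH by the trapezoid rule against bp, each side starting
  from the implicit core point (0, 1); integration stops at the first
  point with EHH `< ehh_cutoff`, excluded.
- `raw_ihs` is `NA` when either integral is 0 (e.g. the first flanking
  point is already below the cutoff) or when a core allele has fewer than
  `min_carriers = 2` haplotypes; standardization bins with fewer than two
  usable values or zero spread go `NA` with a warning rather than
  producing infinities.
- The rightmost standardization bin is closed so the maximum eligible
  derived frequency does not fall into an empty bin of its own.
- Residual imputation (after QC, for the genotype view only) fills the
  population-modal genotype, ties toward the smaller code; phasing is a
  required input and is never inferred here.
- PCA scales each SNP by $\sqrt{2p(1-p)}$, skips monomorphic SNPs, and
  zero-fills missing entries after centering; component signs are
  unconstrained, so tests orient components before comparing.
- Region merging treats book-ended intervals (`next start = end + 1`) as
  one region; merging is idempotent and order-independent (tested).

## Problem sizes used by the test and acceptance suites

The study geometry — three populations of 89/47/12 samples, 1,200 SNPs
over 135.18 Mb — is the simulator default and is used for the recovery
properties (20 seeded replicates). Distributional checks use one or two
populations of 50–100 samples and 1,000 SNPs; oracle-equivalence checks
run on hundreds of random micro-instances (≤ 12 haplotypes × 20 SNPs for
EHH; totals ≤ 50 for the HWE enumeration). These sizes were chosen so the
whole validation runs comfortably on a laptop while keeping every
statistic in the regime it was designed for.

## Known limitations

- Single chromosome per run, biallelic SNPs only, diploid samples only.
- iHS requires phased, complete haplotypes; the package deliberately does
  not phase or impute beyond the documented modal fill of the genotype
  view.
- The F~ST~ estimator carries the small-sample upward bias of the plain
  heterozygosity ratio; with very small populations (~12 samples) the
  boxplot fences are correspondingly wide. This matches the method being
  reproduced rather than the best available estimator.
- The FDR combination mode depends on how per-SNP p-values are defined
  (Gaussian tail for iHS, empirical ranks for F~ST~); empirical ranks are
  granular at ~1,200 SNPs, so q-values below ~1/1200 are unattainable.
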