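#!/usr/bin/env Rscript
# Stage 6: gene annotation of candidate regions.
#
# Candidate regions are padded by 100 kb on each side and intersected with
# the gene models; any 1-bp overlap reports the gene (genes need not be
# fully contained). The gene set here is synthetic (stage 1), so the output
# exercises the mechanics; a real run would supply the assembly annotation.

library(xsweep)

out <- "results/annotation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cand <- read.delim("results/regions/candidate_regions.tsv",
                   stringsAsFactors = FALSE)
genes <- read_gene_models("results/data/genes_synthetic.gff3")
padded <- extend_region(cand, pad_bp = 100000, chrom_length = 135180000)
hits <- genes_in_regions(padded, genes)
write.table(hits, file.path(out, "candidate_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d gene models vs %d padded candidate regions: %d overlaps\n",
            nrow(genes), nrow(padded), nrow(hits)))
per_label <- tapply(hits$gene_id, hits$label,
                    function(g) length(unique(g)))
for (b in names(per_label))
  cat(sprintf("  %s: %d distinct genes in candidate regions\n",
              b, per_label[b]))
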