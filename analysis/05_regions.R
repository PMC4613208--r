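#!/usr/bin/env Rscript
# Stage 5: candidate selection regions, summary table and overlap sharing.
#
# Per breed, the |iHS| > 2 regions are combined with the FST boxplot-outlier
# regions of every scan involving that breed (threshold mode: their merged
# union). The summary mirrors the per-method region accounting (counts,
# average and total length in Mb) and the pairwise overlap between breeds'
# candidate sets quantifies shared selection.

library(xsweep)

out <- "results/regions"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

read_regions <- function(path) {
  r <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(r)) r else r
}
ihs_files <- list.files("results/ihs", "^ihs_regions_.*\\.tsv$",
                        full.names = TRUE)
fst_files <- list.files("results/fst", "^fst_regions_.*\\.tsv$",
                        full.names = TRUE)
ihs_regions <- lapply(ihs_files, read_regions)
names(ihs_regions) <- sub("^ihs_regions_(.*)\\.tsv$", "\\1",
                          basename(ihs_files))
fst_regions <- lapply(fst_files, read_regions)
names(fst_regions) <- sub("^fst_regions_(.*)\\.tsv$", "\\1",
                          basename(fst_files))

breeds <- sort(names(ihs_regions))
candidates <- list()
for (b in breeds) {
  involved <- vapply(strsplit(names(fst_regions), "-", fixed = TRUE),
                     function(p) b %in% p, logical(1))
  fr <- do.call(rbind, fst_regions[involved])
  candidates[[b]] <- combine_candidates(ihs_regions[[b]], fr, label = b)
}
cand <- do.call(rbind, candidates)
write.table(cand, file.path(out, "candidate_regions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_regions_bed(cand, file.path(out, "candidate_regions.bed"))

all_regions <- rbind(do.call(rbind, ihs_regions), do.call(rbind, fst_regions))
summary_tab <- rbind(summarize_regions(all_regions), summarize_regions(cand))
write.table(summary_tab, file.path(out, "summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("region summary (counts and Mb):\n")
print(summary_tab, row.names = FALSE)

prs <- utils::combn(breeds, 2, simplify = FALSE)
ov <- do.call(rbind, lapply(prs, function(p)
  data.frame(label_a = p[1], label_b = p[2],
             overlap_mb = round(overlap_length(candidates[[p[1]]],
                                               candidates[[p[2]]]), 2))))
write.table(ov, file.path(out, "candidate_overlaps.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nshared candidate regions between breeds (Mb):\n")
print(ov, row.names = FALSE)
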