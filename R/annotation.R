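# Gene annotation of candidate regions against a user-supplied gene-model
# file (GFF3 or BED). Regions are optionally padded before the overlap
# query; any 1-bp intersection reports the gene (selection scans are
# strand-agnostic, so strand is carried but ignored).

#' Read gene models from GFF3 or BED
#'
#' GFF3 input keeps `type == "gene"` features; every BED record is used.
#'
#' @param path file path (`.gff`/`.gff3` or `.bed`).
#' @return data.frame with `gene_id`, `gene_name`, `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive), `strand`.
#' @export
read_gene_models <- function(path) {
  fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "BED" else "GFF3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "GFF3") {
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md)) gr <- gr[as.character(md$type) == "gene"]
    md <- S4Vectors::mcols(gr)
    gene_id <- if ("ID" %in% names(md)) as.character(md$ID) else
      as.character(seq_along(gr))
    gene_name <- if ("Name" %in% names(md)) as.character(md$Name) else gene_id
  } else {
    md <- S4Vectors::mcols(gr)
    gene_id <- if ("name" %in% names(md)) as.character(md$name) else
      as.character(seq_along(gr))
    gene_name <- gene_id
  }
  data.frame(gene_id = gene_id, gene_name = gene_name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Pad regions symmetrically
#'
#' Extends each region by `pad_bp` on both sides, clamped to
#' `[1, chrom_length]`.
#'
#' @param regions a region data.frame (see [build_regions()]).
#' @param pad_bp extension in bp (default 100 kb, the usual scan margin
#'   when mapping outlier windows onto genes).
#' @param chrom_length optional chromosome length for clamping.
#' @return the padded regions.
#' @export
extend_region <- function(regions, pad_bp = 100000, chrom_length = NULL) {
  stopifnot(pad_bp >= 0)
  if (nrow(regions) == 0) return(regions)
  regions$start_bp <- pmax(1, regions$start_bp - pad_bp)
  regions$end_bp <- regions$end_bp + pad_bp
  if (!is.null(chrom_length)) regions$end_bp <- pmin(chrom_length, regions$end_bp)
  regions
}

#' Genes overlapping candidate regions
#'
#' A gene is reported for a region when their intervals intersect in at
#' least 1 bp (partial overlap counts); genes are listed by start position.
#'
#' @param regions a region data.frame.
#' @param genes gene models from [read_gene_models()].
#' @return data.frame with one row per (region, gene) overlap: region
#'   coordinates, `method`, `label`, `gene_id`, `gene_name`, `overlap_bp`.
#' @export
genes_in_regions <- function(regions, genes) {
  empty <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), method = character(),
                      label = character(), gene_id = character(),
                      gene_name = character(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0 || nrow(genes) == 0) return(empty)
  if (!any(genes$chrom %in% regions$chrom))
    stop("no shared chromosome names between regions and gene models ",
         "(naming convention mismatch?)")
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start_bp, regions$end_bp))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start_bp, genes$end_bp))
  hits <- GenomicRanges::findOverlaps(rgr, ggr, minoverlap = 1L)
  if (length(hits) == 0) return(empty)
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  ov <- pmin(regions$end_bp[ri], genes$end_bp[gi]) -
    pmax(regions$start_bp[ri], genes$start_bp[gi]) + 1
  out <- data.frame(chrom = regions$chrom[ri],
                    start_bp = regions$start_bp[ri],
                    end_bp = regions$end_bp[ri],
                    method = regions$method[ri], label = regions$label[ri],
                    gene_id = genes$gene_id[gi],
                    gene_name = genes$gene_name[gi], overlap_bp = ov,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start_bp, genes$start_bp[gi]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
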