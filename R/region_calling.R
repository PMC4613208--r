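# Outlier calling and candidate-region construction: the |iHS| > 2 rule,
# the boxplot (Tukey fence) rule for FST, Benjamini-Hochberg FDR, fixed
# half-width windows around outlier SNPs merged into regions, and
# Table-style summaries with pairwise overlap accounting.

#' iHS outliers by absolute threshold
#'
#' @param track an iHS score track (see [ihs_scan()]).
#' @param threshold outliers satisfy `|iHS| > threshold` (strict); `NA`
#'   excluded.
#' @return the outlier rows of `track`.
#' @export
ihs_outliers <- function(track, threshold = 2.0) {
  keep <- !is.na(track$ihs) & abs(track$ihs) > threshold
  track[keep, , drop = FALSE]
}

#' Boxplot (Tukey fence) outlier detection
#'
#' Quartiles `F_L`, `F_U` by linear interpolation at ranks `0.25 (n - 1)`
#' and `0.75 (n - 1)` on the sorted sample (the classic type-7 definition);
#' `Q = F_U - F_L`, fences `UL = F_U + 1.5 Q` and `LL = F_L - 1.5 Q`.
#' Values strictly above `UL` or strictly below `LL` are outliers.
#'
#' @param values numeric vector (`NA` dropped); at least 4 non-missing.
#' @param ids optional identifiers matching `values`.
#' @return list with `thresholds` (`f_l`, `f_u`, `q`, `ul`, `ll`),
#'   `upper`/`lower` (indices or ids of outliers) and `is_upper`/`is_lower`
#'   logical vectors aligned with the input.
#' @export
boxplot_outliers <- function(values, ids = NULL) {
  ok <- !is.na(values)
  if (sum(ok) < 4) stop("boxplot thresholds need at least 4 non-missing values")
  qs <- unname(quantile(values[ok], c(0.25, 0.75), type = 7))
  f_l <- qs[1]; f_u <- qs[2]
  q <- f_u - f_l
  ul <- f_u + 1.5 * q
  ll <- f_l - 1.5 * q
  is_upper <- ok & values > ul
  is_lower <- ok & values < ll
  pick <- function(sel) if (is.null(ids)) which(sel) else ids[sel]
  list(thresholds = list(f_l = f_l, f_u = f_u, q = q, ul = ul, ll = ll),
       upper = pick(is_upper), lower = pick(is_lower),
       is_upper = is_upper, is_lower = is_lower)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues p-values in `[0, 1]`.
#' @return monotone q-values (via [stats::p.adjust()]).
#' @export
bh_fdr <- function(pvalues) {
  pv <- pvalues[!is.na(pvalues)]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Empirical upper-tail p-values for a statistic
#'
#' `p_i = (1 + #\{x_j >= x_i\}) / (1 + n)` over the non-missing values;
#' the add-one keeps p strictly positive.
#'
#' @param values statistic values (`NA` preserved).
#' @return p-values aligned with the input.
#' @export
empirical_upper_p <- function(values) {
  out <- rep(NA_real_, length(values))
  ok <- which(!is.na(values))
  v <- values[ok]
  n <- length(v)
  ge <- n - rank(v, ties.method = "max") + 1  # count of values >= v_i
  out[ok] <- (1 + ge) / (1 + n)
  out
}

#' Build candidate regions around outlier SNPs
#'
#' Each outlier SNP spawns the window `[pos - half_width, pos + half_width]`
#' clamped to `[1, chrom_length]`; overlapping or book-ended windows are
#' merged. The region peak is the member SNP with the largest `|value|`.
#'
#' @param outliers data.frame with `pos`, `snp_id` and a statistic column
#'   named by `value_col`.
#' @param chrom chromosome name.
#' @param half_width_bp window half-width around each outlier SNP.
#' @param chrom_length chromosome length for clamping.
#' @param method,label annotations carried into the regions.
#' @param value_col name of the statistic column in `outliers`.
#' @return data.frame of regions: `chrom`, `start_bp`, `end_bp` (1-based
#'   inclusive), `peak_snp`, `peak_pos`, `peak_value`, `n_snps`, `method`,
#'   `label`.
#' @export
build_regions <- function(outliers, chrom, half_width_bp = 200000,
                          chrom_length = NULL, method = "ihs", label = "",
                          value_col = "ihs") {
  empty <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), peak_snp = character(),
                      peak_pos = numeric(), peak_value = numeric(),
                      n_snps = integer(), method = character(),
                      label = character(), stringsAsFactors = FALSE)
  if (is.null(outliers) || nrow(outliers) == 0) return(empty)
  o <- outliers[order(outliers$pos), , drop = FALSE]
  start <- pmax(1, o$pos - half_width_bp)
  end <- o$pos + half_width_bp
  if (!is.null(chrom_length)) end <- pmin(chrom_length, end)
  val <- o[[value_col]]
  grp <- cumsum(c(1, as.integer(start[-1] > head(end, -1) + 1)))
  res <- lapply(split(seq_along(grp), grp), function(idx) {
    pk <- idx[which.max(abs(val[idx]))]
    data.frame(chrom = chrom, start_bp = min(start[idx]),
               end_bp = max(end[idx]), peak_snp = o$snp_id[pk],
               peak_pos = o$pos[pk], peak_value = val[pk],
               n_snps = length(idx), method = method, label = label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Merge a set of regions (overlapping or book-ended)
#'
#' @param regions a region data.frame (see [build_regions()]); merging is
#'   performed within each `(method, label)` pair unless `by_label = FALSE`.
#' @param by_label merge within labels (default) or across everything.
#' @return the merged region data.frame, sorted by start.
#' @export
merge_regions <- function(regions, by_label = TRUE) {
  if (nrow(regions) == 0) return(regions)
  key <- if (by_label) paste(regions$method, regions$label) else
    rep("all", nrow(regions))
  res <- lapply(split(seq_len(nrow(regions)), key), function(idx) {
    r <- regions[idx, , drop = FALSE]
    r <- r[order(r$start_bp), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(r$start_bp[-1] > head(r$end_bp, -1) + 1)))
    out <- lapply(split(seq_len(nrow(r)), grp), function(ii) {
      pk <- ii[which.max(abs(r$peak_value[ii]))]
      data.frame(chrom = r$chrom[1], start_bp = min(r$start_bp[ii]),
                 end_bp = max(r$end_bp[ii]), peak_snp = r$peak_snp[pk],
                 peak_pos = r$peak_pos[pk], peak_value = r$peak_value[pk],
                 n_snps = sum(r$n_snps[ii]), method = r$method[1],
                 label = r$label[1], stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$label, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine iHS and FST evidence into candidate selection regions
#'
#' `mode = "threshold"` (default, the operational rule of the scan): the
#' union of the `|iHS| > 2` regions and the boxplot-outlier FST regions,
#' merged per label. `mode = "fdr"`: a region is a candidate when the
#' minimum BH q-value among its member SNPs is below 0.1 in **both** method
#' tracks over the region span, or below 0.05 in at least one.
#'
#' @param ihs_regions,fst_regions region data.frames from [build_regions()].
#' @param ihs_q,fst_q data.frames with `pos` and `q` (required for
#'   `mode = "fdr"`).
#' @param mode `"threshold"` or `"fdr"`.
#' @param label label for the combined set.
#' @param q_both,q_single the two FDR cutoffs.
#' @return merged candidate regions with `method = "combined"`.
#' @export
combine_candidates <- function(ihs_regions, fst_regions, ihs_q = NULL,
                               fst_q = NULL, mode = c("threshold", "fdr"),
                               label = "", q_both = 0.1, q_single = 0.05) {
  mode <- match.arg(mode)
  pool <- rbind(ihs_regions, fst_regions)
  if (nrow(pool) == 0) return(pool)
  pool$method <- "combined"
  pool$label <- label
  merged <- merge_regions(pool)
  if (mode == "threshold") return(merged)
  if (is.null(ihs_q) || is.null(fst_q))
    stop("mode='fdr' needs per-SNP q-values for both methods")
  min_q <- function(qdf, s, e) {
    v <- qdf$q[!is.na(qdf$q) & qdf$pos >= s & qdf$pos <= e]
    if (length(v)) min(v) else Inf
  }
  keep <- vapply(seq_len(nrow(merged)), function(i) {
    qi <- min_q(ihs_q, merged$start_bp[i], merged$end_bp[i])
    qf <- min_q(fst_q, merged$start_bp[i], merged$end_bp[i])
    (qi < q_both && qf < q_both) || qi < q_single || qf < q_single
  }, logical(1))
  out <- merged[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize region sets per (method, label)
#'
#' @param regions merged region data.frame.
#' @return data.frame with `method`, `label`, `n_outlier_snps`,
#'   `n_regions`, `avg_length_mb`, `total_length_mb` (lengths as
#'   `end - start` in Mb, 2 decimals).
#' @export
summarize_regions <- function(regions) {
  if (nrow(regions) == 0)
    return(data.frame(method = character(), label = character(),
                      n_outlier_snps = integer(), n_regions = integer(),
                      avg_length_mb = numeric(), total_length_mb = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(regions$method, regions$label, sep = "\r")
  res <- lapply(split(seq_len(nrow(regions)), key), function(idx) {
    r <- regions[idx, , drop = FALSE]
    len <- (r$end_bp - r$start_bp) / 1e6
    data.frame(method = r$method[1], label = r$label[1],
               n_outlier_snps = sum(r$n_snps), n_regions = nrow(r),
               avg_length_mb = round(mean(len), 2),
               total_length_mb = round(sum(len), 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Total pairwise overlap between two region sets
#'
#' Both sets are merged internally first, so no base pair is counted twice.
#'
#' @param regions_a,regions_b region data.frames.
#' @return overlap length in Mb.
#' @export
overlap_length <- function(regions_a, regions_b) {
  if (nrow(regions_a) == 0 || nrow(regions_b) == 0) return(0)
  a <- merge_regions(regions_a, by_label = FALSE)
  b <- merge_regions(regions_b, by_label = FALSE)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start_bp[i], b$start_bp)
    e <- pmin(a$end_bp[i], b$end_bp)
    tot <- tot + sum(pmax(0, e - s))
  }
  tot / 1e6
}
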