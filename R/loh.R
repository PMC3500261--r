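#' Bin-wise loss-of-heterozygosity fractions
#'
#' Sites heterozygous in the normal sample are informative for LOH; in
#' fixed genomic bins (default 5 Mb, tiled from coordinate 1) the
#' fraction of informative sites whose tumor genotype is homozygous is
#' the bin's LOH fraction. Only sites passing the quality gate in both
#' samples count; bins with fewer than `min_sites` informative sites get
#' `NA`.
#'
#' @param normal_calls,tumor_calls genotype tables from
#'   [call_genotypes()] for the same positions.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_width bin size in bp (default 5e6).
#' @param min_sites minimum informative sites for a defined fraction
#'   (default 10).
#' @param min_mpg,min_ratio quality gate (see [quality_pass()]).
#' @return data frame (class `loh_bins`): `chrom`, `start`, `end`,
#'   `informative`, `loh`, `fraction`.
#' @export
loh_bins <- function(normal_calls, tumor_calls, chrom_lengths,
                     bin_width = 5e6, min_sites = 10,
                     min_mpg = 10, min_ratio = 0.5) {
  key <- function(df) paste(df$chrom, df$pos)
  idx <- match(key(normal_calls), key(tumor_calls))
  ok <- !is.na(idx) &
    quality_pass(normal_calls$mpg, normal_calls$mpg_cov_ratio,
                 min_mpg, min_ratio) &
    quality_pass(tumor_calls$mpg[idx], tumor_calls$mpg_cov_ratio[idx],
                 min_mpg, min_ratio)
  n_gt <- normal_calls$genotype
  t_gt <- tumor_calls$genotype[idx]
  het <- function(g) !is.na(g) & substr(g, 1, 1) != substr(g, 2, 2)
  informative <- ok & het(n_gt)
  is_loh <- informative & !het(t_gt)

  bins <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    starts <- seq(1, len, by = bin_width)
    ends <- pmin(starts + bin_width - 1, len)
    on_chr <- normal_calls$chrom == chrom
    bin_of <- function(p) (p - 1) %/% bin_width + 1
    inf_tab <- tabulate(bin_of(normal_calls$pos[on_chr & informative]),
                        nbins = length(starts))
    loh_tab <- tabulate(bin_of(normal_calls$pos[on_chr & is_loh]),
                        nbins = length(starts))
    data.frame(chrom = chrom, start = starts, end = ends,
               informative = inf_tab, loh = loh_tab,
               fraction = ifelse(inf_tab >= min_sites,
                                 loh_tab / inf_tab, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, bins)
  rownames(out) <- NULL
  class(out) <- c("loh_bins", "data.frame")
  out
}

#' Flag copy-neutral LOH bins
#'
#' A bin shows copy-neutral LOH when its LOH fraction is high while the
#' copy-number segmentation over the same interval is flat: fraction at
#' least `loh_min` and the bp-weighted mean segment log2 ratio within
#' `cn_band` of zero. High-LOH bins over deleted segments are
#' deletion-driven LOH and are not flagged.
#'
#' @param bins `loh_bins` for one tumor.
#' @param segments `segment_set` for the same tumor.
#' @param loh_min minimum LOH fraction (default 0.8).
#' @param cn_band maximum absolute segment mean log2 (default 0.2).
#' @return `bins` with columns `segment_mean` and `cn_loh` appended.
#' @export
flag_cn_loh <- function(bins, segments, loh_min = 0.8, cn_band = 0.2) {
  seg_mean <- vapply(seq_len(nrow(bins)), function(i) {
    s <- segments[segments$chrom == bins$chrom[i] &
                  segments$end >= bins$start[i] &
                  segments$start <= bins$end[i], , drop = FALSE]
    if (!nrow(s)) return(NA_real_)
    ov <- pmin(s$end, bins$end[i]) - pmax(s$start, bins$start[i]) + 1
    sum(s$mean_log2 * ov) / sum(ov)
  }, numeric(1))
  bins$segment_mean <- seg_mean
  bins$cn_loh <- !is.na(bins$fraction) & !is.na(seg_mean) &
    bins$fraction >= loh_min & abs(seg_mean) <= cn_band
  bins
}
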