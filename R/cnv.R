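#' Define pseudo-CGH genomic windows from normal-sample read positions
#'
#' Windows are blocks of a fixed number of aligned reads in the normal
#' sample (default 1000), so each window holds the same amount of
#' normal-sample evidence while its genomic width adapts to local
#' capture density. A window ends at the position of the last read of
#' its block; a trailing remainder smaller than one block is merged into
#' the final window. Windows never span chromosomes.
#'
#' @param normal_read_positions data frame with `chrom` and `pos`
#'   (1-based aligned read start positions).
#' @param reads_per_window block size (default 1000).
#' @return data frame: `chrom`, `start`, `end`, `normal_count` (class
#'   `window_set`). A chromosome with fewer reads than one block becomes
#'   a single whole-chromosome window, with a warning.
#' @export
define_windows <- function(normal_read_positions, reads_per_window = 1000) {
  stopifnot(reads_per_window >= 1)
  reads_per_window <- as.integer(reads_per_window)
  out <- lapply(split(normal_read_positions$pos,
                      normal_read_positions$chrom), sort)
  rows <- lapply(names(out), function(chrom) {
    pos <- out[[chrom]]
    n <- length(pos)
    nwin <- n %/% reads_per_window
    if (nwin == 0L) {
      warning(sprintf("chromosome %s has fewer than %d reads; single window",
                      chrom, reads_per_window))
      return(data.frame(chrom = chrom, start = pos[1], end = pos[n],
                        normal_count = as.integer(n),
                        stringsAsFactors = FALSE))
    }
    ends <- pos[seq_len(nwin) * reads_per_window]
    counts <- rep(reads_per_window, nwin)
    rem <- as.integer(n %% reads_per_window)
    if (rem > 0L) {  # merge remainder into the final window
      ends[nwin] <- pos[n]
      counts[nwin] <- counts[nwin] + rem
    }
    starts <- c(pos[1], head(ends, -1L) + 1)
    data.frame(chrom = chrom, start = starts, end = ends,
               normal_count = counts, stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, rows)
  rownames(win) <- NULL
  class(win) <- c("window_set", "data.frame")
  win
}

# per-window read counts; reads outside every window are dropped
.count_in_windows <- function(windows, positions) {
  counts <- integer(nrow(windows))
  pos_by_chrom <- split(positions$pos, positions$chrom)
  for (chrom in unique(windows$chrom)) {
    idx <- which(windows$chrom == chrom)
    p <- pos_by_chrom[[chrom]]
    if (is.null(p)) next
    breaks <- c(windows$start[idx[1]] - 1, windows$end[idx])
    counts[idx] <- as.integer(
      table(cut(p, breaks = breaks, labels = FALSE))[as.character(
        seq_along(idx))])
    counts[idx][is.na(counts[idx])] <- 0L
  }
  counts
}

#' Windowed log2 tumor/normal copy ratios
#'
#' For each window the tumor read count is scaled by the library-size
#' factor (total normal reads over total tumor reads in windows) and the
#' log2 ratio to the normal count is taken with a 0.5 pseudocount on
#' both sides: \eqn{r_i = \log_2((t_i s + 0.5)/(n_i + 0.5))}. Identical
#' tumor and normal profiles — including a uniform library-size rescale —
#' give exactly 0.
#'
#' @param windows a `window_set` from [define_windows()].
#' @param tumor_read_positions data frame with `chrom`, `pos`.
#' @param size_factor override the library-size factor (e.g. 1 to
#'   compare raw counts); default `NULL` computes total-normal /
#'   total-tumor.
#' @return data frame (class `copy_ratio_profile`): windows plus
#'   `tumor_count` and `log2ratio`.
#' @export
compute_log2_ratios <- function(windows, tumor_read_positions,
                                size_factor = NULL) {
  t_counts <- .count_in_windows(windows, tumor_read_positions)
  if (is.null(size_factor)) {
    size_factor <- sum(windows$normal_count) / sum(t_counts)
  }
  profile <- windows
  profile$tumor_count <- t_counts
  profile$log2ratio <- log2((t_counts * size_factor + 0.5) /
                            (windows$normal_count + 0.5))
  class(profile) <- c("copy_ratio_profile", "data.frame")
  profile
}

#' Segment a copy-ratio profile by circular binary segmentation
#'
#' Recursive change-point search: within each region the two-arc mean
#' difference statistic is maximised over all arc pairs and the split is
#' accepted when a permutation test (region values shuffled) gives
#' p < `alpha`; accepted splits recurse until no further split is
#' significant. Chromosomes are segmented independently; regions with
#' fewer than `min_windows` windows stay whole.
#'
#' @param profile a `copy_ratio_profile` from [compute_log2_ratios()]
#'   (columns `chrom`, `start`, `end`, `log2ratio`).
#' @param alpha significance level for a split (default 0.01).
#' @param n_permutations permutations per test (default 1000).
#' @param min_width smallest admissible segment, in windows (default 2).
#' @param min_windows regions smaller than this are never split
#'   (default 3).
#' @param seed optional integer seed for the permutation stream.
#' @return data frame (class `segment_set`): `chrom`, `start`, `end`,
#'   `start_window`, `end_window` (row indices into `profile`),
#'   `n_windows`, `mean_log2`.
#' @export
segment_profile <- function(profile, alpha = 0.01, n_permutations = 1000,
                            min_width = 2, min_windows = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- list()
  offset <- 0L
  for (chrom in unique(profile$chrom)) {
    x <- profile$log2ratio[profile$chrom == chrom]
    m <- length(x)
    ends <- if (m < max(min_windows, 2L)) m
            else .cbs_changepoints(x, alpha, as.integer(n_permutations),
                                   as.integer(min_width),
                                   as.integer(min_windows))
    starts <- c(1L, head(ends, -1L) + 1L)
    segs[[chrom]] <- data.frame(
      chrom = chrom,
      start = profile$start[offset + starts],
      end = profile$end[offset + ends],
      start_window = offset + starts,
      end_window = offset + ends,
      n_windows = ends - starts + 1L,
      mean_log2 = vapply(seq_along(ends), function(k)
        mean(x[starts[k]:ends[k]]), numeric(1)),
      stringsAsFactors = FALSE)
    offset <- offset + m
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("segment_set", "data.frame")
  out
}

# weighted median: smallest x whose cumulative weight reaches half the total
weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

#' Derivative log-ratio spread (DLRS)
#'
#' Robust profile-noise estimate: the interquartile range of
#' adjacent-window log-ratio first differences, divided by
#' \eqn{1.34\sqrt{2}} so that on an iid Gaussian profile the value is on
#' the scale of the per-window standard deviation. Differences never
#' span chromosomes; per-chromosome values are pooled by a weighted
#' median (weights = number of differences).
#'
#' @param profile a `copy_ratio_profile`, or a bare numeric vector of
#'   log2 ratios (treated as one chromosome).
#' @return numeric spread estimate; `NA` when fewer than 3 windows are
#'   available on every chromosome.
#' @export
dlrs <- function(profile) {
  if (is.numeric(profile)) {
    groups <- list(profile)
  } else {
    groups <- split(profile$log2ratio, profile$chrom)
  }
  per <- lapply(groups, function(x) {
    if (length(x) < 3) return(NULL)
    d <- diff(x)
    c(val = stats::IQR(d) / (1.34 * sqrt(2)), w = length(d))
  })
  per <- do.call(rbind, per)
  if (is.null(per)) return(NA_real_)
  if (nrow(per) == 1L) return(unname(per[1, "val"]))
  unname(weighted_median(per[, "val"], per[, "w"]))
}

#' Call copy-number differences between two segmentations
#'
#' Both segmentations are projected back onto the common window grid; a
#' window differs when the absolute difference of the two segment means
#' is strictly greater than `threshold` log2 units (default 0.35, about
#' three standard deviations of typical profile noise as estimated by
#' [dlrs()]). Contiguous differing windows are merged into regions.
#'
#' @param segments_a,segments_b `segment_set`s over the same window set.
#' @param windows the common `window_set` (or profile).
#' @param threshold strict log2 difference threshold (default 0.35).
#' @return list: `regions` (data frame `chrom`, `start`, `end`,
#'   `n_windows`, `mean_delta`), `percent_windows` (share of differing
#'   windows, 2 decimals), `percent_bp` (same, weighted by window width).
#' @export
diff_segments <- function(segments_a, segments_b, windows,
                          threshold = 0.35) {
  nwin <- nrow(windows)
  proj <- function(segs) {
    if (max(segs$end_window) != nwin)
      stop("segmentation does not match the window set")
    v <- numeric(nwin)
    for (k in seq_len(nrow(segs)))
      v[segs$start_window[k]:segs$end_window[k]] <- segs$mean_log2[k]
    v
  }
  delta <- proj(segments_a) - proj(segments_b)
  differs <- abs(delta) > threshold
  pct_win <- round_half_up(100 * mean(differs), 2)
  widths <- windows$end - windows$start + 1
  pct_bp <- round_half_up(100 * sum(widths[differs]) / sum(widths), 2)
  regions <- list()
  r <- rle(paste(windows$chrom, differs))
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    i0 <- idx_start[k]
    if (!differs[i0]) next
    i1 <- idx_end[k]
    regions[[length(regions) + 1L]] <- data.frame(
      chrom = windows$chrom[i0], start = windows$start[i0],
      end = windows$end[i1], n_windows = i1 - i0 + 1L,
      mean_delta = mean(delta[i0:i1]), stringsAsFactors = FALSE)
  }
  regions <- if (length(regions)) do.call(rbind, regions)
    else data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), n_windows = integer(0),
                    mean_delta = numeric(0))
  list(regions = regions, percent_windows = pct_win, percent_bp = pct_bp)
}

#' Summarise window geometry
#'
#' Mean, median and (unscaled) median absolute deviation of the genomic
#' window widths, plus the total number of windows.
#'
#' @param windows a `window_set`.
#' @return one-row data frame: `n_windows`, `mean_size`, `median_size`,
#'   `mad_size`.
#' @export
window_summary <- function(windows) {
  len <- windows$end - windows$start + 1
  data.frame(n_windows = length(len),
             mean_size = mean(len),
             median_size = stats::median(len),
             mad_size = stats::mad(len, constant = 1))
}

#' Plot a copy-ratio profile with its segmentation
#'
#' Simple per-chromosome scatter of window log2 ratios with segment
#' means overdrawn.
#' @param profile a `copy_ratio_profile`.
#' @param segments optional `segment_set`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_profile <- function(profile, segments = NULL, ...) {
  idx <- seq_len(nrow(profile))
  graphics::plot(idx, profile$log2ratio, pch = 16, cex = 0.4,
                 col = "grey40", xlab = "window", ylab = "log2 ratio", ...)
  bound <- cumsum(rle(profile$chrom)$lengths)
  graphics::abline(v = bound + 0.5, col = "grey80", lty = 2)
  if (!is.null(segments)) {
    graphics::segments(segments$start_window, segments$mean_log2,
                       segments$end_window, segments$mean_log2,
                       col = "red", lwd = 2)
  }
  invisible(NULL)
}
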