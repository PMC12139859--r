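#' Bin a genome into fixed-width windows
#'
#' Creates a `BinTrack`: one numeric value per genome bin, ordered by
#' (chromosome, bin index). Bins never cross chromosome boundaries; the
#' last bin of each chromosome may be short.
#'
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bp (default 100 kb, the resolution at
#'   which DAR density is scored).
#' @return A list of class `BinTrack` with elements `layout`, `bin_width`
#'   and `bins` (data frame `chrom`, `start`, `end`, `value`, all values
#'   zero).
#' @export
bin_genome <- function(layout, bin_width = 100000) {
  if (bin_width <= 0) stop("bin_width must be positive")
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    n <- ceiling(L / bin_width)
    start <- (seq_len(n) - 1) * bin_width
    data.frame(chrom = layout$chrom[i], start = start,
               end = pmin(start + bin_width, L), value = 0,
               stringsAsFactors = FALSE)
  })
  structure(list(layout = layout, bin_width = bin_width,
                 bins = do.call(rbind, pieces)),
            class = "BinTrack")
}

#' @export
print.BinTrack <- function(x, ...) {
  cat("BinTrack:", nrow(x$bins), "bins of", x$bin_width, "bp on",
      nrow(x$layout), "chromosome(s); total value", sum(x$bins$value), "\n")
  invisible(x)
}

#' Count qualifying DARs per genome bin
#'
#' Each DAR passing the significance filters (raw `p < p_max` and
#' `|log2FC| > lfc_min`, the hotspot-scoring filters) increments exactly
#' one bin: the bin containing its midpoint. DARs are tiny relative to
#' the bins (~0.5 kb vs 100 kb), so midpoint assignment is used rather
#' than fractional overlap.
#'
#' @param dars a `DARTable` data frame with `chrom`, `start`, `end`,
#'   `log2_fold_change`, `p_value` and (if filtering by direction)
#'   `direction`.
#' @param track a [bin_genome()] track defining the bins.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @param lfc_min strict lower bound on `|log2FC|` (default 1).
#' @param p_max strict upper bound on the raw p-value (default 0.01).
#' @return The `BinTrack` with per-bin DAR counts.
#' @export
count_dars_per_bin <- function(dars, track, direction = c("both", "up", "down"),
                               lfc_min = 1, p_max = 0.01) {
  direction <- match.arg(direction)
  assert_columns(dars, c("chrom", "start", "end"), "dars")
  check_chroms(dars$chrom, track$layout, "DARs")
  keep <- rep(TRUE, nrow(dars))
  if (!is.null(dars$log2_fold_change)) {
    keep <- keep & abs(dars$log2_fold_change) > lfc_min
  }
  if (!is.null(dars$p_value)) keep <- keep & dars$p_value < p_max
  if (direction != "both") keep <- keep & dars$direction == direction
  d <- dars[keep & !is.na(keep), , drop = FALSE]
  bins <- track$bins
  ## global bin index = chromosome offset + local midpoint bin
  n_per_chrom <- ceiling(track$layout$length / track$bin_width)
  offset <- cumsum(c(0, n_per_chrom[-length(n_per_chrom)]))
  names(offset) <- track$layout$chrom
  mid <- floor((d$start + d$end) / 2)
  idx <- offset[d$chrom] + floor(mid / track$bin_width) + 1
  counts <- tabulate(idx, nbins = nrow(bins))
  track$bins$value <- counts
  track
}

## Gaussian taps over offsets -h..h for a window of `window_bins` bins:
## w(j) = exp(-0.5 * (tails * j / (window_bins / 2))^2), later renormalized
## per position over in-bounds offsets.
gaussian_taps <- function(window_bins, tails) {
  h <- floor(window_bins / 2)
  j <- seq(-h, h)
  list(offsets = j, w = exp(-0.5 * (tails * j / (window_bins / 2))^2))
}

#' Gaussian smoothing of a binned track
#'
#' Convolves each chromosome's bin values independently with a symmetric
#' Gaussian kernel of support `window_bins + 1` bins. The `tails`
#' parameter sets how many kernel standard deviations the half-window
#' spans (default 2.5, the common default of window-based Gaussian
#' smoothers). At chromosome edges the kernel is renormalized over the
#' in-bounds bins, so a constant track maps to itself everywhere.
#'
#' @param track a `BinTrack` (typically from [count_dars_per_bin()]).
#' @param window_bins window length in bins (default 20, ~2.1 Mb at
#'   100 kb bins).
#' @param tails kernel shape parameter (default 2.5).
#' @return The `BinTrack` with smoothed values; length unchanged.
#' @export
gaussian_smooth <- function(track, window_bins = 20, tails = 2.5) {
  if (window_bins < 1) stop("window_bins must be >= 1")
  taps <- gaussian_taps(window_bins, tails)
  bins <- track$bins
  out <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    sel <- which(bins$chrom == ch)
    x <- bins$value[sel]
    n <- length(x)
    if (window_bins + 1 > n) {
      warning("smoothing window exceeds chromosome ", ch,
              " (", n, " bins); kernel truncated")
    }
    num <- numeric(n); den <- numeric(n)
    for (k in seq_along(taps$offsets)) {
      j <- taps$offsets[k]; w <- taps$w[k]
      src <- seq_len(n) + j
      ok <- src >= 1 & src <= n
      num[ok] <- num[ok] + w * x[src[ok]]
      den[ok] <- den[ok] + w
    }
    out[sel] <- num / den
  }
  track$bins$value <- out
  track
}

#' Call hotspots from a smoothed track
#'
#' Hotspot bins are those whose smoothed score lies strictly above a
#' threshold: the `quantile` of all bin values genome-wide (zeros
#' included by default; set `include_zero_bins = FALSE` to take the
#' quantile over nonzero bins only), raised to `abs_threshold` when one
#' is supplied. Adjacent hotspot bins on one chromosome merge into a
#' single call. Ties at the threshold are excluded, so an all-equal
#' track yields zero calls.
#'
#' @param track smoothed `BinTrack`.
#' @param quantile quantile defining the call threshold (default 0.99,
#'   i.e. top 1% of bins).
#' @param abs_threshold optional absolute score floor; the effective
#'   threshold is the max of the two. Note an absolute score is only
#'   meaningful on the scale of the track it was derived from.
#' @param domains optional `GRanges`; each call is flagged
#'   `overlaps_domain` if it intersects any domain by >= 1 bp.
#' @param raw_track optional unsmoothed `BinTrack` used to report the raw
#'   DAR count inside each call.
#' @param include_zero_bins include zero-valued bins when taking the
#'   quantile (default `TRUE`).
#' @return A `HotspotCall` data frame: `chrom`, `start`, `end`, `n_bins`,
#'   `peak_score`, `n_dars` (NA without `raw_track`), `overlaps_domain`
#'   (NA without `domains`); attribute `threshold` records the cutoff.
#' @export
call_hotspots <- function(track, quantile = 0.99, abs_threshold = NULL,
                          domains = NULL, raw_track = NULL,
                          include_zero_bins = TRUE) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  v <- track$bins$value
  pool <- if (include_zero_bins) v else v[v != 0]
  if (length(pool) == 0) pool <- 0
  thr <- as.numeric(stats::quantile(pool, probs = quantile, names = FALSE))
  if (!is.null(abs_threshold)) thr <- max(thr, abs_threshold)
  hot <- v > thr
  if (!any(hot)) {
    if (length(unique(v)) == 1L) {
      warning("track is constant; no bins exceed the threshold")
    }
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_bins = integer(0),
                      peak_score = numeric(0), n_dars = numeric(0),
                      overlaps_domain = logical(0))
    attr(out, "threshold") <- thr
    return(out)
  }
  bins <- track$bins
  run <- cumsum(c(TRUE, diff(which(hot)) > 1 |
                    bins$chrom[which(hot)][-1] != bins$chrom[which(hot)][-sum(hot)]))
  hi <- which(hot)
  calls <- do.call(rbind, lapply(split(hi, run), function(ix) {
    data.frame(chrom = bins$chrom[ix[1]],
               start = bins$start[ix[1]],
               end = bins$end[ix[length(ix)]],
               n_bins = length(ix),
               peak_score = max(bins$value[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  calls$n_dars <- NA_real_
  if (!is.null(raw_track)) {
    for (i in seq_len(nrow(calls))) {
      sel <- raw_track$bins$chrom == calls$chrom[i] &
        raw_track$bins$start >= calls$start[i] &
        raw_track$bins$end <= calls$end[i]
      calls$n_dars[i] <- sum(raw_track$bins$value[sel])
    }
  }
  calls$overlaps_domain <- NA
  if (!is.null(domains)) {
    gr <- region_set(calls$chrom, calls$start, calls$end)
    calls$overlaps_domain <- GenomicRanges::countOverlaps(gr, domains) > 0
  }
  attr(calls, "threshold") <- thr
  class(calls) <- c("HotspotCall", "data.frame")
  calls
}
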