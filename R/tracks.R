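#' Construct a genomic region
#'
#' Coordinates are 0-based half-open (BED convention) throughout the package.
#'
#' @param chrom Contig name (haplotype-resolved, e.g. `"chr1_hap1"`).
#' @param start,end Base-pair coordinates, `start` inclusive, `end` exclusive.
#' @return A one-row tibble with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_region("chr4_hap2", 42868000, 42958000)
#' @export
genomic_region <- function(chrom, start, end) {
  stopifnot(is.character(chrom), nzchar(chrom))
  check_interval(start, end)
  tibble::tibble(chrom = chrom, start = as.numeric(start), end = as.numeric(end))
}

check_interval <- function(start, end) {
  if (any(start < 0) || any(start >= end)) {
    stop("invalid interval: need 0 <= start < end", call. = FALSE)
  }
  invisible(TRUE)
}

region_width <- function(region) region$end - region$start

#' Construct a binned signal track
#'
#' A `binned_track` holds per-bin signal values for one contig: bin `i`
#' (1-based) covers `[origin + (i-1)*bin_size, origin + i*bin_size)`. Missing
#' data is an explicit `NA`, never zero; all downstream means skip `NA`.
#'
#' @param values Numeric vector of per-bin values (`NA` = no data).
#' @param chrom Contig name.
#' @param bin_size Bin width in bp (>= 1).
#' @param origin Start coordinate of bin 1 (bp).
#' @param fraction If `TRUE`, validate that finite values lie in \[0, 1\]
#'   (fraction-modified tracks).
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, chrom, bin_size, origin = 0, fraction = FALSE) {
  stopifnot(is.numeric(values), length(values) >= 1, bin_size >= 1, origin >= 0)
  if (fraction) {
    fin <- values[is.finite(values)]
    if (length(fin) && (min(fin) < 0 || max(fin) > 1)) {
      stop("fraction-valued track must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(chrom = chrom, bin_size = as.numeric(bin_size),
         origin = as.numeric(origin), values = as.numeric(values)),
    class = "binned_track"
  )
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %s:%s-%s | %d bins x %g bp | %d missing\n",
              x$chrom, format(x$origin, scientific = FALSE),
              format(track_end(x), scientific = FALSE),
              length(x$values), x$bin_size, sum(is.na(x$values))))
  invisible(x)
}

track_end <- function(track) track$origin + length(track$values) * track$bin_size

#' Region covered by a binned track
#' @param track A [binned_track()].
#' @return A one-row region tibble.
#' @export
track_region <- function(track) {
  genomic_region(track$chrom, track$origin, track_end(track))
}

#' Subset a binned track to a region
#'
#' Keeps the bins whose span intersects `region`; bin boundaries are not
#' re-cut, so the returned origin is aligned to the parent binning.
#'
#' @param track A [binned_track()].
#' @param region One-row region tibble (same contig).
#' @return A [binned_track()].
#' @export
subset_track <- function(track, region) {
  stopifnot(inherits(track, "binned_track"))
  if (region$chrom != track$chrom) stop("region is on a different contig", call. = FALSE)
  bs <- track$bin_size
  j0 <- max(0, floor((region$start - track$origin) / bs))
  j1 <- min(length(track$values) - 1, ceiling((region$end - track$origin) / bs) - 1)
  if (j1 < j0) stop("region does not intersect track", call. = FALSE)
  binned_track(track$values[(j0 + 1):(j1 + 1)], track$chrom, bs,
               origin = track$origin + j0 * bs)
}

# Coverage-weighted mean of track values over [start, end); NA bins skipped.
track_mean <- function(track, start, end) {
  w <- track_overlap_weights(track, start, end)
  if (is.null(w)) return(NA_real_)
  v <- track$values[w$idx]
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  sum(v[ok] * w$bp[ok]) / sum(w$bp[ok])
}

# Overlap-weighted sum of track values over [start, end) (bin value counted
# proportionally to the fraction of the bin inside the window).
track_sum <- function(track, start, end) {
  w <- track_overlap_weights(track, start, end)
  if (is.null(w)) return(NA_real_)
  v <- track$values[w$idx]
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  sum(v[ok] * w$bp[ok] / track$bin_size)
}

track_overlap_weights <- function(track, start, end) {
  bs <- track$bin_size
  j0 <- max(0, floor((start - track$origin) / bs))
  j1 <- min(length(track$values) - 1, ceiling((end - track$origin) / bs) - 1)
  if (j1 < j0) return(NULL)
  idx <- j0:j1
  bstart <- track$origin + idx * bs
  bp <- pmin(bstart + bs, end) - pmax(bstart, start)
  keep <- bp > 0
  if (!any(keep)) return(NULL)
  list(idx = idx[keep] + 1L, bp = bp[keep])
}

# Centered rolling mean over k bins with shrinking windows at the edges and
# NA values excluded from each window's mean (all-NA window -> NA).
rolling_mean <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n == 0) return(x)
  h <- (as.integer(k) - 1L) %/% 2L
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

# Rolling window width in bins for a bp-sized smoothing window; always >= 1.
smooth_bins <- function(smooth_window, bin_size) {
  max(1L, as.integer(round(smooth_window / bin_size)))
}
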