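#' Length-normalization scheme for meta-region rows
#'
#' A row is `flank_bins + body_bins + flank_bins` values: the region body is
#' partitioned into `body_bins` equal sub-intervals and each flank of
#' `flank_bp` into `flank_bins`. Presets: [hor_scheme()] (active HORs, 1,000
#' body bins, +/-1 Mb flanks in 500 bins), [cdr_scheme()] (CDRs, 200 body
#' bins, +/-125 kb in 125 bins) and [aggregate_scheme()] (aggregate traces,
#' 100 bins per region with +/-250 kb flanks).
#'
#' @param body_bins Number of bins over the region body.
#' @param flank_bp Flank width, bp (each side).
#' @param flank_bins Number of bins per flank.
#' @return A list of class `scaling_scheme`.
#' @export
scaling_scheme <- function(body_bins, flank_bp, flank_bins) {
  stopifnot(body_bins >= 1, flank_bins >= 0, flank_bp >= 0)
  structure(list(body_bins = as.integer(body_bins), flank_bp = flank_bp,
                 flank_bins = as.integer(flank_bins)),
            class = "scaling_scheme")
}

#' @rdname scaling_scheme
#' @export
hor_scheme <- function() scaling_scheme(1000, 1e6, 500)

#' @rdname scaling_scheme
#' @export
cdr_scheme <- function() scaling_scheme(200, 125000, 125)

#' @rdname scaling_scheme
#' @export
aggregate_scheme <- function() scaling_scheme(100, 250000, 100)

# Integer-bp half-open partition of [start, end) into n sub-intervals:
# real-valued boundaries rounded half-up; guarantees no gaps or overlaps.
partition_edges <- function(start, end, n) {
  floor(start + (end - start) * (0:n) / n + 0.5)
}

#' Scale a region (plus flanks) into a fixed-length row
#'
#' Each output bin is the coverage-weighted mean of the track over its
#' half-open bp sub-interval; bins with no data are `NA` (missing
#' propagates, never coerced to zero).
#'
#' @param track A [binned_track()].
#' @param region One-row region tibble (the body).
#' @param scheme A [scaling_scheme()].
#' @return Numeric vector of length `body_bins + 2 * flank_bins`.
#' @export
scale_region <- function(track, region, scheme) {
  stopifnot(inherits(track, "binned_track"), inherits(scheme, "scaling_scheme"))
  check_interval(region$start, region$end)
  edges <- c(
    if (scheme$flank_bins > 0)
      partition_edges(region$start - scheme$flank_bp, region$start, scheme$flank_bins)[-(scheme$flank_bins + 1)],
    partition_edges(region$start, region$end, scheme$body_bins),
    if (scheme$flank_bins > 0)
      partition_edges(region$end, region$end + scheme$flank_bp, scheme$flank_bins)[-1]
  )
  vapply(seq_len(length(edges) - 1), function(i) {
    if (edges[i + 1] <= edges[i]) return(NA_real_)
    if (region$chrom != track$chrom) return(NA_real_)
    track_mean(track, edges[i], edges[i + 1])
  }, 0)
}

#' Build a length-normalized heat-map matrix
#'
#' One row per region, in numeric (chromosome number, haplotype) label
#' order; all rows share the scheme's length. Regions without track data
#' yield all-missing rows and are retained.
#'
#' @param tracks Either a single [binned_track()] used for every region on
#'   its contig, or a named list of tracks keyed by region label.
#' @param regions Tibble with `chrom`, `start`, `end` and a `label` column
#'   (unique; e.g. `"chr1_hap1"`).
#' @param scheme A [scaling_scheme()].
#' @return A numeric matrix with region labels as row names.
#' @export
build_heatmap <- function(tracks, regions, scheme) {
  if (!"label" %in% names(regions)) regions$label <- regions$chrom
  if (anyDuplicated(regions$label)) {
    stop("duplicate region labels", call. = FALSE)
  }
  regions <- regions[order_region_labels(regions$label), ]
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    tr <- if (inherits(tracks, "binned_track")) tracks else tracks[[regions$label[i]]]
    if (is.null(tr)) {
      return(rep(NA_real_, scheme$body_bins + 2 * scheme$flank_bins))
    }
    scale_region(tr, regions[i, ], scheme)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- regions$label
  m
}

# Numeric sort of labels like "chr1_hap2" / "cen10_hap1": by chromosome
# number (X, Y after autosomes), then haplotype; unparseable labels last,
# alphabetically.
order_region_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(?:chr|cen|CEN)?([0-9]+|[XYxy])[._-]?(?:hap)?([0-9]*)",
                                  labels, ignore.case = TRUE))
  num <- vapply(m, function(g) {
    if (length(g) < 2 || !nzchar(g[2])) return(NA_real_)
    if (toupper(g[2]) == "X") return(100)
    if (toupper(g[2]) == "Y") return(101)
    as.numeric(g[2])
  }, 0)
  hap <- vapply(m, function(g) {
    if (length(g) < 3 || !nzchar(g[3])) return(0) else as.numeric(g[3])
  }, 0)
  order(is.na(num), num, hap, labels)
}

#' Aggregate profile across centered regions
#'
#' Resamples `+/- flank_bp` around each center into `n_bins` and averages
#' across centers, skipping missing values. Centers are interval midpoints
#' (`center = "midpoint"`), or the interval `start`/`end` boundaries
#' (`center = "boundary"`, two centers per interval with the right-boundary
#' trace mirrored so that "inside the interval" is always on the left).
#'
#' @param track A [binned_track()].
#' @param centers Tibble of intervals (`chrom`, `start`, `end`) or of points
#'   (`chrom`, `pos`).
#' @param flank_bp Half-window, bp.
#' @param n_bins Number of bins across the `2 * flank_bp` window.
#' @param center `"midpoint"` or `"boundary"`.
#' @return A list: `offsets` (bin-center offsets, bp), `mean`, `n` (per-bin
#'   non-missing count), `per_region` (matrix, one row per center).
#' @export
aggregate_profile <- function(track, centers, flank_bp = 250000, n_bins = 100,
                              center = c("midpoint", "boundary")) {
  center <- match.arg(center)
  if ("pos" %in% names(centers)) {
    pts <- centers$pos
    flip <- rep(FALSE, length(pts))
  } else if (center == "midpoint") {
    pts <- (centers$start + centers$end) / 2
    flip <- rep(FALSE, nrow(centers))
  } else {
    pts <- c(centers$start, centers$end)
    flip <- c(rep(TRUE, nrow(centers)), rep(FALSE, nrow(centers)))
  }
  stopifnot(length(pts) >= 1)
  scheme <- scaling_scheme(n_bins, 0, 0)
  rows <- lapply(seq_along(pts), function(i) {
    row <- scale_region(track,
                        genomic_region(track$chrom, pts[i] - flank_bp, pts[i] + flank_bp),
                        scheme)
    if (flip[i]) rev(row) else row
  })
  m <- do.call(rbind, rows)
  list(
    offsets = -flank_bp + (2 * flank_bp) * (seq_len(n_bins) - 0.5) / n_bins,
    mean = colMeans(m, na.rm = TRUE),
    n = colSums(!is.na(m)),
    per_region = m
  )
}

#' Ratio of signal inside a CDR versus its flanks
#'
#' Mean signal within the CDR divided by the mean over the two pooled
#' flanks of `flank_bp` each; a ratio of 1 means equal enrichment inside
#' and outside.
#'
#' @param track A [binned_track()] covering `cdr +/- flank_bp`.
#' @param cdr One-row region tibble.
#' @param flank_bp Flank width, bp.
#' @return A list: `inside`, `outside`, `ratio` (`NA` with
#'   `undefined = TRUE` when the flank mean is zero or missing).
#' @export
inside_outside_ratio <- function(track, cdr, flank_bp = 100000) {
  inside <- track_mean(track, cdr$start, cdr$end)
  lw <- track_overlap_weights(track, cdr$start - flank_bp, cdr$start)
  rw <- track_overlap_weights(track, cdr$end, cdr$end + flank_bp)
  num <- 0; den <- 0
  for (w in list(lw, rw)) {
    if (is.null(w)) next
    v <- track$values[w$idx]
    ok <- !is.na(v)
    num <- num + sum(v[ok] * w$bp[ok])
    den <- den + sum(w$bp[ok])
  }
  outside <- if (den > 0) num / den else NA_real_
  undef <- is.na(outside) || outside == 0
  list(inside = inside, outside = outside,
       ratio = if (undef) NA_real_ else inside / outside,
       undefined = undef)
}
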