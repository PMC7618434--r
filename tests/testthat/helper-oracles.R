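# Independent oracles, deliberately implemented differently from the package.

# Direct (non-cumsum) centered rolling mean with shrinking edge windows.
oracle_smooth <- function(x, k) {
  h <- (as.integer(k) - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, 0)
}

# Exhaustive seeded-expansion oracle: smooth the whole window, label every
# bin against the threshold, then take the maximal contiguous above-threshold
# run containing the CDR-midpoint bin (found via rle, no early exit).
oracle_domain <- function(values, origin, bin_size, cdr_start, cdr_end,
                          window_extension = 30000, smooth_window = 2000,
                          threshold_fraction = 0.01) {
  win_start <- cdr_start - window_extension
  win_end <- cdr_end + window_extension
  j0 <- floor((win_start - origin) / bin_size)
  j1 <- ceiling((win_end - origin) / bin_size) - 1
  idx <- (j0 + 1):(j1 + 1)
  in_cdr <- values[seq_along(values) > (cdr_start - origin) / bin_size &
                     seq_along(values) <= (cdr_end - origin) / bin_size]
  thr <- threshold_fraction * mean(in_cdr, na.rm = TRUE)
  s <- oracle_smooth(values[idx], max(1, round(smooth_window / bin_size)))
  above <- !is.na(s) & s >= thr
  mid <- floor(((cdr_start + cdr_end) / 2 - origin) / bin_size) - j0 + 1
  mid <- min(max(mid, 1L), length(s))
  if (!above[mid]) return(list(degenerate = TRUE))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  run <- which(starts <= mid & ends >= mid)
  list(degenerate = FALSE,
       start = origin + (j0 + starts[run] - 1) * bin_size,
       end = origin + (j0 + ends[run]) * bin_size,
       truncated_left = starts[run] == 1,
       truncated_right = ends[run] == length(s))
}

# Random sparse-background track with one plateau, for oracle cross-checks.
random_domain_case <- function() {
  bin_size <- 200
  cdr <- list(start = 40000, end = 60000)
  n <- (cdr$end - cdr$start + 2 * 30000) / bin_size + 100
  origin <- cdr$start - 30000 - 50 * bin_size
  values <- runif(n, 0, 0.004)
  p_start <- origin + floor(runif(1, 0, n * 0.7)) * bin_size
  p_len <- floor(runif(1, 20, 300)) * bin_size
  lo <- pmax(1, (p_start - origin) / bin_size)
  hi <- pmin(n, lo + p_len / bin_size)
  values[lo:hi] <- values[lo:hi] + runif(1, 0.05, 0.5)
  list(track = binned_track(values, "chrS", bin_size, origin = origin),
       values = values, origin = origin, bin_size = bin_size, cdr = cdr)
}

write_tsv_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A bedmethyl-dialect pileup line with 11 columns.
pileup_line <- function(chrom, start, frac, n_valid = 20) {
  paste(chrom, start, start + 1, "m", n_valid, ".", start, start + 1,
        "0,0,0", n_valid, frac, sep = "\t")
}
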