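#' Seeded-expansion parameters for CENP-A/CENP-C domain calling
#'
#' @param window_extension How far beyond the CDR boundaries the analysis
#'   window extends on each side, bp.
#' @param smooth_window Centered rolling-average width applied to the signal
#'   within the window, bp.
#' @param threshold_fraction Expansion threshold as a fraction of the mean
#'   signal within the CDR.
#' @return A list of class `expansion_params`.
#' @export
expansion_params <- function(window_extension = 30000, smooth_window = 2000,
                             threshold_fraction = 0.01) {
  stopifnot(window_extension > 0, smooth_window > 0,
            threshold_fraction > 0, threshold_fraction < 1)
  structure(list(window_extension = window_extension,
                 smooth_window = smooth_window,
                 threshold_fraction = threshold_fraction),
            class = "expansion_params")
}

#' Call a CENP-A/CENP-C domain by seeded expansion from a CDR
#'
#' The threshold is `threshold_fraction` times the mean (raw) signal within
#' the CDR. The signal over the window `cdr +/- window_extension` is smoothed
#' with a centered rolling average of `smooth_window` (edge bins use
#' shrinking windows); starting from the bin containing the CDR midpoint, the
#' domain expands left and right while the smoothed signal stays at or above
#' the threshold, stopping at the first sub-threshold bin or at the window
#' edge (which sets the corresponding `truncated` flag). Expansion is
#' contiguous: a single sub-threshold smoothed bin terminates that side.
#'
#' If the midpoint bin itself is below threshold the call degenerates to a
#' zero-width interval at the midpoint, flagged `degenerate = TRUE`, with a
#' warning.
#'
#' @param track A [binned_track()] of 6mA fraction covering
#'   `cdr +/- window_extension`.
#' @param cdr One-row region tibble (the seed CDR).
#' @param params An [expansion_params()].
#' @param seed_id Optional identifier copied into the output.
#' @return A one-row tibble: `chrom`, `start`, `end`, `seed_id`, `threshold`,
#'   `truncated_left`, `truncated_right`, `degenerate`.
#' @export
call_domain <- function(track, cdr, params = expansion_params(), seed_id = NA_character_) {
  stopifnot(inherits(track, "binned_track"))
  if (cdr$chrom != track$chrom) stop("CDR is on a different contig", call. = FALSE)
  bs <- track$bin_size
  win_start <- cdr$start - params$window_extension
  win_end <- cdr$end + params$window_extension
  if (win_start < track$origin || win_end > track_end(track)) {
    stop("track does not cover cdr +/- window_extension", call. = FALSE)
  }
  in_cdr <- track_mean(track, cdr$start, cdr$end)
  if (is.na(in_cdr) || in_cdr <= 0) {
    stop("no signal within the CDR: cannot set an expansion threshold", call. = FALSE)
  }
  thr <- params$threshold_fraction * in_cdr

  j0 <- floor((win_start - track$origin) / bs)
  j1 <- ceiling((win_end - track$origin) / bs) - 1
  idx <- (j0 + 1):(j1 + 1)
  s <- rolling_mean(track$values[idx], smooth_bins(params$smooth_window, bs))
  n <- length(s)
  midpoint <- (cdr$start + cdr$end) / 2
  mid <- floor((midpoint - track$origin) / bs) - j0 + 1
  mid <- min(max(mid, 1L), n)
  above <- !is.na(s) & s >= thr
  if (!above[mid]) {
    warning("degenerate domain: smoothed signal at the CDR midpoint is below threshold")
    return(tibble::tibble(chrom = cdr$chrom, start = midpoint, end = midpoint,
                          seed_id = seed_id, threshold = thr,
                          truncated_left = FALSE, truncated_right = FALSE,
                          degenerate = TRUE))
  }
  L <- mid; while (L > 1 && above[L - 1]) L <- L - 1
  R <- mid; while (R < n && above[R + 1]) R <- R + 1
  tibble::tibble(
    chrom = cdr$chrom,
    start = track$origin + (j0 + L - 1) * bs,
    end = track$origin + (j0 + R) * bs,
    seed_id = seed_id,
    threshold = thr,
    truncated_left = (L == 1),
    truncated_right = (R == n),
    degenerate = FALSE
  )
}
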