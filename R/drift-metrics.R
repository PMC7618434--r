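#' Peak center of a binned enrichment profile
#'
#' The profile's peak domain is the maximal contiguous run of bins at or
#' above a background level (`background_frac` of the profile maximum) that
#' contains the global maximum. The center is the signal-weighted centroid
#' of that run, reported as the bp midpoint of the bin containing the
#' centroid; `method = "midpoint"` instead reports the midpoint of the run,
#' as a sensitivity alternative.
#'
#' @param profile A [binned_track()] of non-negative enrichment values
#'   (typically counts-per-million, 1-kb bins).
#' @param background_frac Background level as a fraction of the maximum.
#' @param method `"centroid"` (default) or `"midpoint"`.
#' @return Peak center position in bp.
#' @export
peak_center <- function(profile, background_frac = 0.1,
                        method = c("centroid", "midpoint")) {
  method <- match.arg(method)
  v <- profile$values
  if (all(is.na(v)) || max(v, na.rm = TRUE) <= 0) {
    stop("no peak: profile has no positive signal", call. = FALSE)
  }
  bg <- background_frac * max(v, na.rm = TRUE)
  imax <- which.max(v)
  above <- !is.na(v) & v >= bg
  L <- imax; while (L > 1 && above[L - 1]) L <- L - 1
  R <- imax; while (R < length(v) && above[R + 1]) R <- R + 1
  bs <- profile$bin_size
  if (method == "midpoint") {
    return(profile$origin + ((L + R) / 2 - 0.5) * bs)
  }
  w <- v[L:R]
  centers <- profile$origin + ((L:R) - 0.5) * bs
  pos <- sum(w * centers) / sum(w)
  bin <- floor((pos - profile$origin) / bs)
  profile$origin + (bin + 0.5) * bs
}

#' Peak-center shift between a reference and one or more clone profiles
#'
#' Shift is signed in kb, positive toward increasing coordinate; the summary
#' `mean_abs_shift` averages absolute per-clone shifts (drift occurs in
#' either direction, so the signed mean would cancel).
#'
#' @param reference Reference [binned_track()] profile (early passage).
#' @param samples A single profile or a (optionally named) list of clone
#'   profiles with identical region and bin size.
#' @param ... Passed to [peak_center()].
#' @return A list with `clones` (tibble: `clone`, `center_reference`,
#'   `center_sample`, `shift_kb`) and `mean_abs_shift_kb`.
#' @export
center_shift <- function(reference, samples, ...) {
  if (inherits(samples, "binned_track")) samples <- list(samples)
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("clone", seq_along(samples))
  }
  ref_center <- peak_center(reference, ...)
  rows <- lapply(names(samples), function(nm) {
    p <- samples[[nm]]
    if (p$chrom != reference$chrom || p$bin_size != reference$bin_size ||
        p$origin != reference$origin ||
        length(p$values) != length(reference$values)) {
      stop("incompatible profiles: region and bin size must match the reference",
           call. = FALSE)
    }
    c_s <- peak_center(p, ...)
    tibble::tibble(clone = nm, center_reference = ref_center,
                   center_sample = c_s, shift_kb = (c_s - ref_center) / 1000)
  })
  clones <- do.call(rbind, rows)
  list(clones = clones, mean_abs_shift_kb = mean(abs(clones$shift_kb)))
}

#' Analysis windows for neocentromere enrichment
#'
#' The initial locus window plus flanks of `flank` bp immediately upstream
#' (`left`) and downstream (`right`). Defaults are the 90-kb initial
#' Neo4p13 locus on the neocentromere haplotype.
#'
#' @param chrom Contig name.
#' @param start,end Initial-locus window, bp.
#' @param flank Flank width, bp.
#' @return A tibble: `window` (`left`, `initial`, `right`), `chrom`,
#'   `start`, `end`.
#' @export
drift_windows <- function(chrom = "chr4_hap2", start = 42868000,
                          end = 42958000, flank = 90000) {
  check_interval(start, end)
  win_start <- c(start - flank, start, end)
  win_end <- c(start, end, end + flank)
  tibble::tibble(window = c("left", "initial", "right"), chrom = chrom,
                 start = win_start, end = win_end)
}

#' Window enrichment of a sample profile over a control
#'
#' Per window, the ratio of summed sample signal to summed control signal,
#' so the control against itself is a baseline of 1 in every window.
#' Windows with zero control signal are flagged `undefined` with `NA`
#' ratio.
#'
#' @param sample,control [binned_track()] profiles on the same region.
#' @param windows Window tibble from [drift_windows()].
#' @return `windows` with `sample_sum`, `control_sum`, `ratio`, `undefined`
#'   columns added.
#' @export
window_enrichment <- function(sample, control, windows = drift_windows()) {
  stopifnot(inherits(sample, "binned_track"), inherits(control, "binned_track"))
  if (sample$chrom != control$chrom || sample$bin_size != control$bin_size) {
    stop("incompatible profiles", call. = FALSE)
  }
  ss <- vapply(seq_len(nrow(windows)), function(i) {
    track_sum(sample, windows$start[i], windows$end[i])
  }, 0)
  cs <- vapply(seq_len(nrow(windows)), function(i) {
    track_sum(control, windows$start[i], windows$end[i])
  }, 0)
  undef <- is.na(cs) | cs == 0
  windows$sample_sum <- ss
  windows$control_sum <- cs
  windows$ratio <- ifelse(undef, NA_real_, ss / cs)
  windows$undefined <- undef
  windows
}
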