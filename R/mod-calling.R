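#' Modification-calling threshold scheme
#'
#' Defaults follow the standard modkit-style filtering for antibody-directed
#' 6mA and endogenous 5mCG: a call is confidently modified when its
#' modification probability reaches `mod_threshold` for its code, confidently
#' canonical when the canonical-base probability reaches the base filter
#' threshold, and filtered (discarded from both numerator and denominator of
#' the pileup fraction) otherwise.
#'
#' @param mod_a Modified-call probability threshold for 6mA (`a`).
#' @param mod_m Modified-call probability threshold for 5mCG (`m`).
#' @param filter_A Canonical-call threshold for adenine.
#' @param filter_C Canonical-call threshold for cytosine.
#' @return A list of class `threshold_scheme`.
#' @export
threshold_scheme <- function(mod_a = 0.98, mod_m = 0.8,
                             filter_A = 0.8, filter_C = 0.8) {
  vals <- c(mod_a, mod_m, filter_A, filter_C)
  stopifnot(all(vals > 0), all(vals <= 1), mod_a >= 0.5, mod_m >= 0.5)
  structure(list(mod = c(a = mod_a, m = mod_m),
                 filter = c(a = filter_A, m = filter_C)),
            class = "threshold_scheme")
}

#' Encode a modification probability in the 256-bin integer scheme
#'
#' The standard encoding used by modification-aware read formats:
#' `floor(p * 256)` capped at 255. The default thresholds 0.98 and 0.8 map
#' to the integer cutoffs 250 and 204.
#'
#' @param p Probability (vectorized), each in \[0, 1\].
#' @return Integer vector in \[0, 255\].
#' @examples
#' ml_from_prob(c(0.98, 0.8, 1))
#' @export
ml_from_prob <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probability outside [0, 1]", call. = FALSE)
  }
  as.integer(pmin(floor(p * 256), 255))
}

#' Classify a per-base modification probability
#'
#' `MODIFIED` when `p_mod >= mod_threshold(code)`; otherwise `CANONICAL`
#' when `1 - p_mod >= filter_threshold(base)`; otherwise `FILTERED` (the
#' ambiguous middle band is discarded, not counted as canonical).
#'
#' @param p_mod Modification probability (vectorized).
#' @param mod_code `"a"` (6mA) or `"m"` (5mCG).
#' @param scheme A [threshold_scheme()].
#' @return Character vector of `"MODIFIED"`, `"CANONICAL"`, `"FILTERED"`.
#' @export
classify_call <- function(p_mod, mod_code = c("a", "m"),
                          scheme = threshold_scheme()) {
  mod_code <- match.arg(mod_code)
  if (any(p_mod < 0 | p_mod > 1, na.rm = TRUE)) {
    stop("probability outside [0, 1]", call. = FALSE)
  }
  out <- rep("FILTERED", length(p_mod))
  out[p_mod >= scheme$mod[[mod_code]]] <- "MODIFIED"
  out[p_mod < scheme$mod[[mod_code]] &
        (1 - p_mod) >= scheme$filter[[mod_code]]] <- "CANONICAL"
  out
}

#' Build a fraction-modified pileup from per-position calls
#'
#' Per position, `n_valid` counts MODIFIED plus CANONICAL calls and
#' `frac_modified = MODIFIED / n_valid`; FILTERED calls are excluded from
#' both numerator and denominator, and positions with no valid calls are
#' omitted entirely.
#'
#' @param calls Tibble with columns `pos` (bp, 0-based) and `outcome`
#'   (`"MODIFIED"`/`"CANONICAL"`/`"FILTERED"`), optionally `chrom`.
#' @param region One-row region tibble; calls outside it are dropped.
#' @param mod_code Modification code recorded in the output.
#' @return A pileup tibble as from [read_pileup()].
#' @export
pileup_molecules <- function(calls, region, mod_code = "a") {
  stopifnot(all(c("pos", "outcome") %in% names(calls)))
  if ("chrom" %in% names(calls)) calls <- calls[calls$chrom == region$chrom, ]
  calls <- calls[calls$pos >= region$start & calls$pos < region$end, ]
  calls <- calls[calls$outcome != "FILTERED", ]
  if (!nrow(calls)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), mod_code = character(),
                          n_valid = numeric(), frac_modified = numeric()))
  }
  n_valid <- tapply(calls$outcome, calls$pos, length)
  n_mod <- tapply(calls$outcome == "MODIFIED", calls$pos, sum)
  pos <- as.numeric(names(n_valid))
  out <- tibble::tibble(
    chrom = region$chrom, start = pos, end = pos + 1,
    mod_code = mod_code,
    n_valid = as.numeric(n_valid),
    frac_modified = as.numeric(n_mod) / as.numeric(n_valid)
  )
  out[order(out$start), ]
}
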