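#' Valley-calling parameters for CDR detection
#'
#' CDRs (centromere dip regions) are valleys in the 5mCG fraction-modified
#' track over an active alpha-satellite HOR array. A smoothed local minimum
#' qualifies when its depth below the regional median reaches
#' `height_frac * median` and its topographic prominence reaches
#' `prom_frac * median`. Valleys within `merge_distance` belong to one
#' centromere locus.
#'
#' @param smooth_window Centered rolling-mean window, bp.
#' @param height_frac Minimum valley depth as a fraction of the regional
#'   median signal.
#' @param prom_frac Minimum valley prominence as a fraction of the regional
#'   median signal.
#' @param merge_distance Gap below which CDRs merge into one locus, bp.
#' @return A list of class `valley_params`.
#' @export
valley_params <- function(smooth_window = 5000, height_frac = 0.39,
                          prom_frac = 0.45, merge_distance = 500000) {
  stopifnot(smooth_window >= 1, height_frac > 0, height_frac < 1,
            prom_frac > 0, prom_frac < 1, merge_distance >= 0)
  structure(list(smooth_window = smooth_window, height_frac = height_frac,
                 prom_frac = prom_frac, merge_distance = merge_distance),
            class = "valley_params")
}

#' Detect CDRs as valleys in a 5mCG track
#'
#' The track is smoothed with a centered rolling mean of `smooth_window`;
#' local minima of the smoothed trace are kept when both the depth and the
#' prominence criteria of [valley_params()] hold relative to the regional
#' median of the smoothed signal. Each retained valley's extent is the
#' maximal interval around its minimum where the smoothed signal stays below
#' `median - depth/2` (a deterministic half-depth edge rule standing in for
#' manual curation). Overlapping candidates are resolved in favor of the
#' deeper valley, so returned calls are disjoint and sorted by start.
#'
#' @param track A fraction-valued [binned_track()] over an active HOR with at
#'   least 3 non-missing bins.
#' @param params A [valley_params()].
#' @return A tibble with columns `chrom`, `start`, `end`, `min_pos` (bp of
#'   the smoothed minimum), `depth`, `prominence`.
#' @export
detect_valleys <- function(track, params = valley_params()) {
  stopifnot(inherits(track, "binned_track"))
  v <- track$values
  if (all(is.na(v))) stop("track has no data", call. = FALSE)
  if (sum(!is.na(v)) < 3) stop("need at least 3 non-missing bins", call. = FALSE)
  bs <- track$bin_size
  k <- smooth_bins(params$smooth_window, bs)
  s <- rolling_mean(v, k)
  med <- stats::median(s, na.rm = TRUE)
  sf <- ifelse(is.na(s), med, s)  # missing stretches cannot seed or bound valleys
  mins <- local_minima(sf)
  cand <- list()
  for (i in mins) {
    depth <- med - sf[i]
    if (depth < params$height_frac * med) next
    if (valley_prominence(sf, i) < params$prom_frac * med) next
    cutoff <- med - 0.5 * depth
    L <- i; while (L > 1 && sf[L - 1] < cutoff) L <- L - 1
    R <- i; while (R < length(sf) && sf[R + 1] < cutoff) R <- R + 1
    cand[[length(cand) + 1]] <- c(L = L, R = R, i = i, depth = depth,
                                  prom = valley_prominence(sf, i))
  }
  empty <- tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          min_pos = numeric(), depth = numeric(), prominence = numeric())
  if (!length(cand)) return(empty)
  m <- do.call(rbind, cand)
  m <- m[order(-m[, "depth"], m[, "i"]), , drop = FALSE]
  kept <- matrix(numeric(0), ncol = ncol(m), dimnames = list(NULL, colnames(m)))
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    if (nrow(kept) == 0 ||
        all(row["R"] < kept[, "L"] | row["L"] > kept[, "R"])) {
      kept <- rbind(kept, row)
    }
  }
  kept <- kept[order(kept[, "L"]), , drop = FALSE]
  tibble::tibble(
    chrom = track$chrom,
    start = track$origin + (kept[, "L"] - 1) * bs,
    end = track$origin + kept[, "R"] * bs,
    min_pos = track$origin + (kept[, "i"] - 0.5) * bs,
    depth = kept[, "depth"],
    prominence = kept[, "prom"]
  )
}

# Indices of strict local minima; a flat plateau minimum reports its middle.
local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- integer(0)
  for (j in seq_along(r$values)) {
    if (j == 1 || j == length(r$values)) next
    if (r$values[j] < r$values[j - 1] && r$values[j] < r$values[j + 1]) {
      out <- c(out, as.integer(floor((starts[j] + ends[j]) / 2)))
    }
  }
  out
}

# Topographic prominence of a valley at index i: invert-signal analogue of
# peak prominence. On each side, walk until a strictly lower value (or the
# edge); the lower of the two interval maxima minus x[i] is the prominence.
valley_prominence <- function(x, i) {
  n <- length(x)
  left_max <- x[i]
  j <- i
  while (j > 1 && x[j - 1] >= x[i]) {
    j <- j - 1
    left_max <- max(left_max, x[j])
  }
  if (j == 1) left_max <- max(left_max, x[1])
  right_max <- x[i]
  j <- i
  while (j < n && x[j + 1] >= x[i]) {
    j <- j + 1
    right_max <- max(right_max, x[j])
  }
  if (j == n) right_max <- max(right_max, x[n])
  min(left_max, right_max) - x[i]
}

#' Merge CDR calls into centromere loci
#'
#' Transitive closure of the "gap < merge_distance" relation on sorted calls
#' from one contig; the locus span is the hull of its members. Idempotent.
#'
#' @param cdrs Tibble of CDR calls (`chrom`, `start`, `end`, ...), one contig.
#' @param merge_distance Gap threshold in bp (gaps strictly below it merge).
#' @return A tibble with `chrom`, `start`, `end`, `n_members`,
#'   `members` (list-column of member rows).
#' @export
merge_into_loci <- function(cdrs, merge_distance = 500000) {
  if (!nrow(cdrs)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_members = integer(),
                          members = list()))
  }
  stopifnot(length(unique(cdrs$chrom)) == 1)
  cdrs <- cdrs[order(cdrs$start), ]
  grp <- cumsum(c(1, as.integer(cdrs$start[-1] - cdrs$end[-nrow(cdrs)] >= merge_distance)))
  rows <- lapply(split(seq_len(nrow(cdrs)), grp), function(idx) {
    tibble::tibble(chrom = cdrs$chrom[idx[1]],
                   start = min(cdrs$start[idx]), end = max(cdrs$end[idx]),
                   n_members = length(idx), members = list(cdrs[idx, ]))
  })
  do.call(rbind, rows)
}

#' Classify centromere loci as primary, new or discarded
#'
#' A locus overlapping (or, under the default rule, within `merge_distance`
#' of) a parent primary CDR interval is `primary`; otherwise, a locus
#' intersecting a CENP-A domain is `new` (a newly formed CDR); loci with no
#' CENP-A anywhere are `discarded`, replacing the manual-curation step of
#' removing non-CENP-A-containing calls.
#'
#' @param loci Tibble of loci from [merge_into_loci()].
#' @param parent_primary Tibble of parent primary CDR intervals.
#' @param cenpa_domains Tibble of CENP-A domain intervals.
#' @param merge_distance Distance defining "at the primary site", bp.
#' @param rule `"overlap_or_distance"` (default: within `merge_distance` of a
#'   parent interval counts as primary) or `"overlap_only"`.
#' @return `loci` with a `status` column added.
#' @export
classify_loci <- function(loci, parent_primary, cenpa_domains,
                          merge_distance = 500000,
                          rule = c("overlap_or_distance", "overlap_only")) {
  rule <- match.arg(rule)
  if (!nrow(loci)) return(tibble::tibble(loci, status = character(0)))
  slack <- if (rule == "overlap_or_distance") merge_distance else 0
  status <- vapply(seq_len(nrow(loci)), function(i) {
    near_parent <- nrow(parent_primary) > 0 &&
      any(parent_primary$chrom == loci$chrom[i] &
            loci$start[i] < parent_primary$end + slack &
            loci$end[i] > parent_primary$start - slack)
    if (near_parent) return("primary")
    has_cenpa <- nrow(cenpa_domains) > 0 &&
      any(cenpa_domains$chrom == loci$chrom[i] &
            loci$start[i] < cenpa_domains$end &
            loci$end[i] > cenpa_domains$start)
    if (has_cenpa) "new" else "discarded"
  }, "")
  loci$status <- status
  loci
}

#' Per-centromere CDR size change versus a parent sample
#'
#' Sums primary CDR lengths per centromere in sample and parent, takes the
#' per-centromere ratio and reports the mean percent change across
#' centromeres, after dropping excluded centromeres.
#'
#' @param sample_cdrs,parent_cdrs Tibbles with columns `centromere`, `start`,
#'   `end` (primary CDRs only).
#' @param excluded Character vector of centromere ids to drop (default: the
#'   neocentromere haplotype, the absent X haplotype and the poorly defined
#'   chromosome-18 CDRs).
#' @return A list with `per_centromere` (tibble: `centromere`, `parent_bp`,
#'   `sample_bp`, `ratio`) and `mean_percent_change`.
#' @export
cdr_size_change <- function(sample_cdrs, parent_cdrs,
                            excluded = c("cen4_hap2", "cenX_hap2",
                                         "cen18_hap1", "cen18_hap2")) {
  sample_cdrs <- sample_cdrs[!sample_cdrs$centromere %in% excluded, ]
  parent_cdrs <- parent_cdrs[!parent_cdrs$centromere %in% excluded, ]
  ids <- sort(unique(parent_cdrs$centromere))
  parent_bp <- vapply(ids, function(id) {
    sum(parent_cdrs$end[parent_cdrs$centromere == id] -
          parent_cdrs$start[parent_cdrs$centromere == id])
  }, 0)
  sample_bp <- vapply(ids, function(id) {
    sum(sample_cdrs$end[sample_cdrs$centromere == id] -
          sample_cdrs$start[sample_cdrs$centromere == id])
  }, 0)
  if (any(parent_bp == 0)) {
    stop(sprintf("undefined ratio: parent CDR total is zero for %s",
                 ids[parent_bp == 0][1]), call. = FALSE)
  }
  per <- tibble::tibble(centromere = ids, parent_bp = unname(parent_bp),
                        sample_bp = unname(sample_bp),
                        ratio = unname(sample_bp / parent_bp))
  list(per_centromere = per,
       mean_percent_change = mean((per$ratio - 1) * 100))
}
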