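#' Read a modification pileup (bedmethyl dialect)
#'
#' Parses a tab-separated per-position pileup with at least 11 columns:
#' columns 1-3 are `chrom`, `start`, `end` (0-based half-open, width 1),
#' column 10 the count of valid (unfiltered) calls and column 11 the
#' fraction modified. Pileup emitters disagree on the scale of column 11;
#' the default `percent` dialect divides it by 100, `fraction` takes it
#' as is. Plain or gzip-compressed files are accepted.
#'
#' @param path File path.
#' @param mod_code Modification code the pileup carries: `"a"` (6mA) or
#'   `"m"` (5mCG).
#' @param dialect Scale of column 11: `"percent"` (0-100, default) or
#'   `"fraction"` (0-1).
#' @return A tibble with columns `chrom`, `start`, `end`, `mod_code`,
#'   `n_valid`, `frac_modified`, sorted by (`chrom`, `start`).
#' @export
read_pileup <- function(path, mod_code = c("a", "m"),
                        dialect = c("percent", "fraction")) {
  mod_code <- match.arg(mod_code)
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), mod_code = character(),
                          n_valid = numeric(), frac_modified = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 11)
  if (length(bad)) {
    stop(sprintf("pileup parse error at line %d: expected >= 11 tab-separated columns, got %d",
                 bad[1], ncols[bad[1]]), call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  n_valid <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 10L)))
  frac <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  bad <- which(is.na(start) | is.na(end) | is.na(frac))
  if (length(bad)) {
    stop(sprintf("pileup parse error at line %d: non-numeric coordinate or value",
                 bad[1]), call. = FALSE)
  }
  hi <- if (dialect == "percent") 100 else 1
  bad <- which(frac < 0 | frac > hi)
  if (length(bad)) {
    stop(sprintf("pileup range error at line %d: value %g outside [0, %g] (%s dialect)",
                 bad[1], frac[bad[1]], hi, dialect), call. = FALSE)
  }
  if (dialect == "percent") frac <- frac / 100
  n_valid[is.na(n_valid)] <- 0
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end,
    mod_code = mod_code, n_valid = n_valid, frac_modified = frac
  )
  out[order(out$chrom, out$start), ]
}

#' Read single-molecule modification records (12-column BED)
#'
#' Decodes per-read modified-base positions from the 12-column BED dialect in
#' which column 10 is the block count (number of modification sites), column
#' 11 the block sizes and column 12 the block starts relative to the read
#' start. Block starts become `mod_offsets`, 0-based offsets relative to the
#' alignment start.
#'
#' @param path File path (plain or gzip).
#' @return A tibble with columns `chrom`, `start`, `end`, `read_id`,
#'   `n_mods` and a list-column `mod_offsets` of sorted integer offsets.
#' @export
read_molecules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), read_id = character(),
                          n_mods = integer(), mod_offsets = list())
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 12)
  if (length(bad)) {
    stop(sprintf("molecule parse error at line %d: expected 12 columns, got %d",
                 bad[1], ncols[bad[1]]), call. = FALSE)
  }
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  n_blocks <- as.integer(vapply(fields, `[[`, "", 10L))
  starts_str <- vapply(fields, `[[`, "", 12L)
  offsets <- lapply(seq_along(fields), function(i) {
    s <- sub(",$", "", starts_str[i])
    off <- if (nzchar(s) && s != ".") as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]) else numeric(0)
    if (length(off) != n_blocks[i]) {
      stop(sprintf("molecule consistency error at line %d: block count %d but %d block starts",
                   i, n_blocks[i], length(off)), call. = FALSE)
    }
    if (length(off) && (min(off) < 0 || max(off) >= end[i] - start[i])) {
      stop(sprintf("molecule coordinate error at line %d: offset outside read span", i),
           call. = FALSE)
    }
    sort(off)
  })
  tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end,
    read_id = vapply(fields, `[[`, "", 4L),
    n_mods = n_blocks,
    mod_offsets = offsets
  )
}

#' Write single-molecule records as 12-column BED
#'
#' Inverse of [read_molecules()]: block sizes are written as 1 (point
#' modifications) and block starts as offsets relative to the read start.
#'
#' @param molecules Tibble as returned by [read_molecules()].
#' @param path Output path.
#' @export
write_molecules <- function(molecules, path) {
  lines <- vapply(seq_len(nrow(molecules)), function(i) {
    off <- molecules$mod_offsets[[i]]
    n <- length(off)
    paste(molecules$chrom[i],
          format(molecules$start[i], scientific = FALSE),
          format(molecules$end[i], scientific = FALSE),
          molecules$read_id[i], 0, ".",
          format(molecules$start[i], scientific = FALSE),
          format(molecules$end[i], scientific = FALSE),
          "0,0,0", n,
          paste(rep(1, max(n, 0)), collapse = ","),
          paste(format(off, scientific = FALSE, trim = TRUE), collapse = ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Bin per-position values into a track
#'
#' Produces `ceiling(width/bin_size)` bins over `region`; each bin value is
#' the mean of the covered positions, and bins with no data are `NA`.
#'
#' @param x Either a pileup tibble (as from [read_pileup()]; positions taken
#'   from `start`, values from `frac_modified`) or a numeric vector of
#'   per-base values starting at `region$start`.
#' @param region One-row region tibble.
#' @param bin_size Bin width in bp.
#' @return A [binned_track()] with `origin = region$start`.
#' @export
bin_track <- function(x, region, bin_size) {
  stopifnot(bin_size >= 1)
  check_interval(region$start, region$end)
  n_bins <- ceiling(region_width(region) / bin_size)
  if (is.data.frame(x)) {
    x <- x[x$chrom == region$chrom & x$start >= region$start & x$start < region$end, ]
    pos <- x$start
    val <- x$frac_modified
  } else {
    stopifnot(length(x) == region_width(region))
    pos <- region$start + seq_along(x) - 1
    val <- as.numeric(x)
    keep <- !is.na(val)
    pos <- pos[keep]; val <- val[keep]
  }
  values <- rep(NA_real_, n_bins)
  if (length(pos)) {
    bin <- floor((pos - region$start) / bin_size) + 1
    m <- tapply(val, bin, mean)
    values[as.integer(names(m))] <- as.numeric(m)
  }
  binned_track(values, region$chrom, bin_size, origin = region$start)
}

#' Write a binned track as bedGraph
#'
#' Four-column bedGraph; `NA` bins are omitted (the missing-data contract:
#' absence, never zero).
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  keep <- which(!is.na(track$values))
  starts <- track$origin + (keep - 1) * track$bin_size
  lines <- sprintf("%s\t%s\t%s\t%.6g", track$chrom,
                   format(starts, scientific = FALSE, trim = TRUE),
                   format(starts + track$bin_size, scientific = FALSE, trim = TRUE),
                   track$values[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path File path (plain or gzip).
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), value = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4)
  if (length(bad)) {
    stop(sprintf("bedGraph parse error at line %d", bad[1]), call. = FALSE)
  }
  tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    value = as.numeric(vapply(fields, `[[`, "", 4L))
  )
}

#' Assemble a bedGraph table back into a binned track
#'
#' @param bg Tibble from [read_bedgraph()] with uniform interval widths.
#' @param region Optional region to cover; defaults to the hull of `bg`.
#' @param bin_size Optional bin size; defaults to the modal interval width.
#' @return A [binned_track()].
#' @export
bedgraph_to_track <- function(bg, region = NULL, bin_size = NULL) {
  stopifnot(nrow(bg) > 0)
  if (is.null(bin_size)) bin_size <- stats::median(bg$end - bg$start)
  if (is.null(region)) region <- genomic_region(bg$chrom[1], min(bg$start), max(bg$end))
  n_bins <- ceiling(region_width(region) / bin_size)
  values <- rep(NA_real_, n_bins)
  idx <- floor((bg$start - region$start) / bin_size) + 1
  keep <- idx >= 1 & idx <= n_bins
  values[idx[keep]] <- bg$value[keep]
  binned_track(values, region$chrom, bin_size, origin = region$start)
}

#' Read a BED3/BED4 annotation file
#'
#' @param path File path (plain or gzip).
#' @return A tibble with `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop(sprintf("BED parse error at line %d", bad[1]), call. = FALSE)
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L))
  )
  if (all(lengths(fields) >= 4)) out$name <- vapply(fields, `[[`, "", 4L)
  out
}
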