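#' Parameters for per-molecule 6mA density
#'
#' @param min_overlap Minimum read/CDR overlap for a read to be scored, bp.
#' @param density_unit Density denominator unit, bp (sites per
#'   `density_unit` of overlapping CDR sequence).
#' @param excluded_chroms Contigs excluded from density analysis (defaults:
#'   the neocentromere haplotype, absent or poorly defined centromeres).
#' @return A list of class `density_params`.
#' @export
density_params <- function(min_overlap = 10000, density_unit = 10000,
                           excluded_chroms = c("chr4_2", "chr18", "chrX_2",
                                               "chr13_2", "chr21_2")) {
  stopifnot(min_overlap >= 1, density_unit >= 1)
  structure(list(min_overlap = min_overlap, density_unit = density_unit,
                 excluded_chroms = excluded_chroms),
            class = "density_params")
}

#' Per-read 6mA density within CDR intervals
#'
#' For every (read, CDR) pair on a non-excluded contig whose half-open
#' overlap is at least `min_overlap`, counts the modification sites whose
#' absolute position falls inside the overlap and reports the density in
#' sites per `density_unit` of overlapping sequence. Pairs below the
#' overlap floor emit nothing.
#'
#' @param reads Molecule tibble as from [read_molecules()].
#' @param cdrs Tibble of CDR intervals with columns `chrom`, `start`, `end`
#'   and optionally `cdr_id` (defaults to `chrom:start-end`).
#' @param params A [density_params()].
#' @return A tibble: `read_id`, `cdr_id`, `overlap_len`, `n_mods`, `density`.
#' @export
per_read_density <- function(reads, cdrs, params = density_params()) {
  if (!"cdr_id" %in% names(cdrs)) {
    cdrs$cdr_id <- sprintf("%s:%s-%s", cdrs$chrom,
                           format(cdrs$start, scientific = FALSE, trim = TRUE),
                           format(cdrs$end, scientific = FALSE, trim = TRUE))
  }
  cdrs <- cdrs[!cdrs$chrom %in% params$excluded_chroms, ]
  out <- list()
  for (ci in seq_len(nrow(cdrs))) {
    on_chrom <- which(reads$chrom == cdrs$chrom[ci] &
                        !reads$chrom %in% params$excluded_chroms)
    for (ri in on_chrom) {
      ov_start <- max(reads$start[ri], cdrs$start[ci])
      ov_end <- min(reads$end[ri], cdrs$end[ci])
      ov <- ov_end - ov_start
      if (ov < params$min_overlap) next
      pos <- reads$start[ri] + reads$mod_offsets[[ri]]
      n <- sum(pos >= ov_start & pos < ov_end)
      out[[length(out) + 1]] <- tibble::tibble(
        read_id = reads$read_id[ri], cdr_id = cdrs$cdr_id[ci],
        overlap_len = ov, n_mods = n,
        density = n * params$density_unit / ov)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(read_id = character(), cdr_id = character(),
                          overlap_len = numeric(), n_mods = numeric(),
                          density = numeric()))
  }
  do.call(rbind, out)
}

#' Target-over-control density enrichment
#'
#' Divides the mean per-read target density by the mean control (IgG)
#' density, per CDR by default or pooled across all CDRs. Groups with a
#' zero or missing control mean are reported with `NA` enrichment and
#' `undefined = TRUE`, never a silent infinity.
#'
#' @param target,control Density tibbles from [per_read_density()].
#' @param pooled If `TRUE`, a single pooled enrichment over all reads.
#' @return A tibble: `cdr_id`, `target_mean_density`, `control_mean_density`,
#'   `target_n`, `control_n`, `enrichment`, `undefined`.
#' @export
mod_enrichment <- function(target, control, pooled = FALSE) {
  if (pooled) {
    target$cdr_id <- "pooled"
    control$cdr_id <- "pooled"
  }
  ids <- sort(unique(target$cdr_id))
  rows <- lapply(ids, function(id) {
    td <- target$density[target$cdr_id == id]
    cd <- control$density[control$cdr_id == id]
    tm <- mean(td)
    cm <- if (length(cd)) mean(cd) else NA_real_
    undef <- is.na(cm) || cm == 0
    tibble::tibble(cdr_id = id, target_mean_density = tm,
                   control_mean_density = cm,
                   target_n = length(td), control_n = length(cd),
                   enrichment = if (undef) NA_real_ else tm / cm,
                   undefined = undef)
  })
  do.call(rbind, rows)
}
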