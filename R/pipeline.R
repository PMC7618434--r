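#' End-to-end centromere survey on a simulated (or assembled) bundle
#'
#' Runs the canonical-centromere analysis chain: CDR detection on the 5mCG
#' track over the active HOR, merging into centromere loci, classification
#' against a parent CDR database, seeded CENP-A domain expansion per
#' retained locus, per-molecule 6mA density with IgG normalization, and a
#' CDR-centered aggregate 5mCG profile.
#'
#' @param bundle A `sim_bundle` from [simulate_epigenome()], or any list
#'   providing `tracks$mcg`, `tracks$cenpa`, `molecules$cenpa`,
#'   `molecules$igg` and `hor`.
#' @param parent_primary Parent primary CDR intervals (tibble). Defaults to
#'   the bundle's truth primary CDRs, i.e. the parent database the sample
#'   is compared against.
#' @param valley A [valley_params()].
#' @param expansion An [expansion_params()].
#' @param density A [density_params()].
#' @return A list of class `survey_report`: `cdrs`, `loci` (with status),
#'   `domains`, `density` (per read), `enrichment`, `aggregate_5mcg`,
#'   `params`.
#' @export
run_centromere_survey <- function(bundle, parent_primary = NULL,
                                  valley = valley_params(),
                                  expansion = expansion_params(),
                                  density = density_params()) {
  for (need in c("tracks", "hor", "molecules")) {
    if (is.null(bundle[[need]])) {
      stop(sprintf("configuration error: bundle lacks '%s'", need), call. = FALSE)
    }
  }
  if (is.null(bundle$tracks$mcg)) {
    stop("configuration error: no 5mCG track in bundle", call. = FALSE)
  }
  if (is.null(parent_primary)) {
    parent_primary <- bundle$truth[bundle$truth$status == "primary", ]
  }

  mcg_hor <- subset_track(bundle$tracks$mcg, bundle$hor)
  cdrs <- detect_valleys(mcg_hor, valley)
  loci <- merge_into_loci(cdrs, valley$merge_distance)

  domains_all <- lapply(seq_len(nrow(loci)), function(i) {
    call_domain(bundle$tracks$cenpa, loci[i, c("chrom", "start", "end")],
                expansion, seed_id = sprintf("locus%d", i))
  })
  domains_all <- if (length(domains_all)) do.call(rbind, domains_all) else
    tibble::tibble()
  cenpa_domains <- if (nrow(domains_all)) domains_all[!domains_all$degenerate, ]
    else tibble::tibble(chrom = character(), start = numeric(), end = numeric())

  loci <- classify_loci(loci, parent_primary, cenpa_domains,
                        merge_distance = valley$merge_distance)
  retained <- loci[loci$status != "discarded", ]

  dens <- per_read_density(bundle$molecules$cenpa,
                           retained[, c("chrom", "start", "end")], density)
  dens_ctrl <- per_read_density(bundle$molecules$igg,
                                retained[, c("chrom", "start", "end")], density)
  enr <- if (nrow(dens)) mod_enrichment(dens, dens_ctrl) else tibble::tibble()

  agg <- if (nrow(retained)) {
    aggregate_profile(bundle$tracks$mcg, retained[, c("chrom", "start", "end")],
                      flank_bp = 250000, n_bins = 100, center = "midpoint")
  } else NULL

  structure(list(cdrs = cdrs, loci = loci, domains = domains_all,
                 density = dens, density_control = dens_ctrl,
                 enrichment = enr, aggregate_5mcg = agg,
                 params = list(valley = valley, expansion = expansion,
                               density = density)),
            class = "survey_report")
}

#' Drift analysis of clone profiles against an early-passage reference
#'
#' Per-clone signed peak-center shifts, the mean absolute shift, and
#' initial-locus/flank window enrichment relative to the reference
#' (baseline 1).
#'
#' @param reference Reference [binned_track()] profile.
#' @param clones Named list of clone profiles (same region/bin size).
#' @param windows Window tibble from [drift_windows()].
#' @param ... Passed to [peak_center()].
#' @return A list of class `drift_report`: `shifts` (tibble),
#'   `mean_abs_shift_kb`, `window_enrichment` (tibble with a `clone`
#'   column).
#' @export
run_drift_analysis <- function(reference, clones, windows = drift_windows(), ...) {
  shifts <- center_shift(reference, clones, ...)
  wins <- lapply(names(clones), function(nm) {
    tibble::tibble(clone = nm, window_enrichment(clones[[nm]], reference, windows))
  })
  structure(list(shifts = shifts$clones,
                 mean_abs_shift_kb = shifts$mean_abs_shift_kb,
                 window_enrichment = do.call(rbind, wins)),
            class = "drift_report")
}

#' Default parameter audit
#'
#' Collects every user-facing default in one tibble (name, value) so that a
#' configuration can be checked against the published analysis parameters at
#' a glance.
#'
#' @return A tibble with columns `parameter`, `value`.
#' @export
default_parameters <- function() {
  vp <- valley_params(); ep <- expansion_params(); dp <- density_params()
  ts <- threshold_scheme(); hs <- hor_scheme(); cs <- cdr_scheme()
  dw <- drift_windows()
  tibble::tibble(
    parameter = c("valley.height_frac", "valley.prom_frac",
                  "valley.merge_distance", "valley.smooth_window",
                  "expansion.threshold_fraction", "expansion.smooth_window",
                  "expansion.window_extension",
                  "density.min_overlap", "density.density_unit",
                  "threshold.mod_a", "threshold.mod_m",
                  "threshold.filter_A", "threshold.filter_C",
                  "hor.body_bins", "hor.flank_bins", "hor.flank_bp",
                  "cdr.body_bins", "cdr.flank_bins", "cdr.flank_bp",
                  "profile.bin_size", "window.initial_start",
                  "window.initial_end", "window.flank"),
    value = c(vp$height_frac, vp$prom_frac, vp$merge_distance, vp$smooth_window,
              ep$threshold_fraction, ep$smooth_window, ep$window_extension,
              dp$min_overlap, dp$density_unit,
              ts$mod[["a"]], ts$mod[["m"]], ts$filter[["a"]], ts$filter[["m"]],
              hs$body_bins, hs$flank_bins, hs$flank_bp,
              cs$body_bins, cs$flank_bins, cs$flank_bp,
              1000, dw$start[dw$window == "initial"],
              dw$end[dw$window == "initial"],
              dw$start[dw$window == "initial"] - dw$start[dw$window == "left"])
  )
}
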