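#' Configuration for the synthetic centromere epigenome
#'
#' Defines one haplotype-resolved synthetic contig carrying an active
#' alpha-satellite HOR array with pericentromeric flanks, ground-truth CDRs
#' (5mCG dips co-occupied by CENP-A/CENP-C), a hypermethylated 5mCG
#' background, H3K9me3 across HOR and pericentromere with a dip at each CDR,
#' and nonspecific IgG background labeling. Modification sites sit on a
#' fixed lattice (one candidate site per `site_spacing` bp, approximating
#' nucleosome spacing). Per-site call probabilities follow a two-component
#' beta noise model (concentration `call_conc` around `call_mu_mod` for
#' truly modified sites and `call_mu_unmod` otherwise) so that probability
#' thresholding is meaningfully exercised.
#'
#' Genotypes emulate heterochromatin-mutant phenotypes as multiplicative
#' H3K9me3 erosion: `suv39_like` scales H3K9me3 globally (x0.3),
#' `setdb1_like` only within the HOR (x0.4) and `triple_like` scales the
#' HOR strongly (x0.05) and the pericentromere moderately (x0.3).
#'
#' @param seed Integer seed; a fixed seed gives identical bundles.
#' @param contig,contig_length Contig name and length (bp).
#' @param hor Active HOR interval, `c(start, end)` bp.
#' @param pericentromere_flank Pericentromere width on each side of the HOR, bp.
#' @param truth_cdrs Tibble of primary truth CDRs: `start`, `end`,
#'   `occupancy` (CENP-A site rate inside the CDR), `dip_level` (5mCG rate
#'   inside the CDR).
#' @param new_cdr Optional one-row tibble (`start`, `end`, `occupancy`,
#'   `dip_level`) for a distal newly formed CDR; must lie at least 500 kb
#'   from every primary CDR.
#' @param decoy_dips Tibble of sub-threshold 5mCG dips (`start`, `end`,
#'   `dip_level`) that a correct valley caller must not call.
#' @param bg_5mcg,nonhor_5mcg 5mCG rate inside the HOR / outside it.
#' @param h3k9me3_level,h3k9me3_dip,bg_h3k9me3 H3K9me3 rate over
#'   HOR+pericentromere, inside CDRs, and elsewhere.
#' @param cenpa_rate Default CENP-A in-domain 6mA site rate (used when a CDR
#'   row omits `occupancy`).
#' @param igg_rate Background 6mA site rate (IgG and off-target).
#' @param site_spacing Candidate-site lattice spacing, bp.
#' @param read_length_median,read_length_sdlog Lognormal read lengths, bp.
#' @param reads_per_target Molecules simulated per target.
#' @param read_focus Optional region tibble; reads are drawn to overlap it
#'   by at least `read_focus_overlap` bp (otherwise reads sample the HOR
#'   +/- pericentromere).
#' @param read_focus_overlap Guaranteed minimum overlap with `read_focus`, bp.
#' @param call_mu_mod,call_mu_unmod,call_conc Beta noise-model parameters.
#' @param genotype One of `"parental"`, `"suv39_like"`, `"setdb1_like"`,
#'   `"triple_like"`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       contig = "chr1_hap1", contig_length = 8e6,
                       hor = c(3e6, 5e6), pericentromere_flank = 1e6,
                       truth_cdrs = tibble::tibble(start = 3.80e6, end = 3.95e6,
                                                   occupancy = 0.05, dip_level = 0.10),
                       new_cdr = NULL,
                       decoy_dips = tibble::tibble(start = 4.5e6, end = 4.6e6,
                                                   dip_level = 0.60),
                       bg_5mcg = 0.80, nonhor_5mcg = 0.60,
                       h3k9me3_level = 0.30, h3k9me3_dip = 0.02, bg_h3k9me3 = 0.01,
                       cenpa_rate = 0.05, igg_rate = 0.005,
                       site_spacing = 200,
                       read_length_median = 50000, read_length_sdlog = 0.4,
                       reads_per_target = 150, read_focus = NULL,
                       read_focus_overlap = 10000,
                       call_mu_mod = 0.995, call_mu_unmod = 0.005, call_conc = 200,
                       genotype = c("parental", "suv39_like", "setdb1_like",
                                    "triple_like")) {
  genotype <- match.arg(genotype)
  stopifnot(contig_length > 0, hor[1] < hor[2], hor[1] >= 0,
            hor[2] <= contig_length, site_spacing >= 1,
            all(c(bg_5mcg, nonhor_5mcg, h3k9me3_level, h3k9me3_dip,
                  bg_h3k9me3, cenpa_rate, igg_rate) >= 0),
            all(c(bg_5mcg, nonhor_5mcg, h3k9me3_level) <= 1))
  if (!"occupancy" %in% names(truth_cdrs)) truth_cdrs$occupancy <- cenpa_rate
  all_cdrs <- truth_cdrs
  if (!is.null(new_cdr)) {
    gap <- min(abs(c(new_cdr$start - truth_cdrs$end, truth_cdrs$start - new_cdr$end)))
    if (gap < 500000) stop("new_cdr must be at least 500 kb from every primary CDR",
                           call. = FALSE)
    all_cdrs <- rbind(truth_cdrs[, c("start", "end", "occupancy", "dip_level")],
                      new_cdr[, c("start", "end", "occupancy", "dip_level")])
  }
  if (any(all_cdrs$start < hor[1]) || any(all_cdrs$end > hor[2])) {
    stop("truth CDRs must lie within the active HOR", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), contig = contig, contig_length = contig_length,
    hor = hor, pericentromere_flank = pericentromere_flank,
    truth_cdrs = truth_cdrs, new_cdr = new_cdr, decoy_dips = decoy_dips,
    bg_5mcg = bg_5mcg, nonhor_5mcg = nonhor_5mcg,
    h3k9me3_level = h3k9me3_level, h3k9me3_dip = h3k9me3_dip,
    bg_h3k9me3 = bg_h3k9me3, cenpa_rate = cenpa_rate, igg_rate = igg_rate,
    site_spacing = site_spacing,
    read_length_median = read_length_median, read_length_sdlog = read_length_sdlog,
    reads_per_target = reads_per_target, read_focus = read_focus,
    read_focus_overlap = read_focus_overlap,
    call_mu_mod = call_mu_mod, call_mu_unmod = call_mu_unmod, call_conc = call_conc,
    genotype = genotype
  ), class = "sim_config")
}

sim_targets <- c("cenpa", "cenpc", "h3k9me3", "igg", "mcg")

sim_mod_code <- function(target) if (target == "mcg") "m" else "a"

in_intervals <- function(pos, starts, ends) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_along(starts)) hit <- hit | (pos >= starts[i] & pos < ends[i])
  hit
}

# Per-site generating rate (probability a lattice site is truly modified)
# for one target under the configured genotype.
sim_rate_at <- function(config, target, pos) {
  hor <- config$hor
  peri_s <- c(hor[1] - config$pericentromere_flank, hor[2])
  peri_e <- c(hor[1], hor[2] + config$pericentromere_flank)
  cdrs <- config$truth_cdrs
  if (!is.null(config$new_cdr)) {
    cdrs <- rbind(cdrs[, c("start", "end", "occupancy", "dip_level")],
                  config$new_cdr[, c("start", "end", "occupancy", "dip_level")])
  }
  in_hor <- pos >= hor[1] & pos < hor[2]
  in_peri <- in_intervals(pos, peri_s, peri_e)
  r <- switch(target,
    mcg = {
      out <- ifelse(in_hor | in_peri, config$bg_5mcg, config$nonhor_5mcg)
      for (i in seq_len(nrow(cdrs))) {
        out[pos >= cdrs$start[i] & pos < cdrs$end[i]] <- cdrs$dip_level[i]
      }
      if (!is.null(config$decoy_dips)) {
        for (i in seq_len(nrow(config$decoy_dips))) {
          out[pos >= config$decoy_dips$start[i] & pos < config$decoy_dips$end[i]] <-
            config$decoy_dips$dip_level[i]
        }
      }
      out
    },
    h3k9me3 = {
      out <- ifelse(in_hor | in_peri, config$h3k9me3_level, config$bg_h3k9me3)
      out[in_intervals(pos, cdrs$start, cdrs$end)] <- config$h3k9me3_dip
      mult <- rep(1, length(pos))
      if (config$genotype == "suv39_like") mult[] <- 0.3
      if (config$genotype == "setdb1_like") mult[in_hor] <- 0.4
      if (config$genotype == "triple_like") {
        mult[in_peri] <- 0.3
        mult[in_hor] <- 0.05
      }
      out * mult
    },
    cenpa = ,
    cenpc = {
      out <- rep(config$igg_rate, length(pos))
      occ <- if (target == "cenpa") cdrs$occupancy else 0.8 * cdrs$occupancy
      for (i in seq_len(nrow(cdrs))) {
        out[pos >= cdrs$start[i] & pos < cdrs$end[i]] <- occ[i]
      }
      out
    },
    igg = rep(config$igg_rate, length(pos))
  )
  r
}

# Exact expected pileup fraction under the beta call-noise model and the
# default threshold scheme: valid calls are MODIFIED or CANONICAL, FILTERED
# calls drop out of both numerator and denominator.
sim_expected_fraction <- function(config, rate, mod_code,
                                  scheme = threshold_scheme()) {
  a_m <- config$call_conc * config$call_mu_mod
  b_m <- config$call_conc * (1 - config$call_mu_mod)
  a_u <- config$call_conc * config$call_mu_unmod
  b_u <- config$call_conc * (1 - config$call_mu_unmod)
  t_mod <- scheme$mod[[mod_code]]
  t_filt <- scheme$filter[[mod_code]]
  pMM <- stats::pbeta(t_mod, a_m, b_m, lower.tail = FALSE)
  pCM <- stats::pbeta(1 - t_filt, a_m, b_m)
  pMU <- stats::pbeta(t_mod, a_u, b_u, lower.tail = FALSE)
  pCU <- stats::pbeta(1 - t_filt, a_u, b_u)
  num <- rate * pMM + (1 - rate) * pMU
  den <- rate * (pMM + pCM) + (1 - rate) * (pMU + pCU)
  ifelse(den > 0, num / den, NA_real_)
}

#' Simulate a synthetic centromere epigenome bundle
#'
#' Deterministic given the config seed. Emits, per target (CENP-A, CENP-C,
#' H3K9me3, IgG, 5mCG):
#'
#' * `tracks` — [binned_track()]s over the whole contig at the site-lattice
#'   resolution, holding the *exact expectation* of the pileup fraction
#'   under the generative noise model (no sampling noise);
#' * `molecules` — simulated long reads (tibble compatible with
#'   [read_molecules()]) whose `mod_offsets` are the thresholded modified
#'   calls, as in single-molecule BED extracts;
#' * `calls` — per-site call probabilities (`chrom`, `pos`, `p_mod`,
#'   `state`) for every site on every read, feeding [classify_call()] and
#'   [pileup_molecules()];
#' * `truth` — ground-truth CDR intervals with status (`primary`/`new`),
#'   occupancy and dip levels, recorded before noise injection, plus the
#'   sub-threshold `decoys`;
#' * `hor`, `pericentromere` — annotation regions.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_bundle`.
#' @export
simulate_epigenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(2^30, length(sim_targets))
  names(sub_seeds) <- sim_targets

  lattice <- seq(0, config$contig_length - 1, by = config$site_spacing)
  tracks <- list()
  for (target in sim_targets) {
    rate <- sim_rate_at(config, target, lattice)
    vals <- sim_expected_fraction(config, rate, sim_mod_code(target))
    tracks[[target]] <- binned_track(vals, config$contig, config$site_spacing,
                                     origin = 0, fraction = TRUE)
  }

  molecules <- list()
  calls <- list()
  scheme <- threshold_scheme()
  sample_lo <- max(0, config$hor[1] - config$pericentromere_flank)
  sample_hi <- min(config$contig_length, config$hor[2] + config$pericentromere_flank)
  for (target in sim_targets) {
    set.seed(sub_seeds[[target]])
    n <- config$reads_per_target
    len <- pmin(pmax(round(stats::rlnorm(n, log(config$read_length_median),
                                         config$read_length_sdlog)), 5000),
                config$contig_length)
    if (!is.null(config$read_focus)) {
      req <- pmin(config$read_focus_overlap, len,
                  config$read_focus$end - config$read_focus$start)
      lo <- pmax(0, config$read_focus$start - len + req)
      hi <- pmax(lo, pmin(config$contig_length - len, config$read_focus$end - req))
    } else {
      lo <- rep(sample_lo, n)
      hi <- pmax(lo, pmin(config$contig_length - len, sample_hi - len))
    }
    start <- floor(lo + stats::runif(n) * pmax(hi - lo, 0))
    end <- start + len
    t_mod <- scheme$mod[[sim_mod_code(target)]]
    offs <- vector("list", n)
    call_rows <- vector("list", n)
    for (i in seq_len(n)) {
      first <- ceiling(start[i] / config$site_spacing) * config$site_spacing
      sites <- seq(first, end[i] - 1, by = config$site_spacing)
      if (!length(sites)) {
        offs[[i]] <- numeric(0)
        next
      }
      rate <- sim_rate_at(config, target, sites)
      state <- stats::runif(length(sites)) < rate
      mu <- ifelse(state, config$call_mu_mod, config$call_mu_unmod)
      p <- stats::rbeta(length(sites), config$call_conc * mu,
                        config$call_conc * (1 - mu))
      offs[[i]] <- sites[p >= t_mod] - start[i]
      call_rows[[i]] <- tibble::tibble(pos = sites, p_mod = p, state = state)
    }
    molecules[[target]] <- tibble::tibble(
      chrom = config$contig, start = start, end = end,
      read_id = sprintf("%s_read_%04d", target, seq_len(n)),
      n_mods = lengths(offs), mod_offsets = offs)
    cr <- do.call(rbind, call_rows[!vapply(call_rows, is.null, TRUE)])
    calls[[target]] <- tibble::tibble(chrom = config$contig, cr)
  }

  truth <- tibble::tibble(
    chrom = config$contig,
    config$truth_cdrs[, c("start", "end", "occupancy", "dip_level")],
    status = "primary")
  if (!is.null(config$new_cdr)) {
    truth <- rbind(truth, tibble::tibble(
      chrom = config$contig,
      config$new_cdr[, c("start", "end", "occupancy", "dip_level")],
      status = "new"))
  }
  peri <- tibble::tibble(
    chrom = config$contig,
    start = c(config$hor[1] - config$pericentromere_flank, config$hor[2]),
    end = c(config$hor[1], config$hor[2] + config$pericentromere_flank))

  structure(list(
    config = config,
    hor = genomic_region(config$contig, config$hor[1], config$hor[2]),
    pericentromere = peri,
    truth = truth,
    decoys = if (is.null(config$decoy_dips)) NULL else
      tibble::tibble(chrom = config$contig, config$decoy_dips),
    tracks = tracks, molecules = molecules, calls = calls
  ), class = "sim_bundle")
}

#' Simulate a clonal drift time course
#'
#' Each clone's CENP-A domain center performs a per-generation random walk
#' (`drift_sd_kb` per generation, mean zero) while the domain width is held
#' constant; alternatively `displacement_kb` programs a deterministic total
#' displacement per clone. Enrichment profiles are trapezoids (constant
#' `amplitude` with linear `edge_ramp` shoulders) sampled into 1-kb bins,
#' emulating counts-per-million CUT&RUN profiles of a drifting
#' neocentromere.
#'
#' @param n_clones Number of clones.
#' @param n_generations Random-walk steps per clone.
#' @param drift_sd_kb Per-generation center displacement s.d., kb.
#' @param displacement_kb Optional deterministic total displacement per
#'   clone, kb (recycled across clones); overrides the random walk.
#' @param region Profile region (default the 200-kb neocentromere analysis
#'   window on the neocentromere haplotype).
#' @param domain_center,domain_width Initial domain center and width, bp.
#' @param bin_size Profile bin size, bp.
#' @param amplitude Plateau enrichment value (above baseline).
#' @param baseline Background enrichment outside the domain (nonzero, as in
#'   library-normalized coverage tracks).
#' @param edge_ramp Linear shoulder width, bp.
#' @param seed Integer seed.
#' @return A list: `reference` [binned_track()], `clones` (named list of
#'   profiles), `truth` (tibble: `clone`, `center`, `true_shift_kb`).
#' @export
simulate_timecourse <- function(n_clones = 9, n_generations = 10,
                                drift_sd_kb = 5, displacement_kb = NULL,
                                region = genomic_region("chr4_hap2", 42.8e6, 43.0e6),
                                domain_center = 42913000, domain_width = 90000,
                                bin_size = 1000, amplitude = 10, baseline = 0.5,
                                edge_ramp = 5000, seed = 1) {
  set.seed(seed)
  profile_for <- function(center) {
    n_bins <- ceiling(region_width(region) / bin_size)
    mids <- region$start + (seq_len(n_bins) - 0.5) * bin_size
    half <- domain_width / 2
    d <- abs(mids - center)
    v <- baseline + pmax(0, pmin(1, (half - d) / edge_ramp)) * amplitude
    binned_track(v, region$chrom, bin_size, origin = region$start)
  }
  centers <- vapply(seq_len(n_clones), function(i) {
    if (!is.null(displacement_kb)) {
      domain_center + rep_len(displacement_kb, n_clones)[i] * 1000
    } else {
      domain_center + sum(stats::rnorm(n_generations, 0, drift_sd_kb * 1000))
    }
  }, 0)
  clones <- lapply(centers, profile_for)
  names(clones) <- sprintf("clone%d", seq_len(n_clones))
  list(reference = profile_for(domain_center),
       clones = clones,
       truth = tibble::tibble(clone = names(clones), center = centers,
                              true_shift_kb = (centers - domain_center) / 1000))
}
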