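# cendrift

Quantitative analysis of centromere chromatin domains from single-molecule
methylation data.

Human centromeres form on megabase arrays of hypermethylated alpha-satellite
higher-order repeats (HORs). The functional CENP-A/CENP-C domain occupies a
localized *centromere dip region* (CDR) — a valley in 5mCG (and H3K9me3)
within the array. Long-read, antibody-directed methylation profiling
(DiMeLo-seq style) records protein occupancy as exogenous 6mA and endogenous
5mCG on the same molecules, at haplotype resolution. `cendrift` turns those
per-position pileups and single-molecule records into the quantities used to
study centromere position, size and number:

* **CDR detection** — valleys in the smoothed 5mCG fraction f(x) over an
  active HOR are called where, relative to the regional median *m*,
  depth `m − f(x) ≥ 0.39 m` and topographic prominence `≥ 0.45 m`; valley
  edges are taken at half depth, calls within 500 kb merge into one
  centromere locus, and loci are classified `primary` / `new` (CENP-A
  supported, distal to the parent CDR) / `discarded`.
* **Seeded domain expansion** — CENP-A/CENP-C domain boundaries grow
  outward from the CDR midpoint over a 2-kb-smoothed signal until it falls
  below 1% of the in-CDR mean, within a ±30-kb window.
* **Per-molecule density** — 6mA sites per 10 kb of read/CDR overlap
  (minimum 10-kb overlap), with target/IgG enrichment per centromere.
* **Drift metrics** — signed peak-center shifts (signal-weighted centroid
  of the above-background peak run, 1-kb bins) between an early-passage
  reference and evolved clones; mean absolute shift; enrichment in the
  initial 90-kb locus window (42.868–42.958 Mb) and ±90-kb flanks,
  baseline 1.
* **Meta-region scaling** — length-normalized heat-map rows (HORs:
  500+1,000+500 bins with ±1-Mb flanks; CDRs: 125+200+125 bins with
  ±125-kb flanks), aggregate traces and inside/outside-CDR ratios.
* **Synthetic epigenome** — a seeded generator of annotations, expectation
  tracks and single molecules with recorded ground truth (including
  knockout-style H3K9me3 erosion, distal new-CDR seeding and clonal drift
  time courses), so the entire pipeline is testable without sequencing
  data.

## Worked example

Simulate a centromere with one primary CDR and one newly seeded distal CDR,
then run the survey pipeline:

```r
library(cendrift)
library(tibble)

cfg <- sim_config(seed = 7, reads_per_target = 60,
                  new_cdr = tibble(start = 4.6e6, end = 4.68e6,
                                   occupancy = 0.05, dip_level = 0.08))
bundle <- simulate_epigenome(cfg)
report <- run_centromere_survey(bundle)
report$loci[, c("chrom", "start", "end", "status")]
#> # A tibble: 2 × 4
#>   chrom       start     end status
#>   <chr>       <dbl>   <dbl> <chr>
#> 1 chr1_hap1 3800000 3950000 primary
#> 2 chr1_hap1 4599000 4680000 new
```

The truth CDRs were placed at 3.80–3.95 Mb and 4.60–4.68 Mb: the primary
locus is recovered at its exact boundaries and the distal CDR — more than
500 kb away and CENP-A-supported — is classified as newly formed. CENP-A
6mA density within the CDRs, normalized to the IgG control:

```r
report$enrichment[, c("cdr_id", "target_mean_density", "enrichment")]
#> # A tibble: 2 × 3
#>   cdr_id                    target_mean_density enrichment
#>   <chr>                                   <dbl>      <dbl>
#> 1 chr1_hap1:3800000-3950000                3.25       13.2
#> 2 chr1_hap1:4599000-4680000                1.92       13.0
```

(3.25 sites per 10 kb ≈ the programmed 0.05 occupancy on a 200-bp site
lattice; 13-fold over IgG.) A drift time course with a 3-kb-per-generation
random walk of the domain center:

```r
tc <- simulate_timecourse(n_clones = 3, drift_sd_kb = 3, seed = 7)
drift <- run_drift_analysis(tc$reference, tc$clones)
drift$shifts$shift_kb
#> [1]  3 23  9
drift$mean_abs_shift_kb
#> [1] 11.66667
```

The recovered per-clone shifts (3, 23, 9 kb) match the generator's true
centroid displacements (3.1, 23.5, 9.0 kb) to within one 1-kb bin.

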