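---
title: "Methods: detecting and quantifying centromere chromatin domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying centromere chromatin domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cendrift)
library(tibble)
```

## The biological signal model

Human centromeres assemble on megabase-scale arrays of alpha-satellite
higher-order repeats (HORs). Within an otherwise hypermethylated array, the
functional centromere — the CENP-A/CENP-C chromatin domain — sits in a
localized dip of CpG methylation, the *centromere dip region* (CDR), and in
a matching dip of the heterochromatin mark H3K9me3. Antibody-directed
methyltransferase labeling (DiMeLo-seq) records a protein's binding
footprint as exogenous 6mA on the same long reads that carry endogenous
5mCG, so a single molecule reports both protein occupancy and DNA
methylation at haplotype resolution.

`cendrift` operates entirely downstream of basecalling and alignment. Its
inputs are the standard text artifacts of that workflow: per-position
fraction-modified pileups (bedmethyl dialect), single-molecule modification
records (12-column BED with block fields encoding per-read 6mA/CpG sites),
interval annotations (BED) and binned coverage profiles (bedGraph).

## Coordinate, track and missing-data conventions

All coordinates are 0-based half-open (BED convention). Strand is ignored:
fraction-modified and density quantities are strand-collapsed. A
`binned_track` stores per-bin means; a bin with no underlying data is an
explicit `NA`, never zero, and every mean in the package skips `NA`. This
matters for fraction tracks over repetitive DNA, where mapping gaps are
common and coercing them to zero would fabricate artificial valleys.

The column-11 dialect of pileup files is configurable (`percent`, the
default, divides by 100; `fraction` takes values as-is) because emitters
disagree about the scale of the "fraction modified" column.

## Modification calling

Per-base modification probabilities are trichotomized by
`classify_call()`: confidently modified (probability at or above the
modified-call threshold: 0.98 for 6mA, 0.8 for 5mCG), confidently canonical
(canonical probability at or above 0.8), or filtered. Filtered calls drop
out of both the numerator and the denominator of the pileup fraction — the
only reading under which "fraction modified" is a fraction of *passing*
calls. The ambiguous middle band maps to filtered rather than canonical,
matching the purpose of the filter thresholds. `ml_from_prob()` provides
the standard 256-bin integer encoding (`floor(p * 256)`, capped at 255) for
interoperability with single-molecule extract tools; the default thresholds
encode to 250 and 204.

## CDR detection as valley calling

`detect_valleys()` works on a fraction-modified 5mCG track restricted to an
active HOR:

1. smooth with a centered rolling mean (default window 5 kb; edge bins use
   shrinking windows);
2. find local minima of the smoothed trace (a flat minimum reports its
   middle bin);
3. keep a minimum when its depth below the regional median reaches
   `height_frac` × median (default 0.39) **and** its topographic prominence
   reaches `prom_frac` × median (default 0.45);
4. define the valley extent as the maximal interval around the minimum
   where the smoothed trace stays below `median − depth/2`.

Both thresholds are interpreted as fractions of the regional median signal.
The half-depth edge rule is this package's deterministic stand-in for what
is otherwise a manually curated boundary decision: it needs no tuning, is
monotone in the thresholds (raising either never adds a valley) and, on
rectangular dips, lands within one smoothing window of the true edge. When
two candidate minima claim overlapping extents the deeper valley wins, so
returned calls are disjoint and sorted.

Valleys within 500 kb merge into one centromere locus
(`merge_into_loci()`; the merge is a transitive closure, idempotent, and
degenerates to singleton loci at merge distance 0). `classify_loci()` then
replaces manual curation with three deterministic rules: a locus
overlapping — or, under the default rule, within the merge distance of — a
parent primary CDR is `primary`; otherwise a locus intersecting a CENP-A
domain is `new` (a newly formed CDR); loci with no CENP-A support are
`discarded`. Whether "absent from the parent database" should be judged by
overlap alone or by the distance rule is genuinely ambiguous, so both are
exposed (`rule = "overlap_or_distance"` / `"overlap_only"`).

Size reports (`cdr_size_change()`) sum primary CDR lengths per centromere
and compare them with the parent sample as a ratio; four centromeres are
excluded by default (the neocentromere-bearing haplotype, an X haplotype
absent from the assembly, and the two chromosome-18 haplotypes whose CDRs
are poorly defined).

## Seeded domain expansion

`call_domain()` calls a CENP-A or CENP-C domain from a CDR seed. The
threshold is 1% of the mean signal within the CDR — implemented literally.
That threshold is permissive by construction: over a nonzero background the
30-kb window extension, not the threshold, is what bounds the call, and the
`truncated_left`/`truncated_right` flags make this visible. The signal over
`CDR ± 30 kb` is smoothed with a 2-kb centered rolling average (tracks are
expected at ~100-bp resolution; edge bins shrink) and expansion proceeds
outward from the CDR-midpoint bin while the smoothed signal stays at or
above threshold. Expansion is contiguous — one sub-threshold bin terminates
a side — which makes the result identical to the maximal above-threshold
run containing the midpoint; the test suite exploits this by checking the
expansion against an exhaustive run-enumeration oracle on a thousand random
tracks. Whether the 1% refers to the mean fraction modified or to a
coverage-normalized signal is not determinable from the method's
description; the fraction reading is used. If the midpoint bin itself is
below threshold the call is returned as a zero-width, `degenerate`-flagged
record with a warning rather than a hard error, so a survey over many
centromeres can proceed and report the degenerate seeds.

## Per-molecule density and IgG normalization

`per_read_density()` scores each read against each CDR interval it
overlaps by at least 10 kb (half-open intersection; a site exactly at the
CDR end coordinate is outside) and reports 6mA sites per 10 kb of
overlapping sequence — a depth-free, per-molecule quantity. Contigs on the
exclusion list contribute nothing. `mod_enrichment()` divides mean target
density by mean IgG density per CDR (the "corresponding control" reading);
a pooled mode exists but is not the default, since matching target and
control within each centromere controls for regional accessibility. A zero
or missing control mean yields an explicit `undefined` flag, never a
silent infinity.

## Drift metrics

Enrichment profiles are compared in 1-kb bins over a fixed region (default
42.8–43.0 Mb on the neocentromere haplotype). No standard definition of
"peak center" exists for such profiles, so the package commits to one and
exposes it: the background level is 10% of the profile maximum; the peak
domain is the maximal contiguous above-background run containing the global
maximum; the center is the signal-weighted centroid of that run, snapped to
the midpoint of its bin. A `midpoint`-of-domain alternative is provided for
sensitivity checks. The centroid definition is translation-equivariant and
invariant under global rescaling — the two properties a drift statistic
must have under library-size normalization.

Per-clone shifts are signed (positive toward increasing coordinate);
the summary is the mean *absolute* shift, because domain drift occurs in
either direction and a signed mean would cancel. `window_enrichment()`
compares summed signal in the initial 90-kb locus window
(42,868,000–42,958,000) and its ±90-kb flanks against an early-passage
control, so the control against itself is a baseline of exactly 1.

## Meta-region scaling

`scale_region()` resamples a track into a fixed-length row: the body into
`body_bins` equal sub-intervals, each flank of `flank_bp` into
`flank_bins`. Two presets reproduce the published heat-map geometries —
active HORs at 500 + 1,000 + 500 = 2,000 bins with ±1-Mb flanks, CDRs at
125 + 200 + 125 = 450 bins with ±125-kb flanks. Sub-bin boundaries are
computed in real arithmetic and rounded half-up to integer bp, which
guarantees a gap-free, overlap-free partition; each output value is the
coverage-weighted mean of the track over its sub-interval (mean, not sum,
so constant tracks map to constant rows and affine transforms commute with
scaling). Heat-map rows are sorted numerically by chromosome then
haplotype. Aggregate traces use 100 bins across a centered window; for
CDR-midpoint aggregates the window is ±250 kb (the figure-style preset)
while CDR heat maps keep the ±125-kb scheme — the two conventions differ at
the source and both are honored rather than reconciled. Boundary-centered
aggregates mirror the right-boundary trace so "inside the CDR" is always
plotted on the left. `inside_outside_ratio()` divides the mean signal
within a CDR by the pooled mean over its ±100-kb flanks; 1 means equal
enrichment inside and out.

## The synthetic epigenome

`simulate_epigenome()` exists so that every stage above can be tested
against recorded ground truth without sequencing data. Its default
geometry — chosen once, for realism at a size where the full test suite
runs in seconds — is a single 8-Mb contig with a 2-Mb active HOR flanked by
1-Mb pericentromeres, one 150-kb primary CDR (5mCG dip to 0.10 on a 0.80
hypermethylated background; CENP-A site rate 0.05 against an IgG background
of 0.005), and one shallow decoy dip (to 0.60) that a correct valley caller
must ignore because its depth is below the 0.39 criterion. H3K9me3 sits at
0.30 across HOR and pericentromere with a dip to 0.02 at the CDR; no
quantitative occupancy for centromeric H3K9me3 is available, so these are
detectability-motivated placeholders, not biological estimates. Genotype
settings erode H3K9me3 multiplicatively: globally (×0.3,
`suv39_like`), HOR-restricted (×0.4, `setdb1_like`), or strongly in the
HOR with moderate pericentromeric loss (×0.05 / ×0.3, `triple_like`) —
the compartment structure, not the magnitudes, is the modeled phenotype.

Candidate modification sites sit on a 200-bp lattice, approximating
nucleosome spacing (centromere occupancy is naturally reasoned about in
nucleosome counts, on the order of a hundred CENP-A nucleosomes in a
~100-kb domain, i.e. roughly one in five nucleosome positions). Each
molecule samples a lognormal length (median 50 kb) and a start, then
per-site modification probabilities from a two-component beta model
(concentration 200 around 0.995 for modified sites and 0.005 otherwise),
so the thresholding of `classify_call()` is exercised with realistic
near-0/near-1 probability mass. Emitted fraction tracks are the *exact
expectation* of the thresholded pileup under this model (computed with
beta tail probabilities), which makes track-level tests deterministic
while molecule-level tests remain stochastic with known binomial error.
All randomness flows from one seed through per-target sub-streams, so a
fixed seed reproduces the bundle exactly.

`simulate_timecourse()` models clonal domain drift: each clone's domain
center performs a mean-zero random walk (or a programmed deterministic
displacement) while the width is held constant; profiles are trapezoids
with 5-kb shoulders on a nonzero baseline, sampled into 1-kb bins, so peak
centers are well-defined and flank windows have control signal.

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real data: alpha-satellite sequence content and
mappability artifacts, read-level basecalling error structure, coverage
heterogeneity, inter-centromere variability in CDR shape, and any coupling
between 5mCG loss and CENP-A gain beyond their programmed co-location.
Recovery guarantees on rectangular-dip truth (boundary error within twice
the smoothing window) should be read as algorithmic correctness checks,
not as accuracy claims for biological boundary calls, which in real data
have gradual shoulders and required curation in the source workflow.

## Numerical choices and degenerate inputs

* Rolling means shrink at the edges (mean over available bins) and skip
  `NA`; an all-`NA` window is `NA`.
* Smoothing windows in bp convert to bins by rounding, with a floor of one
  bin.
* Valley prominence follows the standard topographic definition applied to
  the inverted trace; missing bins are treated as the regional median, so
  they can neither seed nor bound a valley.
* `bin_track` with bin size 1 is the identity on covered positions;
  all-missing tracks raise a no-data error in `detect_valleys`.
* Ratios never silently divide by zero: zero denominators yield `NA` plus
  an `undefined` flag (density enrichment, window enrichment,
  inside/outside ratio) or a named error (parent CDR total of zero).
* Sub-bin edges round half-up (`floor(x + 0.5)`), making partitions exact
  for any region length and bin count.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use the default 8-Mb contig
(40,000 lattice sites), tens to a few hundred molecules per target, 1,000
random tracks for the expansion-oracle comparison, 9 clones for null-drift
checks and 500 reads per group for the density null — sizes chosen so the
entire suite completes in well under two minutes on one CPU while leaving
every statistical check with comfortable power.
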