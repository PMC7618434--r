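# A 2-Mb HOR-like track at 1-kb bins: hypermethylated background with
# rectangular dips.
dip_track <- function(dips, background = 0.8, bin_size = 1000,
                      origin = 3e6, n_bins = 2000) {
  v <- rep(background, n_bins)
  for (d in dips) {
    lo <- (d$start - origin) / bin_size + 1
    hi <- (d$end - origin) / bin_size
    v[lo:hi] <- d$level
  }
  binned_track(v, "chr1_hap1", bin_size, origin = origin, fraction = TRUE)
}

test_that("a deep rectangular dip yields one valley at the true boundaries", {
  truth <- list(start = 3.5e6, end = 3.6e6, level = 0.1)
  calls <- detect_valleys(dip_track(list(truth)))
  expect_equal(nrow(calls), 1)
  sw <- valley_params()$smooth_window
  expect_lt(abs(calls$start - truth$start), sw + 1)
  expect_lt(abs(calls$end - truth$end), sw + 1)
  expect_gt(calls$depth, 0.39 * 0.8)
  expect_true(calls$min_pos >= calls$start && calls$min_pos < calls$end)
})

test_that("constant and sub-threshold tracks yield no valleys", {
  flat <- binned_track(rep(0.8, 2000), "chr1_hap1", 1000, 3e6)
  expect_equal(nrow(detect_valleys(flat)), 0)
  # depth 0.2 < 0.39 * 0.8 = 0.312
  shallow <- dip_track(list(list(start = 3.5e6, end = 3.6e6, level = 0.6)))
  expect_equal(nrow(detect_valleys(shallow)), 0)
  expect_error(detect_valleys(binned_track(rep(NA_real_, 10), "c", 1000)),
               "no data")
})

test_that("valley calls are disjoint and shrink as thresholds rise", {
  dips <- list(list(start = 3.2e6, end = 3.3e6, level = 0.05),
               list(start = 3.6e6, end = 3.65e6, level = 0.35),
               list(start = 4.3e6, end = 4.45e6, level = 0.15))
  tr <- dip_track(dips)
  base <- detect_valleys(tr)
  expect_true(all(base$end[-nrow(base)] <= base$start[-1]))
  for (hf in c(0.5, 0.7, 0.9)) {
    tighter <- detect_valleys(tr, valley_params(height_frac = hf))
    expect_lte(nrow(tighter), nrow(base))
    for (i in seq_len(nrow(tighter))) {
      expect_true(any(abs(tighter$min_pos[i] - base$min_pos) < 1))
    }
  }
  stricter_prom <- detect_valleys(tr, valley_params(prom_frac = 0.95))
  expect_lte(nrow(stricter_prom), nrow(base))
})

test_that("loci merge under the 500-kb rule and merging is idempotent", {
  near <- tibble::tibble(chrom = "chr1_hap1",
                         start = c(3.0e6, 3.4e6), end = c(3.1e6, 3.5e6))
  expect_equal(nrow(merge_into_loci(near)), 1)          # 300-kb gap
  far <- tibble::tibble(chrom = "chr1_hap1",
                        start = c(3.0e6, 3.7e6), end = c(3.1e6, 3.8e6))
  expect_equal(nrow(merge_into_loci(far)), 2)           # 600-kb gap
  once <- merge_into_loci(near)
  twice <- merge_into_loci(once[, c("chrom", "start", "end")])
  expect_equal(twice[, c("chrom", "start", "end")],
               once[, c("chrom", "start", "end")])
  # zero merge distance: singleton loci, order-independent
  shuffled <- near[c(2, 1), ]
  expect_equal(nrow(merge_into_loci(shuffled, 0)), 2)
  expect_equal(merge_into_loci(shuffled)$start, merge_into_loci(near)$start)
})

test_that("loci classify as primary, new or discarded", {
  loci <- merge_into_loci(tibble::tibble(
    chrom = "chr1_hap1",
    start = c(3.0e6, 6.2e6, 7.5e6), end = c(3.1e6, 6.3e6, 7.6e6)))
  parent <- tibble::tibble(chrom = "chr1_hap1", start = 3.05e6, end = 3.2e6)
  cenpa <- tibble::tibble(chrom = "chr1_hap1", start = 6.21e6, end = 6.29e6)
  out <- classify_loci(loci, parent, cenpa)
  expect_equal(out$status, c("primary", "new", "discarded"))
  # distance-only slack: a locus 400 kb from the parent is still primary
  near <- merge_into_loci(tibble::tibble(chrom = "chr1_hap1",
                                         start = 3.6e6, end = 3.7e6))
  expect_equal(classify_loci(near, parent, cenpa)$status, "primary")
  expect_equal(classify_loci(near, parent, cenpa, rule = "overlap_only")$status,
               "discarded")
})

test_that("CDR size report compares summed lengths per centromere", {
  parent <- tibble::tibble(centromere = c("cen1_hap1", "cen2_hap1", "cen18_hap1"),
                           start = c(0, 0, 0), end = c(100e3, 200e3, 50e3))
  sample <- tibble::tibble(centromere = c("cen1_hap1", "cen2_hap1", "cen18_hap1"),
                           start = c(0, 0, 0), end = c(150e3, 200e3, 500e3))
  rep <- cdr_size_change(sample, parent)
  expect_false("cen18_hap1" %in% rep$per_centromere$centromere)
  expect_equal(rep$per_centromere$ratio, c(1.5, 1.0))
  expect_equal(rep$mean_percent_change, 25)
  self <- cdr_size_change(parent, parent)
  expect_equal(self$mean_percent_change, 0)
  zero_parent <- tibble::tibble(centromere = "cen5_hap1", start = 0, end = 0)
  expect_error(cdr_size_change(zero_parent, zero_parent), "undefined ratio")
})
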