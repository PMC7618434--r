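test_that("scaling presets give the published row lengths", {
  hs <- hor_scheme(); cs <- cdr_scheme()
  expect_equal(hs$body_bins + 2 * hs$flank_bins, 2000)
  expect_equal(cs$body_bins + 2 * cs$flank_bins, 450)
  tr <- binned_track(rep(0.5, 5000), "chr1_hap1", 1000, origin = 0)
  row <- scale_region(tr, genomic_region("chr1_hap1", 2.2e6, 2.8e6), hs)
  expect_equal(length(row), 2000)
  expect_equal(length(scale_region(tr, genomic_region("chr1_hap1", 2.2e6, 2.4e6), cs)),
               450)
})

test_that("constant tracks map to constant rows and ramps stay monotone", {
  tr <- binned_track(rep(0.5, 4000), "chr1_hap1", 1000, origin = 0)
  row <- scale_region(tr, genomic_region("chr1_hap1", 1.5e6, 2.5e6), hor_scheme())
  expect_true(all(row == 0.5))

  ramp <- binned_track(seq(0, 1, length.out = 1000), "chr1_hap1", 100, origin = 0)
  body <- scale_region(ramp, genomic_region("chr1_hap1", 0, 1e5),
                       scaling_scheme(50, 0, 0))
  expect_true(all(diff(body) > 0))
  expect_lt(body[1], 1 / 50)
  expect_gt(body[50], 1 - 1 / 50)
})

test_that("scale_region commutes with affine transforms of the signal", {
  set.seed(3)
  vals <- runif(800)
  tr <- binned_track(vals, "chr2_hap1", 250, origin = 1e5)
  region <- genomic_region("chr2_hap1", 1.4e5, 2.3e5)
  scheme <- scaling_scheme(37, 20000, 11)
  base <- scale_region(tr, region, scheme)
  aff <- scale_region(binned_track(3 * vals + 2, "chr2_hap1", 250, 1e5),
                      region, scheme)
  expect_equal(aff, 3 * base + 2, tolerance = 1e-12)
})

test_that("heat-map rows are numerically sorted and missing rows retained", {
  regions <- tibble::tibble(
    chrom = c("chr10_hap1", "chr2_hap1", "chr1_hap2", "chr1_hap1"),
    start = 1e6, end = 1.2e6,
    label = chrom)
  tracks <- list(
    chr1_hap1 = binned_track(rep(0.1, 4000), "chr1_hap1", 1000),
    chr1_hap2 = binned_track(rep(0.2, 4000), "chr1_hap2", 1000),
    chr2_hap1 = binned_track(rep(0.3, 4000), "chr2_hap1", 1000))
  m <- build_heatmap(tracks, regions, cdr_scheme())
  expect_equal(dim(m), c(4, 450))
  expect_equal(rownames(m), c("chr1_hap1", "chr1_hap2", "chr2_hap1", "chr10_hap1"))
  expect_true(all(is.na(m["chr10_hap1", ])))
  expect_equal(unname(m["chr1_hap2", 200]), 0.2)
  # input order is irrelevant
  m2 <- build_heatmap(tracks, regions[c(3, 1, 4, 2), ], cdr_scheme())
  expect_identical(m, m2)
  dup <- regions; dup$label <- "same"
  expect_error(build_heatmap(tracks, dup, cdr_scheme()), "duplicate")
})

test_that("aggregate profiles average centered windows", {
  set.seed(9)
  v <- runif(3000)
  tr <- binned_track(v, "chr3_hap1", 200, origin = 0)
  one <- tibble::tibble(chrom = "chr3_hap1", start = 290000, end = 310000)
  agg1 <- aggregate_profile(tr, one, flank_bp = 50000, n_bins = 40)
  expect_equal(agg1$mean,
               scale_region(tr, genomic_region("chr3_hap1", 250000, 350000),
                            scaling_scheme(40, 0, 0)))
  # k identical centers equal the single-center trace
  three <- one[rep(1, 3), ]
  agg3 <- aggregate_profile(tr, three, flank_bp = 50000, n_bins = 40)
  expect_equal(agg3$mean, agg1$mean)
  expect_equal(unname(agg3$n), rep(3, 40))
  # two mirror-image regions give a symmetric aggregate
  w <- c(seq(0, 1, length.out = 250), rep(0, 2500), seq(1, 0, length.out = 250))
  trm <- binned_track(w, "chr3_hap1", 200, origin = 0)
  two <- tibble::tibble(chrom = "chr3_hap1",
                        start = c(20000, 560000), end = c(30000, 580000))
  aggm <- aggregate_profile(trm, tibble::tibble(chrom = "chr3_hap1",
                                                pos = c(25000, 575000)),
                            flank_bp = 25000, n_bins = 50)
  expect_equal(aggm$mean, rev(aggm$mean), tolerance = 1e-9)
})

test_that("boundary-centered aggregation crosses at the boundary bin", {
  # step track: high outside the CDR, low inside [400k, 500k)
  v <- rep(0.8, 3000)
  pos <- (seq_len(3000) - 0.5) * 200
  v[pos > 400000 & pos < 500000] <- 0.1
  tr <- binned_track(v, "chr5_hap1", 200, origin = 0)
  cdr <- tibble::tibble(chrom = "chr5_hap1", start = 400000, end = 500000)
  agg <- aggregate_profile(tr, cdr, flank_bp = 50000, n_bins = 50,
                           center = "boundary")
  # inside (low) on the left half, outside (high) on the right half
  expect_lt(mean(agg$mean[1:20]), 0.2)
  expect_gt(mean(agg$mean[31:50]), 0.7)
  expect_true(all(diff(agg$mean) >= -1e-9))
})

test_that("inside/outside CDR ratio behaves at its reference points", {
  flat <- binned_track(rep(0.4, 3000), "chr6_hap1", 200, origin = 0)
  cdr <- genomic_region("chr6_hap1", 300000, 400000)
  expect_equal(inside_outside_ratio(flat, cdr)$ratio, 1.0)

  v <- rep(0.1, 3000)
  pos <- (seq_len(3000) - 0.5) * 200
  v[pos > 300000 & pos < 400000] <- 0.2
  half <- binned_track(v, "chr6_hap1", 200, origin = 0)
  expect_equal(inside_outside_ratio(half, cdr)$ratio, 2.0)

  v0 <- v; v0[!(pos > 300000 & pos < 400000)] <- 0
  zero_flank <- binned_track(v0, "chr6_hap1", 200, origin = 0)
  res <- inside_outside_ratio(zero_flank, cdr)
  expect_true(res$undefined)
  expect_true(is.na(res$ratio))
})
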