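test_that("read_pileup applies the column-11 dialect and sorts records", {
  path <- write_tsv_lines(c(
    pileup_line("chr1_hap1", 200, "0.00"),
    pileup_line("chr1_hap1", 100, "45.00")
  ))
  rec <- read_pileup(path, mod_code = "m", dialect = "percent")
  expect_equal(rec$start, c(100, 200))
  expect_equal(rec$frac_modified, c(0.45, 0))

  rec_f <- read_pileup(write_tsv_lines(pileup_line("chr1_hap1", 100, "0.45")),
                       mod_code = "m", dialect = "fraction")
  expect_equal(rec_f$frac_modified, 0.45)
})

test_that("read_pileup handles empty, malformed and out-of-range input", {
  expect_equal(nrow(read_pileup(write_tsv_lines(character(0)))), 0)
  expect_error(read_pileup(write_tsv_lines("chr1\t1\t2")), "line 1")
  expect_error(read_pileup(write_tsv_lines(pileup_line("chr1", 5, "145.0"))),
               "range error")
  expect_error(read_pileup(write_tsv_lines(pileup_line("chr1", 5, "0.45")),
                           dialect = "fraction"), NA)
  expect_error(read_pileup(write_tsv_lines(pileup_line("chr1", 5, "1.45")),
                           dialect = "fraction"), "range error")
})

test_that("read_pileup accepts gzip-compressed files", {
  path <- tempfile(fileext = ".gz")
  con <- gzfile(path, "w")
  writeLines(pileup_line("chr1_hap1", 100, "45.00"), con)
  close(con)
  expect_equal(read_pileup(path)$frac_modified, 0.45)
})

test_that("read_molecules decodes block fields into absolute mod positions", {
  line <- paste("chr1_hap1", 1000, 1500, "read1", 0, ".", 1000, 1500,
                "0,0,0", 3, "1,1,1", "0,100,200", sep = "\t")
  mol <- read_molecules(write_tsv_lines(line))
  expect_equal(mol$mod_offsets[[1]], c(0, 100, 200))
  expect_equal(mol$start + mol$mod_offsets[[1]], c(1000, 1100, 1200))

  none <- paste("chr1_hap1", 1000, 1500, "read2", 0, ".", 1000, 1500,
                "0,0,0", 0, ".", ".", sep = "\t")
  expect_equal(read_molecules(write_tsv_lines(none))$mod_offsets[[1]], numeric(0))
})

test_that("read_molecules rejects inconsistent block fields", {
  bad_count <- paste("chr1", 1000, 1500, "r", 0, ".", 1000, 1500,
                     "0,0,0", 2, "1,1,1", "0,100,200", sep = "\t")
  expect_error(read_molecules(write_tsv_lines(bad_count)), "consistency")
  bad_span <- paste("chr1", 1000, 1500, "r", 0, ".", 1000, 1500,
                    "0,0,0", 1, "1", "600", sep = "\t")
  expect_error(read_molecules(write_tsv_lines(bad_span)), "coordinate")
})

test_that("molecule records survive a write/read round trip byte-for-byte", {
  mol <- tibble::tibble(chrom = "chr1_hap1", start = 1000, end = 31000,
                        read_id = "r1", n_mods = 3L,
                        mod_offsets = list(c(0, 150, 29999)))
  p1 <- tempfile(); p2 <- tempfile()
  write_molecules(mol, p1)
  back <- read_molecules(p1)
  expect_equal(back$mod_offsets[[1]], mol$mod_offsets[[1]])
  write_molecules(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("bin_track averages covered positions and marks empty bins missing", {
  region <- genomic_region("chr1", 0, 6)
  pile <- tibble::tibble(chrom = "chr1", start = c(0, 1), end = c(1, 2),
                         mod_code = "m", n_valid = 10,
                         frac_modified = c(0.2, 0.4))
  tr <- bin_track(pile, region, 2)
  expect_equal(tr$values, c(0.3, NA, NA))

  per_base <- c(0.2, 0.4, NA, NA, 0.5, 0.7)
  expect_equal(bin_track(per_base, region, 1)$values, per_base)
  expect_equal(length(bin_track(per_base[1:5], genomic_region("chr1", 0, 5), 2)$values), 3)
})

test_that("bin_track on a constant input returns that constant in covered bins", {
  region <- genomic_region("chr1", 100, 1100)
  tr <- bin_track(rep(0.62, 1000), region, 64)
  expect_true(all(tr$values == 0.62))
  expect_equal(length(tr$values), ceiling(1000 / 64))
})

test_that("bedGraph output omits missing bins and round-trips to 1e-6", {
  tr <- binned_track(c(0.1, NA, 0.333333, 0.9), "chr1", 100, origin = 5000)
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  expect_equal(length(readLines(path)), 3)
  back <- bedgraph_to_track(read_bedgraph(path), track_region(tr), 100)
  expect_true(is.na(back$values[2]))
  expect_equal(back$values[-2], tr$values[-2], tolerance = 1e-6)
})

test_that("subset_track and track_mean respect bin alignment", {
  tr <- binned_track(1:10 / 10, "chr1", 100, origin = 1000)
  sub <- subset_track(tr, genomic_region("chr1", 1250, 1550))
  expect_equal(sub$origin, 1200)
  expect_equal(sub$values, c(0.3, 0.4, 0.5, 0.6))
  expect_error(subset_track(tr, genomic_region("chr2", 1250, 1550)), "contig")
})
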