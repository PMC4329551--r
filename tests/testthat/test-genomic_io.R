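test_that("read_bed parses, validates and reports line numbers", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t120\tCTCF", f)
  df <- read_bed(f)
  expect_equal(nrow(df), 1)
  expect_equal(df$end - df$start, 20)
  expect_equal(site_positions(df), 110)
  expect_equal(df$tf_id, "CTCF")

  writeLines(character(0), f)
  expect_equal(nrow(read_bed(f)), 0)

  writeLines("chr1\t50\t50", f)
  expect_error(read_bed(f), "line 1")

  writeLines(c("chr1\t1\t2\tA", "chr1\tx\t5\tB"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("BED round-trips preserve intervals exactly", {
  f <- withr::local_tempfile(fileext = ".bed")
  df <- sites_df(c(100L, 5000L, 20000L), tf = c("A", "B", "C"))
  write_bed(df, f)
  back <- read_bed(f)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$tf_id, df$tf_id)
})

test_that("signal tracks sum overlaps and read missing bases as 0", {
  tr <- signal_track(data.frame(chrom = "chr1", start = 0, end = 10), 2.0)
  expect_equal(track_values(tr, "chr1", 0, 10), rep(2, 10))
  expect_equal(track_total(tr), 20)

  tr2 <- signal_track(data.frame(chrom = c("chr1", "chr1"),
                                 start = c(0, 0), end = c(10, 10)),
                      c(1, 1))
  expect_equal(track_values(tr2, "chr1", 0, 10), rep(2, 10))

  expect_equal(track_values(tr, "chr1", 50, 55), rep(0, 5))
  expect_equal(track_values(tr, "chrX", 0, 5), rep(0, 5))
})

test_that("bedGraph and wig parsing agree with manual construction", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t10\t2.0", "chr1\t5\t15\t1.0"), f)
  tr <- read_signal_track(f)
  expect_equal(track_values(tr, "chr1", 0, 15),
               c(rep(2, 5), rep(3, 5), rep(1, 5)))

  w <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr2 start=11 step=5 span=5",
               "1.5", "2.5"), w)
  tw <- read_signal_track(w)
  expect_equal(track_values(tw, "chr2", 10, 20), c(rep(1.5, 5), rep(2.5, 5)))

  writeLines(c("variableStep chrom=chr3 span=2", "101\t7"), w)
  tv <- read_signal_track(w)
  expect_equal(track_values(tv, "chr3", 100, 102), c(7, 7))

  writeLines(c("fixedStep chrom=chr2 start=1 step=-5", "1"), w)
  expect_error(read_signal_track(w), "step")
  writeLines(c("fixedStep chrom=chr2 start=1 step=5 span=0", "1"), w)
  expect_error(read_signal_track(w), "span")
})

test_that("bedGraph write/read round-trips a track", {
  tr <- signal_track(data.frame(chrom = c("chr1", "chr1"),
                                start = c(0, 20), end = c(10, 25)),
                     c(2, 0.5))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_signal_track(f)
  expect_equal(track_values(back, "chr1", 0, 25),
               track_values(tr, "chr1", 0, 25))
})

test_that("merge_intervals takes unions with half-open adjacency", {
  df <- data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 20))
  expect_equal(merge_intervals(df),
               data.frame(chrom = "chr1", start = 0, end = 20))
  # abutting merge
  ab <- data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 20))
  expect_equal(merge_intervals(ab)$end, 20)
  # disjoint unchanged
  dj <- data.frame(chrom = "chr1", start = c(0, 10), end = c(5, 15))
  expect_equal(nrow(merge_intervals(dj)), 2)
})

test_that("merge_intervals is idempotent and never grows total width", {
  set.seed(42)
  for (i in 1:20) {
    df <- data.frame(chrom = sample(c("c1", "c2"), 30, TRUE),
                     start = sample(0:500, 30))
    df$end <- df$start + sample(1:80, 30, TRUE)
    m <- merge_intervals(df)
    expect_identical(merge_intervals(m), m)
    expect_lte(sum(m$end - m$start), sum(df$end - df$start))
  }
})

test_that("gene annotation extracts strand-aware TSS and introns", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "t", "gene", "1001", "2000", ".", "+", ".",
          'gene_id "g1";', sep = "\t"),
    paste("chr1", "t", "CDS", "1101", "1300", ".", "+", ".",
          'gene_id "g1";', sep = "\t"),
    paste("chr1", "t", "CDS", "1501", "1700", ".", "+", ".",
          'gene_id "g1";', sep = "\t"),
    paste("chr1", "t", "gene", "5001", "6000", ".", "-", ".",
          'gene_id "g2";', sep = "\t")), gtf)
  ann <- read_gene_annotation(gtf)
  expect_equal(ann$genes$tss[ann$genes$gene_id == "g1"], 1000)
  expect_equal(ann$genes$tss[ann$genes$gene_id == "g2"], 5999)
  # intron = gap between the two CDS blocks
  expect_equal(ann$introns[, c("start", "end")],
               data.frame(start = 1300, end = 1500),
               ignore_attr = TRUE)
})

test_that("features outside the gene span are clamped with a warning", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "t", "gene", "1001", "2000", ".", "+", ".",
          'gene_id "g1";', sep = "\t"),
    paste("chr1", "t", "CDS", "901", "1300", ".", "+", ".",
          'gene_id "g1";', sep = "\t")), gtf)
  expect_warning(ann <- read_gene_annotation(gtf), "clamped")
  expect_equal(ann$cds$start, 1000)
})

test_that("genomic_intervals validates coordinates", {
  expect_error(genomic_intervals("chr1", 50, 50), "width")
  expect_error(genomic_intervals("chr1", -1, 5), "negative")
  gi <- genomic_intervals("chr1", c(10, 0), c(20, 5))
  expect_equal(gi$start, c(0, 10))  # sorted
})
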