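region_row <- function(cell, start, end, C, chrom = "chr1") {
  data.frame(cell_type = cell, chrom = chrom, peak = floor((start + end) / 2),
             start = start, end = end, complexity = C, n_sites = 1L,
             n_distinct_tfs = 1L, category = "TC0", band = "low",
             is_hot = FALSE, is_cold = TRUE, stringsAsFactors = FALSE)
}

test_that("master list keeps the highest-complexity representative", {
  a <- region_row("A", 100, 700, 5)
  b <- region_row("B", 400, 900, 9)
  m <- build_master_list(list(a, b))
  expect_equal(nrow(m), 1)
  expect_equal(m$cell_type, "B")
  expect_equal(m$ubiquity, 2L)

  # identical region in 3 cells: one entry, ubiquity 3
  m2 <- build_master_list(list(region_row("A", 10, 50, 3),
                               region_row("B", 10, 50, 3),
                               region_row("C", 10, 50, 3)))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$ubiquity, 3L)
  expect_equal(m2$cell_type, "A")  # tie broken by cell name

  # chain: B wins, displacing both neighbours
  ch <- list(region_row("A", 0, 100, 3), region_row("B", 90, 200, 9),
             region_row("C", 190, 300, 5))
  m3 <- build_master_list(ch)
  expect_equal(m3$cell_type, "B")
  expect_equal(nrow(m3), 1)
})

test_that("master windows are disjoint and order-free", {
  ls <- tiny_landscape()
  rls <- lapply(ls$cells, call_regions)
  m <- build_master_list(rls)
  o <- order(m$chrom, m$start)
  same_chrom <- m$chrom[o][-1] == m$chrom[o][-nrow(m)]
  expect_true(all(m$start[o][-1][same_chrom] >=
                    m$end[o][-nrow(m)][same_chrom]))
  m_rev <- build_master_list(rev(rls))
  expect_equal(m[, c("chrom", "start", "end", "complexity")],
               m_rev[, c("chrom", "start", "end", "complexity")])
})

test_that("ubiquity requires at least 1 bp of overlap", {
  master <- region_row("A", 100, 200, 5)
  abut <- region_row("B", 200, 300, 5)    # touches, no shared base
  over <- region_row("C", 199, 300, 5)
  expect_equal(cell_ubiquity(master, list(master, abut, over)), 2L)
  expect_equal(cell_ubiquity(master, list(master, abut)), 1L)
})

test_that("saturation curve matches closed-form cases", {
  shared <- region_row("X", c(0, 1000, 2000), c(500, 1500, 2500),
                       c(1, 1, 1))
  lists <- lapply(c("A", "B", "C"),
                  function(cl) { d <- shared; d$cell_type <- cl; d })
  sc <- saturation_curve(lists, n_samples = 50, seed = 1)
  expect_equal(sc$mean_elements, rep(3, 3))          # constant at m
  expect_true(all(diff(sc$mean_elements) >= 0))

  # disjoint private sets: mean at x is x * m
  priv <- lapply(1:3, function(i)
    region_row(paste0("c", i), 10000 * i + c(0, 2000),
               10000 * i + c(500, 2500), c(1, 1)))
  sp <- saturation_curve(priv, n_samples = 50, seed = 1)
  expect_equal(sp$mean_elements, 2 * (1:3))

  # a 12000-bp merged run chunks into 5000 + 5000 + 2000
  big <- list(region_row("A", 0, 12000, 2), region_row("B", 0, 12000, 1))
  sb <- saturation_curve(big, n_samples = 10, seed = 1)
  expect_equal(sb$mean_elements, c(3, 3))
  expect_equal(sb$mean_bp, c(12000, 12000))
})

test_that("at full cell count the saturation mean is the exact union", {
  ls <- tiny_landscape()
  rls <- lapply(ls$cells, call_regions)
  sc <- saturation_curve(rls, n_samples = 30, seed = 2)
  full <- merge_intervals(do.call(rbind, lapply(rls, function(d)
    as.data.frame(d)[, c("chrom", "start", "end")])))
  expect_equal(sc$mean_bp[length(ls$cells)], sum(full$end - full$start))
  expect_true(all(diff(sc$mean_elements) >= -1e-9))
})

test_that("Weibull fit recovers the asymptote", {
  x <- 1:40
  y <- 1000 * (1 - exp(-(x / 10)^1))
  f <- fit_weibull_saturation(x, y)
  expect_lt(abs(f$A - 1000) / 1000, 0.01)
  expect_lt(abs(f$lambda - 10) / 10, 0.05)

  # saturated-from-the-start curve
  fc <- fit_weibull_saturation(1:6, rep(50, 6))
  expect_lt(abs(fc$A - 50) / 50, 0.01)

  expect_error(fit_weibull_saturation(1:3, c(1, 2, 3)), "4 distinct")
})

test_that("region classes follow the priority cascade", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "t", "gene", "10001", "20000", ".", "+", ".",
          'gene_id "g1";', sep = "\t"),
    paste("chr1", "t", "CDS", "12001", "12200", ".", "+", ".",
          'gene_id "g1";', sep = "\t"),
    paste("chr1", "t", "CDS", "14001", "14200", ".", "+", ".",
          'gene_id "g1";', sep = "\t"),
    paste("chr1", "t", "UTR", "12200", "12400", ".", "+", ".",
          'gene_id "g1";', sep = "\t")), gtf)
  ann <- read_gene_annotation(gtf)

  master <- data.frame(
    chrom = "chr1",
    start = c(10500, 12126, 12900, 90000),
    end = c(10700, 12326, 13100, 90200),
    stringsAsFactors = FALSE)
  master$peak <- floor((master$start + master$end) / 2)
  cls <- annotate_region_classes(master, ann)
  expect_equal(cls[1], "promoter")   # peak 10600 within 1 kb of TSS 10000
  # region 2: CDS overlap 74 bp fails the 75-bp rule, UTR >= 1 bp wins
  expect_equal(cls[2], "UTR")
  expect_equal(cls[3], "intron")     # inside the CDS-block gap
  expect_equal(cls[4], "intergenic")
})

test_that("nearest gene minimises TSS distance with lexicographic ties", {
  ann <- list(genes = data.frame(
    gene_id = c("gB", "gA", "gC"), chrom = "chr1",
    start = c(4000, 7000, 50000), end = c(4500, 7500, 50100),
    strand = "+", tss = c(4000, 7000, 50000), stringsAsFactors = FALSE))
  class(ann) <- "gene_annotation"
  m <- data.frame(chrom = "chr1", start = 4900, end = 5100)  # centre 5000
  expect_equal(assign_nearest_gene(m, ann), "gB")
  # equidistant TSS at 4800/5200: tie broken lexicographically
  ann$genes$tss <- c(4800, 5200, 50000)
  expect_equal(assign_nearest_gene(m, ann), "gA")
  expect_error(assign_nearest_gene(m, list(genes = ann$genes[0, ])),
               "empty")
})
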