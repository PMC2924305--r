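test_that("browser coordinates convert to internal 0-based half-open", {
  iv <- browser_interval("chr7", 96030294, 96030493)
  expect_equal(iv$start, 96030293)
  expect_equal(iv$end, 96030493)
  expect_equal(interval_length(iv), 200)

  # CGH breakpoint positions are half-open boundary coordinates
  del <- gintervals("chr7", 95390000, 96270000)
  expect_equal(interval_length(del), 880000)

  expect_equal(interval_length(gintervals("chr1", 0, 1)), 1)
})

test_that("interval validation rejects degenerate ranges", {
  expect_error(gintervals("chr1", 200, 100), "end must exceed start")
  expect_error(gintervals("chr1", -5, 100), "start")
  expect_error(gintervals("chr1", 10, 20, strand = "x"), "strand")
})

test_that("distance is gap between nearest edges, Inf across chromosomes", {
  a <- gintervals("chr1", 100, 200)
  b <- gintervals("chr1", 500, 600)
  expect_equal(interval_distance(a, b), 300)
  expect_equal(interval_distance(a, gintervals("chr1", 150, 300)), 0)
  expect_equal(interval_distance(a, gintervals("chr2", 500, 600)), Inf)

  x <- gintervals("chr1", 300, 310)
  expect_true(lies_between(x, a, b))
  expect_true(lies_between(x, b, a))  # order-free
  expect_false(lies_between(gintervals("chr1", 50, 60), a, b))
  expect_false(lies_between(x, a, gintervals("chr1", 150, 300)))
})

test_that("distance is symmetric and satisfies the triangle inequality", {
  set.seed(11)
  for (rep in 1:50) {
    s <- sort(sample.int(1000, 6))
    iv <- lapply(1:3, function(k) gintervals("chr1", s[2 * k - 1], s[2 * k]))
    d12 <- interval_distance(iv[[1]], iv[[2]])
    expect_identical(d12, interval_distance(iv[[2]], iv[[1]]))
    expect_lte(interval_distance(iv[[1]], iv[[3]]),
               d12 + interval_length(iv[[2]]) +
                 interval_distance(iv[[2]], iv[[3]]))
  }
})

test_that("BED peaks read with summit and height conventions", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t199\tp1\t50",
               "chr1\t300\t400\tp2\t7\t+\t25",
               "chr2\t0\t10"), f)
  pk <- read_peaks_bed(f)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$summit[1], 149)  # midpoint default
  expect_equal(pk$height[1], 50)
  expect_equal(pk$summit[2], 325)  # explicit offset from start
  expect_equal(pk$height[3], 0)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(read_peaks_bed(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t199", "chr1\t200\t100"), bad)
  expect_error(read_peaks_bed(bad), "line 2")
})

test_that("BED round-trip is byte-identical for canonical peak files", {
  pk <- peaks(c("chr1", "chr1", "chr2"), c(10, 500, 0), c(200, 700, 90),
              name = c("a", "b", "c"), height = c(12, 40, 3),
              summit = c(100, 600, 45), strand = c("+", "*", "-"))
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(pk, f1)
  write_peaks_bed(read_peaks_bed(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gene models load equivalently from BED12 and GTF", {
  bed <- withr::local_tempfile(fileext = ".bed")
  # two blocks on the minus strand: first exon is the rightmost block
  writeLines(paste("chr1", 1000, 3000, "geneA", 0, "-", 1000, 3000, 0, 2,
                   "200,300,", "0,1700,", sep = "\t"), bed)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "test", "exon", 1001, 1200, ".", "-", ".",
          'gene_id "geneA";', sep = "\t"),
    paste("chr1", "test", "exon", 2701, 3000, ".", "-", ".",
          'gene_id "geneA";', sep = "\t")), gtf)
  gb <- read_gene_models(bed)
  gg <- read_gene_models(gtf)
  for (g in list(gb[[1]], gg[[1]])) {
    expect_equal(g$start, 1000)
    expect_equal(g$end, 3000)
    expect_equal(g$strand, "-")
    expect_equal(unname(g$exons[, "start"]), c(1000, 2700))
    expect_equal(unname(g$exons[, "end"]), c(1200, 3000))
  }
  expect_equal(gene_tss(gb[[1]]), 2999)  # minus strand: TSS at end - 1
  ex1 <- regupeaks:::exons_tx_order(gb[[1]])[1, ]
  expect_equal(unname(ex1["start"]), 2700)  # rightmost block first

  unstranded <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", 1000, 3000, "geneB", 0, ".", 1000, 3000, 0, 1,
                   "2000,", "0,", sep = "\t"), unstranded)
  expect_error(read_gene_models(unstranded), "unstranded")
})

test_that("gene model validation enforces exon structure", {
  expect_error(gene_models(list(list(
    gene_id = "g", chrom = "chr1", start = 0, end = 100, strand = "+",
    exons = NULL))), "no exons")
  expect_error(gene_models(list(list(
    gene_id = "g", chrom = "chr1", start = 0, end = 100, strand = "+",
    exons = cbind(start = c(0, 10), end = c(20, 40))))), "overlap")
})

test_that("sequence fetch respects strand and bounds", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTGGCCA"))
  fwd <- fetch_sequence(genome, gintervals("chr1", 2, 8, "+"))
  rev <- fetch_sequence(genome, gintervals("chr1", 2, 8, "-"))
  expect_equal(fwd, "GTACGT")
  expect_equal(rev, "ACGTAC")
  expect_equal(nchar(fwd), 6)
  expect_error(fetch_sequence(genome, gintervals("chr1", 10, 20)), "bounds")
  expect_error(fetch_sequence(genome, gintervals("chrX", 0, 5)), "absent")
})

test_that("FASTA write/read round-trips a synthetic genome exactly", {
  g <- make_genome(c(chrA = 1200, chrB = 1500), gc_content = 0.5, seed = 3)
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  expect_true(file.exists(paste0(f, ".fai")))
  g2 <- load_genome(f)
  expect_identical(as.character(g), as.character(g2))
})
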