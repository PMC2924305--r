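test_that("summit classification follows the category definitions", {
  genes <- toy_genes()
  # gplus: [10000,20000) + strand, first exon [10000,10200),
  # first intron [10200,12000)
  summits <- c(8000, 10000, 10150, 11500, 15000, 22000, 42000, 200500)
  pk <- peaks("chr1", summits - 100, summits + 100, summit = summits)
  got <- classify_peaks(pk, genes)
  expect_equal(as.character(got),
               c("TSS_flanking",  # 8000: within 5 kb upstream
                 "TSS_flanking",  # 10000: first exon start
                 "TSS_flanking",  # 10150: first exon
                 "TSS_flanking",  # 11500: first intron
                 "intragenic",    # 15000: later exon/intron
                 "near",          # 22000: 2 kb downstream of gene end
                 "near",          # 42000: 22 kb downstream
                 "intergenic"))
  # minus-strand gene gminus [60000,70000): TSS at 69999, upstream rightwards
  pk2 <- peaks("chr1", c(71000, 69100, 58000, 99000) - 500,
               c(71000, 69100, 58000, 99000) + 500,
               summit = c(71000, 69100, 58000, 99000))
  expect_equal(as.character(classify_peaks(pk2, genes)),
               c("TSS_flanking",  # 71000: 1 kb upstream on minus strand
                 "TSS_flanking",  # 69100: first exon (rightmost)
                 "near",          # 58000: 2 kb downstream of gene end (start)
                 "intergenic"))
})

test_that("every peak gets exactly one category (partition property)", {
  genes <- toy_genes()
  set.seed(22)
  summits <- sample.int(250000, 400) - 1
  pk <- peaks("chr1", pmax(summits - 50, 0), summits + 50, summit = summits)
  got <- classify_peaks(pk, genes)
  expect_false(any(is.na(got)))
  expect_equal(length(got), 400)
})

test_that("PTG mapping is many-to-many within the window", {
  genes <- gene_models(list(
    list(gene_id = "left", chrom = "chr1", start = 0, end = 10000,
         strand = "+", exons = cbind(start = 0, end = 10000)),
    list(gene_id = "right", chrom = "chr1", start = 40000, end = 50000,
         strand = "+", exons = cbind(start = 40000, end = 50000))))
  # peak 10 kb from both flanking genes
  pk <- peaks("chr1", 20000, 30000, name = "mid")
  m <- map_to_ptg(pk, genes)
  expect_setequal(m$gene_id, c("left", "right"))

  # peak 26 kb away maps nowhere
  lone <- gene_models(list(list(gene_id = "g", chrom = "chr1", start = 0,
                                end = 1000, strand = "+",
                                exons = cbind(start = 0, end = 1000))))
  far <- peaks("chr1", 27000, 27500, name = "far")
  expect_equal(nrow(map_to_ptg(far, lone)), 0)
  # at exactly the window edge the gene is retained
  edge <- peaks("chr1", 26000, 26500, name = "edge")
  expect_equal(map_to_ptg(edge, lone)$gene_id, "g")
})

test_that("PTG mapping equals a brute-force all-pairs check", {
  set.seed(23)
  pk_start <- sample.int(500000, 200)
  pk <- peaks("chr1", pk_start, pk_start + sample(200:800, 200, TRUE))
  g_start <- sample.int(500000, 50)
  genes <- gene_models(lapply(seq_len(50), function(i)
    list(gene_id = sprintf("g%02d", i), chrom = "chr1", start = g_start[i],
         end = g_start[i] + 5000, strand = "+",
         exons = cbind(start = g_start[i], end = g_start[i] + 5000))))
  got <- map_to_ptg(pk, genes)
  brute <- list()
  for (g in genes) for (i in seq_len(nrow(pk))) {
    d <- max(g$start - pk$end[i], pk$start[i] - g$end, 0)
    if (d <= 25000)
      brute[[length(brute) + 1]] <- paste(g$gene_id, pk$name[i])
  }
  expect_setequal(paste(got$gene_id, got$peak), unlist(brute))

  # monotonicity: shrinking the window never adds PTGs
  smaller <- map_to_ptg(pk, genes, annotation_config(ptg_window = 10000))
  expect_true(all(paste(smaller$gene_id, smaller$peak) %in%
                    paste(got$gene_id, got$peak)))
})

test_that("CTCF sites strictly between peak and gene break the pair", {
  genes <- gene_models(list(list(
    gene_id = "g", chrom = "chr1", start = 100000, end = 110000,
    strand = "+", exons = cbind(start = 100000, end = 110000))))
  pk <- peaks("chr1", 150000, 150500, name = "p")
  none <- gintervals(character(0), numeric(0), numeric(0))
  expect_equal(nrow(candidate_elements(pk, genes, none)), 1)

  blocking <- gintervals("chr1", 130000, 130200)
  expect_equal(nrow(candidate_elements(pk, genes, blocking)), 0)

  # a CTCF site overlapping the gene does not block
  touching <- gintervals("chr1", 109000, 111000)
  expect_equal(nrow(candidate_elements(pk, genes, touching)), 1)

  # beyond max_distance the pair is dropped regardless
  far <- peaks("chr1", 500000, 500500, name = "far")
  expect_equal(nrow(candidate_elements(far, genes, none)), 0)

  # overlapping peak and gene always retained
  inside <- peaks("chr1", 105000, 105500, name = "in")
  expect_equal(nrow(candidate_elements(inside, genes,
                                       gintervals("chr1", 104000, 106000))),
               1)
})

test_that("candidate elements equal a brute-force triple loop", {
  set.seed(24)
  pk_start <- sample.int(2000000, 100)
  pk <- peaks("chr1", pk_start, pk_start + 500)
  g_start <- sample.int(2000000, 10)
  genes <- gene_models(lapply(1:10, function(i)
    list(gene_id = sprintf("g%d", i), chrom = "chr1", start = g_start[i],
         end = g_start[i] + 8000, strand = "+",
         exons = cbind(start = g_start[i], end = g_start[i] + 8000))))
  ct_start <- sample.int(2000000, 20)
  ctcf <- gintervals("chr1", ct_start, ct_start + 200)

  got <- candidate_elements(pk, genes, ctcf)
  brute <- list()
  for (g in genes) for (i in seq_len(nrow(pk))) {
    d <- max(g$start - pk$end[i], pk$start[i] - g$end, 0)
    if (d > 300000) next
    if (d > 0) {
      gap_lo <- min(pk$end[i], g$end)
      gap_hi <- max(pk$start[i], g$start)
      blocked <- any(ctcf$start >= gap_lo & ctcf$end <= gap_hi)
      if (blocked) next
    }
    brute[[length(brute) + 1]] <- paste(g$gene_id, pk$name[i])
  }
  expect_setequal(paste(got$gene_id, got$peak), unlist(brute))

  # monotone in max_distance, anti-monotone in the CTCF set
  nearer <- candidate_elements(pk, genes, ctcf, domain_config(100000))
  expect_true(all(paste(nearer$gene_id, nearer$peak) %in%
                    paste(got$gene_id, got$peak)))
  fewer_ctcf <- candidate_elements(pk, genes, ctcf[1:5, ], domain_config())
  expect_true(all(paste(got$gene_id, got$peak) %in%
                    paste(fewer_ctcf$gene_id, fewer_ctcf$peak)))
})

test_that("category permutation test flags planted TSS enrichment", {
  genes <- toy_genes()
  chrom_lengths <- c(chr1 = 250000, chr2 = 100000)
  # summits planted exclusively in the 5 kb windows upstream of the TSSs
  set.seed(25)
  summits <- c(sample(5000:9999, 15, TRUE), sample(70000:74999, 15, TRUE))
  pk <- peaks("chr1", summits - 100, summits + 100, summit = summits)
  res <- category_enrichment(pk, genes, chrom_lengths, n_perm = 199,
                             seed = 26)
  expect_equal(res$p_empirical[res$category == "TSS_flanking"], 1 / 200)
  expect_equal(res$observed[res$category == "TSS_flanking"], 30)

  res1 <- category_enrichment(pk, genes, chrom_lengths, n_perm = 1, seed = 27)
  expect_true(all(res1$p_empirical %in% c(0.5, 1)))
})
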