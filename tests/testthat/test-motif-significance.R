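test_that("train/eval split uses floor of the training fraction", {
  pk <- peaks("chr1", seq(0, by = 300, length.out = 11369),
              seq(0, by = 300, length.out = 11369) + 200)
  sp <- split_train_eval(pk, train_fraction = 0.2, window = 200, seed = 9)
  expect_equal(length(sp$train_idx), 2273)
  expect_equal(length(sp$eval_idx), 11369 - 2273)
  expect_equal(sort(c(sp$train_idx, sp$eval_idx)), 1:11369)

  pk4 <- peaks("chr1", c(0, 300, 600, 900), c(200, 500, 800, 1100))
  sp4 <- split_train_eval(pk4, 0.5, window = 100, seed = 1)
  expect_equal(length(sp4$train_idx), 2)
  expect_equal(length(sp4$eval_idx), 2)

  again <- split_train_eval(pk4, 0.5, window = 100, seed = 1)
  expect_identical(sp4$train_idx, again$train_idx)
})

test_that("split windows are summit-centred sequences of the window size", {
  g <- make_genome(c(chr1 = 50000), seed = 2)
  pk <- peaks("chr1", c(1000, 4000), c(1400, 4400), summit = c(1200, 4150))
  sp <- split_train_eval(pk, 0.5, window = 200, seed = 3, genome = g)
  all_regions <- rbind(sp$train_regions, sp$eval_regions)
  expect_setequal(all_regions$start, c(1100, 4050))
  expect_equal(unique(interval_length(all_regions)), 200)
  expect_equal(nchar(sp$train_seqs), 200)
})

test_that("genomic background matches template lengths and chromosomes", {
  g <- make_genome(c(chr1 = 60000, chr2 = 30000), seed = 4)
  templates <- gintervals(rep(c("chr1", "chr2"), c(660, 340)),
                          rep(0, 1000), rep(200, 1000))
  bg <- sample_genomic_background(g, templates, n = 1000, seed = 5)
  expect_equal(nrow(bg), 1000)
  expect_equal(unique(interval_length(bg)), 200)
  counts <- table(bg$chrom)
  expect_lte(abs(counts[["chr1"]] - 660), 2)
  expect_lte(abs(counts[["chr2"]] - 340), 2)

  expect_error(
    sample_genomic_background(g, templates, 10, seed = 6,
                              exclude = gintervals(c("chr1", "chr2"), c(0, 0),
                                                   c(60000, 30000))),
    "excluded")
})

test_that("Markov background reproduces training composition", {
  # absorbing chain: an all-A training set yields almost all-A output
  # (training long enough that add-one smoothing leaks < 5%)
  out <- markov_background(strrep("A", 10000), 1, n = 20,
                           length = 50, seed = 7)
  leak <- 1 - mean(strsplit(paste(out, collapse = ""), "")[[1]] == "A")
  expect_lt(leak, 0.05)

  # dinucleotide frequencies converge (n x length = 1e5)
  train <- random_dna(50, 400, seed = 8, p = c(0.4, 0.1, 0.2, 0.3))
  gen <- markov_background(train, 1, n = 500, length = 200, seed = 9)
  dinuc <- function(seqs) {
    pairs <- unlist(lapply(seqs, function(s)
      substring(s, 1:(nchar(s) - 1), 2:nchar(s))))
    tab <- table(factor(pairs, levels = outer(c("A", "C", "G", "T"),
                                              c("A", "C", "G", "T"),
                                              paste0)))
    tab / sum(tab)
  }
  expect_lt(sum(abs(dinuc(train) - dinuc(gen))), 0.02)

  # order 0 reduces to i.i.d. mononucleotide sampling
  gen0 <- markov_background(train, 0, n = 100, length = 500, seed = 10)
  mono <- function(seqs) {
    b <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    table(factor(b, levels = c("A", "C", "G", "T"))) / length(b)
  }
  expect_lt(sum(abs(mono(train) - mono(gen0))), 0.03)
})

test_that("hypergeometric enrichment matches the urn computation", {
  pwm <- build_pwm("AAAA", pseudocount = 0, name = "polyA")
  ev <- c(rep("CCAAAACC", 4), "CCCCCCCC")
  bg <- rep("GGGGGGGG", 5)
  res <- motif_enrichment(pwm, ev, bg, bg, threshold = 5)
  expect_equal(res$x_eval, 4)
  expect_equal(res$p_hyper, 6 / 252, tolerance = 1e-12)
  expect_equal(res$fold_genomic, Inf)

  # identical eval and background sets: fold 1, p >= 0.5
  res2 <- motif_enrichment(pwm, ev, ev, ev, threshold = 5)
  expect_equal(res2$fold_genomic, 1)
  expect_gte(res2$p_hyper, 0.5)
})

test_that("hypergeometric and binomial tails equal enumeration", {
  for (N in c(6, 11, 17, 20)) {
    for (K in c(0, 3, N %/% 2, N)) {
      for (n in c(1, N %/% 3, N - 1)) {
        if (n < 1) next
        for (x in unique(c(0, 1, min(K, n)))) {
          expect_equal(
            stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE),
            hyper_tail_enum(x, K, N, n), tolerance = 1e-12,
            info = sprintf("N=%d K=%d n=%d x=%d", N, K, n, x))
        }
      }
    }
  }
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(1:20, 1)
    x <- sample(0:n, 1)
    p <- stats::runif(1)
    got <- if (x == 0) 1
    else stats::pbinom(x - 1, n, p, lower.tail = FALSE)
    expect_equal(got, binom_tail_enum(x, n, p), tolerance = 1e-12)
  }
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(0.37), 0.37)
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  # order invariance; re-adjusting never shrinks adjusted values, and a
  # flat adjusted vector is a fixed point
  p <- c(0.001, 0.04, 0.2, 0.8, 0.01)
  o <- c(3, 1, 5, 2, 4)
  expect_equal(bh_correct(p)[o], bh_correct(p[o]))
  adj <- sort(bh_correct(p))
  expect_true(all(bh_correct(adj) >= adj))
  expect_equal(bh_correct(rep(0.04, 4)), rep(0.04, 4))
})

test_that("binomial over-representation follows the set-B rate", {
  pwm <- build_pwm("AAAA", pseudocount = 0, name = "polyA")
  setA <- c(rep("GGAAAAGG", 8), rep("GGGGGGGG", 2))
  setB <- c(rep("GGAAAAGG", 5), rep("GGGGGGGG", 5))
  res <- binomial_overrepresentation(list(pwm), setA, setB, thresholds = 5)
  expect_equal(res$x_A, 8)
  expect_equal(res$rate_B, 0.5)
  expect_equal(res$p_binomial, 56 / 1024, tolerance = 1e-12)
  expect_equal(res$p_bonferroni, res$p_binomial)  # single eligible motif

  none <- binomial_overrepresentation(list(pwm), rep("GGGGGGGG", 4), setB, 5)
  expect_equal(none$p_binomial, 1)

  two <- binomial_overrepresentation(
    list(pwm, build_pwm("GGAA", pseudocount = 0, name = "m2")),
    setA, setB, thresholds = 5)
  expect_equal(two$p_bonferroni, pmin(1, two$p_binomial * 2))

  degen <- binomial_overrepresentation(list(pwm), setA, rep("GGGGGGGG", 5), 5)
  expect_true(degen$degenerate)
  expect_equal(degen$p_binomial, 0)
})

test_that("motif discovery recovers a planted word and is deterministic", {
  set.seed(13)
  word <- "ACGTACGT"
  bgs <- random_dna(40, 60, seed = 14)
  seqs <- vapply(seq_along(bgs), function(i) {
    pos <- sample(1:(60 - 8), 1)
    s <- bgs[i]
    substr(s, pos, pos + 7) <- word
    s
  }, "")
  cands <- discover_motifs(seqs, widths = 8, n_per_width = 3, seed = 15)
  consensi <- vapply(cands, pwm_consensus, "")
  rcword <- regupeaks:::reverse_complement(word)
  expect_true(word %in% consensi || rcword %in% consensi)

  again <- discover_motifs(seqs, widths = 8, n_per_width = 3, seed = 15)
  expect_identical(lapply(cands, `[[`, "half_a"),
                   lapply(again, `[[`, "half_a"))

  expect_warning(short <- discover_motifs(random_dna(12, 6, seed = 16),
                                          widths = 10),
                 "shorter than width")
  expect_length(short, 0)
})

test_that("significance filter requires enrichment against both backgrounds", {
  pwm <- build_pwm("AAAAAA", pseudocount = 0, name = "polyA")
  with_word <- function(n, seed) {
    s <- random_dna(n, 40, seed = seed, p = c(0.1, 0.4, 0.4, 0.1))
    vapply(s, function(x) {
      substr(x, 10, 15) <- "AAAAAA"
      x
    }, "", USE.NAMES = FALSE)
  }
  ev <- with_word(40, 17)
  bg_markov <- random_dna(40, 40, seed = 18, p = c(0.1, 0.4, 0.4, 0.1))
  # genomic background carries the same compositional bias AND the word:
  # enrichment only against the Markov background must not count
  bg_genomic <- with_word(40, 19)
  res <- score_candidates(list(pwm), ev, bg_genomic, bg_markov,
                          threshold = 8)
  expect_false(res$significant)
  expect_lte(res$fold_genomic, 1.5)
  expect_gt(res$fold_markov, 1.5)
})

test_that("the best significant motif is selected by AUC", {
  pwm <- toy_dimer()
  weak <- build_pwm(c("AACA", "AACT", "AACG"), name = "weak")
  results <- data.frame(significant = c(TRUE, TRUE, FALSE),
                        auc = c(0.9, 0.7, 0.99))
  expect_identical(select_best_motif(list(pwm, weak, weak), results)$name,
                   "toy_dimer")
  expect_error(select_best_motif(list(pwm), data.frame(significant = FALSE,
                                                       auc = 0.9)),
               "no significant")
})
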