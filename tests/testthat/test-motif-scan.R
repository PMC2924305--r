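test_that("PWM construction follows the pseudocount rule", {
  pwm <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0.25)
  expect_equal(unname(pwm$half_a["A", 1]), 2.25 / 3)
  expect_equal(unname(pwm$half_a["C", 1]), 0.25 / 3)
  expect_equal(colSums(pwm$half_a), rep(1, 4), ignore_attr = TRUE)

  uniform <- build_pwm(c("ACGT", "CGTA", "GTAC", "TACG"), pseudocount = 0)
  expect_equal(unname(uniform$half_a), matrix(0.25, 4, 4))

  expect_error(build_pwm(c("ACGT", "ACG")), "equal length")
  expect_error(build_pwm(character(0)), "at least one")
})

test_that("zero-probability cells score at the floor, not -Inf", {
  pwm <- build_pwm(c("A", "A"), pseudocount = 0)
  expect_equal(unname(pwm$half_a["A", 1]), 1)
  r <- scan_sequence(pwm, "C")
  expect_true(is.finite(r$best$score))
  expect_equal(r$best$score, -10)
})

test_that("scanning scores placements as summed log2 odds", {
  pwm <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0.25)
  r <- scan_sequence(pwm, "ACGT")
  expect_equal(r$best$score, 4 * log2(0.75 / 0.25), tolerance = 1e-10)
  expect_equal(r$best$position, 0)
  expect_equal(r$best$strand, "+")

  # N bases contribute zero
  rn <- scan_sequence(pwm, "ACGN")
  expect_equal(rn$best$score, 3 * log2(0.75 / 0.25) + 0, tolerance = 1e-10)

  # sequence below the minimal span
  short <- scan_sequence(pwm, "AC")
  expect_true(short$too_short)
  expect_null(short$best)
})

test_that("best score is strand-symmetric", {
  pwm <- toy_dimer(spacer_range = c(0, 2))
  seqs <- random_dna(50, 60, seed = 21)
  rc <- regupeaks:::reverse_complement(seqs)
  expect_equal(best_scores(pwm, seqs), best_scores(pwm, rc))
})

test_that("scanner equals brute-force placement enumeration", {
  set.seed(31)
  pwms <- list(build_pwm(c("ACGT", "ACTT", "AGGT"), pseudocount = 0.25),
               toy_dimer(),
               toy_dimer(spacer_range = c(0, 3)))
  for (pwm in pwms) {
    lens <- sample(12:50, 25, TRUE)
    for (L in lens) {
      s <- random_dna(1, L, seed = sample.int(1e6, 1))
      expect_equal(scan_sequence(pwm, s)$best$score, brute_best_score(pwm, s),
                   tolerance = 1e-9)
    }
  }
})

test_that("batch and per-sequence scanning agree", {
  pwm <- toy_dimer(spacer_range = c(0, 2))
  seqs <- random_dna(40, 45, seed = 5)
  per_seq <- vapply(seqs, function(s) scan_sequence(pwm, s)$best$score, 0,
                    USE.NAMES = FALSE)
  expect_equal(regupeaks:::batch_best_scores(pwm, seqs), per_seq)
  d <- regupeaks:::batch_best_scores(pwm, seqs, details = TRUE)
  for (i in c(1, 7, 20)) {
    b <- scan_sequence(pwm, seqs[i])$best
    expect_equal(d$score[i], b$score)
  }
})

test_that("threshold calibration maximises the f-measure", {
  cal <- calibrate_threshold(c(5, 6, 7), c(1, 2, 3))
  expect_equal(cal$threshold, 5)
  expect_equal(cal$f_measure, 1)

  overlapping <- calibrate_threshold(c(1, 2, 3), c(1, 2, 3))
  expect_equal(overlapping$f_measure, 2 / 3)
  expect_equal(overlapping$threshold, 1)  # smallest maximising threshold

  expect_warning(calibrate_threshold(c(2, 2), c(2, 2)), "identical")
})

test_that("calibration sweep matches an exhaustive oracle on random scores", {
  set.seed(41)
  for (rep in 1:5) {
    pos <- round(stats::rnorm(25, 1), 2)
    bg <- round(stats::rnorm(25), 2)
    cand <- sort(unique(c(pos, bg)))
    f_at <- vapply(cand, function(t) {
      tp <- sum(pos >= t); fp <- sum(bg >= t)
      p <- if (tp + fp) tp / (tp + fp) else 0
      r <- tp / length(pos)
      if (p + r) 2 * p * r / (p + r) else 0
    }, 0)
    best_t <- cand[which.max(f_at)]  # first index = smallest t on ties
    cal <- calibrate_threshold(pos, bg)
    expect_equal(cal$threshold, best_t)
    expect_equal(cal$f_measure, max(f_at))
  }
})

test_that("FDR estimate is the background/positive call-rate ratio", {
  pos <- c(rep(1, 5), rep(9, 5))
  bg <- c(rep(1, 9), 9)
  expect_equal(estimate_fdr(5, pos, bg), 0.2)
  expect_equal(estimate_fdr(100, pos, bg), 1)  # no positive calls
  expect_equal(estimate_fdr(5, pos, rep(0, 10)), 0)
})

test_that("ROC AUC is the Mann-Whitney probability with ties at one half", {
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_auc(c(2, 4), c(1, 3)), 0.75)
  set.seed(51)
  pos <- stats::rnorm(30, 1)
  bg <- stats::rnorm(30)
  expect_equal(roc_auc(pos, bg), roc_auc(exp(pos), exp(bg)))  # rank property
  # pair-enumeration oracle
  expect_equal(roc_auc(pos, bg),
               mean(outer(pos, bg, ">") + 0.5 * outer(pos, bg, "==")))
})

test_that("scanner comparison evaluates each scanner at its own threshold", {
  pwm <- toy_dimer()
  pos <- c(vapply(sample_pwm_instances_seeded(pwm, 30, seed = 61),
                  function(x) paste0("ACGTACGTAC", x, "GTACGTACGT"), ""))
  bg <- random_dna(30, 28, seed = 62)
  tab <- compare_scanners(list(a = pwm, b = pwm), pos, bg)
  expect_equal(tab[1, -1], tab[2, -1], ignore_attr = TRUE)

  # a random-score scanner cannot separate the sets
  rand <- function(seq) sum(utf8ToInt(seq)) %% 97  # arbitrary, label-free
  tab2 <- compare_scanners(list(noise = rand), pos, bg)
  expect_lt(abs(tab2$sensitivity - (1 - tab2$specificity)), 0.45)

  # corrupting the PWM cannot improve the planted-motif benchmark
  corrupt <- dimeric_pwm(pwm$half_a[4:1, c(2, 4, 1, 3)],
                         pwm$half_b[4:1, ], name = "corrupt")
  tab3 <- compare_scanners(list(true = pwm, corrupt = corrupt), pos, bg)
  expect_gte(tab3$auc[1], tab3$auc[2])
  expect_gte(tab3$f_measure[1], tab3$f_measure[2])
})

test_that("MEME motif files round-trip with dimeric structure", {
  pwm <- toy_dimer(spacer_range = c(0, 2))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(list(pwm, build_pwm(c("ACGTT"), name = "mono")), f)
  back <- read_meme_motifs(f)
  expect_equal(names(back), c("toy_dimer", "mono"))
  expect_equal(back$toy_dimer$half_a, pwm$half_a, tolerance = 1e-4)
  expect_equal(back$toy_dimer$spacer_range, pwm$spacer_range)
  expect_null(back$mono$half_b)
  expect_equal(best_scores(back$toy_dimer, "AACATGTT"),
               best_scores(pwm, "AACATGTT"), tolerance = 1e-3)
})
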