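#' Discover candidate motifs by word seeding and PWM refinement
#'
#' A deliberately simple de novo discoverer standing in for external motif
#' finders: for each width it (1) counts every exact word of that width on
#' both strands of the training sequences, (2) ranks words by the ratio of
#' observed to expected count under a first-order Markov model of the
#' training set, (3) takes the `n_per_width` most over-represented words as
#' seeds, and (4) refines each seed into a PWM by iterative realignment —
#' scan, take the best hit per sequence with a positive log-odds score,
#' rebuild the PWM from those hits — until the mean per-column information
#' content changes by less than `tol` bits or `max_iter` iterations.
#' External PWMs (e.g. read with [read_meme_motifs()]) are first-class
#' candidates alongside these.
#'
#' @param train_seqs character vector of at least 10 training sequences.
#' @param widths integer vector of motif widths to try (default 6:20).
#' @param n_per_width seeds refined per width (default 10).
#' @param seed integer seed; used only when `max_seqs` subsamples a large
#'   training set, the procedure is otherwise deterministic.
#' @param min_count minimum occurrences for a word to seed a motif.
#' @param max_seqs cap on training sequences used (subsampled above this).
#' @param max_iter,tol refinement stopping rule.
#' @return A named list of single-block `dimeric_pwm` candidates.
#' @export
discover_motifs <- function(train_seqs, widths = 6:20, n_per_width = 10,
                            seed = 1, min_count = 3, max_seqs = 1000,
                            max_iter = 50, tol = 1e-3) {
  if (length(train_seqs) < 10)
    stop("at least 10 training sequences are required")
  if (length(train_seqs) > max_seqs)
    train_seqs <- with_seed(seed,
                            sample(train_seqs, max_seqs))
  train_seqs <- toupper(train_seqs)
  bg <- mono_frequencies(train_seqs)
  markov <- markov_params(train_seqs)
  out <- list()
  for (w in sort(unique(as.integer(widths)))) {
    if (all(nchar(train_seqs) < w)) {
      warning("all training sequences shorter than width ", w, "; skipped")
      next
    }
    seeds <- seed_words(train_seqs, w, n_per_width, markov, min_count)
    for (i in seq_along(seeds)) {
      pwm <- refine_seed(seeds[i], train_seqs, bg, max_iter, tol)
      pwm$name <- sprintf("w%d_seed%d_%s", w, i, seeds[i])
      out[[pwm$name]] <- pwm
    }
  }
  out
}

mono_frequencies <- function(seqs) {
  cd <- unlist(lapply(seqs, encode_seq), use.names = FALSE)
  counts <- tabulate(cd[cd <= 4], 4) + 1
  stats::setNames(counts / sum(counts), DNA)
}

## First-order Markov parameters (add-one smoothed) for expected word counts.
markov_params <- function(seqs) {
  trans <- matrix(1, 4, 4, dimnames = list(DNA, DNA))
  init <- rep(1, 4)
  for (s in seqs) {
    cd <- encode_seq(s)
    cd <- cd[cd <= 4]
    if (length(cd) < 2) next
    a <- cd[-length(cd)]
    b <- cd[-1]
    for (i in 1:4) trans[i, ] <- trans[i, ] + tabulate(b[a == i], 4)
    init <- init + tabulate(cd, 4)
  }
  list(init = init / sum(init), trans = trans / rowSums(trans))
}

word_probability <- function(word, markov) {
  cd <- encode_seq(word)
  if (any(cd > 4)) return(0)
  p <- markov$init[cd[1]]
  if (length(cd) > 1)
    for (i in 2:length(cd)) p <- p * markov$trans[cd[i - 1], cd[i]]
  p
}

## Most over-represented width-w words (observed / Markov-expected), counted
## on both strands with a word and its reverse complement pooled.
seed_words <- function(seqs, w, n_top, markov, min_count) {
  both <- c(seqs, reverse_complement(seqs))
  words <- unlist(lapply(both, function(s) {
    L <- nchar(s)
    if (L < w) return(character(0))
    substring(s, 1:(L - w + 1), w:L)
  }), use.names = FALSE)
  words <- words[!grepl("[^ACGT]", words)]
  if (!length(words)) return(character(0))
  counts <- table(words)
  counts <- counts[counts >= min_count]
  if (!length(counts)) return(character(0))
  n_pos <- length(words)
  expected <- n_pos * vapply(names(counts), word_probability, 0,
                             markov = markov)
  ratio <- as.numeric(counts) / expected
  o <- order(-ratio, names(counts))
  chosen <- character(0)
  for (word in names(counts)[o]) {
    if (length(chosen) >= n_top) break
    if (reverse_complement(word) %in% chosen) next
    chosen <- c(chosen, word)
  }
  chosen
}

## Iterative expectation-style realignment of a seed word into a PWM.
refine_seed <- function(word, seqs, bg, max_iter = 50, tol = 1e-3) {
  w <- nchar(word)
  pwm <- build_pwm(word, pseudocount = 0.5, background = bg)
  ic <- pwm_information(pwm)
  for (it in seq_len(max_iter)) {
    hits <- aligned_best_hits(pwm, seqs)
    keep <- hits$score > 0
    if (sum(keep) < 5) {
      o <- order(-hits$score)
      keep <- seq_along(hits$score) %in% o[seq_len(min(10, length(o)))]
    }
    inst <- hits$instance[keep & !is.na(hits$instance)]
    inst <- inst[!grepl("[^ACGT]", inst)]
    if (!length(inst)) break
    pwm <- build_pwm(inst, pseudocount = 0.5, background = bg)
    ic_new <- pwm_information(pwm)
    if (abs(ic_new - ic) < tol) {
      ic <- ic_new
      break
    }
    ic <- ic_new
  }
  pwm
}

## Best hit per sequence with the matched subsequence, oriented to the motif
## strand. Uses the batch scanner when sequence lengths are uniform.
aligned_best_hits <- function(pwm, seqs) {
  w <- pwm_width(pwm)  # single-block refinement: span == width
  lens <- nchar(seqs)
  if (length(seqs) > 1 && all(lens == lens[1])) {
    d <- batch_best_scores(pwm, seqs, details = TRUE)
  } else {
    d <- do.call(rbind, lapply(seqs, function(s) {
      r <- scan_sequence(pwm, s)
      if (is.null(r$best))
        data.frame(score = -Inf, position = NA_integer_,
                   strand = NA_character_, spacer = NA_integer_)
      else r$best[, c("score", "position", "strand", "spacer")]
    }))
  }
  inst <- rep(NA_character_, length(seqs))
  ok <- which(is.finite(d$score))
  if (length(ok)) {
    inst[ok] <- substr(seqs[ok], d$position[ok] + 1, d$position[ok] + w)
    neg <- ok[d$strand[ok] == "-"]
    if (length(neg)) inst[neg] <- reverse_complement(inst[neg])
  }
  data.frame(score = d$score, instance = inst, stringsAsFactors = FALSE)
}
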