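## Encode A,C,G,T as 1..4 and every ambiguous base as 5, matching the N row
## of the log-odds matrices (score contribution 0).
encode_seq <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], DNA)
  codes[is.na(codes)] <- 5L
  codes
}

## Score every placement of one half-site log-odds matrix (5 x w) along an
## encoded sequence; returns scores at start positions 1..(L - w + 1).
half_site_scores <- function(lo, codes) {
  w <- ncol(lo)
  np <- length(codes) - w + 1
  if (np < 1) return(numeric(0))
  s <- numeric(np)
  for (j in seq_len(w))
    s <- s + lo[cbind(codes[j:(j + np - 1)], j)]
  s
}

## All placements of a dimeric PWM on one strand of an encoded sequence:
## data.frame(position (0-based), spacer, score).
strand_placements <- function(lo, wa, wb, spacers, codes) {
  a <- half_site_scores(lo$A, codes)
  if (is.null(lo$B)) {
    if (!length(a)) return(NULL)
    return(data.frame(position = seq_along(a) - 1, spacer = 0L, score = a))
  }
  b <- half_site_scores(lo$B, codes)
  out <- lapply(spacers, function(s) {
    np <- length(codes) - (wa + s + wb) + 1
    if (np < 1) return(NULL)
    idx <- seq_len(np)
    data.frame(position = idx - 1, spacer = s,
               score = a[idx] + b[idx + wa + s])
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Scan a sequence with a dimeric PWM
#'
#' Scores every placement of the motif — all start positions, both strands,
#' every allowed spacer — as the summed log-odds (bits, base 2) of both
#' half-sites against the PWM's background frequencies. Ambiguous bases (N)
#' contribute 0; zero-probability cells are floored at -10 bits. Minus-strand
#' hits are reported at the forward-strand coordinate of their leftmost base.
#'
#' @param pwm a `dimeric_pwm`.
#' @param seq a nucleotide string.
#' @param score_floor per-position log-odds floor in bits.
#' @return A list with `best` (row with `position`, `strand`, `spacer`,
#'   `score`, or `NULL`), `hits` (data frame of all placements), and
#'   `too_short` (`TRUE` when the sequence is shorter than the minimal motif
#'   span).
#' @examples
#' pwm <- build_pwm(c("ACGT", "ACGT"))
#' scan_sequence(pwm, "TTACGTTT")$best
#' @export
scan_sequence <- function(pwm, seq, score_floor = -10) {
  lo <- pwm_logodds(pwm, floor = score_floor)
  wa <- ncol(pwm$half_a)
  wb <- if (is.null(pwm$half_b)) 0L else ncol(pwm$half_b)
  min_span <- wa + wb + min(pwm$spacer_range)
  L <- nchar(seq)
  empty <- data.frame(position = integer(), strand = character(),
                      spacer = integer(), score = numeric())
  if (L < min_span)
    return(list(best = NULL, hits = empty, too_short = TRUE))
  fwd <- strand_placements(lo, wa, wb, pwm$spacer_range, encode_seq(seq))
  rev <- strand_placements(lo, wa, wb, pwm$spacer_range,
                           encode_seq(reverse_complement(seq)))
  hits <- list()
  if (!is.null(fwd)) {
    fwd$strand <- "+"
    hits <- c(hits, list(fwd))
  }
  if (!is.null(rev)) {
    span <- wa + rev$spacer + wb
    rev$position <- L - rev$position - span
    rev$strand <- "-"
    hits <- c(hits, list(rev))
  }
  if (!length(hits))
    return(list(best = NULL, hits = empty, too_short = TRUE))
  hits <- do.call(rbind, hits)
  hits <- hits[, c("position", "strand", "spacer", "score")]
  o <- order(-hits$score, hits$position, hits$strand)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  list(best = hits[1, , drop = FALSE], hits = hits, too_short = FALSE)
}

#' Best motif score per sequence
#'
#' One best hit per sequence is the unit of calibration, FDR estimation and
#' ROC analysis. Sequences shorter than the minimal motif span score `-Inf`.
#'
#' @inheritParams scan_sequence
#' @param seqs character vector of sequences.
#' @return Numeric vector of best scores.
#' @export
best_scores <- function(pwm, seqs, score_floor = -10) {
  if (!length(seqs)) return(numeric(0))
  lens <- nchar(seqs)
  if (length(seqs) > 1 && all(lens == lens[1]))
    return(batch_best_scores(pwm, seqs, score_floor))
  vapply(seqs, function(s) {
    r <- scan_sequence(pwm, s, score_floor)
    if (is.null(r$best)) -Inf else r$best$score
  }, 0, USE.NAMES = FALSE)
}

#' Calibrate a scan threshold by maximum f-measure
#'
#' Sweeps candidate thresholds over the union of observed best scores from a
#' positive (bound) and a background sequence set. At threshold `t`,
#' TP = positives scoring >= t, FP = background >= t, FN = positives < t;
#' the threshold maximising F = 2PR/(P+R) is returned, ties resolved to the
#' smallest maximising threshold (favouring recall).
#'
#' @param pos_best_scores best scores of the positive set.
#' @param bg_best_scores best scores of the background set.
#' @return A list of class `"scan_calibration"` with `threshold`,
#'   `f_measure`, `estimated_fdr`, `sensitivity`, `specificity`.
#' @export
calibrate_threshold <- function(pos_best_scores, bg_best_scores) {
  if (!length(pos_best_scores) || !length(bg_best_scores))
    stop("both score sets must be non-empty")
  cand <- sort(unique(c(pos_best_scores, bg_best_scores)))
  if (length(cand) == 1)
    warning("all scores identical: positive and background sets are not separated")
  tp <- vapply(cand, function(t) sum(pos_best_scores >= t), 0)
  fp <- vapply(cand, function(t) sum(bg_best_scores >= t), 0)
  fn <- length(pos_best_scores) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- tp / (tp + fn)
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  best <- which(f == max(f))[1]  # cand sorted ascending: first = smallest t
  threshold <- cand[best]
  structure(list(threshold = threshold,
                 f_measure = f[best],
                 estimated_fdr = estimate_fdr(threshold, pos_best_scores,
                                              bg_best_scores),
                 sensitivity = recall[best],
                 specificity = 1 - fp[best] / length(bg_best_scores)),
            class = "scan_calibration")
}

#' @export
print.scan_calibration <- function(x, ...) {
  cat(sprintf(
    "scan calibration: threshold %.3f bits (F = %.3f, est. FDR = %.3f)\n",
    x$threshold, x$f_measure, x$estimated_fdr))
  invisible(x)
}

#' Estimate the false discovery rate at a score threshold
#'
#' The FDR of motif calls is estimated as the background call rate divided by
#' the positive call rate, clipped to `[0, 1]`; with no positive calls the
#' estimate is 1 by convention.
#'
#' @param threshold score cutoff in bits.
#' @inheritParams calibrate_threshold
#' @return A fraction in `[0, 1]`.
#' @export
estimate_fdr <- function(threshold, pos_best_scores, bg_best_scores) {
  pos_rate <- mean(pos_best_scores >= threshold)
  if (pos_rate == 0) return(1)
  bg_rate <- mean(bg_best_scores >= threshold)
  min(1, bg_rate / pos_rate)
}

#' ROC area under the curve from two score sets
#'
#' The probability that a random positive outscores a random background
#' sequence, ties counting one half (the Mann-Whitney formulation).
#'
#' @inheritParams calibrate_threshold
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pos_best_scores, bg_best_scores) {
  n <- length(pos_best_scores)
  m <- length(bg_best_scores)
  if (!n || !m) stop("both score sets must be non-empty")
  r <- rank(c(pos_best_scores, bg_best_scores))
  (sum(r[seq_len(n)]) - n * (n + 1) / 2) / (n * m)
}

#' Compare motif scanners at their own calibrated thresholds
#'
#' Each scanner (a `dimeric_pwm`, or any function mapping a sequence to a
#' best score) is calibrated by maximum f-measure on the supplied sets and
#' evaluated at its own threshold: sensitivity is the fraction of positives
#' called, specificity the fraction of background not called.
#'
#' @param scanners named list of `dimeric_pwm` objects and/or scoring
#'   functions.
#' @param pos_seqs,bg_seqs character vectors of sequences.
#' @return A data frame with one row per scanner: `scanner`, `threshold`,
#'   `f_measure`, `sensitivity`, `specificity`, `auc`.
#' @export
compare_scanners <- function(scanners, pos_seqs, bg_seqs) {
  if (!length(scanners)) stop("at least one scanner is required")
  if (is.null(names(scanners)))
    names(scanners) <- paste0("scanner_", seq_along(scanners))
  rows <- lapply(names(scanners), function(nm) {
    sc <- scanners[[nm]]
    score <- if (methods::is(sc, "dimeric_pwm"))
      function(seqs) best_scores(sc, seqs)
    else function(seqs) vapply(seqs, sc, 0, USE.NAMES = FALSE)
    pos <- score(pos_seqs)
    bg <- score(bg_seqs)
    cal <- calibrate_threshold(pos, bg)
    data.frame(scanner = nm, threshold = cal$threshold,
               f_measure = cal$f_measure,
               sensitivity = mean(pos >= cal$threshold),
               specificity = 1 - mean(bg >= cal$threshold),
               auc = roc_auc(pos, bg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- batch scanning over equal-length sequence sets -----------------------
## Peak windows and generated backgrounds are fixed-width, so scoring can be
## vectorised across sequences: one n x positions score matrix per strand.

encode_matrix <- function(seqs) {
  L <- nchar(seqs[1])
  codes <- match(unlist(strsplit(toupper(seqs), ""), use.names = FALSE), DNA)
  codes[is.na(codes)] <- 5L
  matrix(codes, nrow = length(seqs), ncol = L, byrow = TRUE)
}

batch_half_scores <- function(lo, cm) {
  w <- ncol(lo)
  np <- ncol(cm) - w + 1
  if (np < 1) return(NULL)
  s <- matrix(0, nrow(cm), np)
  for (j in seq_len(w))
    s <- s + matrix(lo[cbind(as.vector(cm[, j:(j + np - 1)]), j)], nrow(cm))
  s
}

## Per-sequence best score over positions x strands x spacers for a set of
## equal-length sequences. Returns -Inf rows when sequences are shorter than
## the minimal motif span.
batch_best_scores <- function(pwm, seqs, score_floor = -10, details = FALSE) {
  lo <- pwm_logodds(pwm, floor = score_floor)
  wa <- ncol(pwm$half_a)
  wb <- if (is.null(pwm$half_b)) 0L else ncol(pwm$half_b)
  n <- length(seqs)
  L <- nchar(seqs[1])
  if (L < wa + wb + min(pwm$spacer_range)) {
    if (details)
      return(data.frame(score = rep(-Inf, n), position = NA_integer_,
                        strand = NA_character_, spacer = NA_integer_))
    return(rep(-Inf, n))
  }
  best <- rep(-Inf, n)
  best_pos <- rep(NA_integer_, n)
  best_strand <- rep(NA_character_, n)
  best_spacer <- rep(NA_integer_, n)
  for (strand in c("+", "-")) {
    cm <- encode_matrix(if (strand == "+") seqs else reverse_complement(seqs))
    a <- batch_half_scores(lo$A, cm)
    b <- if (is.null(lo$B)) NULL else batch_half_scores(lo$B, cm)
    for (s in pwm$spacer_range) {
      total <- if (is.null(b)) a else {
        np <- L - (wa + s + wb) + 1
        if (np < 1) next
        a[, seq_len(np), drop = FALSE] +
          b[, seq_len(np) + wa + s, drop = FALSE]
      }
      mx <- apply(total, 1, max)
      upd <- mx > best
      if (any(upd)) {
        pos0 <- max.col(total[upd, , drop = FALSE], ties.method = "first") - 1
        if (strand == "-") pos0 <- L - pos0 - (wa + s + wb)
        best[upd] <- mx[upd]
        best_pos[upd] <- pos0
        best_strand[upd] <- strand
        best_spacer[upd] <- s
      }
    }
  }
  if (details)
    data.frame(score = best, position = best_pos, strand = best_strand,
               spacer = best_spacer, stringsAsFactors = FALSE)
  else best
}
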