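#' Hypergeometric motif enrichment against dual backgrounds
#'
#' Counts the sequences containing at least one motif hit (best score at or
#' above `threshold`) in the evaluation set and in each background set, and
#' tests enrichment with the hypergeometric upper tail: the population is the
#' pooled evaluation + background sequences, successes are the sequences with
#' a hit, and the sample is the evaluation set. The reported `p_hyper` is the
#' larger (more conservative) of the two backgrounds' p-values. A motif is
#' `significant` when its BH-adjusted p-value (attached later across a
#' candidate set, see [bh_correct()]) is below `p_cutoff` and its fold
#' enrichment exceeds `fold_cutoff` against both backgrounds.
#'
#' @param candidate a `dimeric_pwm`.
#' @param eval_seqs evaluation (peak) sequences.
#' @param bg_genomic_seqs genomic background sequences.
#' @param bg_markov_seqs Markov background sequences.
#' @param threshold score threshold in bits; when `NULL` it is calibrated by
#'   maximum f-measure on (`eval_seqs`, `bg_markov_seqs`).
#' @param p_cutoff,fold_cutoff significance filters (defaults 0.001 and 1.5).
#' @return A one-row data frame: `motif`, `threshold`, `x_eval`,
#'   `hits_genomic`, `hits_markov`, `p_genomic`, `p_markov`, `p_hyper`,
#'   `fold_genomic`, `fold_markov`, `auc`, `q_bh` (`NA` until adjusted),
#'   `significant` (computed on raw p until adjusted).
#' @export
motif_enrichment <- function(candidate, eval_seqs, bg_genomic_seqs,
                             bg_markov_seqs, threshold = NULL,
                             p_cutoff = 0.001, fold_cutoff = 1.5) {
  if (!length(eval_seqs) || !length(bg_genomic_seqs) || !length(bg_markov_seqs))
    stop("all three sequence sets must be non-empty")
  ev <- best_scores(candidate, eval_seqs)
  bg_g <- best_scores(candidate, bg_genomic_seqs)
  bg_m <- best_scores(candidate, bg_markov_seqs)
  if (is.null(threshold))
    threshold <- calibrate_threshold(ev, bg_m)$threshold
  x <- sum(ev >= threshold)
  one_bg <- function(bg) {
    k_bg <- sum(bg >= threshold)
    N <- length(ev) + length(bg)
    K <- x + k_bg
    p <- stats::phyper(x - 1, K, N - K, length(ev), lower.tail = FALSE)
    rate_bg <- k_bg / length(bg)
    fold <- if (rate_bg == 0) Inf else (x / length(ev)) / rate_bg
    list(p = p, fold = fold, hits = k_bg)
  }
  g <- one_bg(bg_g)
  m <- one_bg(bg_m)
  p_hyper <- max(g$p, m$p)
  data.frame(motif = candidate$name, threshold = threshold, x_eval = x,
             hits_genomic = g$hits, hits_markov = m$hits,
             p_genomic = g$p, p_markov = m$p, p_hyper = p_hyper,
             fold_genomic = g$fold, fold_markov = m$fold,
             auc = roc_auc(ev, c(bg_g, bg_m)),
             q_bh = NA_real_,
             significant = p_hyper < p_cutoff & g$fold > fold_cutoff &
               m$fold > fold_cutoff,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`: adjusted
#' values are monotone in rank, at least the raw p, and capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_correct <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Score a set of motif candidates and apply the dual-background filter
#'
#' Runs [motif_enrichment()] for every candidate, BH-adjusts the
#' (conservative, max-over-backgrounds) p-values across candidates, and marks
#' as significant the motifs with adjusted p below `p_cutoff` and more than
#' `fold_cutoff`-fold enrichment against both backgrounds. Set
#' `adjust = FALSE` to filter on raw p-values instead.
#'
#' @param candidates list of `dimeric_pwm` objects.
#' @inheritParams motif_enrichment
#' @param adjust filter on BH-adjusted (default) or raw p-values.
#' @return A data frame with one row per candidate (see [motif_enrichment()]),
#'   with `q_bh` and `significant` filled in.
#' @export
score_candidates <- function(candidates, eval_seqs, bg_genomic_seqs,
                             bg_markov_seqs, threshold = NULL,
                             p_cutoff = 0.001, fold_cutoff = 1.5,
                             adjust = TRUE) {
  res <- do.call(rbind, lapply(candidates, motif_enrichment,
                               eval_seqs = eval_seqs,
                               bg_genomic_seqs = bg_genomic_seqs,
                               bg_markov_seqs = bg_markov_seqs,
                               threshold = threshold,
                               p_cutoff = p_cutoff,
                               fold_cutoff = fold_cutoff))
  res$q_bh <- bh_correct(res$p_hyper)
  p_used <- if (adjust) res$q_bh else res$p_hyper
  res$significant <- p_used < p_cutoff & res$fold_genomic > fold_cutoff &
    res$fold_markov > fold_cutoff
  res
}

#' Select the best-performing significant motif
#'
#' Among significant candidates, picks the one with the highest ROC AUC;
#' ties go to the narrower motif, then to the lexicographically smaller
#' consensus.
#'
#' @param candidates list of `dimeric_pwm` objects.
#' @param results the matching data frame from [score_candidates()].
#' @return The winning `dimeric_pwm`.
#' @export
select_best_motif <- function(candidates, results) {
  keep <- which(results$significant)
  if (!length(keep))
    stop("no significant motif candidates to select from")
  widths <- vapply(candidates[keep], pwm_width, 0L)
  cons <- vapply(candidates[keep], pwm_consensus, "")
  o <- order(-results$auc[keep], widths, cons)
  candidates[[keep[o[1]]]]
}

#' Binomial over-representation of library motifs between two sequence sets
#'
#' For each motif in a library, estimates its per-sequence hit rate in set B
#' and tests whether set A carries more motif-containing sequences than that
#' rate predicts (binomial upper tail). Bonferroni correction uses as factor
#' the number of motifs with at least one hit in either set.
#'
#' @param motif_library list of `dimeric_pwm` objects.
#' @param setA_seqs,setB_seqs character vectors of sequences.
#' @param thresholds numeric vector of per-motif score thresholds (recycled).
#' @return Data frame: `motif`, `x_A`, `rate_B`, `p_binomial`,
#'   `p_bonferroni`, `degenerate` (`TRUE` when the set-B rate is 0 but set A
#'   has hits, which forces p = 0).
#' @export
binomial_overrepresentation <- function(motif_library, setA_seqs, setB_seqs,
                                        thresholds) {
  if (!length(motif_library)) stop("motif library must be non-empty")
  thresholds <- rep_len(thresholds, length(motif_library))
  rows <- lapply(seq_along(motif_library), function(i) {
    m <- motif_library[[i]]
    t <- thresholds[i]
    a <- best_scores(m, setA_seqs) >= t
    b <- best_scores(m, setB_seqs) >= t
    x <- sum(a)
    p_hat <- mean(b)
    p <- if (x == 0) 1
    else stats::pbinom(x - 1, length(setA_seqs), p_hat, lower.tail = FALSE)
    data.frame(motif = m$name, x_A = x, rate_B = p_hat, p_binomial = p,
               any_hit = x > 0 || any(b),
               degenerate = p_hat == 0 && x > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  factor <- max(1L, sum(out$any_hit))
  out$p_bonferroni <- pmin(1, out$p_binomial * factor)
  out$any_hit <- NULL
  out[, c("motif", "x_A", "rate_B", "p_binomial", "p_bonferroni",
          "degenerate")]
}
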