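## Evaluate expr under a fixed RNG seed without disturbing the caller's
## random-number stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Fan a global seed out to a per-component child seed by stable string
## hashing, so adding a component never perturbs the draws of another.
child_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

#' Split peaks into motif-discovery training and evaluation sets
#'
#' Randomly assigns `floor(train_fraction * n)` peaks to the training set and
#' the rest to evaluation; each peak contributes a `window`-bp sequence
#' centred on its summit. Windows extending past a chromosome end are clipped
#' with a warning.
#'
#' @param peaks a `peaks` data frame.
#' @param train_fraction fraction of peaks used for discovery (default 0.2).
#' @param window sequence window in bp centred on the summit (default 200).
#' @param seed integer seed making the split reproducible.
#' @param genome optional FASTA path or `DNAStringSet`; when supplied the
#'   window sequences are extracted and returned.
#' @return A list with `train_idx`, `eval_idx`, `train_regions`,
#'   `eval_regions` (`gintervals`), and — when `genome` is given —
#'   `train_seqs`, `eval_seqs`.
#' @export
split_train_eval <- function(peaks, train_fraction = 0.2, window = 200,
                             seed = 1, genome = NULL) {
  n <- nrow(peaks)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- floor(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  train_idx <- sort(idx)
  eval_idx <- setdiff(seq_len(n), train_idx)
  regions <- summit_window(peaks, window,
                           chrom_lengths = genome_lengths(genome))
  out <- list(train_idx = train_idx, eval_idx = eval_idx,
              train_regions = regions[train_idx, , drop = FALSE],
              eval_regions = regions[eval_idx, , drop = FALSE])
  if (!is.null(genome)) {
    out$train_seqs <- fetch_sequence(genome, out$train_regions)
    out$eval_seqs <- fetch_sequence(genome, out$eval_regions)
  }
  out
}

genome_lengths <- function(genome) {
  if (is.null(genome)) return(NULL)
  g <- load_genome(genome)
  stats::setNames(Biostrings::width(g), names(g))
}

#' Sample a genomic background matched to template regions
#'
#' Draws `n` random genomic regions reproducing the template set's length
#' distribution and per-chromosome proportions (counts allocated by largest
#' remainder, so proportions are matched deterministically). Regions
#' overlapping `exclude` are rejected and resampled.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param template_regions `gintervals` whose lengths/chromosomes to emulate.
#' @param n number of regions.
#' @param seed integer seed.
#' @param exclude optional `gintervals` that sampled regions must not touch.
#' @param max_tries resampling attempts per region before giving up.
#' @return A `gintervals` data frame of `n` rows.
#' @export
sample_genomic_background <- function(genome, template_regions, n, seed = 1,
                                      exclude = NULL, max_tries = 1000) {
  g <- load_genome(genome)
  lens <- genome_lengths(g)
  tab <- table(template_regions$chrom)
  props <- as.numeric(tab) / sum(tab)
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(props * n - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  counts <- stats::setNames(base, names(tab))
  with_seed(seed, {
    rows <- lapply(names(counts), function(ch) {
      k <- counts[[ch]]
      if (k == 0) return(NULL)
      tlens <- interval_length(
        template_regions[template_regions$chrom == ch, , drop = FALSE])
      out_start <- numeric(k)
      out_len <- numeric(k)
      for (i in seq_len(k)) {
        L <- tlens[sample.int(length(tlens), 1)]
        if (L > lens[[ch]]) stop("template longer than chromosome ", ch)
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          s <- sample.int(lens[[ch]] - L + 1, 1) - 1
          if (is.null(exclude) ||
              !any(exclude$chrom == ch & exclude$start < s + L &
                   exclude$end > s)) {
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("could not place a background region on ", ch,
               " outside the excluded intervals")
        out_start[i] <- s
        out_len[i] <- L
      }
      data.frame(chrom = ch, start = out_start, end = out_start + out_len,
                 strand = "*", stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    gintervals(rows$chrom, rows$start, rows$end)
  })
}

#' Generate Markov-model background sequences
#'
#' Fits an order-`order` Markov chain (add-one smoothing) to the training
#' sequences and samples `n` sequences of the given length from it. Order 1
#' matches the training set's dinucleotide frequencies; order 0 reduces to
#' i.i.d. sampling at mononucleotide frequencies.
#'
#' @param seqs training sequences (A/C/G/T; other characters are ignored
#'   during counting).
#' @param order Markov order (0 or more).
#' @param n number of sequences to generate.
#' @param length length of each sequence in bp.
#' @param seed integer seed.
#' @return Character vector of `n` sequences.
#' @export
markov_background <- function(seqs, order = 1, n, length, seed = 1) {
  if (!length(seqs)) stop("training sequences required")
  if (order < 0) stop("order must be >= 0")
  codes <- lapply(seqs, encode_seq)
  if (order == 0) {
    counts <- tabulate(unlist(codes)[unlist(codes) <= 4], 4) + 1
    p <- counts / sum(counts)
    return(with_seed(seed, vapply(seq_len(n), function(i)
      paste(DNA[sample.int(4, length, TRUE, p)], collapse = ""), "")))
  }
  k <- as.integer(order)
  nstates <- 4L^k
  trans <- matrix(1, nstates, 4)  # add-one smoothing
  start_counts <- rep(1, nstates)
  for (cd in codes) {
    cd <- cd[cd <= 4]
    if (length(cd) <= k) next
    ctx <- state_codes(cd, k)
    nxt <- cd[(k + 1):length(cd)]
    for (i in seq_along(nxt))
      trans[ctx[i], nxt[i]] <- trans[ctx[i], nxt[i]] + 1
    start_counts[ctx] <- start_counts[ctx] + 1
  }
  trans <- trans / rowSums(trans)
  cum <- t(apply(trans, 1, cumsum))
  start_p <- start_counts / sum(start_counts)
  with_seed(seed, {
    out <- matrix(0L, n, length)
    state <- sample.int(nstates, n, TRUE, prob = start_p)
    for (j in seq_len(k))  # unpack the initial context into bases
      out[, j] <- ((state - 1L) %/% 4L^(k - j)) %% 4L + 1L
    for (j in (k + 1):length) {
      u <- stats::runif(n)
      nxt <- 1L + (u > cum[state, 1]) + (u > cum[state, 2]) +
        (u > cum[state, 3])
      out[, j] <- nxt
      state <- ((state - 1L) %% 4L^(k - 1L)) * 4L + nxt
    }
    apply(out, 1, function(r) paste(DNA[r], collapse = ""))
  })
}

## Overlapping order-k context codes (1-based) for an encoded A/C/G/T vector:
## positions 1..(L-k) give the context preceding base at position k+i.
state_codes <- function(cd, k) {
  L <- length(cd)
  ctx <- rep(0L, L - k)
  for (j in seq_len(k))
    ctx <- ctx * 4L + (cd[j:(L - k + j - 1)] - 1L)
  ctx + 1L
}
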