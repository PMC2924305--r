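DNA <- c("A", "C", "G", "T")

#' Construct a dimeric position weight matrix
#'
#' p53-family factors bind dimeric sites: two half-sites separated by a short
#' spacer (usually 0 bp). The model stores the two half-site probability
#' matrices, the allowed spacer lengths, and the background nucleotide
#' frequencies used for log-odds scoring. A single-block (monomeric) motif is
#' the degenerate case with an empty second half and spacer 0.
#'
#' @param half_a 4 x w_a column-stochastic matrix over A,C,G,T.
#' @param half_b 4 x w_b matrix, or `NULL` for a single-block motif.
#' @param spacer_range integer vector of allowed gap lengths in bp
#'   (a scalar, or `c(min, max)` expanded to the inclusive range).
#' @param background length-4 nucleotide frequency vector summing to 1.
#' @param name motif identifier.
#' @return An object of class `"dimeric_pwm"`.
#' @export
dimeric_pwm <- function(half_a, half_b = NULL, spacer_range = 0L,
                        background = rep(0.25, 4), name = "motif") {
  half_a <- check_prob_matrix(half_a, "half_a")
  if (!is.null(half_b) && ncol(half_b) > 0)
    half_b <- check_prob_matrix(half_b, "half_b")
  else half_b <- NULL
  if (length(spacer_range) == 2)
    spacer_range <- seq.int(spacer_range[1], spacer_range[2])
  spacer_range <- sort(unique(as.integer(spacer_range)))
  if (any(spacer_range < 0)) stop("spacer lengths must be >= 0")
  if (is.null(half_b)) spacer_range <- 0L
  background <- as.numeric(background)
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0))
    stop("background must be 4 positive frequencies summing to 1")
  names(background) <- DNA
  structure(list(half_a = half_a, half_b = half_b,
                 spacer_range = spacer_range, background = background,
                 name = name),
            class = "dimeric_pwm")
}

check_prob_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (nrow(m) != 4) stop(what, " must have 4 rows (A,C,G,T)")
  rownames(m) <- DNA
  if (any(m < 0)) stop(what, " must be non-negative")
  if (any(abs(colSums(m) - 1) > 1e-9))
    stop(what, " columns must sum to 1")
  m
}

#' Build a PWM from aligned motif instances
#'
#' Column frequencies are `(count + pseudocount) / (n + 4 * pseudocount)`.
#' When `split_at` is supplied the matrix is split into two half-sites after
#' that many columns; the instances themselves must be contiguous (spacers
#' are a property of scanning, not of the alignment).
#'
#' @param instances character vector of equal-length A/C/G/T strings.
#' @param pseudocount non-negative weight added per cell before normalisation.
#' @param background length-4 frequency vector for downstream scoring.
#' @param split_at columns in the first half-site, or `NULL` for a
#'   single-block motif.
#' @param spacer_range allowed spacer lengths for scanning (see
#'   [dimeric_pwm()]).
#' @param name motif identifier.
#' @return A `dimeric_pwm`.
#' @examples
#' build_pwm(c("ACGT", "ACGT"), pseudocount = 0.25)
#' @export
build_pwm <- function(instances, pseudocount = 0.25,
                      background = rep(0.25, 4), split_at = NULL,
                      spacer_range = 0L, name = "motif") {
  if (!length(instances)) stop("at least one instance is required")
  instances <- toupper(instances)
  w <- unique(nchar(instances))
  if (length(w) != 1) stop("instances must all have equal length")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  chars <- matrix(unlist(strsplit(instances, "")), nrow = length(instances),
                  byrow = TRUE)
  counts <- vapply(seq_len(w), function(j)
    vapply(DNA, function(b) sum(chars[, j] == b), 0), numeric(4))
  n_eff <- colSums(counts)  # ambiguous bases don't count toward any base
  freq <- sweep(counts + pseudocount, 2, n_eff + 4 * pseudocount, "/")
  rownames(freq) <- DNA
  if (!is.null(split_at)) {
    if (split_at <= 0 || split_at >= w)
      stop("split_at must fall strictly inside the motif")
    dimeric_pwm(freq[, seq_len(split_at), drop = FALSE],
                freq[, (split_at + 1):w, drop = FALSE],
                spacer_range = spacer_range, background = background,
                name = name)
  } else {
    dimeric_pwm(freq, NULL, background = background, name = name)
  }
}

#' Motif widths and span
#'
#' `pwm_width` is the total number of informative columns; `motif_span` the
#' genomic footprint for a given spacer.
#' @param pwm a `dimeric_pwm`.
#' @return Integer.
#' @export
pwm_width <- function(pwm) {
  ncol(pwm$half_a) + if (is.null(pwm$half_b)) 0L else ncol(pwm$half_b)
}

#' @rdname pwm_width
#' @param spacer gap length in bp.
#' @export
motif_span <- function(pwm, spacer = 0L) {
  pwm_width(pwm) + as.integer(spacer)
}

## Log-odds matrices in bits with a floor of -10 bits per position for
## zero-probability cells; row 5 scores ambiguous bases (N) as 0.
pwm_logodds <- function(pwm, floor = -10) {
  lo <- function(m) {
    x <- log2(sweep(m, 1, pwm$background, "/"))
    x[!is.finite(x) | x < floor] <- floor
    rbind(x, N = 0)
  }
  list(A = lo(pwm$half_a),
       B = if (is.null(pwm$half_b)) NULL else lo(pwm$half_b))
}

#' Consensus sequence of a PWM
#'
#' Highest-probability base per column; the spacer (at its minimum length)
#' is rendered as `N`.
#'
#' @param pwm a `dimeric_pwm`.
#' @return A single string.
#' @export
pwm_consensus <- function(pwm) {
  cons <- function(m) paste(DNA[apply(m, 2, which.max)], collapse = "")
  s <- cons(pwm$half_a)
  if (!is.null(pwm$half_b))
    s <- paste0(s, strrep("N", min(pwm$spacer_range)), cons(pwm$half_b))
  s
}

## Mean information content per column (bits), used as the convergence
## criterion during motif refinement.
pwm_information <- function(pwm) {
  ic <- function(m) sum(apply(m, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  }))
  total <- ic(pwm$half_a) + if (is.null(pwm$half_b)) 0 else ic(pwm$half_b)
  total / pwm_width(pwm)
}

#' Sample motif instances from a PWM
#'
#' Draws each column independently from its probability vector; spacer
#' lengths are drawn uniformly from the allowed range and spacer bases from
#' the background. Used by the synthetic-data generators so planted sites
#' have a realistic score spread rather than consensus-only strength.
#'
#' @param pwm a `dimeric_pwm`.
#' @param n number of instances.
#' @return Character vector of length `n`.
#' @export
sample_pwm_instances <- function(pwm, n = 1) {
  draw <- function(m, k) apply(m, 2, function(p) sample(DNA, k, TRUE, p))
  a <- matrix(draw(pwm$half_a, n), nrow = n)
  out <- apply(a, 1, paste, collapse = "")
  if (!is.null(pwm$half_b)) {
    b <- matrix(draw(pwm$half_b, n), nrow = n)
    spacers <- sample(rep(pwm$spacer_range, 2), n, TRUE)
    gap <- vapply(spacers, function(s)
      paste(sample(DNA, s, TRUE, pwm$background), collapse = ""), "")
    out <- paste0(out, gap, apply(b, 1, paste, collapse = ""))
  }
  out
}

#' @export
print.dimeric_pwm <- function(x, ...) {
  cat(sprintf("dimeric_pwm '%s': half-sites %d + %d bp, spacer %s, consensus %s\n",
              x$name, ncol(x$half_a),
              if (is.null(x$half_b)) 0L else ncol(x$half_b),
              paste(range(x$spacer_range), collapse = "-"),
              pwm_consensus(x)))
  invisible(x)
}

#' Per-column correlation between two PWMs
#'
#' Mean Pearson correlation of matched probability columns at the best
#' ungapped alignment of the two matrices, considering every offset and the
#' reverse complement, with at least half of the shorter motif overlapping.
#' Used to judge whether a discovered motif recovers a planted one.
#'
#' @param a,b `dimeric_pwm` objects (half-sites are concatenated at spacer 0).
#' @return The best mean per-column correlation in `[-1, 1]`.
#' @export
pwm_column_correlation <- function(a, b) {
  full <- function(p) cbind(p$half_a, p$half_b)
  rc <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  ma <- full(a)
  score <- function(mb) {
    wa <- ncol(ma)
    wb <- ncol(mb)
    min_ov <- ceiling(min(wa, wb) / 2)
    best <- -1
    for (off in -(wb - min_ov):(wa - min_ov)) {
      ia <- max(1, 1 + off):min(wa, wb + off)
      ib <- ia - off
      cors <- vapply(seq_along(ia), function(k) {
        ca <- ma[, ia[k]]
        cb <- mb[, ib[k]]
        if (stats::sd(ca) == 0 || stats::sd(cb) == 0) return(1 * all(ca == cb))
        stats::cor(ca, cb)
      }, 0)
      best <- max(best, mean(cors))
    }
    best
  }
  mb <- full(b)
  max(score(mb), score(rc(mb)))
}
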