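#' Construct a per-base conservation score track
#'
#' A score track holds one numeric vector per chromosome with values in
#' `[0, 1]` and `NA` marking bases without data (assembly gaps, unaligned
#' regions).
#'
#' @param scores named list of numeric vectors, one per chromosome.
#' @return An object of class `"score_track"`.
#' @export
score_track <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("score vectors must be named by chromosome")
  for (v in scores) {
    ok <- v[!is.na(v)]
    if (any(ok < 0 | ok > 1))
      stop("conservation scores must lie in [0, 1]")
  }
  structure(list(scores = scores), class = "score_track")
}

#' Read a conservation track from bedGraph or fixed-step wiggle
#'
#' Uses \pkg{rtracklayer} for parsing. Positions not covered by any record
#' are missing (`NA`); chromosome lengths default to the last covered base
#' unless supplied.
#'
#' @param path bedGraph (`.bedgraph`/`.bg`) or wiggle (`.wig`) file.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @param format `"auto"`, `"bedGraph"` or `"wig"`.
#' @return A `score_track`.
#' @export
read_score_track <- function(path, chrom_lengths = NULL,
                             format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bedgraph = "bedGraph", bg = "bedGraph",
                     wig = "wig",
                     stop("cannot infer track format from '.", ext, "'"))
  }
  gr <- rtracklayer::import(path, format = format)
  seqn <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  vals <- gr$score
  chroms <- unique(seqn)
  scores <- lapply(chroms, function(ch) {
    on_ch <- seqn == ch
    s <- starts[on_ch]
    e <- ends[on_ch]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(e)
    w <- e - s + 1
    v <- rep(NA_real_, len)
    v[rep(s, w) + sequence(w) - 1] <- rep(vals[on_ch], w)
    v
  })
  names(scores) <- chroms
  score_track(scores)
}

#' Write a score track as bedGraph
#'
#' Runs of equal, non-missing score are merged into single records.
#'
#' @param track a `score_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$scores)) {
    v <- track$scores[[ch]]
    if (!any(!is.na(v))) next
    runs <- rle(sprintf("%.6g", v))  # NA renders as "NA" and groups missing runs
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths
    keep <- runs$values != "NA"
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                       runs$values[keep]), con)
  }
  invisible(path)
}

#' Mean conservation of a region
#'
#' The region score is the mean per-base conservation over all bases of the
#' interval; bases without data count as 0 (uncovered treated as
#' unconserved), with the covered fraction reported so the alternative
#' reading is auditable.
#'
#' @param track a `score_track`.
#' @param iv a `gintervals` data frame (rows summarised independently).
#' @return Data frame: `chrom`, `start`, `end`, `pccs`, `covered_fraction`.
#' @export
region_mean_score <- function(track, iv) {
  missing <- setdiff(unique(iv$chrom), names(track$scores))
  if (length(missing))
    stop("chromosome(s) absent from track: ",
         paste(missing, collapse = ", "))
  res <- vapply(seq_len(nrow(iv)), function(i) {
    v <- track$scores[[iv$chrom[i]]]
    lo <- iv$start[i] + 1
    hi <- min(iv$end[i], length(v))
    x <- if (lo <= hi) v[lo:hi] else numeric(0)
    n <- iv$end[i] - iv$start[i]  # bases beyond the vector count as missing
    c(sum(x, na.rm = TRUE) / n, sum(!is.na(x)) / n)
  }, numeric(2))
  data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
             pccs = res[1, ], covered_fraction = res[2, ])
}

#' Window of a given size centred on each peak summit
#'
#' Returns `[summit - floor(size/2), summit + ceiling(size/2))`, clipped with
#' a warning at position 0 and — when `chrom_lengths` is supplied — at
#' chromosome ends.
#'
#' @param peaks a `peaks` data frame.
#' @param size window size in bp (odd sizes split floor/ceiling).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return A `gintervals` data frame.
#' @export
summit_window <- function(peaks, size, chrom_lengths = NULL) {
  stopifnot(size >= 2)
  start <- peaks$summit - floor(size / 2)
  end <- peaks$summit + ceiling(size / 2)
  clipped <- start < 0
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[peaks$chrom]
    clipped <- clipped | end > lim
    end <- pmin(end, lim)
  }
  if (any(clipped))
    warning(sum(clipped), " summit window(s) clipped at chromosome bounds")
  gintervals(peaks$chrom, start, end, peaks$strand)
}

#' Cumulative fraction of scores at or above decreasing cutoffs
#'
#' One point per cutoff: the fraction of scores greater than or equal to it,
#' non-decreasing as cutoffs decrease and reaching 1 at or below the minimum
#' observed score.
#'
#' @param scores numeric vector.
#' @param cutoffs cutoff values (any order; returned as given).
#' @return Data frame: `cutoff`, `fraction`.
#' @export
cumulative_curve <- function(scores, cutoffs = seq(1, 0, by = -0.05)) {
  if (!length(scores)) stop("scores must be non-empty")
  data.frame(cutoff = cutoffs,
             fraction = vapply(cutoffs, function(ct) mean(scores >= ct), 0))
}

#' Compare two conservation-score sets
#'
#' Two-sided Mann-Whitney rank-sum test: exact when both sets are small and
#' tie-free, otherwise the normal approximation with tie correction (as
#' implemented by [stats::wilcox.test()]).
#'
#' @param scores_a,scores_b numeric vectors.
#' @return A list with `statistic` (the rank-sum U for `scores_a`), `p_value`
#'   and `auc` (the probability a random `a` exceeds a random `b`).
#' @export
compare_sets <- function(scores_a, scores_b) {
  if (!length(scores_a) || !length(scores_b))
    stop("both score sets must be non-empty")
  exact <- min(length(scores_a), length(scores_b)) <= 8 &&
    !anyDuplicated(c(scores_a, scores_b))
  wt <- suppressWarnings(stats::wilcox.test(scores_a, scores_b,
                                            exact = exact, correct = FALSE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # zero rank variance: the sets are indistinguishable
  list(statistic = unname(wt$statistic),
       p_value = min(p, 1),
       auc = unname(wt$statistic) / (length(scores_a) * length(scores_b)))
}

#' Five-number summaries by quartile of a stratifying variable
#'
#' Ranks `stratify_by` (ties broken by input order), splits the observations
#' into four rank quartiles, and summarises `values` within each: used to
#' relate conservation or motif score to peak height.
#'
#' @param values numeric vector to summarise.
#' @param stratify_by numeric vector defining quartile membership.
#' @return Data frame with one row per quartile: `quartile`, `n`, `min`,
#'   `q1`, `median`, `q3`, `max`.
#' @export
quartile_summary <- function(values, stratify_by) {
  if (length(values) != length(stratify_by))
    stop("values and stratify_by must have equal length")
  n <- length(values)
  if (n < 4) stop("at least 4 observations are required")
  r <- rank(stratify_by, ties.method = "first")
  q <- ceiling(4 * r / n)
  out <- lapply(1:4, function(k) {
    v <- values[q == k]
    f <- stats::fivenum(v)
    data.frame(quartile = k, n = length(v), min = f[1], q1 = f[2],
               median = f[3], q3 = f[4], max = f[5])
  })
  do.call(rbind, out)
}
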