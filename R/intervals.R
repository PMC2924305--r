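#' Construct genomic intervals
#'
#' Intervals are plain data frames with class `"gintervals"` and columns
#' `chrom`, `start`, `end`, `strand`. Coordinates are 0-based half-open
#' throughout the package; conversions from 1-based inclusive ("browser")
#' coordinates happen only at I/O boundaries (see [browser_interval()]).
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, 0-based exclusive end positions.
#' @param strand character vector in `"+"`, `"-"`, `"*"` (unstranded).
#' @return A `gintervals` data frame.
#' @examples
#' gintervals("chr1", 99, 199)
#' @export
gintervals <- function(chrom, start, end, strand = "*") {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  strand = rep_len(as.character(strand),
                                   length.out = length(chrom)),
                  stringsAsFactors = FALSE)
  validate_gintervals(x)
  class(x) <- c("gintervals", "data.frame")
  x
}

validate_gintervals <- function(x) {
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("interval coordinates must be non-missing")
  if (any(x$start < 0))
    stop("interval start must be >= 0")
  bad <- which(x$end <= x$start)
  if (length(bad))
    stop(sprintf("interval end must exceed start (record %d: [%s, %s))",
                 bad[1], x$start[bad[1]], x$end[bad[1]]))
  if (!all(x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(x)
}

#' Convert 1-based inclusive browser coordinates to an internal interval
#'
#' Genome-browser style coordinates (as printed in publications and carried
#' by GTF) are 1-based with an inclusive end. Internally the package uses
#' 0-based half-open coordinates, so browser `(s, e)` maps to `(s - 1, e)`.
#'
#' @param chrom chromosome name.
#' @param start1,end1 1-based inclusive coordinates.
#' @inheritParams gintervals
#' @return A `gintervals` data frame.
#' @examples
#' iv <- browser_interval("chr7", 96030294, 96030493)
#' interval_length(iv)  # 200 bp
#' @export
browser_interval <- function(chrom, start1, end1, strand = "*") {
  gintervals(chrom, as.numeric(start1) - 1, as.numeric(end1), strand)
}

#' Interval length in base pairs
#'
#' @param iv a `gintervals` data frame.
#' @return Numeric vector of lengths, `end - start`.
#' @export
interval_length <- function(iv) {
  iv$end - iv$start
}

#' Distance between two intervals
#'
#' The gap between nearest edges in base pairs; 0 when the intervals overlap
#' or touch, `Inf` when they lie on different chromosomes.
#'
#' @param a,b single-row `gintervals` data frames (or equal-length ones,
#'   compared row-wise).
#' @return Numeric vector of distances.
#' @export
interval_distance <- function(a, b) {
  d <- pmax(a$start, b$start) - pmin(a$end, b$end)
  d <- pmax(d, 0)
  d[a$chrom != b$chrom] <- Inf
  d
}

#' Does an interval lie strictly within the gap separating two others?
#'
#' `TRUE` iff `a` and `b` are disjoint on the same chromosome and `x` is
#' entirely contained in the gap between their nearest edges. An `x` that
#' overlaps `a` or `b` (touching their edges is still inside the gap in
#' half-open coordinates) does not separate them and returns `FALSE` unless
#' fully interior.
#'
#' @param x,a,b single-row `gintervals` data frames.
#' @return Logical.
#' @export
lies_between <- function(x, a, b) {
  if (a$chrom != b$chrom || x$chrom != a$chrom) return(FALSE)
  gap_start <- pmin(a$end, b$end)
  gap_end <- pmax(a$start, b$start)
  if (gap_end <= gap_start) return(FALSE)  # a and b overlap: no gap
  x$start >= gap_start && x$end <= gap_end
}

#' @export
print.gintervals <- function(x, ...) {
  cat(sprintf("gintervals with %d range(s) (0-based half-open)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

## Convert internal intervals to a GRanges (1-based closed) for interop with
## Bioconductor readers/writers.
as_granges <- function(iv, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end),
    strand = ifelse(iv$strand == "*", "*", iv$strand))
  if (!is.null(seqlengths))
    GenomeInfoDb_safe_seqlengths(gr, seqlengths)
  gr
}

GenomeInfoDb_safe_seqlengths <- function(gr, seqlengths) {
  sl <- seqlengths[GenomicRanges::seqnames(GenomicRanges::seqinfo(gr))]
  suppressWarnings(GenomicRanges::seqlengths(gr) <- sl)
  gr
}

from_granges <- function(gr) {
  gintervals(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1,
             GenomicRanges::end(gr),
             as.character(GenomicRanges::strand(gr)))
}
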