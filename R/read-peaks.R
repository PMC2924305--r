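#' Read ChIP-seq peaks from a BED file
#'
#' Accepts 3-7 column BED: `chrom start end [name] [score] [strand] [summit]`.
#' The optional 7th column carries a summit offset relative to `start`
#' (MACS convention). The score column is interpreted as peak height
#' (read count). Peaks without an explicit summit default to the interval
#' midpoint (floor); missing height defaults to 0.
#'
#' @param path path to a BED file.
#' @return A `peaks` data frame with columns `chrom`, `start`, `end`,
#'   `name`, `height`, `strand`, `summit` (absolute position).
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(empty_peaks())
  fields <- strsplit(lines, "[ \t]+")
  nfield <- lengths(fields)
  if (any(nfield < 3))
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 which(nfield < 3)[1]))
  get_col <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  chrom <- get_col(1)
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]))
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop(sprintf("invalid interval at line %d: end must exceed start >= 0",
                 bad[1]))
  name <- get_col(4)
  name[is.na(name)] <- paste0("peak_", which(is.na(name)))
  height <- suppressWarnings(as.numeric(get_col(5)))
  height[is.na(height)] <- 0
  strand <- get_col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  offset <- suppressWarnings(as.numeric(get_col(7)))
  summit <- ifelse(is.na(offset), start + floor((end - start) / 2),
                   start + offset)
  peaks(chrom, start, end, name = name, height = height, summit = summit,
        strand = strand)
}

#' Construct a peaks table
#'
#' @param chrom,start,end,strand as in [gintervals()].
#' @param name peak identifiers (unique names are generated when omitted).
#' @param height non-negative read counts (default 0).
#' @param summit absolute summit positions; defaults to interval midpoints.
#' @return A `peaks` data frame (also a `gintervals`).
#' @export
peaks <- function(chrom, start, end, name = NULL, height = 0, summit = NULL,
                  strand = "*") {
  iv <- gintervals(chrom, start, end, strand)
  n <- nrow(iv)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  if (is.null(summit)) summit <- iv$start + floor((iv$end - iv$start) / 2)
  height <- rep_len(height, n)
  summit <- rep_len(as.numeric(summit), n)
  if (any(height < 0)) stop("peak height must be non-negative")
  if (any(summit < iv$start | summit >= iv$end))
    stop("peak summit must lie within [start, end)")
  iv$name <- as.character(name)
  iv$height <- height
  iv$summit <- summit
  class(iv) <- c("peaks", "gintervals", "data.frame")
  iv
}

empty_peaks <- function() {
  x <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), name = character(),
                  height = numeric(), summit = numeric(),
                  stringsAsFactors = FALSE)
  class(x) <- c("peaks", "gintervals", "data.frame")
  x
}

#' Write peaks back to BED
#'
#' Emits `chrom start end name height strand summit_offset`; reading the file
#' back with [read_peaks_bed()] reproduces the table.
#'
#' @param x a `peaks` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(x, path) {
  strand <- ifelse(x$strand == "*", ".", x$strand)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%d",
                   x$chrom, as.integer(x$start), as.integer(x$end), x$name,
                   format(x$height, trim = TRUE, scientific = FALSE),
                   strand, as.integer(x$summit - x$start))
  writeLines(lines, path)
  invisible(path)
}
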