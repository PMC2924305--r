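#' Read stranded gene models with exon structure
#'
#' Reads BED12 or GTF/GFF3 (exon features grouped by `gene_id`, or by
#' `transcript_id`/`Parent` when no gene attribute is present) via
#' \pkg{rtracklayer} and returns one model per gene. Exons are stored in
#' genomic order; transcription order is derived from strand, so the first
#' exon of a minus-strand gene is its rightmost block. Unstranded records and
#' genes without exons are rejected: the TSS and first-exon/intron categories
#' used downstream are undefined for them.
#'
#' @param path path to a BED12, GTF or GFF3 file (format by extension;
#'   override with `format`).
#' @param format `"auto"`, `"bed"`, `"gtf"` or `"gff3"`.
#' @return A list of gene models, each a list with `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, and `exons` (two-column matrix of 0-based
#'   half-open start/end, genomic order), of class `"gene_models"`.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gtf = "gtf", gff = "gff3",
                     gff3 = "gff3",
                     stop("cannot infer gene-model format from '.", ext, "'"))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    models <- lapply(seq_along(gr), function(i) {
      g <- gr[i]
      blocks <- if (!is.null(g$blocks) && length(g$blocks[[1]]) > 0) {
        b <- g$blocks[[1]]  # block starts are relative, 1-based within gene
        cbind(start = GenomicRanges::start(g) - 1 + (IRanges::start(b) - 1),
              end = GenomicRanges::start(g) - 1 + IRanges::end(b))
      } else {
        cbind(start = GenomicRanges::start(g) - 1,
              end = GenomicRanges::end(g))
      }
      list(gene_id = if (!is.null(g$name) && !is.na(g$name)) g$name
                     else sprintf("gene_%d", i),
           chrom = as.character(GenomicRanges::seqnames(g)),
           start = GenomicRanges::start(g) - 1,
           end = GenomicRanges::end(g),
           strand = as.character(GenomicRanges::strand(g)),
           exons = blocks)
    })
  } else {
    gr <- rtracklayer::import(path, format = format)
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    if (!length(ex)) stop("no exon features found in ", path)
    key <- NULL
    for (attr in c("gene_id", "gene", "transcript_id", "Parent")) {
      v <- S4Vectors::mcols(ex)[[attr]]
      if (!is.null(v)) {
        key <- as.character(v)
        break
      }
    }
    if (is.null(key)) stop("exon features carry no gene/transcript attribute")
    idx <- split(seq_along(ex), key)
    models <- lapply(names(idx), function(id) {
      e <- ex[idx[[id]]]
      strand <- unique(as.character(GenomicRanges::strand(e)))
      chrom <- unique(as.character(GenomicRanges::seqnames(e)))
      if (length(strand) != 1 || length(chrom) != 1)
        stop("gene ", id, " has inconsistent strand or chromosome")
      o <- order(GenomicRanges::start(e))
      list(gene_id = id,
           chrom = chrom,
           start = min(GenomicRanges::start(e)) - 1,
           end = max(GenomicRanges::end(e)),
           strand = strand,
           exons = cbind(start = GenomicRanges::start(e)[o] - 1,
                         end = GenomicRanges::end(e)[o]))
    })
  }
  gene_models(models)
}

#' Assemble gene models from components
#'
#' @param models a list of lists with fields `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `exons` (two-column matrix, 0-based half-open).
#' @return The validated list with class `"gene_models"`.
#' @export
gene_models <- function(models) {
  for (g in models) {
    if (!g$strand %in% c("+", "-"))
      stop("gene ", g$gene_id, " is unstranded; gene models must be stranded")
    if (is.null(g$exons) || nrow(g$exons) == 0)
      stop("gene ", g$gene_id, " has no exons")
    ex <- g$exons
    if (is.unsorted(ex[, "start"]))
      stop("gene ", g$gene_id, ": exons must be sorted by start")
    if (any(ex[, "end"] <= ex[, "start"]))
      stop("gene ", g$gene_id, ": exon end must exceed start")
    if (nrow(ex) > 1 && any(ex[-1, "start"] < ex[-nrow(ex), "end"]))
      stop("gene ", g$gene_id, ": exons overlap")
    if (ex[1, "start"] < g$start || ex[nrow(ex), "end"] > g$end)
      stop("gene ", g$gene_id, ": exons extend beyond the gene interval")
  }
  names(models) <- vapply(models, `[[`, "", "gene_id")
  class(models) <- "gene_models"
  models
}

#' Transcription start site of a gene model
#'
#' The first transcribed base: `start` on the plus strand, `end - 1` on the
#' minus strand.
#'
#' @param gene a single gene model.
#' @return Integer position.
#' @export
gene_tss <- function(gene) {
  if (gene$strand == "+") gene$start else gene$end - 1
}

## Exons in transcription order (first exon first).
exons_tx_order <- function(gene) {
  ex <- gene$exons
  if (gene$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

## First intron in transcription order as c(start, end), or NULL for
## single-exon genes.
first_intron <- function(gene) {
  ex <- exons_tx_order(gene)
  if (nrow(ex) < 2) return(NULL)
  if (gene$strand == "+") c(ex[1, "end"], ex[2, "start"])
  else c(ex[2, "end"], ex[1, "start"])
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d gene(s)\n", length(x)))
  for (g in utils::head(x, 5))
    cat(sprintf("  %s %s:[%d,%d) %s, %d exon(s)\n", g$gene_id, g$chrom,
                g$start, g$end, g$strand, nrow(g$exons)))
  if (length(x) > 5) cat("  ...\n")
  invisible(x)
}
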