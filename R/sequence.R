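#' Load a genome as an in-memory sequence set
#'
#' Small genomes (synthetic scenarios, test fixtures) are held in memory as a
#' [Biostrings::DNAStringSet]. A path is read with
#' [Biostrings::readDNAStringSet()]; FASTA headers are trimmed to the first
#' word so `chr1 description` matches `chr1`.
#'
#' @param genome a FASTA path or a `DNAStringSet`.
#' @return A `DNAStringSet` named by chromosome.
#' @export
load_genome <- function(genome) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("no such file: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a FASTA path or a DNAStringSet")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Fetch the sequence of a genomic interval
#'
#' Returns uppercase A/C/G/T/N of length `interval_length(iv)` for each row
#' of `iv`; minus-strand intervals are reverse-complemented.
#'
#' @param genome a FASTA path or `DNAStringSet` (see [load_genome()]).
#' @param iv a `gintervals` data frame.
#' @return Character vector of sequences.
#' @export
fetch_sequence <- function(genome, iv) {
  genome <- load_genome(genome)
  missing <- setdiff(unique(iv$chrom), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  lens <- Biostrings::width(genome)[match(iv$chrom, names(genome))]
  if (any(iv$end > lens) || any(iv$start < 0))
    stop("interval extends beyond chromosome bounds")
  seqs <- as.character(Biostrings::subseq(
    genome[iv$chrom], start = iv$start + 1, end = iv$end))
  neg <- which(iv$strand == "-")
  if (length(neg))
    seqs[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[neg])))
  toupper(unname(seqs))
}

#' Write a genome to FASTA with a sidecar index
#'
#' @param genome a `DNAStringSet`.
#' @param path output FASTA path; an `.fai` index is written alongside.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70)
  Rsamtools::indexFa(path)
  invisible(path)
}

reverse_complement <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}
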