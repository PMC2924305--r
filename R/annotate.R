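#' Configuration for genomic-category peak classification
#'
#' Defaults follow the standard scheme for binding-site annotation: the TSS
#' flanking region covers 5 kb upstream of the TSS plus the first exon and
#' first intron; intragenic covers the rest of the gene body; "near" covers
#' 5-25 kb upstream of the TSS and up to 25 kb downstream of the gene end;
#' everything else is intergenic. `ptg_window` is the distance within which a
#' peak makes a gene a potential target gene.
#'
#' @param tss_upstream bp upstream of the TSS in the TSS-flanking class.
#' @param near_upstream_max outer upstream bound of the "near" class (bp).
#' @param near_downstream_max downstream bound of the "near" class (bp).
#' @param ptg_window peak-to-gene distance defining potential target genes.
#' @return A list of class `"annotation_config"`.
#' @export
annotation_config <- function(tss_upstream = 5000, near_upstream_max = 25000,
                              near_downstream_max = 25000,
                              ptg_window = 25000) {
  stopifnot(tss_upstream > 0, near_upstream_max > tss_upstream,
            near_downstream_max > 0, ptg_window > 0)
  structure(list(tss_upstream = tss_upstream,
                 near_upstream_max = near_upstream_max,
                 near_downstream_max = near_downstream_max,
                 ptg_window = ptg_window),
            class = "annotation_config")
}

#' Configuration for the CTCF-bounded candidate-element search
#'
#' @param max_distance maximum peak-to-gene distance in bp (default 300 kb).
#' @return A list of class `"domain_config"`.
#' @export
domain_config <- function(max_distance = 300000) {
  stopifnot(max_distance > 0)
  structure(list(max_distance = max_distance), class = "domain_config")
}

peak_categories <- c("TSS_flanking", "intragenic", "near", "intergenic")

#' Classify peaks by genomic category
#'
#' Classifies each peak by its summit position relative to the gene models,
#' strand-aware: `TSS_flanking` (within `tss_upstream` bp upstream of a TSS,
#' or in a first exon or first intron), `intragenic` (elsewhere in a gene
#' body), `near` (5-25 kb upstream of a TSS or up to 25 kb downstream of a
#' gene end), else `intergenic`. When several genes apply the priority is
#' TSS_flanking > intragenic > near, so every peak gets exactly one category.
#'
#' @param peaks a `peaks` data frame.
#' @param genes a `gene_models` list.
#' @param cfg an [annotation_config()].
#' @return A factor over the four categories, one per peak.
#' @export
classify_peaks <- function(peaks, genes, cfg = annotation_config()) {
  classify_summits(peaks$chrom, peaks$summit, category_regions(genes, cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Expand gene models into a flat table of category regions with priorities
## (1 = TSS_flanking, 2 = intragenic, 3 = near); classification of a summit
## is the smallest priority of a region containing it, else intergenic.
category_regions <- function(genes, cfg) {
  rows <- lapply(genes, function(g) {
    tss <- gene_tss(g)
    plus <- g$strand == "+"
    up <- function(d_lo, d_hi) {
      if (plus) c(tss - d_hi, tss - d_lo)
      else c(tss + d_lo + 1, tss + d_hi + 1)
    }
    ex1 <- exons_tx_order(g)[1, ]
    in1 <- first_intron(g)
    down <- if (plus) c(g$end, g$end + cfg$near_downstream_max)
    else c(g$start - cfg$near_downstream_max, g$start)
    r <- rbind(c(up(0, cfg$tss_upstream), 1),
               c(ex1["start"], ex1["end"], 1),
               if (!is.null(in1)) c(in1[1], in1[2], 1),
               c(g$start, g$end, 2),
               c(up(cfg$tss_upstream, cfg$near_upstream_max), 3),
               c(down, 3))
    data.frame(chrom = g$chrom, start = pmax(r[, 1], 0), end = r[, 2],
               priority = r[, 3], stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows)
  if (is.null(regions))
    regions <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), priority = numeric())
  rownames(regions) <- NULL
  regions[regions$end > regions$start, , drop = FALSE]
}

classify_summits <- function(chrom, summit, regions) {
  pr <- rep(4, length(summit))
  for (ch in unique(regions$chrom)) {
    on_ch <- which(chrom == ch)
    if (!length(on_ch)) next
    r <- regions[regions$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(r))) {
      inside <- summit[on_ch] >= r$start[k] & summit[on_ch] < r$end[k]
      pr[on_ch[inside]] <- pmin(pr[on_ch[inside]], r$priority[k])
    }
  }
  factor(peak_categories[pr], levels = peak_categories)
}

#' Permutation test for genomic-category enrichment
#'
#' Builds a null by relocating every peak to a uniform random position on its
#' own chromosome (length and summit offset preserved), re-classifying, and
#' repeating `n_perm` times. The empirical p-value for each category is
#' `(1 + #null counts >= observed) / (1 + n_perm)`.
#'
#' @inheritParams classify_peaks
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return Data frame: `category`, `observed`, `expected` (null mean),
#'   `p_empirical`.
#' @export
category_enrichment <- function(peaks, genes, chrom_lengths,
                                cfg = annotation_config(), n_perm = 999,
                                seed = 1) {
  stopifnot(n_perm >= 1)
  regions <- category_regions(genes, cfg)
  observed <- table(classify_summits(peaks$chrom, peaks$summit, regions))
  lens <- interval_length(peaks)
  off <- peaks$summit - peaks$start
  chr_len <- chrom_lengths[peaks$chrom]
  if (any(is.na(chr_len))) stop("chrom_lengths missing some peak chromosomes")
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      start <- floor(stats::runif(nrow(peaks)) * (chr_len - lens))
      table(classify_summits(peaks$chrom, start + off, regions))
    }, numeric(4))
  })
  data.frame(category = peak_categories,
             observed = as.numeric(observed),
             expected = rowMeans(null_counts),
             p_empirical = (1 + rowSums(null_counts >=
                                          as.numeric(observed))) /
               (1 + n_perm))
}

#' Map peaks to potential target genes
#'
#' A gene is a potential target gene (PTG) when at least one peak interval
#' lies within `ptg_window` bp of the gene interval (overlap counts as
#' distance 0). Mapping is deliberately many-to-many: one peak can support
#' several genes.
#'
#' @inheritParams classify_peaks
#' @return Data frame with one row per (gene, peak) pair: `gene_id`,
#'   `peak`, `distance`.
#' @export
map_to_ptg <- function(peaks, genes, cfg = annotation_config()) {
  rows <- lapply(genes, function(g) {
    same <- which(peaks$chrom == g$chrom)
    if (!length(same)) return(NULL)
    d <- pmax(pmax(g$start - peaks$end[same], peaks$start[same] - g$end), 0)
    hit <- which(d <= cfg$ptg_window)
    if (!length(hit)) return(NULL)
    data.frame(gene_id = g$gene_id, peak = peaks$name[same][hit],
               distance = d[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(), peak = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' CTCF-bounded candidate regulatory elements
#'
#' Pairs each peak with each gene within `max_distance` bp provided no CTCF
#' site lies strictly inside the gap separating them — an insulator must
#' separate peak and gene to break the pair, so CTCF sites overlapping either
#' do not block, and overlapping peak/gene pairs are always retained.
#'
#' @inheritParams classify_peaks
#' @param ctcf_sites a `gintervals` data frame of CTCF binding sites.
#' @param dcfg a [domain_config()].
#' @return Data frame: `gene_id`, `peak`, `distance`, `blocked` is already
#'   filtered out — only retained pairs are returned.
#' @export
candidate_elements <- function(peaks, genes, ctcf_sites,
                               dcfg = domain_config()) {
  rows <- lapply(genes, function(g) {
    same <- which(peaks$chrom == g$chrom)
    if (!length(same)) return(NULL)
    d <- pmax(pmax(g$start - peaks$end[same], peaks$start[same] - g$end), 0)
    near <- same[d <= dcfg$max_distance]
    d <- d[d <= dcfg$max_distance]
    if (!length(near)) return(NULL)
    ctcf <- ctcf_sites[ctcf_sites$chrom == g$chrom, , drop = FALSE]
    keep <- vapply(seq_along(near), function(k) {
      i <- near[k]
      if (d[k] == 0) return(TRUE)  # overlapping pairs always retained
      gap_start <- min(peaks$end[i], g$end)
      gap_end <- max(peaks$start[i], g$start)
      !any(ctcf$start >= gap_start & ctcf$end <= gap_end)
    }, TRUE)
    if (!any(keep)) return(NULL)
    data.frame(gene_id = g$gene_id, peak = peaks$name[near][keep],
               distance = d[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(), peak = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
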