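#' Generate a random genome
#'
#' I.i.d. bases at a specified GC content; deterministic under `seed`.
#'
#' @param chrom_lengths named vector of chromosome lengths (>= 1 kb each).
#' @param gc_content fraction of G+C in `(0, 1]`.
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
make_genome <- function(chrom_lengths, gc_content = 0.41, seed = 1) {
  stopifnot(all(chrom_lengths >= 1000), gc_content > 0, gc_content <= 1)
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  with_seed(child_seed(seed, "genome"), {
    seqs <- vapply(chrom_lengths, function(L)
      paste(sample(DNA, L, TRUE, p), collapse = ""), "")
    Biostrings::DNAStringSet(stats::setNames(seqs, names(chrom_lengths)))
  })
}

#' Generate gene models on a genome
#'
#' Places non-overlapping stranded genes with 2-5 exons at sizes typical of
#' compact vertebrate annotation (exons 100-300 bp, introns 500-3000 bp).
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_genes number of genes.
#' @param min_gap minimum distance between genes in bp; the default keeps the
#'   upstream/downstream annotation windows of neighbouring genes disjoint.
#' @param seed integer seed.
#' @return A `gene_models` list.
#' @export
make_gene_models <- function(chrom_lengths, n_genes, min_gap = 55000,
                             seed = 1) {
  with_seed(child_seed(seed, "genes"), {
    models <- list()
    occupied <- lapply(chrom_lengths, function(x) NULL)
    for (i in seq_len(n_genes)) {
      placed <- FALSE
      for (try in 1:500) {
        ch <- sample(names(chrom_lengths), 1,
                     prob = chrom_lengths / sum(chrom_lengths))
        n_ex <- sample(2:5, 1)
        ex_len <- sample(100:300, n_ex, TRUE)
        in_len <- sample(500:3000, n_ex - 1, TRUE)
        span <- sum(ex_len) + sum(in_len)
        if (span + 2 >= chrom_lengths[[ch]]) next
        s <- sample.int(chrom_lengths[[ch]] - span, 1) - 1
        occ <- occupied[[ch]]
        if (!is.null(occ) &&
            any(occ[, 1] < s + span + min_gap & occ[, 2] > s - min_gap)) next
        starts <- s + cumsum(c(0, utils::head(ex_len, -1) + in_len))
        models[[length(models) + 1]] <- list(
          gene_id = sprintf("gene_%03d", i), chrom = ch,
          start = s, end = s + span,
          strand = sample(c("+", "-"), 1),
          exons = cbind(start = starts, end = starts + ex_len))
        occupied[[ch]] <- rbind(occ, c(s, s + span))
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place gene ", i, " without overlap")
    }
    gene_models(models)
  })
}

#' Plant peaks with embedded motif instances into a genome
#'
#' Places `n` peaks realising `category_mix` against the supplied gene models
#' (all intergenic when `genes` is `NULL`), embeds a PWM-sampled motif
#' instance centred at each summit with probability `planting_rate` (strand
#' uniform), and draws peak heights from a log-normal. Returns the modified
#' genome alongside the peaks and a per-peak ground-truth table.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param n number of peaks.
#' @param pwm the `dimeric_pwm` to plant.
#' @param planting_rate probability a peak carries a motif instance.
#' @param peak_length peak interval length in bp.
#' @param category_mix named numeric vector over the four genomic categories,
#'   summing to 1.
#' @param genes optional `gene_models` (required for non-intergenic
#'   categories).
#' @param cfg an [annotation_config()] used to verify planted categories.
#' @param seed integer seed.
#' @param height_meanlog,height_sdlog log-normal peak-height parameters.
#' @return A list: `genome` (with instances embedded), `peaks`, `truth`
#'   (data frame: `name`, `category`, `planted`, `strand`, `motif_start`,
#'   `spacer`).
#' @export
plant_peaks <- function(genome, n, pwm, planting_rate = 0.94,
                        peak_length = 500,
                        category_mix = c(TSS_flanking = 0.13,
                                         intragenic = 0.30,
                                         near = 0.17,
                                         intergenic = 0.40),
                        genes = NULL, cfg = annotation_config(), seed = 1,
                        height_meanlog = log(30), height_sdlog = 0.8) {
  stopifnot(planting_rate >= 0, planting_rate <= 1)
  category_mix <- category_mix[category_mix > 0]
  if (abs(sum(category_mix) - 1) > 1e-6)
    stop("category_mix must sum to 1")
  if (is.null(genes) && any(names(category_mix) != "intergenic"))
    stop("gene models are required for categories other than intergenic")
  genome <- load_genome(genome)
  chrom_lengths <- genome_lengths(genome)
  seqs <- stats::setNames(as.character(genome), names(genome))
  regions <- if (is.null(genes))
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               priority = numeric())
  else category_regions(genes, cfg)
  quota <- round(category_mix * n)
  quota[1] <- quota[1] + n - sum(quota)
  half <- floor(peak_length / 2)
  with_seed(child_seed(seed, "peaks"), {
    cat_of_peak <- rep(names(quota), quota)
    summits <- vapply(cat_of_peak, function(cat)
      place_summit(cat, regions, chrom_lengths, half), numeric(2))
    chrom <- names(chrom_lengths)[summits[1, ]]
    summit <- summits[2, ]
    planted <- stats::runif(n) < planting_rate
    strand <- sample(c("+", "-"), n, TRUE)
    inst <- sample_pwm_instances(pwm, n)
    inst[strand == "-"] <- reverse_complement(inst[strand == "-"])
    motif_start <- rep(NA_real_, n)
    for (i in which(planted)) {
      w <- nchar(inst[i])
      s <- summit[i] - floor(w / 2)
      substr(seqs[[chrom[i]]], s + 1, s + w) <- inst[i]
      motif_start[i] <- s
    }
    pk <- peaks(chrom, summit - half, summit - half + peak_length,
                name = sprintf("peak_%05d", seq_len(n)),
                height = round(stats::rlnorm(n, height_meanlog,
                                             height_sdlog)),
                summit = summit)
    truth <- data.frame(name = pk$name, category = cat_of_peak,
                        planted = planted,
                        strand = ifelse(planted, strand, NA),
                        motif_start = motif_start,
                        spacer = ifelse(planted,
                                        nchar(inst) - pwm_width(pwm), NA),
                        stringsAsFactors = FALSE)
    list(genome = Biostrings::DNAStringSet(seqs), peaks = pk, truth = truth)
  })
}

## Draw one summit of the requested category: propose inside the matching
## category regions (uniform over the genome for intergenic), verify with the
## classifier, retry up to 200 times. Returns c(chrom index, summit).
place_summit <- function(cat, regions, chrom_lengths, half) {
  pr <- match(cat, peak_categories)
  pool <- regions[regions$priority == pr, , drop = FALSE]
  if (pr < 4 && !nrow(pool))
    stop("no genomic space to place a ", cat, " peak")
  for (try in 1:200) {
    if (pr == 4) {
      ch <- sample(names(chrom_lengths), 1,
                   prob = chrom_lengths / sum(chrom_lengths))
      s <- sample.int(chrom_lengths[[ch]], 1) - 1
    } else {
      k <- sample.int(nrow(pool), 1,
                      prob = pool$end - pool$start)
      ch <- pool$chrom[k]
      s <- pool$start[k] + sample.int(pool$end[k] - pool$start[k], 1) - 1
    }
    if (s - half < 0 || s - half + 2 * half > chrom_lengths[[ch]]) next
    got <- as.character(classify_summits(ch, s, regions))
    if (got == cat)
      return(c(match(ch, names(chrom_lengths)), s))
  }
  stop("could not place a peak of category ", cat)
}

#' Generate a conservation score track with elevated segments
#'
#' Per-base scores are beta-distributed with the stated means (exact constant
#' means when `noise_sd` is 0), elevated inside `elevated_regions`, clipped
#' to `[0, 1]`.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param baseline_mean,elevated_mean means in `[0, 1]`.
#' @param elevated_regions `gintervals` of elevated segments (may be empty).
#' @param noise_sd per-base standard deviation (must satisfy
#'   `noise_sd^2 < mean * (1 - mean)` for both means).
#' @param seed integer seed.
#' @return A list: `track` (a `score_track`), `truth` (the elevated regions).
#' @export
make_conservation_track <- function(chrom_lengths, baseline_mean = 0.10,
                                    elevated_regions = NULL,
                                    elevated_mean = 0.60, noise_sd = 0.10,
                                    seed = 1) {
  stopifnot(baseline_mean >= 0, baseline_mean <= 1,
            elevated_mean >= 0, elevated_mean <= 1, noise_sd >= 0)
  rbeta_mean <- function(k, m) {
    if (noise_sd == 0) return(rep(m, k))
    v <- noise_sd^2
    if (v >= m * (1 - m))
      stop("noise_sd too large for a beta distribution with mean ", m)
    nu <- m * (1 - m) / v - 1
    stats::rbeta(k, m * nu, (1 - m) * nu)
  }
  with_seed(child_seed(seed, "conservation"), {
    scores <- lapply(chrom_lengths, function(L) rbeta_mean(L, baseline_mean))
    names(scores) <- names(chrom_lengths)
    if (!is.null(elevated_regions)) {
      for (i in seq_len(nrow(elevated_regions))) {
        ch <- elevated_regions$chrom[i]
        idx <- (elevated_regions$start[i] + 1):elevated_regions$end[i]
        scores[[ch]][idx] <- rbeta_mean(length(idx), elevated_mean)
      }
    }
    list(track = score_track(scores),
         truth = elevated_regions %||%
           gintervals(character(0), numeric(0), numeric(0)))
  })
}

#' Generate CTCF-like insulator site intervals
#'
#' Uniformly placed fixed-width sites, the boundary set for the
#' candidate-element search.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n number of sites.
#' @param width site width in bp (default 200).
#' @param seed integer seed.
#' @return A `gintervals` data frame.
#' @export
make_ctcf_sites <- function(chrom_lengths, n, width = 200, seed = 1) {
  with_seed(child_seed(seed, "ctcf"), {
    ch <- sample(names(chrom_lengths), n, TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    s <- vapply(ch, function(c1)
      sample.int(chrom_lengths[[c1]] - width, 1) - 1, 0)
    o <- order(ch, s)
    gintervals(ch[o], s[o], s[o] + width)
  })
}

#' Generate a disease-by-term matrix with one planted cluster
#'
#' Background cells are Bernoulli(`background_density`); the first
#' `cluster_size` diseases additionally share a dense block of
#' `cluster_term_block` terms (each present with probability
#' `cluster_block_density`), giving them elevated pairwise similarity.
#'
#' @param n_diseases,n_terms matrix dimensions.
#' @param cluster_size diseases in the planted cluster (0 for none).
#' @param cluster_term_block terms in the shared block.
#' @param background_density Bernoulli rate outside the block.
#' @param cluster_block_density Bernoulli rate inside the block.
#' @param seed integer seed.
#' @return A list: `matrix` (binary, diseases x terms), `truth` (data frame
#'   `disease`, `clustered`).
#' @export
make_disease_matrix <- function(n_diseases = 2033, n_terms = 400,
                                cluster_size = 904, cluster_term_block = 40,
                                background_density = 0.08,
                                cluster_block_density = 0.5, seed = 1) {
  stopifnot(cluster_size <= n_diseases, cluster_term_block <= n_terms)
  with_seed(child_seed(seed, "diseases"), {
    m <- matrix(stats::rbinom(n_diseases * n_terms, 1, background_density),
                n_diseases, n_terms,
                dimnames = list(sprintf("disease_%04d", seq_len(n_diseases)),
                                sprintf("term_%03d", seq_len(n_terms))))
    if (cluster_size > 0 && cluster_term_block > 0) {
      block <- matrix(stats::rbinom(cluster_size * cluster_term_block, 1,
                                    cluster_block_density),
                      cluster_size, cluster_term_block)
      m[seq_len(cluster_size), seq_len(cluster_term_block)] <-
        pmax(m[seq_len(cluster_size), seq_len(cluster_term_block)], block)
    }
    empty <- rowSums(m) == 0
    if (any(empty)) {  # every disease must carry at least one term
      fill <- sample.int(n_terms, sum(empty), TRUE)
      m[cbind(which(empty), fill)] <- 1
    }
    storage.mode(m) <- "double"
    list(matrix = validate_disease_matrix(m),
         truth = data.frame(disease = rownames(m),
                            clustered = seq_len(n_diseases) <= cluster_size,
                            stringsAsFactors = FALSE))
  })
}
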