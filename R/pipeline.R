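#' Default synthetic scenario parameters
#'
#' A compact genome (two chromosomes, 500 kb and 300 kb), a dimeric 8+8 bp
#' motif, 300 peaks at the package's default category mix and planting rate,
#' a conservation track elevated under the peak summits, 40 CTCF sites, and a
#' disease matrix with one planted cluster.
#'
#' @param seed global integer seed fanned out to per-generator child seeds.
#' @return A named list of scenario parameters.
#' @export
default_scenario <- function(seed = 1) {
  list(seed = seed,
       chrom_lengths = c(chr1 = 500000, chr2 = 300000),
       gc_content = 0.41,
       n_genes = 8,
       n_peaks = 300,
       peak_length = 500,
       planting_rate = 0.94,
       motif_instances = c("AACATGTTAACATGTT", "AACATGTCGACATGTT",
                           "AGCATGTTAACATGCT", "AACATGTTTACATGTT",
                           "CACATGTTAACATGTG", "AACGTGTTAACATGTT"),
       motif_split = 8,
       n_ctcf = 40,
       baseline_mean = 0.10, elevated_mean = 0.60, noise_sd = 0.10,
       n_diseases = 400, n_terms = 200, cluster_size = 60,
       cluster_term_block = 25, background_density = 0.08)
}

#' Generate a full synthetic scenario on disk
#'
#' Writes every input the pipeline consumes — genome FASTA (+ index), gene
#' models (BED12), peaks (BED), conservation track (bedGraph), CTCF sites
#' (BED), motif (MEME format), disease matrix (TSV) — plus ground-truth
#' tables for peaks, conservation and diseases.
#'
#' @param out_dir output directory (created if needed).
#' @param scenario parameter list, see [default_scenario()].
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_scenario <- function(out_dir, scenario = default_scenario()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- scenario
  p <- function(f) file.path(out_dir, f)
  pwm <- build_pwm(sc$motif_instances, pseudocount = 0.25,
                   split_at = sc$motif_split, name = "planted_dimer")
  genome <- make_genome(sc$chrom_lengths, sc$gc_content, sc$seed)
  genes <- make_gene_models(sc$chrom_lengths, sc$n_genes, sc$seed)
  planted <- plant_peaks(genome, sc$n_peaks, pwm, sc$planting_rate,
                         sc$peak_length, genes = genes, seed = sc$seed)
  cons <- make_conservation_track(
    sc$chrom_lengths, sc$baseline_mean,
    summit_window(planted$peaks, 100, sc$chrom_lengths),
    sc$elevated_mean, sc$noise_sd, sc$seed)
  ctcf <- make_ctcf_sites(sc$chrom_lengths, sc$n_ctcf, seed = sc$seed)
  dm <- make_disease_matrix(sc$n_diseases, sc$n_terms, sc$cluster_size,
                            sc$cluster_term_block, sc$background_density,
                            seed = sc$seed)
  write_genome_fasta(planted$genome, p("genome.fa"))
  write_gene_models_bed12(genes, p("genes.bed"))
  write_peaks_bed(planted$peaks, p("peaks.bed"))
  write_score_track(cons$track, p("conservation.bedgraph"))
  writeLines(sprintf("%s\t%d\t%d\tctcf_%03d", ctcf$chrom,
                     as.integer(ctcf$start), as.integer(ctcf$end),
                     seq_len(nrow(ctcf))), p("ctcf.bed"))
  write_meme_motifs(pwm, p("motif.meme"))
  write_disease_matrix(dm$matrix, p("disease_matrix.tsv"))
  writeLines(dm$truth$disease[dm$truth$clustered], p("disease_set.txt"))
  write_tsv(planted$truth, p("truth_peaks.tsv"))
  write_tsv(as.data.frame(cons$truth), p("truth_conservation.tsv"))
  write_tsv(dm$truth, p("truth_diseases.tsv"))
  invisible(list(genome = p("genome.fa"), genes = p("genes.bed"),
                 peaks = p("peaks.bed"), track = p("conservation.bedgraph"),
                 ctcf = p("ctcf.bed"), motif = p("motif.meme"),
                 disease_matrix = p("disease_matrix.tsv"),
                 disease_set = p("disease_set.txt")))
}

#' Write gene models as BED12
#'
#' @param genes a `gene_models` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    sizes <- g$exons[, "end"] - g$exons[, "start"]
    rel <- g$exons[, "start"] - g$start
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            g$chrom, as.integer(g$start), as.integer(g$end), g$gene_id,
            g$strand, as.integer(g$start), as.integer(g$end),
            nrow(g$exons),
            paste0(paste(as.integer(sizes), collapse = ","), ","),
            paste0(paste(as.integer(rel), collapse = ","), ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis end to end in dependency order:
#' `simulate` (when `config$scenario` is given) or input loading, `scan`
#' (threshold calibration on a Markov background and motif scanning of all
#' peaks), `enrich` (dual-background hypergeometric enrichment of the motif),
#' `annotate` (genomic-category classification and potential-target-gene
#' mapping), `conserve` (summit-window conservation and cumulative curve,
#' compared against random regions), `domains` (CTCF-bounded candidate
#' elements), and `phenosim` (disease-set similarity with resampling null and
#' term ranking). Every stage writes TSV/BED artifacts under `out_dir` and is
#' recorded in a JSON manifest; a rerun with the same config reproduces the
#' artifacts byte for byte (the timestamped `run.log` aside).
#'
#' @param config a named list: `out_dir`, `seed`, and either `scenario`
#'   (see [default_scenario()]) or explicit input paths `genome`, `peaks`,
#'   `genes`, `track`, `ctcf`, `motif`, `disease_matrix`, `disease_set`.
#'   Optional parameter blocks: `annotation` ([annotation_config()]),
#'   `domain` ([domain_config()]), `scan_window` (default 200),
#'   `train_fraction` (default 0.2), `n_resamples` (default 999).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  acfg <- config$annotation %||% annotation_config()
  dcfg <- config$domain %||% domain_config()
  window <- config$scan_window %||% 200
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  manifest <- list(package = "regupeaks",
                   version = as.character(utils::packageVersion("regupeaks")),
                   seed = seed, stages = list())
  t_all <- Sys.time()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      log_line(log_path, sprintf("stage %s FAILED: %s", name,
                                 conditionMessage(e)))
      writeLines(name, file.path(out_dir, "FAILED_STAGE"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line(log_path, sprintf("stage %s done in %.1fs (%d records)", name,
                               as.numeric(Sys.time() - t0, units = "secs"),
                               res$n %||% NA_integer_))
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(name = name, outputs = res$outputs %||% character(0),
           n_records = res$n %||% NA_integer_)
    res
  }

  inputs <- if (!is.null(config$scenario)) {
    stage("simulate", function() {
      paths <- simulate_scenario(file.path(out_dir, "inputs"),
                                 config$scenario)
      list(outputs = unlist(lapply(paths, basename), use.names = FALSE),
           n = length(paths), paths = paths)
    })$paths
  } else {
    needed <- c("genome", "peaks", "genes", "track", "ctcf", "motif",
                "disease_matrix", "disease_set")
    stage("simulate", function() {
      missing <- needed[vapply(needed, function(k)
        is.null(config[[k]]) || !file.exists(config[[k]]), TRUE)]
      if (length(missing))
        stop("missing input(s): ", paste(missing, collapse = ", "))
      list(outputs = character(0), n = length(needed))
    })
    config[needed]
  }

  genome <- load_genome(inputs$genome)
  chrom_lengths <- genome_lengths(genome)
  pk <- read_peaks_bed(inputs$peaks)
  genes <- read_gene_models(inputs$genes)
  pwm <- read_meme_motifs(inputs$motif)[[1]]

  scan_res <- stage("scan", function() {
    split <- split_train_eval(pk, config$train_fraction %||% 0.2, window,
                              seed = child_seed(seed, "split"),
                              genome = genome)
    bg_markov <- markov_background(split$train_seqs, 1,
                                   n = max(200, length(split$train_seqs)),
                                   length = window,
                                   seed = child_seed(seed, "markov"))
    cal <- calibrate_threshold(best_scores(pwm, split$train_seqs),
                               best_scores(pwm, bg_markov))
    all_seqs <- fetch_sequence(genome,
                               summit_window(pk, window, chrom_lengths))
    sc <- best_scores(pwm, all_seqs)
    hits <- data.frame(name = pk$name, best_score = sc,
                       has_motif = sc >= cal$threshold)
    write_tsv(hits, file.path(out_dir, "motif_hits.tsv"))
    write_tsv(data.frame(threshold = cal$threshold,
                         f_measure = cal$f_measure,
                         estimated_fdr = cal$estimated_fdr),
              file.path(out_dir, "calibration.tsv"))
    list(outputs = c("motif_hits.tsv", "calibration.tsv"), n = nrow(hits),
         split = split, bg_markov = bg_markov, cal = cal, hits = hits)
  })

  stage("enrich", function() {
    split <- scan_res$split
    bg_gen <- sample_genomic_background(genome, split$eval_regions,
                                        n = length(split$eval_idx),
                                        seed = child_seed(seed, "bg"))
    enr <- motif_enrichment(pwm, split$eval_seqs,
                            fetch_sequence(genome, bg_gen),
                            scan_res$bg_markov,
                            threshold = scan_res$cal$threshold)
    enr$q_bh <- bh_correct(enr$p_hyper)
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    list(outputs = "enrichment.tsv", n = nrow(enr))
  })

  stage("annotate", function() {
    categories <- classify_peaks(pk, genes, acfg)
    ann <- data.frame(name = pk$name, category = as.character(categories))
    ptg <- map_to_ptg(pk, genes, acfg)
    write_tsv(ann, file.path(out_dir, "peak_categories.tsv"))
    write_tsv(ptg, file.path(out_dir, "ptg.tsv"))
    list(outputs = c("peak_categories.tsv", "ptg.tsv"), n = nrow(ann))
  })

  stage("conserve", function() {
    track <- read_score_track(inputs$track, chrom_lengths)
    win <- summit_window(pk, 100, chrom_lengths)
    cs <- region_mean_score(track, win)
    cs <- cbind(name = pk$name, cs)
    rnd <- sample_genomic_background(genome, win, n = nrow(pk),
                                     seed = child_seed(seed, "cons_bg"))
    cs_rnd <- region_mean_score(track, rnd)
    cmp <- compare_sets(cs$pccs, cs_rnd$pccs)
    curve <- cumulative_curve(cs$pccs)
    write_tsv(cs, file.path(out_dir, "conservation.tsv"))
    write_tsv(curve, file.path(out_dir, "conservation_curve.tsv"))
    write_tsv(data.frame(statistic = cmp$statistic, p_value = cmp$p_value,
                         auc = cmp$auc),
              file.path(out_dir, "conservation_test.tsv"))
    list(outputs = c("conservation.tsv", "conservation_curve.tsv",
                     "conservation_test.tsv"), n = nrow(cs))
  })

  stage("domains", function() {
    ctcf <- read_peaks_bed(inputs$ctcf)
    cand <- candidate_elements(pk, genes, ctcf, dcfg)
    write_tsv(cand, file.path(out_dir, "candidate_elements.tsv"))
    list(outputs = "candidate_elements.tsv", n = nrow(cand))
  })

  stage("phenosim", function() {
    m <- read_disease_matrix(inputs$disease_matrix)
    dset <- readLines(inputs$disease_set)
    dset <- dset[nzchar(dset)]
    obs <- set_similarity(m, dset)
    null <- resampling_null(m, length(dset),
                            n_samples = config$n_resamples %||% 999,
                            seed = child_seed(seed, "phenosim"),
                            observed = obs)
    ranked <- term_overrepresentation(m, dset)
    write_tsv(data.frame(set_score = obs, null_mean = null$null_mean,
                         p_empirical = null$p_empirical),
              file.path(out_dir, "phenosim.tsv"))
    write_tsv(ranked, file.path(out_dir, "term_ranking.tsv"))
    list(outputs = c("phenosim.tsv", "term_ranking.tsv"), n = nrow(ranked))
  })

  manifest$config <- config_for_manifest(config)
  manifest$artifact_md5 <- artifact_checksums(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line(log_path, sprintf("pipeline done in %.1fs",
                             as.numeric(Sys.time() - t_all, units = "secs")))
  invisible(manifest)
}

log_line <- function(path, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  message(line)
}

## The manifest records the config verbatim except the output directory
## (recorded as ".") so reruns into different directories stay comparable.
config_for_manifest <- function(config) {
  config$out_dir <- "."
  for (k in c("genome", "peaks", "genes", "track", "ctcf", "motif",
              "disease_matrix", "disease_set"))
    if (!is.null(config[[k]])) config[[k]] <- basename(config[[k]])
  config
}

artifact_checksums <- function(out_dir) {
  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- files[!files %in% c("run.log", "manifest.json")]
  files <- files[!grepl("\\.fai$", files)]
  md5 <- tools::md5sum(file.path(out_dir, files))
  stats::setNames(as.list(unname(md5)), files)
}
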