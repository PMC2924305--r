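#' Write motifs in MEME minimal format
#'
#' Emits standard MEME minimal motif format. The dimeric structure (split
#' point and spacer range), which MEME format cannot express, is carried in a
#' comment line `# dimer: split=<k> spacer=<min>-<max>` directly after each
#' letter-probability matrix; MEME-suite parsers ignore comment lines and
#' [read_meme_motifs()] restores the structure from them.
#'
#' @param pwms a `dimeric_pwm` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(pwms, path) {
  if (methods::is(pwms, "dimeric_pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  out <- c("MEME version 4", "",
           "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
           "")
  for (p in pwms) {
    m <- cbind(p$half_a, p$half_b)
    out <- c(out,
             sprintf("MOTIF %s", p$name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     ncol(m)),
             apply(m, 2, function(col) sprintf("%.6f %.6f %.6f %.6f",
                                               col[1], col[2], col[3], col[4])),
             sprintf("# dimer: split=%d spacer=%d-%d",
                     if (is.null(p$half_b)) 0L else ncol(p$half_a),
                     min(p$spacer_range), max(p$spacer_range)),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' Parses MEME minimal motif files, restoring dimeric structure from the
#' `# dimer:` sidecar comment when present (motifs without it load as
#' single-block PWMs).
#'
#' @param path a MEME-format motif file.
#' @return A list of `dimeric_pwm` objects, named by motif.
#' @export
read_meme_motifs <- function(path) {
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    tok <- strsplit(lines[bg_at[1] + 1], "\\s+")[[1]]
    bg <- as.numeric(tok[seq(2, 8, by = 2)])
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF records in ", path)
  out <- lapply(starts, function(i) {
    name <- strsplit(lines[i], "\\s+")[[1]][2]
    j <- i + 1
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j]))
      j <- j + 1
    if (j > length(lines)) stop("motif ", name, ": no probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1):(j + w)]
    m <- t(vapply(strsplit(rows, "\\s+"),
                  function(x) as.numeric(x[1:4]), numeric(4)))
    m <- t(m)  # 4 x w
    m <- sweep(m, 2, colSums(m), "/")  # renormalise printed roundings
    split <- 0L
    spacer <- c(0L, 0L)
    k <- j + w + 1
    if (k <= length(lines) && grepl("^# dimer:", lines[k])) {
      split <- as.integer(sub(".*split=(\\d+).*", "\\1", lines[k]))
      spacer <- as.integer(strsplit(
        sub(".*spacer=(\\d+-\\d+).*", "\\1", lines[k]), "-")[[1]])
    }
    if (split > 0)
      dimeric_pwm(m[, seq_len(split), drop = FALSE],
                  m[, (split + 1):w, drop = FALSE],
                  spacer_range = spacer, background = bg, name = name)
    else
      dimeric_pwm(m, NULL, background = bg, name = name)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
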