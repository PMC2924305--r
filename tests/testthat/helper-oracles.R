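# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles are deliberately naive re-derivations, kept free of the
# package's scanning/counting code paths.

random_dna <- function(n, len, seed,
                       p = c(0.295, 0.205, 0.205, 0.295)) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, p), collapse = ""), "")
}

# Exhaustive placement enumeration: best log-odds score over positions x
# strands x spacers, computed base by base from the probability matrices.
brute_best_score <- function(pwm, seq, floor = -10) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  lo_col <- function(m, j, base) {
    if (base == "N" || !base %in% rownames(m)) return(0)
    max(log2(m[base, j] / pwm$background[base]), floor)
  }
  score_at <- function(s, pos, spacer) {
    chars <- strsplit(s, "")[[1]]
    total <- 0
    for (j in seq_len(ncol(pwm$half_a)))
      total <- total + lo_col(pwm$half_a, j, chars[pos + j - 1])
    if (!is.null(pwm$half_b)) {
      off <- pos + ncol(pwm$half_a) + spacer
      for (j in seq_len(ncol(pwm$half_b)))
        total <- total + lo_col(pwm$half_b, j, chars[off + j - 1])
    }
    total
  }
  wa <- ncol(pwm$half_a)
  wb <- if (is.null(pwm$half_b)) 0 else ncol(pwm$half_b)
  best <- -Inf
  for (s in c(seq, rc(seq))) {
    for (sp in pwm$spacer_range) {
      span <- wa + sp + wb
      if (nchar(s) < span) next
      for (pos in 1:(nchar(s) - span + 1))
        best <- max(best, score_at(s, pos, sp))
    }
  }
  best
}

# Hypergeometric upper tail by direct summation over the urn outcomes.
hyper_tail_enum <- function(x, K, N, n) {
  j <- seq(max(x, 0), min(K, n))
  if (!length(j) || x > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Binomial upper tail by direct summation.
binom_tail_enum <- function(x, n, p) {
  if (x <= 0) return(1)
  j <- x:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# Exact two-sided Mann-Whitney p by enumerating every group assignment of the
# pooled (tie-free) values; matches the classic exact two-sided convention.
mw_exact_enum <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n <- length(a)
  m <- length(b)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  if (u_obs > n * m / 2) p <- 2 * mean(us >= u_obs)
  else p <- 2 * mean(us <= u_obs)
  min(1, p)
}

# A strongly informative two-block test motif.
toy_dimer <- function(spacer_range = 0L) {
  build_pwm(c("AACATGTT", "AACATGTC", "AGCATGTT", "AACATGTT"),
            pseudocount = 0.25, split_at = 4, spacer_range = spacer_range,
            name = "toy_dimer")
}

toy_genes <- function() {
  gene_models(list(
    list(gene_id = "gplus", chrom = "chr1", start = 10000, end = 20000,
         strand = "+",
         exons = cbind(start = c(10000, 12000, 15000),
                       end = c(10200, 12300, 20000))),
    list(gene_id = "gminus", chrom = "chr1", start = 60000, end = 70000,
         strand = "-",
         exons = cbind(start = c(60000, 68000),
                       end = c(61000, 70000))),
    list(gene_id = "gchr2", chrom = "chr2", start = 30000, end = 34000,
         strand = "+",
         exons = cbind(start = c(30000, 32000),
                       end = c(30500, 34000)))))
}

sample_pwm_instances_seeded <- function(pwm, n, seed) {
  set.seed(seed)
  sample_pwm_instances(pwm, n)
}
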