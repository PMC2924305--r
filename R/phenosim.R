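#' Read a disease-by-feature-term matrix from TSV
#'
#' Rows are diseases, columns are feature terms, cells are non-negative
#' weights (binary presence or text-mining weights). The first column holds
#' disease identifiers.
#'
#' @param path TSV path with a header of term identifiers.
#' @return A numeric matrix with disease rownames and term colnames.
#' @export
read_disease_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_disease_matrix(m)
}

validate_disease_matrix <- function(m) {
  if (any(m < 0)) stop("term weights must be non-negative")
  if (anyDuplicated(rownames(m))) stop("duplicate disease identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate term identifiers")
  if (any(rowSums(m) == 0))
    stop("every disease must carry at least one nonzero term")
  m
}

#' Write a disease-by-term matrix to TSV
#'
#' @param m a disease-by-term matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disease_matrix <- function(m, path) {
  df <- data.frame(disease = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cosine similarity between two disease term vectors
#'
#' 0 means no term overlap, 1 identical term profiles.
#'
#' @param d1,d2 non-negative weight vectors of equal length.
#' @return A value in `[0, 1]`.
#' @export
pairwise_similarity <- function(d1, d2) {
  n1 <- sqrt(sum(d1^2))
  n2 <- sqrt(sum(d2^2))
  if (n1 == 0 || n2 == 0) stop("term vectors must be nonzero")
  sum(d1 * d2) / (n1 * n2)
}

#' Mean pairwise similarity of a disease set
#'
#' The arithmetic mean of cosine similarity over all unordered pairs in the
#' set.
#'
#' @param m a disease-by-term matrix.
#' @param disease_set disease identifiers (or row indices), at least 2.
#' @return A value in `[0, 1]`.
#' @export
set_similarity <- function(m, disease_set) {
  idx <- resolve_diseases(m, disease_set)
  if (length(idx) < 2) stop("the disease set must contain at least 2 diseases")
  x <- m[idx, , drop = FALSE]
  x <- x / sqrt(rowSums(x^2))
  s <- tcrossprod(x)
  k <- length(idx)
  (sum(s) - k) / (k * (k - 1))  # off-diagonal mean; diagonal is exactly k
}

resolve_diseases <- function(m, disease_set) {
  if (is.numeric(disease_set)) return(as.integer(disease_set))
  idx <- match(disease_set, rownames(m))
  if (any(is.na(idx)))
    stop("unknown disease(s): ",
         paste(disease_set[is.na(idx)], collapse = ", "))
  idx
}

#' Resampling null for a disease-set similarity score
#'
#' Draws `n_samples` uniform without-replacement sets of the same size and
#' computes their mean pairwise similarity; the empirical p-value for the
#' observed score is `(1 + #null >= observed) / (1 + n_samples)`, so it is
#' never exactly 0.
#'
#' @param m a disease-by-term matrix.
#' @param set_size number of diseases per resampled set.
#' @param n_samples number of resamples (default 999).
#' @param seed integer seed.
#' @param observed optional observed score to test.
#' @return A list with `null_scores`, `null_mean`, and — when `observed` is
#'   given — `observed` and `p_empirical`.
#' @export
resampling_null <- function(m, set_size, n_samples = 999, seed = 1,
                            observed = NULL) {
  stopifnot(set_size >= 2, set_size <= nrow(m), n_samples >= 1)
  xn <- m / sqrt(rowSums(m^2))
  null_scores <- with_seed(seed, vapply(seq_len(n_samples), function(i) {
    idx <- sample.int(nrow(m), set_size)
    s <- tcrossprod(xn[idx, , drop = FALSE])
    (sum(s) - set_size) / (set_size * (set_size - 1))
  }, 0))
  out <- list(null_scores = null_scores, null_mean = mean(null_scores))
  if (!is.null(observed)) {
    out$observed <- observed
    out$p_empirical <- (1 + sum(null_scores >= observed)) / (1 + n_samples)
  }
  out
}

#' Rank feature terms over-represented in a disease set
#'
#' Per term, tests whether the diseases of the set carry the term more often
#' than the whole matrix predicts (hypergeometric upper tail on the count of
#' set diseases with nonzero weight), and ranks terms by ascending p.
#'
#' @param m a disease-by-term matrix.
#' @param disease_set disease identifiers or row indices.
#' @return Data frame ranked by `p_hyper`: `term`, `in_set`, `in_matrix`,
#'   `p_hyper`.
#' @export
term_overrepresentation <- function(m, disease_set) {
  idx <- resolve_diseases(m, disease_set)
  present <- m > 0
  K_all <- colSums(present)
  x_set <- colSums(present[idx, , drop = FALSE])
  N <- nrow(m)
  n <- length(idx)
  p <- stats::phyper(x_set - 1, K_all, N - K_all, n, lower.tail = FALSE)
  out <- data.frame(term = colnames(m), in_set = x_set, in_matrix = K_all,
                    p_hyper = p, stringsAsFactors = FALSE)
  out <- out[order(out$p_hyper, -out$in_set, out$term), ]
  rownames(out) <- NULL
  out
}

#' Enrichment of query terms among the top fraction of ranked terms
#'
#' Tests by hypergeometric upper tail whether the query terms fall into the
#' top `ceiling(k_fraction * n_terms)` of the over-representation ranking
#' more often than chance.
#'
#' @param ranked_terms output of [term_overrepresentation()] (or any data
#'   frame with a `term` column in rank order).
#' @param query_terms character vector of terms, all present in the ranking.
#' @param k_fraction top fraction of the ranking to consider (default 0.10).
#' @return A list with `overlap`, `top_size`, `p_hyper`.
#' @export
top_k_enrichment <- function(ranked_terms, query_terms, k_fraction = 0.10) {
  if (!length(query_terms)) stop("query term set must be non-empty")
  all_terms <- ranked_terms$term
  if (!all(query_terms %in% all_terms))
    stop("query terms absent from the ranking: ",
         paste(setdiff(query_terms, all_terms), collapse = ", "))
  n_terms <- length(all_terms)
  top_size <- ceiling(k_fraction * n_terms)
  top <- all_terms[seq_len(min(top_size, n_terms))]
  x <- sum(query_terms %in% top)
  p <- stats::phyper(x - 1, length(top), n_terms - length(top),
                     length(query_terms), lower.tail = FALSE)
  list(overlap = x, top_size = length(top), p_hyper = p)
}
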