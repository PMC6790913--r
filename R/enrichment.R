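#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` are annotated.
#' The one-sided over-representation p-value. Summed in log space from
#' log binomial coefficients for numerical stability at large N.
#'
#' @param k observed overlap.
#' @param K annotated genes in the universe (set size).
#' @param n query size.
#' @param N universe size.
#' @return The tail probability in (0, 1].
#' @export
hypergeometric_tail_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (is.na(k) || is.na(K) || is.na(n) || is.na(N) ||
      k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric arguments: require 0 <= k <= min(K, n) <= N")
  }
  lo <- max(0, n + K - N)
  if (k <= lo) return(1)
  i <- k:min(K, n)
  logterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logterms)
  min(1, exp(mx + log(sum(exp(logterms - mx)))))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH q-values with monotonicity enforcement, returned in
#' the input order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis against a gene-set collection
#'
#' Hypergeometric test of the overlap between a query gene list (for
#' example the consistently down-regulated proteins) and each gene set,
#' within a stated universe — by default the post-filter quantified
#' proteome, not the whole genome. Gene identity is by upper-cased
#' symbol. One-sided (over-representation only), BH-adjusted across all
#' tested sets.
#'
#' @param query_genes character vector of query gene symbols; genes
#'   outside the universe are dropped with a warning.
#' @param sets a `gene_set_collection` (see [read_gmt()]).
#' @param universe_genes character vector defining the universe.
#' @param min_overlap report only sets with overlap >= this. Default 0
#'   (report every set).
#' @return Tibble sorted by p (ties by set name) with columns `set_name`,
#'   `universe_size`, `query_size`, `set_size`, `overlap`, `p_hypergeom`,
#'   `q_bh`, `overlap_genes` (semicolon-joined).
#' @export
ora <- function(query_genes, sets, universe_genes, min_overlap = 0) {
  universe <- unique(toupper(universe_genes))
  universe <- universe[nzchar(universe)]
  query <- unique(toupper(query_genes))
  query <- query[nzchar(query)]
  if (length(universe) == 0) stop("empty universe")
  if (length(query) == 0) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (length(query) == 0) stop("no query genes remain within the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(toupper(sets[[nm]])), universe)
    K <- length(members)
    hits <- intersect(query, members)
    k <- length(hits)
    tibble::tibble(
      set_name = nm, universe_size = N, query_size = n, set_size = K,
      overlap = k,
      p_hypergeom = if (K == 0) 1 else hypergeometric_tail_p(k, K, n, N),
      overlap_genes = paste(sort(hits), collapse = ";")
    )
  })
  out <- do.call(rbind, rows)
  out$q_bh <- bh_fdr(out$p_hypergeom)
  out <- out[out$overlap >= min_overlap, , drop = FALSE]
  out <- out[order(out$p_hypergeom, out$set_name), , drop = FALSE]
  out[, c("set_name", "universe_size", "query_size", "set_size", "overlap",
          "p_hypergeom", "q_bh", "overlap_genes")]
}
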