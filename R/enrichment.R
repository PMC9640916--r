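#' Hypergeometric upper-tail over-representation probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` carry the annotation.
#' Identical to the one-sided Fisher exact test on the 2x2 overlap table.
#'
#' @param k observed overlap count.
#' @param K genes in the set (within the universe).
#' @param n genes in the query (within the universe).
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(k > pmin(K, n)) ||
      any(K > N) || any(n > N))
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(K, n) <= N)",
         call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values numeric vector of probabilities in `[0, 1]`.
#' @return adjusted values, clipped at 1, in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list
#'
#' Tests each gene set for over-representation in the query with the
#' hypergeometric upper tail and adjusts across all tested sets with
#' Benjamini-Hochberg. Query genes outside the universe are dropped (their
#' count is reported as an attribute); set members are restricted to the
#' universe. Only sets overlapping the query (`k >= 1`) are reported.
#'
#' @param query character vector of gene ids.
#' @param collection a `gene_set_collection` (see [read_gmt()]) or named
#'   list of member vectors.
#' @param universe background gene ids; defaults to the union of all
#'   collection members, the measured-background convention.
#' @return tibble sorted by ascending p: `set_id`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p_value`, `q_value`; attribute
#'   `n_query_outside_universe`.
#' @export
enrich <- function(query, collection, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(collection, use.names = FALSE))
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query0 <- unique(query)
  query <- intersect(query0, universe)
  dropped <- length(query0) - length(query)
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]], universe)
    k <- length(intersect(query, members))
    if (k < 1L) return(NULL)
    K <- length(members)
    tibble::tibble(set_id = id, k = k, K = K, n = n, N = N,
                   fold_enrichment = (k / n) / (K / N),
                   p_value = hypergeom_test(k, K, n, N))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(set_id = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(),
                          fold_enrichment = numeric(), p_value = numeric(),
                          q_value = numeric())
  } else {
    out$q_value <- benjamini_hochberg(out$p_value)
    out <- dplyr::arrange(out, .data$p_value, .data$set_id)
  }
  attr(out, "n_query_outside_universe") <- dropped
  out
}
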