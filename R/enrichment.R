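#' One-sided set-overlap enrichment against a custom background
#'
#' Upper tail of the hypergeometric law: the probability of seeing at least
#' `k` marked genes in a query of `n`, drawn without replacement from a
#' background of `N` genes of which `K` are marked. The tail is an exact
#' summation of hypergeometric terms evaluated as log-space binomial
#' coefficients and combined by log-sum-exp, so extreme tables (p far below
#' double underflow, as in genome-scale backgrounds) still return a finite
#' log10 p.
#'
#' @param k Marked genes in the query.
#' @param n Query size.
#' @param K Marked genes in the background.
#' @param N Background size.
#' @return list: N, K, n, k, fold (= (k/n)/(K/N)), p (upper-tail
#'   probability; exactly 1 when k = 0), log10_p.
#' @export
set_enrichment <- function(k, n, K, N) {
  v <- c(k = k, n = n, K = K, N = N)
  if (any(v != round(v)) || any(v < 0)) {
    stop("k, n, K, N must be non-negative integers")
  }
  if (n > N || K > N) stop("query and marked set must fit the background")
  if (k > n) stop("k cannot exceed the query size n")
  if (k > K) stop("k cannot exceed the background marked count K")
  if (n == 0 || N == 0) stop("empty query or background")
  fold <- (k / n) / (K / N)
  if (k == 0) {
    return(list(N = N, K = K, n = n, k = k, fold = fold, p = 1,
                log10_p = 0))
  }
  i <- k:min(n, K)
  # lchoose is -Inf for impossible terms (n - i > N - K); drop them
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  lt <- lt[is.finite(lt)]
  if (!length(lt)) stop("no admissible configuration for these counts")
  m <- max(lt)
  log_p <- m + log(sum(exp(lt - m)))
  log_p <- min(log_p, 0)
  list(N = N, K = K, n = n, k = k, fold = fold,
       p = exp(log_p), log10_p = log_p / log(10))
}

#' Enrichment of annotation terms in a query gene set
#'
#' Runs [set_enrichment()] per term of a term-to-gene table against a
#' supplied background (e.g. the genes expressed in the tissue under
#' study), the standard guard against tissue-expression bias.
#'
#' @param query Character vector of query gene ids.
#' @param term_table data.frame with columns `term` and `gene_id`.
#' @param background Character vector of background gene ids; the query
#'   must be a subset.
#' @return data.frame, one row per term: term, N, K, n, k, fold, p,
#'   log10_p, sorted by p.
#' @export
term_enrichment <- function(query, term_table, background) {
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background)) {
    stop("query contains genes outside the background")
  }
  terms <- unique(term_table$term)
  rows <- lapply(terms, function(tm) {
    marked <- intersect(
      unique(term_table$gene_id[term_table$term == tm]), background)
    r <- set_enrichment(k = length(intersect(query, marked)),
                        n = length(query), K = length(marked),
                        N = length(background))
    data.frame(term = tm, N = r$N, K = r$K, n = r$n, k = r$k,
               fold = r$fold, p = r$p, log10_p = r$log10_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
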