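#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked items when `n` items are drawn without
#' replacement from `N` of which `K` are marked. The inclusive upper tail
#' is the standard enrichment convention.
#'
#' @param k observed hits.
#' @param K marked items in the universe (e.g. pathway size).
#' @param n draws (query-set size).
#' @param N universe size.
#' @return probability in (0, 1\].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (K < 0 || n < 0 || K > N || n > N || k < 0 || k > min(K, n))
    stop("inconsistent hypergeometric counts: k=", k, " K=", K,
         " n=", n, " N=", N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement; input
#' order is preserved.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Pathway enrichment of a reaction set
#'
#' One upper-tail hypergeometric test per pathway (labels from the model)
#' with at least one member in the universe, followed by
#' Benjamini-Hochberg adjustment across pathways. The default universe is
#' every model reaction carrying a pathway label.
#'
#' @param query character vector of reaction ids (must lie in the
#'   universe).
#' @param model a `metabolic_model`.
#' @param universe character vector of reaction ids; default all labeled
#'   reactions.
#' @param alpha FDR level for the `enriched` flag (default 0.05).
#' @param depletion also test the lower tail (under-representation);
#'   off by default.
#' @return data.frame sorted by p-value with columns `pathway`, `k`, `K`,
#'   `n`, `N`, `p`, `q`, `enriched`.
#' @export
enrich_pathways <- function(query, model, universe = NULL, alpha = 0.05,
                            depletion = FALSE) {
  labeled <- model$reactions$id[nzchar(model$reactions$pathway)]
  if (is.null(universe)) universe <- labeled
  universe <- unique(universe)
  if (!length(universe)) stop("empty enrichment universe")
  query <- unique(intersect(query, universe))
  pw <- stats::setNames(model$reactions$pathway, model$reactions$id)
  pathways <- sort(unique(pw[universe][nzchar(pw[universe])]))
  if (!length(pathways)) stop("no pathway labels in universe")
  N <- length(universe); n <- length(query)
  res <- lapply(pathways, function(p) {
    members <- universe[pw[universe] == p & !is.na(pw[universe])]
    K <- length(members)
    k <- length(intersect(members, query))
    pval <- if (depletion) stats::phyper(k, K, N - K, n)
      else hypergeom_upper_tail(k, K, n, N)
    data.frame(pathway = p, k = k, K = K, n = n, N = N, p = pval,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_adjust(res$p)
  res$enriched <- res$q <= alpha
  res[order(res$p, res$pathway), , drop = FALSE]
}

#' Hypergeometric overlap test for two sets
#'
#' Upper-tail probability of observing at least the realized overlap
#' between two subsets of a common universe.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector.
#' @return probability.
#' @export
overlap_test <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
    stop("overlap_test: sets must be subsets of the universe")
  hypergeom_upper_tail(length(intersect(setA, setB)),
                       length(setA), length(setB), length(universe))
}
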