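#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` carry the
#' annotation. This is the one-sided over-representation p-value
#' (equivalently Fisher's exact test, upper tail).
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Annotated genes in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; output order matches input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis against a gene-set collection
#'
#' Each term is intersected with the universe and tested with the
#' one-sided hypergeometric test; p-values are BH-adjusted across all
#' tested terms and called significant below `alpha`. The universe
#' defaults to all genes annotated to at least one term (intersected
#' with any user-supplied background); query genes outside the universe
#' are dropped before testing, mirroring annotation-restricted
#' enrichment tools. Results are sorted by (adjusted p, raw p, term id)
#' for deterministic ranking.
#'
#' @param query Character vector of gene symbols.
#' @param collection A [gene_set_collection()].
#' @param universe Optional background gene set.
#' @param alpha Significance cutoff on the adjusted p-value.
#' @param top Optional integer: keep only the `top` best-ranked terms.
#' @return A data frame of class `enrichment_result` with columns
#'   `term_id`, `term_name`, `k` (overlap), `K` (term size in universe),
#'   `n` (query size in universe), `N` (universe size), `p`, `p_adj`,
#'   `significant`.
#' @export
enrich <- function(query, collection, universe = NULL, alpha = 0.05,
                   top = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  annotated <- unique(unlist(collection$genes))
  uni <- if (is.null(universe)) annotated
         else intersect(annotated, unique(as.character(universe)))
  if (length(uni) == 0) stop("empty universe")
  q <- intersect(unique(as.character(query)), uni)
  if (length(q) == 0)
    stop("query is empty after restriction to the universe")
  N <- length(uni); n <- length(q)
  term_genes <- lapply(collection$genes, intersect, uni)
  K <- lengths(term_genes)
  keep <- K >= 1
  k <- vapply(term_genes[keep], function(g) length(intersect(g, q)),
              integer(1))
  Kk <- K[keep]
  p <- mapply(function(k, K) hypergeom_upper_tail(k, K, n, N), k, Kk)
  res <- data.frame(term_id = collection$term_id[keep],
                    term_name = collection$term_name[keep],
                    k = unname(k), K = unname(Kk), n = n, N = N,
                    p = unname(p), p_adj = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p_adj, res$p, res$term_id, method = "radix"),
             , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(top)) res <- utils::head(res, top)
  structure(res, alpha = alpha,
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %d terms tested (query n = %d, universe N = %d), %d significant at p_adj < %g\n",
    nrow(x), if (nrow(x)) x$n[1] else 0, if (nrow(x)) x$N[1] else 0,
    sum(x$significant), attr(x, "alpha")))
  if (nrow(x))
    print.data.frame(utils::head(
      x[, c("term_id", "k", "K", "p", "p_adj", "significant")], 10))
  invisible(x)
}
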