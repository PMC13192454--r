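#' Hypergeometric upper-tail probability of an overlap
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K` carry
#' the annotation. This is the over-representation p-value used for
#' functional-bin enrichment; it is evaluated through [stats::phyper()],
#' which works on log scale internally and is stable for large universes.
#'
#' @param k observed overlap (genes of the query set in the bin).
#' @param K bin size in the universe.
#' @param n query-set size.
#' @param N universe size.
#' @return upper-tail probability `P(X >= k)`.
#' @examples
#' hypergeomTest(5, 5, 5, 10) # 1/choose(10,5)
#' @export
hypergeomTest <- function(k, K, n, N) {
  stopifnot(length(N) == 1L || length(N) == length(k))
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, shared by all
#' modules so every FDR gate in the pipeline uses one implementation.
#'
#' @param p vector of raw p-values in `[0, 1]` (NAs propagated).
#' @return q-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Functional-bin over-representation analysis
#'
#' Tests each functional bin for enrichment of `geneSet` against `universe`
#' with the hypergeometric upper tail, adjusts across the tested bins with
#' Benjamini-Hochberg, and flags bins with q <= `alpha` as enriched. Bins
#' with no universe member are skipped. Genes may belong to several bins
#' (and several hierarchy levels); each bin is tested independently and the
#' correction is joint across all tested bins of the one query set.
#'
#' @param geneSet character vector of query gene ids; must be a subset of
#'   `universe`.
#' @param binMap data.frame with columns `gene_id` and `bin_id` (optionally
#'   `bin_name`); the functional annotation, e.g. a Mercator/MapMan bin map.
#' @param universe character vector of annotated genes forming the
#'   background; defaults to all genes present in `binMap`.
#' @param alpha FDR gate for the `enriched` flag.
#' @return data.frame with one row per tested bin: `bin_id`, `k`, `K`, `n`,
#'   `N`, `gene_ratio` (= k/n), `p`, `q`, `enriched`.
#' @export
enrich <- function(geneSet, binMap, universe = unique(binMap$gene_id),
                   alpha = 0.05) {
  geneSet <- unique(geneSet)
  universe <- unique(universe)
  if (!all(geneSet %in% universe))
    stop("gene set contains genes outside the universe; the universe must ",
         "be the annotated transcriptome")
  binMap <- binMap[binMap$gene_id %in% universe, , drop = FALSE]
  bins <- split(unique(binMap[c("gene_id", "bin_id")]),
                unique(binMap[c("gene_id", "bin_id")])$bin_id)
  bins <- bins[vapply(bins, nrow, 1L) > 0L]
  if (!length(bins))
    return(data.frame(bin_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), gene_ratio = numeric(),
                      p = numeric(), q = numeric(), enriched = logical()))
  n <- length(geneSet); N <- length(universe)
  K <- vapply(bins, nrow, 1L)
  k <- vapply(bins, function(b) sum(b$gene_id %in% geneSet), 1L)
  p <- hypergeomTest(k, K, n, N)
  q <- bhAdjust(p)
  out <- data.frame(bin_id = names(bins), k = k, K = K, n = n, N = N,
                    gene_ratio = k / n, p = p, q = q, enriched = q <= alpha,
                    row.names = NULL)
  if ("bin_name" %in% names(binMap)) {
    nm <- binMap$bin_name[match(out$bin_id, binMap$bin_id)]
    out$bin_name <- nm
  }
  out[order(out$p, out$bin_id), , drop = FALSE]
}
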