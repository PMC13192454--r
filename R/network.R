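#' Pairwise Pearson correlation matrix
#'
#' @param x genes x observations matrix (at least 3 observations); genes
#'   with zero variance must be removed upstream.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pccMatrix <- function(x) {
  if (ncol(x) < 3) stop("at least 3 observations per gene are required")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) stop("zero-variance gene(s): ",
                          paste(rownames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(t(x))
  diag(r) <- 1
  r
}

#' Fisher Z transformation of correlation coefficients
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`; variance-stabilizes the
#' PCC before thresholding. Coefficients at or beyond +-1 (collinear
#' synthetic profiles) are clamped to `1 - 1e-12` in magnitude with a
#' warning.
#'
#' @param r correlations.
#' @return transformed values.
#' @export
fisherZ <- function(r) {
  out <- abs(r) >= 1
  if (any(out, na.rm = TRUE)) {
    warning(sum(out, na.rm = TRUE), " |r| >= 1 value(s) clamped to 1 - 1e-12")
    r[which(out)] <- sign(r[which(out)]) * (1 - 1e-12)
  }
  atanh(r)
}

#' Build a thresholded co-expression network
#'
#' Computes all pairwise PCCs of the expression submatrix, applies the
#' Fisher Z transformation, standardizes the Z values over all gene pairs
#' (subtract their mean, divide by their SD), and retains as edges the
#' pairs whose standardized value reaches the normal quantile
#' `qnorm(quantile)` and whose raw PCC reaches `pccFloor`. Both filters are
#' conjunctive and independently configurable; the retained fraction of
#' each step and the effective PCC threshold implied by the quantile are
#' recorded in `params`. By default only positive correlations form edges.
#'
#' @param expr genes x observations expression matrix (e.g. replicate-level
#'   `log2(TPM + 1)` of one FR-DEG direction set).
#' @param quantile normal quantile cutoff on standardized Z (default 0.945).
#' @param pccFloor minimum raw PCC of an edge; the study used 0.98 for the
#'   upregulated and 0.97 for the downregulated set. Use `-1` to disable.
#' @param hubs optional designated hub gene ids; hubs absent from the graph
#'   are kept in the slot and skipped by queries with a warning.
#' @param positiveOnly admit only positive correlations as edges.
#' @return a [CoexprNetwork-class].
#' @export
buildAdjacency <- function(expr, quantile = 0.945, pccFloor = 0.98,
                           hubs = character(), positiveOnly = TRUE) {
  r <- pccMatrix(expr)
  ut <- upper.tri(r)
  if (sum(ut) <= 2) stop("need more than 2 gene pairs to standardize Z")
  pcc <- r[ut]
  idx <- which(ut, arr.ind = TRUE)
  z <- fisherZ(pcc)
  sdz <- stats::sd(z)
  if (!is.finite(sdz) || sdz == 0)
    stop("degenerate Z distribution (all pairs equal); cannot standardize")
  stdz <- (z - mean(z)) / sdz
  cut <- stats::qnorm(quantile)
  passQ <- stdz >= cut
  passP <- pcc >= pccFloor & (!positiveOnly | pcc > 0)
  keep <- passQ & passP
  # PCC implied by the quantile step alone: invert the standardization
  effPcc <- tanh(mean(z) + cut * sdz)
  edges <- data.frame(gene_a = rownames(r)[idx[keep, 1]],
                      gene_b = rownames(r)[idx[keep, 2]],
                      pcc = pcc[keep], z = z[keep], std_z = stdz[keep])
  edges <- edges[order(-abs(edges$std_z)), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges[c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = rownames(r))
  net <- new("CoexprNetwork", graph = g, edges = edges,
             hubs = as.character(hubs), levels = integer(),
             params = list(quantile = quantile, pccFloor = pccFloor,
                           effectivePccFromQuantile = effPcc,
                           fracQuantile = mean(passQ), fracPcc = mean(passP),
                           fracRetained = mean(keep), nPairs = length(pcc)))
  net@levels <- .hubLevels(net)
  net
}

.presentHubs <- function(network) {
  h <- hubGenes(network)
  present <- h[h %in% igraph::V(network@graph)$name]
  if (length(present) < length(h))
    warning("hub(s) absent from network, skipped: ",
            paste(setdiff(h, present), collapse = ", "))
  present
}

.hubLevels <- function(network) {
  nodes <- igraph::V(network@graph)$name
  lev <- rep(NA_integer_, length(nodes))
  names(lev) <- nodes
  h <- hubGenes(network)
  h <- h[h %in% nodes]
  if (length(h)) {
    d <- igraph::distances(network@graph, v = h)
    best <- apply(d, 2, min)
    lev[] <- as.integer(ifelse(is.finite(best), best, NA_real_))
  }
  lev
}

#' Hub neighborhood subnetwork
#'
#' Induced subgraph of all nodes within BFS distance `maxLevel` of any hub;
#' each retained node keeps its depth from the nearest hub (0 = hub).
#'
#' @param network a [CoexprNetwork-class].
#' @param hubs hub gene ids; defaults to the network's designated hubs.
#' @param maxLevel neighborhood depth (default 2, the first- and
#'   second-level connections).
#' @return a [CoexprNetwork-class] restricted to the neighborhood.
#' @export
hubNeighborhood <- function(network, hubs = hubGenes(network), maxLevel = 2) {
  network@hubs <- as.character(hubs)
  present <- .presentHubs(network)
  lev <- .hubLevels(network)
  keep <- names(lev)[!is.na(lev) & lev <= maxLevel]
  g <- igraph::induced_subgraph(network@graph, keep)
  ed <- network@edges
  ed <- ed[ed$gene_a %in% keep & ed$gene_b %in% keep, , drop = FALSE]
  rownames(ed) <- NULL
  new("CoexprNetwork", graph = g, edges = ed, hubs = present,
      levels = lev[keep], params = c(network@params, maxLevel = maxLevel))
}

#' Shortest paths from every node to its nearest hub
#'
#' Unweighted BFS shortest paths; when several hubs or routes are equally
#' near, the path whose node-id sequence is lexicographically smallest is
#' returned, making the choice deterministic.
#'
#' @param network a [CoexprNetwork-class].
#' @param hubs hub gene ids; defaults to the network's hubs.
#' @return named list: for each reachable non-hub node, the character
#'   vector of node ids from the node to its hub; unreachable nodes map to
#'   `NULL` entries (marked unreachable).
#' @export
shortestPathsToHubs <- function(network, hubs = hubGenes(network)) {
  network@hubs <- as.character(hubs)
  present <- sort(.presentHubs(network))
  nodes <- igraph::V(network@graph)$name
  out <- stats::setNames(vector("list", length(nodes)), nodes)
  if (!length(present)) return(out)
  d <- igraph::distances(network@graph, v = present)
  adj <- igraph::as_adj_list(network@graph)
  adj <- lapply(adj, function(v) sort(v$name))
  dmin <- apply(d, 2, min)[nodes]
  for (node in nodes) {
    if (!is.finite(dmin[node])) next
    # greedy lexicographic walk: always step to the smallest-id neighbor
    # that still decreases the distance to the nearest hub
    path <- node
    cur <- node
    while (min(d[, cur]) > 0) {
      nb <- adj[[cur]]
      nb <- nb[apply(d[, nb, drop = FALSE], 2, min) == min(d[, cur]) - 1]
      cur <- nb[1]
      path <- c(path, cur)
    }
    out[[node]] <- path
  }
  out
}
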