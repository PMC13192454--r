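#' Select genes eligible for soft clustering
#'
#' A gene enters the clustering when it (i) is differentially expressed in
#' at least one of the supplied pairwise comparisons and (ii) has at least
#' `minCount` size-factor-normalized counts in at least `minSamples` samples
#' regardless of treatment.
#'
#' @param x `CountExperiment` or count matrix.
#' @param deList list of data.frames from [deTest()], one per pairwise
#'   contrast.
#' @param sizeFactors optional precomputed size factors.
#' @param minCount,minSamples thresholds of criterion (ii); defaults 5 and 3.
#' @return character vector of gene ids satisfying both criteria.
#' @export
selectClusterInput <- function(x, deList, sizeFactors = NULL,
                               minCount = 5, minSamples = 3) {
  cs <- .countsAndSheet(x)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(cs$counts)
  norm <- sweep(cs$counts, 2, sizeFactors, "/")
  de <- unique(unlist(lapply(deList, function(d)
    d$gene_id[d$status != "ns"]), use.names = FALSE))
  expressed <- rownames(norm)[rowSums(norm >= minCount) >= minSamples]
  sort(intersect(de, expressed))
}

#' Row-wise z-scores
#'
#' Centres each gene's profile at its mean and scales by its sample
#' standard deviation, so a positive value marks samples where the gene is
#' expressed above its own average. Zero-variance rows cannot be scaled and
#' are dropped with a warning.
#'
#' @param x numeric matrix, typically `log2(TPM + 1)` (genes x samples).
#' @return z-scored matrix, possibly with fewer rows.
#' @export
zscoreRows <- function(x) {
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  keep <- sd > 0
  if (!all(keep))
    warning(sum(!keep), " constant row(s) dropped before z-scoring")
  (x[keep, , drop = FALSE] - mu[keep]) / sd[keep]
}

#' Empirical fuzzifier for fuzzy c-means
#'
#' The Schwaemmle-Jensen rule estimating a suitable fuzzifier from the
#' number of features `N` and the data dimension `D`; values shrink towards
#' 1 as datasets grow.
#'
#' @param N number of items to cluster (genes).
#' @param D profile dimension (samples).
#' @return fuzzifier m > 1.
#' @export
estimateFuzzifier <- function(N, D) {
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

.kmeansppInit <- function(x, c) {
  n <- nrow(x)
  centers <- matrix(NA_real_, c, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(c)[-1]) {
    pick <- if (sum(d2) > 0) sample.int(n, 1, prob = d2) else sample.int(n, 1)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

.fcmMembership <- function(d2, m) {
  # u_ij proportional to d_ij^(-2/(m-1)); a point coincident with one or
  # more centroids takes membership 1 split over the coincident centroids
  zero <- d2 < .Machine$double.eps
  u <- d2^(-1 / (m - 1))
  u <- u / rowSums(u)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Fuzzy c-means soft clustering
#'
#' Standard fuzzy c-means with alternating updates: memberships proportional
#' to inverse squared distance to the power `1/(m-1)`, centroids as
#' membership^m-weighted means, iterated until the largest centroid shift
#' falls below `tol`. Initialization is k-means++-style seeding derived from
#' `seed`; `nstart` restarts are run and the solution with the lowest
#' objective is kept. The objective is checked to be non-increasing at every
#' iteration. Genes whose maximum membership reaches `membershipMin` are
#' hard-assigned to that cluster (ties broken by the lowest cluster index);
#' the rest are left unassigned.
#'
#' Input rows are processed in sorted rowname order, so permuting the input
#' permutes the output identically.
#'
#' @param z genes x samples z-score matrix with rownames.
#' @param c number of clusters (>= 2, < number of genes).
#' @param m fuzzifier; defaults to [estimateFuzzifier()] on `dim(z)`.
#' @param tol centroid-shift convergence tolerance.
#' @param maxIter iteration cap per restart.
#' @param seed RNG seed for initialization.
#' @param nstart number of random restarts.
#' @param membershipMin retention threshold on the maximum membership.
#' @return a [ClusterModel-class].
#' @export
fuzzyCMeans <- function(z, c = 10, m = NULL, tol = 1e-6, maxIter = 300,
                        seed = 1, nstart = 10, membershipMin = 0.7) {
  stopifnot(c >= 2, nrow(z) > c)
  ord <- order(rownames(z))
  x <- z[ord, , drop = FALSE]
  if (is.null(m)) m <- max(estimateFuzzifier(nrow(x), ncol(x)), 1.05)
  best <- NULL
  set.seed(seed)
  for (s in seq_len(nstart)) {
    v <- .kmeansppInit(x, c)
    obj <- numeric()
    for (it in seq_len(maxIter)) {
      d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(v) +
        outer(rep(1, nrow(x)), rowSums(v^2))
      d2 <- pmax(d2, 0)
      u <- .fcmMembership(d2, m)
      um <- u^m
      obj <- c(obj, sum(um * d2))
      if (it > 1 && obj[it] > obj[it - 1] + 1e-8 * (abs(obj[it - 1]) + 1))
        stop("fuzzy c-means objective increased; numerical failure")
      vNew <- (t(um) %*% x) / colSums(um)
      empty <- !is.finite(rowSums(vNew))
      if (any(empty)) vNew[empty, ] <- v[empty, ]
      shift <- max(abs(vNew - v))
      v <- vNew
      if (shift < tol) break
    }
    if (is.null(best) || obj[length(obj)] < best$obj[length(best$obj)])
      best <- list(v = v, u = u, obj = obj)
  }
  u <- best$u[match(rownames(z), rownames(x)), , drop = FALSE]
  rownames(u) <- rownames(z)
  colnames(u) <- seq_len(c)
  maxm <- apply(u, 1, max)
  cl <- apply(u, 1, which.max)          # which.max takes the lowest index on ties
  keep <- maxm >= membershipMin
  asg <- data.frame(gene_id = rownames(z)[keep], cluster = cl[keep],
                    membership = maxm[keep], row.names = NULL)
  new("ClusterModel", centroids = best$v, membership = u, m = m,
      objective = best$obj, assignments = asg, membershipMin = membershipMin)
}

#' Label cluster direction relative to far-red light
#'
#' A cluster is `FR-up` when its centroid, averaged over FR samples, exceeds
#' the average over R samples by more than `delta` z-units at day 1, day 3,
#' or both; `FR-down` when the difference falls below `-delta`; anything
#' flat or conflicting is `other`.
#'
#' @param model [ClusterModel-class] whose centroid columns follow
#'   `sampleSheet` order.
#' @param sampleSheet sample sheet of the clustered matrix columns.
#' @param delta z-score margin (default 0.5).
#' @param timepoints the two assayed timepoints in hours (day 1, day 3).
#' @return named character vector, cluster index -> label.
#' @export
labelClusterDirection <- function(model, sampleSheet, delta = 0.5,
                                  timepoints = c(23, 71)) {
  v <- centroids(model)
  grp <- sampleGroups(sampleSheet)
  diffAt <- function(tp) {
    fr <- grp == paste0("FR_", tp); r <- grp == paste0("R_", tp)
    rowMeans(v[, fr, drop = FALSE]) - rowMeans(v[, r, drop = FALSE])
  }
  d1 <- diffAt(timepoints[1]); d3 <- diffAt(timepoints[2])
  up <- d1 > delta | d3 > delta
  down <- d1 < -delta | d3 < -delta
  lab <- ifelse(up & !down, "FR-up", ifelse(down & !up, "FR-down", "other"))
  stats::setNames(lab, seq_len(nrow(v)))
}

#' Group redundant clusters by centroid correlation
#'
#' Single-linkage grouping of clusters whose centroid Pearson correlation
#' reaches `rMin` with a correlation-test p-value below `alpha`; the
#' grouping is the transitive closure of that similarity graph.
#'
#' @param model [ClusterModel-class].
#' @param rMin correlation threshold (default 0.8).
#' @param alpha test gate (default 0.05).
#' @return integer vector, cluster index -> group id.
#' @export
mergeRedundantClusters <- function(model, rMin = 0.8, alpha = 0.05) {
  v <- centroids(model)
  c <- nrow(v)
  stopifnot(c >= 2)
  adj <- diag(c) == 1
  for (i in seq_len(c - 1)) for (j in (i + 1):c) {
    r <- stats::cor(v[i, ], v[j, ])
    if (!is.na(r) && r >= rMin) {
      pv <- tryCatch(stats::cor.test(v[i, ], v[j, ])$p.value, error = function(e) 1)
      if (r >= 1 - 1e-12 || pv < alpha) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  grp <- igraph::components(g)$membership
  stats::setNames(as.integer(grp), seq_len(c))
}
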