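# Independent reference implementations used as oracles. These are kept
# deliberately naive (enumeration, O(n^2) scans, textbook formulas) and
# never share code with the package internals they check.

# exhaustive hypergeometric upper tail by enumerating all draws
bruteHypergeom <- function(k, K, n, N) {
  tot <- choose(N, n)
  sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), 1)) / tot
}

# naive BH step-up
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# textbook two-pass Pearson correlation
brutePcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# O(n^2) interval overlap scan on 1-based closed intervals
bruteOverlap <- function(s1, e1, s2, e2, minOverlap = 1) {
  out <- matrix(0L, 0, 2)
  for (i in seq_along(s1)) for (j in seq_along(s2)) {
    ov <- min(e1[i], e2[j]) - max(s1[i], s2[j]) + 1
    if (ov >= minOverlap) out <- rbind(out, c(i, j))
  }
  out
}

# brute-force BFS distances on an adjacency matrix
bruteBfs <- function(adj, from) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & is.infinite(d))
    d[nb] <- d[v] + 1
    queue <- c(queue, nb)
  }
  d
}

# exclusive Venn regions by direct membership enumeration
bruteVenn <- function(sets) {
  genes <- unique(unlist(sets))
  pat <- vapply(genes, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
          collapse = "&"), "")
  table(pat)
}

# small deterministic annotation: two genes (one per strand) and one TE
tinyAnnotation <- function() {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(3001, 6001), c(3400, 6500)), strand = c("+", "-"))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    type = "gene", gene_id = c("gA", "gB"))
  exons <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(3001, 3201, 6001), c(3100, 3400, 6500)),
    strand = c("+", "+", "-"))
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
    type = "exon", gene_id = c("gA", "gA", "gB"))
  intr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3101, 3200),
                                 strand = "+")
  S4Vectors::mcols(intr) <- S4Vectors::DataFrame(type = "intron",
                                                 gene_id = "gA")
  prom <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1001, 6501), c(3000, 8500)), strand = c("+", "-"))
  S4Vectors::mcols(prom) <- S4Vectors::DataFrame(
    type = "promoter", gene_id = c("gA", "gB"))
  te <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3300, 4000),
                               strand = "+")
  S4Vectors::mcols(te) <- S4Vectors::DataFrame(type = "TE",
                                               gene_id = NA_character_)
  c(genes, exons, intr, prom, te)
}

# cytosine report builder
makeReport <- function(pos, M, U, context, strand = "+", chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = rep_len(context, length(pos)), M = as.integer(M),
    U = as.integer(U))
  gr
}

# shared small-but-complete pipeline configuration for integration-style
# tests; the full default conditions are exercised in the acceptance suite
tinyConfig <- function(seed = 7) {
  simConfig(seed = seed, nGenes = 80, nTE = 20, chromLength = 600000,
            nPlantedDmrs = 40, nNullMethWindows = 160, nRddmGenes = 6)
}

.fixtureCache <- new.env(parent = emptyenv())

cachedSim <- function(seed = 7) {
  key <- paste0("sim", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- simulateExperiment(tinyConfig(seed))
  .fixtureCache[[key]]
}
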