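#' Gene-level count container
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one `counts`
#' assay of nonnegative integers, per-gene lengths in `rowData(x)$length`
#' (bp), and the sample sheet (`sample_id`, `condition`, `timepoint`,
#' `replicate`) as `colData`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @aliases CountExperiment
#' @export
setClass("CountExperiment",
         contains = "SummarizedExperiment")

setValidity("CountExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be nonnegative integers")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"length" %in% names(rd) || any(rd$length <= 0))
    msg <- c(msg, "rowData(x)$length must give positive gene lengths (bp)")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "condition", "timepoint", "replicate")
  if (!all(need %in% names(cd)))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  else if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a CountExperiment
#'
#' @param counts genes x samples matrix of nonnegative integer counts with
#'   row and column names.
#' @param lengths per-gene lengths in bp (same order as `rownames(counts)`).
#' @param sampleSheet data.frame with `sample_id`, `condition`, `timepoint`,
#'   `replicate`; rows are matched to count columns by `sample_id`.
#' @return a [CountExperiment-class] object.
#' @export
countExperiment <- function(counts, lengths, sampleSheet) {
  sampleSheet <- sampleSheet[match(colnames(counts), sampleSheet$sample_id), ,
                             drop = FALSE]
  if (anyNA(sampleSheet$sample_id))
    stop("every count column must map to exactly one sample sheet row")
  new("CountExperiment", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(length = lengths, row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(sampleSheet, row.names = sampleSheet$sample_id)))
}

#' @rdname CountExperiment-class
#' @param object a `CountExperiment`.
#' @export
setGeneric("geneLengths", function(object) standardGeneric("geneLengths"))
#' @rdname CountExperiment-class
#' @export
setMethod("geneLengths", "CountExperiment", function(object)
  stats::setNames(SummarizedExperiment::rowData(object)$length, rownames(object)))

#' Condition_timepoint group label per sample
#'
#' @param sampleSheet data.frame (or `CountExperiment` colData) with
#'   `condition` and `timepoint` columns.
#' @return character vector like `"FR_71"`.
#' @export
sampleGroups <- function(sampleSheet) {
  if (is(sampleSheet, "CountExperiment"))
    sampleSheet <- as.data.frame(SummarizedExperiment::colData(sampleSheet))
  paste(sampleSheet$condition, sampleSheet$timepoint, sep = "_")
}

.countsAndSheet <- function(x, sampleSheet = NULL) {
  if (is(x, "CountExperiment")) {
    list(counts = SummarizedExperiment::assay(x, "counts"),
         sheet = as.data.frame(SummarizedExperiment::colData(x)))
  } else list(counts = as.matrix(x), sheet = sampleSheet)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' gene-wise geometric mean, computed over genes with all-positive counts
#' (the DESeq-style pseudo-reference). Scaling one sample's counts by a
#' constant scales its factor by the same constant.
#'
#' @param counts genes x samples count matrix or a `CountExperiment`.
#' @param pseudoReference if `TRUE`, fall back to geometric means over the
#'   positive counts of each gene when no gene has all-positive counts
#'   (sparse matrices).
#' @return positive numeric vector, one factor per sample.
#' @export
computeSizeFactors <- function(counts, pseudoReference = FALSE) {
  counts <- .countsAndSheet(counts)$counts
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    if (!pseudoReference)
      stop("no gene has positive counts in every sample; ",
           "rerun with pseudoReference = TRUE")
    logref <- apply(counts, 1, function(x) mean(log(x[x > 0])))
    keep <- is.finite(logref)
    ratios <- log(counts[keep, , drop = FALSE]) - logref[keep]
    sf <- apply(ratios, 2, function(r) exp(stats::median(r[is.finite(r)])))
  } else {
    logref <- rowMeans(log(counts[allpos, , drop = FALSE]))
    sf <- apply(log(counts[allpos, , drop = FALSE]) - logref, 2,
                function(r) exp(stats::median(r)))
  }
  # normalize to geometric mean 1 so per-sample rescaling acts one-to-one
  # on its own factor
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Transcripts per kilobase million
#'
#' Per sample: rate = count / length in kb; TPM = rate / sum(rate) * 1e6,
#' so every column with any signal sums to exactly one million.
#'
#' @param counts genes x samples matrix or `CountExperiment`.
#' @param lengths gene lengths in bp (> 0); taken from the object when a
#'   `CountExperiment` is given.
#' @return matrix of TPM values.
#' @export
tpm <- function(counts, lengths = NULL) {
  if (is(counts, "CountExperiment")) {
    lengths <- geneLengths(counts)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  stopifnot(length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / (lengths / 1e3)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("sample(s) with all-zero counts yield all-zero TPM columns: ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Negative-binomial Wald differential expression test
#'
#' A deliberately simple NB engine with the study's decision gates: counts
#' are normalized by median-of-ratios size factors; a per-gene NB dispersion
#' is estimated by method of moments on the normalized counts (pooled across
#' the two groups, floored at 1e-8); the log2 fold change of group means is
#' tested with a Wald statistic whose null distribution is taken as t with
#' `nA + nB - 2` degrees of freedom (the small-sample correction that keeps
#' the raw type-I error near its nominal level at n = 4); p-values are
#' BH-adjusted and genes are called up/down only when `q <= alpha` and
#' `|log2FC| >= lfcMin`. No shrinkage and no independent filtering are
#' applied.
#'
#' @param x `CountExperiment` or genes x samples count matrix.
#' @param sampleSheet sample sheet (ignored for a `CountExperiment`).
#' @param contrast character of length 2, `c(groupB, groupA)` as
#'   `condition_timepoint` labels; the reported log2FC is B over A.
#' @param alpha FDR gate (default 0.05).
#' @param lfcMin minimum absolute log2 fold change (default 1.5).
#' @param sizeFactors optional precomputed per-sample factors covering at
#'   least the contrasted samples.
#' @return data.frame: `gene_id`, `base_mean` (mean normalized count over
#'   the contrasted samples), `log2fc`, `p`, `q`, `status` in up/down/ns.
#' @export
deTest <- function(x, sampleSheet = NULL, contrast, alpha = 0.05,
                   lfcMin = 1.5, sizeFactors = NULL) {
  cs <- .countsAndSheet(x, sampleSheet)
  grp <- sampleGroups(cs$sheet)
  if (!all(contrast %in% grp)) stop("contrast groups not found in samples: ",
                                    paste(setdiff(contrast, grp), collapse = ", "))
  sel <- grp %in% contrast
  cnt <- cs$counts[, sel, drop = FALSE]
  g <- grp[sel]
  if (min(table(g)) < 2) stop("at least 2 replicates per group are required")
  if (is.null(sizeFactors)) {
    sf <- computeSizeFactors(cs$counts)[sel]
  } else sf <- sizeFactors[colnames(cnt)]
  norm <- sweep(cnt, 2, sf, "/")
  isB <- g == contrast[1]
  a <- norm[, !isB, drop = FALSE]; b <- norm[, isB, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  da <- (va - ma) / ma^2; db <- (vb - mb) / mb^2
  disp <- (ifelse(is.finite(da), da, 0) * (na - 1) +
           ifelse(is.finite(db), db, 0) * (nb - 1)) / (na + nb - 2)
  disp <- pmax(disp, 1e-8)
  # group means of zero give no information for a ratio; floor them at 1/8
  # of a normalized count for the statistic (planted effects sit far above)
  fl <- 0.125
  maf <- pmax(ma, fl); mbf <- pmax(mb, fl)
  sa <- sf[!isB]; sb <- sf[isB]
  vma <- (maf * sum(1 / sa) + disp * maf^2 * na) / na^2
  vmb <- (mbf * sum(1 / sb) + disp * mbf^2 * nb) / nb^2
  lfc <- ifelse(ma > 0 & mb > 0, log2(mb / ma), log2(mbf / maf))
  se <- sqrt(vma / maf^2 + vmb / mbf^2) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pt(-abs(stat), df = na + nb - 2)
  p[ma == 0 & mb == 0] <- 1
  q <- bhAdjust(p)
  status <- ifelse(q <= alpha & lfc >= lfcMin, "up",
                   ifelse(q <= alpha & lfc <= -lfcMin, "down", "ns"))
  status[ma == 0 & mb == 0] <- "ns"
  data.frame(gene_id = rownames(cnt), base_mean = (ma * na + mb * nb) / (na + nb),
             log2fc = lfc, p = p, q = q, status = status, row.names = NULL)
}

#' Exclusive Venn regions of DEG sets
#'
#' Counts genes in every exclusive intersection region of up to a handful of
#' sets; region labels join set names with `&`. Region counts sum to the
#' size of the union.
#'
#' @param sets named list of character vectors.
#' @return data.frame (`region`, `count`), regions with zero members kept.
#' @export
vennPartition <- function(sets) {
  stopifnot(length(names(sets)) == length(sets))
  genes <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) memb <- matrix(memb, nrow = 1,
                                          dimnames = list(NULL, names(sets)))
  nm <- names(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  region <- apply(patterns, 1, function(p) paste(nm[unlist(p)], collapse = "&"))
  count <- apply(patterns, 1, function(p)
    if (length(genes)) sum(apply(memb, 1, function(m) all(m == unlist(p)))) else 0L)
  data.frame(region = region, count = as.integer(count), row.names = NULL)
}

#' FR-regulated DEG set from labeled clusters
#'
#' The FR-DEG set is the union of retained members of every cluster labeled
#' FR-up or FR-down; each gene carries the direction of its cluster. Hard
#' assignment (one retained cluster per gene) guarantees the union is
#' disjoint.
#'
#' @param model a [ClusterModel-class] with retained assignments.
#' @param labels named character from [labelClusterDirection()]:
#'   cluster -> `"FR-up"`, `"FR-down"` or `"other"`.
#' @return data.frame (`gene_id`, `cluster`, `direction` in up/down).
#' @export
defineFrDegs <- function(model, labels) {
  asg <- clusterAssignments(model)
  keep <- labels[as.character(asg$cluster)] %in% c("FR-up", "FR-down")
  out <- asg[keep, c("gene_id", "cluster"), drop = FALSE]
  out$direction <- ifelse(labels[as.character(out$cluster)] == "FR-up",
                          "up", "down")
  rownames(out) <- NULL
  out
}
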