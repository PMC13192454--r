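#' Construct an SRNAProfile
#'
#' @param counts loci x size x sample integer array; the size dimension
#'   must be named `"18"`..`"28"`.
#' @param regions `GRanges` of loci, one per count row, named.
#' @param libSizes per-sample totals of genome-matching 18--28 nt reads.
#' @param sampleSheet sample sheet rows matching the sample dimension.
#' @return an [SRNAProfile-class].
#' @export
srnaProfile <- function(counts, regions, libSizes, sampleSheet) {
  new("SRNAProfile", counts = counts, regions = regions,
      libSizes = libSizes, sampleSheet = sampleSheet,
      rpm = array(numeric(0), dim = c(0, 0, 0)))
}

#' Reads-per-million normalization
#'
#' Scales every sample's counts by its library total of genome-matching
#' 18--28 nt reads: `rpm = counts / libSize * 1e6`. Raw counts are kept.
#'
#' @param profile an [SRNAProfile-class].
#' @return the profile with its `rpm` slot filled.
#' @export
rpmNormalize <- function(profile) {
  ls <- libSizes(profile)
  if (any(ls <= 0)) stop("library totals must be positive")
  cnt <- srnaCounts(profile)
  rpm <- sweep(cnt, 3, ls, "/") * 1e6
  profile@rpm <- rpm
  profile
}

#' Per-size-class abundance by sample group
#'
#' Sums RPM over loci within each sample, then reports mean and SD across
#' the samples of each group for every size class.
#'
#' @param profile an [SRNAProfile-class] with RPM computed.
#' @param groups character vector of group labels, one per sample; defaults
#'   to `condition_timepoint` from the profile's sample sheet.
#' @return data.frame (`size`, `group`, `mean_rpm`, `sd_rpm`).
#' @export
sizeDistribution <- function(profile, groups = NULL) {
  if (is.null(groups)) groups <- sampleGroups(profile@sampleSheet)
  rpm <- srnaRpm(profile)
  persample <- apply(rpm, c(2, 3), sum)     # size x sample
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    sel <- groups == g
    data.frame(size = as.integer(rownames(persample)), group = g,
               mean_rpm = rowMeans(persample[, sel, drop = FALSE]),
               sd_rpm = apply(persample[, sel, drop = FALSE], 1, stats::sd))
  }))
  rownames(out) <- NULL
  out
}

#' Sequential read categorization
#'
#' Each read (row) carries the set of reference indexes it matches; under
#' the default priority assignment a read is counted once, towards the
#' first matching category in priority order, and towards `other` when it
#' matches none. With `independent = TRUE` every matching category counts
#' the read (overlapping totals, mirroring separate alignments).
#'
#' @param assignments data.frame with one logical column per category named
#'   in `priority` and optionally a `count` column of read multiplicities
#'   (default 1 per row).
#' @param priority category order; default genes, miRNAs, TEs, rRNA, tRNA.
#' @param independent count reads in every matching category instead.
#' @return named numeric of category counts (includes `other`), with the
#'   category fractions of the priority assignment as attribute
#'   `"fraction"`.
#' @export
categorizeReads <- function(assignments,
                            priority = c("genes", "miRNAs", "TEs",
                                         "rRNA", "tRNA"),
                            independent = FALSE) {
  stopifnot(all(priority %in% names(assignments)))
  count <- if ("count" %in% names(assignments)) assignments$count
           else rep(1, nrow(assignments))
  m <- as.matrix(assignments[priority]) > 0
  if (independent) {
    res <- c(colSums(m * count), other = sum(count[rowSums(m) == 0]))
  } else {
    first <- apply(m, 1, function(x) if (any(x)) which(x)[1] else NA_integer_)
    res <- vapply(seq_along(priority),
                  function(i) sum(count[!is.na(first) & first == i]), 1)
    names(res) <- priority
    res <- c(res, other = sum(count[is.na(first)]))
  }
  attr(res, "fraction") <- res / sum(count)
  res
}

#' Differential accumulation of miRNA families
#'
#' Runs the negative-binomial engine on a family x sample count matrix,
#' with size factors taken from the sRNA library totals so families are
#' compared on the reads-per-million scale, and BH adjustment across
#' families.
#'
#' @param familyCounts families x samples count matrix.
#' @param sampleSheet sample sheet for the columns.
#' @param contrast `c(groupB, groupA)` condition_timepoint labels.
#' @param libSizes per-sample library totals; size factors are these totals
#'   scaled to geometric mean 1.
#' @param alpha,lfcMin decision gates passed to [deTest()].
#' @return data.frame as [deTest()] with `gene_id` renamed `family`.
#' @export
mirnaFamilyDe <- function(familyCounts, sampleSheet, contrast, libSizes,
                          alpha = 0.05, lfcMin = 1.5) {
  sf <- libSizes / exp(mean(log(libSizes)))
  res <- deTest(familyCounts, sampleSheet, contrast, alpha = alpha,
                lfcMin = lfcMin, sizeFactors = sf)
  names(res)[names(res) == "gene_id"] <- "family"
  res
}

#' Cross-reference differential miRNA families with FR-DEG targets
#'
#' For each differentially accumulating family, intersects its target genes
#' (an input map; target prediction is upstream) with the FR-DEG set and
#' records both directions; a pair is flagged `inverse` when miRNA and
#' target move in opposite directions (the expected silencing signature).
#'
#' @param familyDe data.frame from [mirnaFamilyDe()].
#' @param frDegs data.frame from [defineFrDegs()] (`gene_id`, `direction`).
#' @param targetMap data.frame (`family`, `gene_id`).
#' @return data.frame (`family`, `family_direction`, `gene_id`,
#'   `target_direction`, `inverse`); families without FR-DEG targets yield
#'   no rows.
#' @export
crossrefMirnaTargets <- function(familyDe, frDegs, targetMap) {
  de <- familyDe[familyDe$status != "ns", , drop = FALSE]
  out <- merge(de[c("family", "status")], targetMap, by = "family")
  out <- merge(out, frDegs[c("gene_id", "direction")], by = "gene_id")
  if (!nrow(out))
    return(data.frame(family = character(), family_direction = character(),
                      gene_id = character(), target_direction = character(),
                      inverse = logical()))
  out <- data.frame(family = out$family, family_direction = out$status,
                    gene_id = out$gene_id, target_direction = out$direction)
  out$inverse <- out$family_direction != out$target_direction
  out[order(out$family, out$gene_id), , drop = FALSE]
}

#' Differential sRNA accumulation at arbitrary regions
#'
#' Aggregates locus counts onto the query regions by >= 1 bp overlap, then
#' tests each region and size class for differential accumulation between
#' the two groups with the negative-binomial engine (library-total size
#' factors), BH-adjusting within each size class. Regions with zero
#' coverage everywhere come back non-significant.
#'
#' @param profile an [SRNAProfile-class].
#' @param regions named `GRanges` of query regions (e.g. DMRs).
#' @param contrast `c(groupB, groupA)` condition_timepoint labels.
#' @param sizes size classes to test (default 21, 22, 24 nt).
#' @param alpha FDR gate for the reported direction.
#' @return data.frame (`region_id`, `size`, `log2fc`, `p`, `q`,
#'   `direction` in up/down/ns).
#' @export
srnaAtRegions <- function(profile, regions, contrast, sizes = c(21, 22, 24),
                          alpha = 0.05) {
  stopifnot(!is.null(names(regions)))
  hits <- GenomicRanges::findOverlaps(srnaRegions(profile), regions,
                                      minoverlap = 1, ignore.strand = TRUE)
  cnt <- srnaCounts(profile)
  ls <- libSizes(profile)
  sf <- ls / exp(mean(log(ls)))
  out <- list()
  for (s in sizes) {
    mat <- matrix(0, length(regions), dim(cnt)[3],
                  dimnames = list(names(regions), dimnames(cnt)[[3]]))
    if (length(hits)) {
      sl <- cnt[S4Vectors::queryHits(hits), as.character(s), , drop = FALSE]
      for (j in seq_len(dim(cnt)[3]))
        mat[, j] <- tapply(sl[, 1, j],
                           factor(S4Vectors::subjectHits(hits),
                                  levels = seq_along(regions)),
                           sum, default = 0)
    }
    res <- deTest(mat, profile@sampleSheet, contrast, alpha = alpha,
                  lfcMin = 0, sizeFactors = sf)
    out[[as.character(s)]] <- data.frame(
      region_id = res$gene_id, size = as.integer(s), log2fc = res$log2fc,
      p = res$p, q = res$q,
      direction = ifelse(res$q <= alpha & res$log2fc > 0, "up",
                         ifelse(res$q <= alpha & res$log2fc < 0, "down",
                                "ns")))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
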