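#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
NULL

# vectorized context assignment on a plain character vector of bases
# (one chromosome); pos is 1-based, strand "+" or "-"
.contextFromChars <- function(chars, pos, strand) {
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b2 <- b3 <- rep(NA_character_, length(pos))
  plus <- strand == "+"
  i2 <- ifelse(plus, pos + 1L, pos - 1L)
  i3 <- ifelse(plus, pos + 2L, pos - 2L)
  ok2 <- i2 >= 1L & i2 <= n
  ok3 <- i3 >= 1L & i3 <= n
  b2[ok2] <- chars[i2[ok2]]
  b3[ok3] <- chars[i3[ok3]]
  b2[!plus & ok2] <- comp[b2[!plus & ok2]]
  b3[!plus & ok3] <- comp[b3[!plus & ok3]]
  ctx <- ifelse(!is.na(b2) & b2 == "G", "CG",
         ifelse(!is.na(b3) & b3 == "G", "CHG", "CHH"))
  # near contig ends CG is decidable from one base; otherwise CHH by default,
  # flagged ambiguous
  ambiguous <- (!ok2) | (!ok3 & !(ok2 & b2 == "G"))
  attr(ctx, "ambiguous") <- ambiguous
  ctx
}

#' Cytosine context (CG / CHG / CHH) at genomic positions
#'
#' Reads the two bases downstream of the cytosine 5'->3' on the cytosine's
#' own strand (for minus-strand cytosines the genome shows a G and the
#' downstream bases are the complemented upstream genome bases): `CG` when
#' the next base is G, `CHG` when the next is H (not G) and the second is G,
#' `CHH` otherwise. Positions within 2 bp of a contig end use the available
#' bases; CG remains decidable from one base, anything else defaults to CHH
#' and is flagged ambiguous in the `"ambiguous"` attribute.
#'
#' @param genome a [Biostrings::DNAStringSet] (or single `DNAString`).
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s); the genome base must be C on `+`, G on
#'   `-`.
#' @param strand `"+"` or `"-"`, recycled.
#' @return character vector of contexts with a logical `"ambiguous"`
#'   attribute.
#' @export
assignContext <- function(genome, chrom, pos, strand) {
  if (is(genome, "DNAString")) genome <- Biostrings::DNAStringSet(list(chr = genome))
  strand <- rep_len(strand, length(pos))
  chrom <- rep_len(chrom, length(pos))
  ctx <- rep(NA_character_, length(pos))
  amb <- rep(NA, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    chars <- strsplit(as.character(genome[[ch]]), "")[[1]]
    base <- chars[pos[sel]]
    want <- ifelse(strand[sel] == "+", "C", "G")
    if (any(base != want))
      stop("position(s) without a cytosine on the requested strand: ",
           paste(utils::head(pos[sel][base != want], 3), collapse = ", "))
    cc <- .contextFromChars(chars, pos[sel], strand[sel])
    ctx[sel] <- cc
    amb[sel] <- attr(cc, "ambiguous")
  }
  attr(ctx, "ambiguous") <- amb
  ctx
}

#' Methylation level of a cytosine
#'
#' `m / (m + u)`; `NA` (missing) when the site has no coverage, so
#' zero-coverage sites are excluded from every aggregate.
#'
#' @param m,u methylated / unmethylated read counts (vectors).
#' @return fraction in `[0, 1]` or `NA`.
#' @export
methylationLevel <- function(m, u) {
  stopifnot(all(m >= 0), all(u >= 0))
  ifelse(m + u == 0, NA_real_, m / (m + u))
}

#' Global (pooled) methylation level per context
#'
#' Pools read counts over all covered cytosines of each context:
#' `sum(M) / sum(M + U)`. Pooling weights sites by coverage; it is not the
#' mean of per-site levels.
#'
#' @param records cytosine report `GRanges` with mcols `context`, `M`, `U`.
#' @param context contexts to report (default all three).
#' @return named numeric vector of pooled levels.
#' @export
globalMethylation <- function(records, context = c("CG", "CHG", "CHH")) {
  mc <- mcols(records)
  vapply(context, function(ctx) {
    sel <- mc$context == ctx & (mc$M + mc$U) > 0
    if (!any(sel)) return(NA_real_)
    sum(mc$M[sel]) / sum(mc$M[sel] + mc$U[sel])
  }, numeric(1))
}

#' Metagene methylation profile (upstream / gene body / downstream)
#'
#' For each gene the 2-kb upstream flank, the body rescaled to
#' `binsPerSegment` bins, and the 2-kb downstream flank are binned;
#' per-bin counts are pooled over genes and converted to methylation
#' levels. Minus-strand genes are reversed so that bin 1 is always the far
#' upstream end (TSS at the upstream/body boundary, TTS at body/downstream).
#' Genes shorter than `binsPerSegment` bp are skipped; their number is
#' reported in the `"skipped"` attribute.
#'
#' @param records cytosine report `GRanges` (mcols `context`, `M`, `U`).
#' @param genes `GRanges` of gene spans (strand-aware).
#' @param flank flank width in bp (default 2000, clipped at contig ends).
#' @param binsPerSegment bins per segment (default 20).
#' @return data.frame (`context`, `bin`, `segment`, `level`); `bin` runs
#'   1..3*binsPerSegment across upstream, body, downstream.
#' @export
metageneProfile <- function(records, genes, flank = 2000,
                            binsPerSegment = 20) {
  B <- binsPerSegment
  keep <- width(genes) >= B
  skipped <- sum(!keep)
  genes <- genes[keep]
  cov <- records[(mcols(records)$M + mcols(records)$U) > 0]
  ext <- GenomicRanges::GRanges(seqnames(genes),
                                IRanges(pmax(start(genes) - flank, 1),
                                        end(genes) + flank))
  hits <- GenomicRanges::findOverlaps(cov, ext, ignore.strand = TRUE)
  ri <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  pos <- start(cov)[ri]
  gs <- start(genes)[gi]; ge <- end(genes)[gi]
  minus <- as.character(strand(genes))[gi] == "-"
  len <- ge - gs + 1
  # strand-aware coordinate from the far upstream edge; binning this (and
  # not flipping bin indices) makes strand reversal an exact symmetry
  rel <- ifelse(minus, ge + flank - pos, pos - (gs - flank))
  isUp <- rel < flank
  isBody <- !isUp & rel < flank + len
  isDn <- !isUp & !isBody
  bin <- integer(length(ri))
  bin[isUp] <- pmin(floor(rel[isUp] / flank * B), B - 1)
  bin[isBody] <- B + pmin(floor((rel[isBody] - flank) / len[isBody] * B),
                          B - 1)
  bin[isDn] <- 2L * B + pmin(floor((rel[isDn] - flank - len[isDn]) /
                                     flank * B), B - 1)
  bin <- bin + 1L
  ctx <- mcols(cov)$context[ri]
  M <- tapply(mcols(cov)$M[ri], list(ctx, bin), sum)
  Tt <- tapply(mcols(cov)$M[ri] + mcols(cov)$U[ri], list(ctx, bin), sum)
  out <- expand.grid(context = rownames(M), bin = as.integer(colnames(M)),
                     stringsAsFactors = FALSE)
  out$level <- mapply(function(c1, b1) {
    m <- M[c1, as.character(b1)]; t <- Tt[c1, as.character(b1)]
    if (is.na(t) || t == 0) NA_real_ else m / t
  }, out$context, out$bin)
  out$segment <- c("upstream", "body", "downstream")[(out$bin - 1L) %/% B + 1L]
  out <- out[order(out$context, out$bin), c("context", "bin", "segment", "level")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Call differentially methylated regions
#'
#' Candidate regions are maximal runs of same-context cytosines covered in
#' both conditions with inter-cytosine gaps of at most `maxGap` bp. Within
#' each candidate the per-cytosine methylation levels of the two conditions
#' (replicate-pooled counts per site) are compared by a Mann-Whitney U
#' test; the region's methylation difference is the difference of pooled
#' levels (FR - R). P-values are BH-adjusted across all candidate regions
#' of the context, and a region is reported as a DMR only when it passes
#' all three filters: more than `minC - 1` cytosines, absolute difference
#' above `minDiff`, and adjusted p below `alpha`. Direction is `hyper`
#' when methylation is higher under FR than R, `hypo` otherwise.
#'
#' @param recordsR,recordsFR cytosine report `GRanges` of the R and FR
#'   conditions (mcols `context`, `M`, `U`).
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @param maxGap maximum gap between consecutive covered cytosines in a
#'   candidate region (default 300 bp).
#' @param minC minimum cytosines per DMR (default 6; the filter is
#'   "number of Cs > 5").
#' @param minDiff minimum absolute pooled-level difference (default 0.1).
#' @param alpha FDR gate (default 0.05).
#' @return `GRanges` of DMRs with mcols `context`, `n_cytosines`,
#'   `mean_level_R`, `mean_level_FR`, `diff`, `p`, `q`, `direction`; the
#'   number of candidate regions tested is stored in
#'   `metadata()$n_candidates`.
#' @export
callDmrs <- function(recordsR, recordsFR, context, maxGap = 300, minC = 6,
                     minDiff = 0.1, alpha = 0.05) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  selR <- mcols(recordsR)$context == context &
    (mcols(recordsR)$M + mcols(recordsR)$U) > 0
  selF <- mcols(recordsFR)$context == context &
    (mcols(recordsFR)$M + mcols(recordsFR)$U) > 0
  r <- recordsR[selR]; f <- recordsFR[selF]
  keyR <- paste(seqnames(r), start(r), strand(r))
  keyF <- paste(seqnames(f), start(f), strand(f))
  common <- intersect(keyR, keyF)
  empty <- GenomicRanges::GRanges()
  if (!length(common)) return(empty)
  r <- r[match(common, keyR)]; f <- f[match(common, keyF)]
  ord <- order(as.character(seqnames(r)), start(r))
  r <- r[ord]; f <- f[ord]
  chrom <- as.character(seqnames(r)); pos <- start(r)
  newRun <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                diff(pos) > maxGap)
  run <- cumsum(newRun)
  lr <- methylationLevel(mcols(r)$M, mcols(r)$U)
  lf <- methylationLevel(mcols(f)$M, mcols(f)$U)
  regs <- lapply(split(seq_along(run), run), function(ii) {
    mR <- sum(mcols(r)$M[ii]); tR <- sum(mcols(r)$M[ii] + mcols(r)$U[ii])
    mF <- sum(mcols(f)$M[ii]); tF <- sum(mcols(f)$M[ii] + mcols(f)$U[ii])
    p <- if (length(ii) < 2) 1 else
      suppressWarnings(stats::wilcox.test(lf[ii], lr[ii])$p.value)
    c(start = pos[ii[1]], end = pos[ii[length(ii)]], n = length(ii),
      mR = mR / tR, mF = mF / tF, p = if (is.na(p)) 1 else p)
  })
  tab <- do.call(rbind, regs)
  chromPer <- vapply(split(chrom, run), `[`, "", 1)
  q <- bhAdjust(tab[, "p"])
  diffs <- tab[, "mF"] - tab[, "mR"]
  pass <- tab[, "n"] >= minC & abs(diffs) > minDiff & q < alpha
  out <- GenomicRanges::GRanges(chromPer[pass],
                                IRanges(tab[pass, "start"], tab[pass, "end"]))
  mcols(out) <- S4Vectors::DataFrame(
    context = rep(context, sum(pass)), n_cytosines = as.integer(tab[pass, "n"]),
    mean_level_R = tab[pass, "mR"], mean_level_FR = tab[pass, "mF"],
    diff = diffs[pass], p = tab[pass, "p"], q = q[pass],
    direction = ifelse(diffs[pass] > 0, "hyper", "hypo"))
  if (length(out)) names(out) <- sprintf("dmr_%s_%04d", context, seq_along(out))
  metadata(out)$n_candidates <- nrow(tab)
  out
}

#' Overlap DMRs with genomic features
#'
#' Annotates every DMR with all features it overlaps by at least
#' `minOverlap` bp (a DMR may carry multiple feature labels) and derives a
#' per-DMR class: `gene-only`, `TE-only`, `both` or `neither`, where "gene"
#' means any overlap with a gene span.
#'
#' @param dmrs named `GRanges` of DMRs.
#' @param annotation feature `GRanges` with mcols `type` (gene, exon,
#'   intron, promoter, TE) and `gene_id`.
#' @param minOverlap minimum overlap in bp (default 1).
#' @return list with `assignments` (data.frame `dmr_id`, `feature_type`,
#'   `gene_id`) and `classes` (named character per DMR).
#' @export
overlapFeatures <- function(dmrs, annotation, minOverlap = 1) {
  hits <- GenomicRanges::findOverlaps(dmrs, annotation,
                                      minoverlap = minOverlap,
                                      ignore.strand = TRUE)
  asg <- data.frame(
    dmr_id = names(dmrs)[S4Vectors::queryHits(hits)],
    feature_type = mcols(annotation)$type[S4Vectors::subjectHits(hits)],
    gene_id = mcols(annotation)$gene_id[S4Vectors::subjectHits(hits)],
    row.names = NULL)
  asg <- unique(asg)
  geneHit <- tapply(asg$feature_type == "gene", asg$dmr_id, any)
  teHit <- tapply(asg$feature_type == "TE", asg$dmr_id, any)
  cls <- stats::setNames(rep("neither", length(dmrs)), names(dmrs))
  hitIds <- names(geneHit)
  cls[hitIds] <- ifelse(geneHit & teHit, "both",
                        ifelse(geneHit, "gene-only",
                               ifelse(teHit, "TE-only", "neither")))
  list(assignments = asg, classes = cls)
}
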