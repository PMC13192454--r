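#' Join DMRs with FR-DEGs by feature overlap
#'
#' Produces one record per (gene, DMR) pair in which the DMR overlaps the
#' gene's promoter, an exon or an intron by at least 1 bp. When a DMR
#' touches several features of the same gene, the record's `feature` label
#' follows the priority promoter > exon > intron and all labels are kept in
#' `features`.
#'
#' @param dmrs named `GRanges` of DMRs (mcols `context`, `direction`).
#' @param frDegs data.frame from [defineFrDegs()] (`gene_id`, `direction`).
#' @param annotation feature `GRanges` (mcols `type`, `gene_id`).
#' @return data.frame (`gene_id`, `dmr_id`, `context`, `feature`,
#'   `features`, `meth_direction`, `expr_direction`).
#' @export
associateDmrsWithDegs <- function(dmrs, frDegs, annotation) {
  feats <- annotation[mcols(annotation)$type %in%
                        c("promoter", "exon", "intron") &
                        mcols(annotation)$gene_id %in% frDegs$gene_id]
  hits <- GenomicRanges::findOverlaps(dmrs, feats, minoverlap = 1,
                                      ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(gene_id = character(), dmr_id = character(),
                      context = character(), feature = character(),
                      features = character(), meth_direction = character(),
                      expr_direction = character()))
  df <- data.frame(
    dmr_id = names(dmrs)[S4Vectors::queryHits(hits)],
    gene_id = mcols(feats)$gene_id[S4Vectors::subjectHits(hits)],
    feature = as.character(mcols(feats)$type[S4Vectors::subjectHits(hits)]))
  prio <- c(promoter = 1, exon = 2, intron = 3)
  df <- df[order(df$gene_id, df$dmr_id, prio[df$feature]), ]
  key <- paste(df$gene_id, df$dmr_id)
  first <- !duplicated(key)
  features <- tapply(df$feature, key, function(x)
    paste(unique(x), collapse = ","))
  out <- df[first, , drop = FALSE]
  out$features <- as.character(features[paste(out$gene_id, out$dmr_id)])
  di <- match(out$dmr_id, names(dmrs))
  out$context <- mcols(dmrs)$context[di]
  out$meth_direction <- mcols(dmrs)$direction[di]
  out$expr_direction <- frDegs$direction[match(out$gene_id, frDegs$gene_id)]
  rownames(out) <- NULL
  out[c("gene_id", "dmr_id", "context", "feature", "features",
        "meth_direction", "expr_direction")]
}

#' Attach sRNA differential-accumulation directions to records
#'
#' Maps the per-DMR per-size-class sRNA results onto the (gene, DMR)
#' records: `up`/`down` where the size class is significant, `ns`
#' otherwise. DMRs absent from the sRNA results get `ns` everywhere with a
#' warning.
#'
#' @param records data.frame from [associateDmrsWithDegs()].
#' @param srnaRes data.frame from [srnaAtRegions()] keyed by `region_id`.
#' @param sizes size classes carried (default 21, 22, 24).
#' @return records with added columns `srna_21`, `srna_22`, `srna_24` and
#'   `rddm_consistent` from [rddmVerdict()].
#' @export
attachSrna <- function(records, srnaRes, sizes = c(21, 22, 24)) {
  missing <- setdiff(records$dmr_id, srnaRes$region_id)
  if (length(missing))
    warning("DMR(s) absent from sRNA results, set to ns: ",
            paste(utils::head(missing, 5), collapse = ", "))
  for (s in sizes) {
    sub <- srnaRes[srnaRes$size == s, , drop = FALSE]
    dir <- sub$direction[match(records$dmr_id, sub$region_id)]
    dir[is.na(dir)] <- "ns"
    records[[paste0("srna_", s)]] <- dir
  }
  srnaMat <- as.matrix(records[paste0("srna_", sizes)])
  records$rddm_consistent <- rddmVerdict(records$meth_direction, srnaMat,
                                         records$expr_direction)
  records
}

#' RdDM-consistency verdict
#'
#' Under RNA-directed DNA methylation, methylation and sRNA accumulation
#' are expected to move together and opposite to mRNA expression. A record
#' is consistent iff (hypermethylated AND sRNA up in at least one of the
#' 21/22/24-nt classes AND expression down) OR (hypomethylated AND sRNA
#' down in at least one class AND expression up). A non-significant sRNA
#' class never supports consistency.
#'
#' @param methDirection `"hyper"`/`"hypo"` per record.
#' @param srnaDirections character matrix (records x size classes) of
#'   `"up"`/`"down"`/`"ns"`, or a single vector for one class.
#' @param exprDirection `"up"`/`"down"` per record.
#' @return logical vector.
#' @export
rddmVerdict <- function(methDirection, srnaDirections, exprDirection) {
  if (is.null(dim(srnaDirections)))
    srnaDirections <- matrix(srnaDirections, ncol = 1)
  anyUp <- rowSums(srnaDirections == "up") > 0
  anyDown <- rowSums(srnaDirections == "down") > 0
  (methDirection == "hyper" & anyUp & exprDirection == "down") |
    (methDirection == "hypo" & anyDown & exprDirection == "up")
}

#' Sankey path tallies of the multi-omics strata
#'
#' Counts records along (methylation direction -> sRNA direction ->
#' expression direction) paths, separately per size class, keeping only
#' records whose sRNA direction in that class is significant. Path weights
#' within a size class sum exactly to the number of such records.
#'
#' @param records data.frame from [attachSrna()].
#' @param sizes size classes (default 21, 22, 24).
#' @return data.frame (`size`, `meth_direction`, `srna_direction`,
#'   `expr_direction`, `n`).
#' @export
tallySankey <- function(records, sizes = c(21, 22, 24)) {
  out <- list()
  for (s in sizes) {
    dir <- records[[paste0("srna_", s)]]
    sel <- dir != "ns"
    if (!any(sel)) next
    t <- stats::aggregate(list(n = rep(1L, sum(sel))),
                          list(meth_direction = records$meth_direction[sel],
                               srna_direction = dir[sel],
                               expr_direction = records$expr_direction[sel]),
                          sum)
    t$size <- as.integer(s)
    out[[as.character(s)]] <- t[c("size", "meth_direction", "srna_direction",
                                  "expr_direction", "n")]
  }
  if (!length(out))
    return(data.frame(size = integer(), meth_direction = character(),
                      srna_direction = character(),
                      expr_direction = character(), n = integer()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-gene evidence report for RdDM candidate genes
#'
#' One row per (gene, DMR) record of every gene with at least one
#' RdDM-consistent record. Additional DMRs of the same gene that lack a
#' significant sRNA shift are listed too, flagged `srna_silent`. When a
#' network is given, each gene is annotated with its hub-neighborhood
#' level.
#'
#' @param records data.frame from [attachSrna()].
#' @param network optional [CoexprNetwork-class] with hubs set, or a named
#'   integer vector of node levels (gene -> BFS depth from nearest hub).
#' @return data.frame of candidate-gene evidence rows.
#' @export
candidateReport <- function(records, network = NULL) {
  cons <- tapply(records$rddm_consistent, records$gene_id, any)
  genes <- names(cons)[cons]
  out <- records[records$gene_id %in% genes, , drop = FALSE]
  srnaCols <- grep("^srna_", names(out), value = TRUE)
  out$srna_silent <- rowSums(as.matrix(out[srnaCols]) != "ns") == 0
  if (!is.null(network)) {
    lev <- if (is(network, "CoexprNetwork")) nodeLevels(network) else network
    out$network_level <- lev[out$gene_id]
    out$in_hub_network <- !is.na(out$network_level) & out$network_level <= 2
  }
  out <- out[order(out$gene_id, out$dmr_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
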