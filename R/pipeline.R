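.ALL_STAGES <- c("simulate", "de", "cluster", "network", "enrich", "srna",
                 "methylome", "integrate")

.need <- function(path, stage, from) {
  if (!file.exists(path))
    stop("stage '", stage, "' requires ", basename(path),
         "; run stage '", from, "' first")
  path
}

.provenance <- function(dir, stage, seed, params, inputs) {
  prov <- list(stage = stage, seed = seed, params = params,
               inputs = as.list(tools::md5sum(inputs)))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE,
                              na = "null"),
             file.path(dir, "provenance.json"))
}

.loadCounts <- function(outdir, stage) {
  simdir <- file.path(outdir, "simulate")
  sheet <- readSampleSheet(.need(file.path(simdir, "sample_sheet.tsv"),
                                 stage, "simulate"))
  readCounts(.need(file.path(simdir, "counts.tsv"), stage, "simulate"),
             sheet)
}

.stageDe <- function(outdir, config) {
  dir <- file.path(outdir, "de")
  dir.create(dir, showWarnings = FALSE)
  ce <- .loadCounts(outdir, "de")
  sheet <- as.data.frame(SummarizedExperiment::colData(ce))
  grp <- unique(sampleGroups(sheet))
  light <- setdiff(grp, "Ctrl_0")
  sf <- computeSizeFactors(ce)
  files <- character()
  sets <- list()
  for (g in light) {
    res <- deTest(ce, contrast = c(g, "Ctrl_0"), sizeFactors = sf)
    f <- file.path(dir, paste0("de_vsctrl_", g, ".tsv"))
    .writeTsv(res, f)
    files <- c(files, f)
    sets[[g]] <- res$gene_id[res$status != "ns"]
  }
  for (pair in utils::combn(light, 2, simplify = FALSE)) {
    res <- deTest(ce, contrast = pair, sizeFactors = sf)
    f <- file.path(dir, paste0("de_pairwise_", pair[1], "_", pair[2],
                               ".tsv"))
    .writeTsv(res, f)
    files <- c(files, f)
  }
  venn <- vennPartition(sets)
  writeLines(jsonlite::toJSON(venn, pretty = TRUE),
             file.path(dir, "venn.json"))
  .provenance(dir, "de", config@seed,
              list(alpha = 0.05, lfcMin = 1.5),
              file.path(outdir, "simulate", c("counts.tsv",
                                              "sample_sheet.tsv")))
  invisible(files)
}

.stageCluster <- function(outdir, config, nClusters = 10,
                          membershipMin = 0.7) {
  dir <- file.path(outdir, "cluster")
  dir.create(dir, showWarnings = FALSE)
  ce <- .loadCounts(outdir, "cluster")
  sheet <- as.data.frame(SummarizedExperiment::colData(ce))
  pw <- list.files(file.path(outdir, "de"), "^de_pairwise_.*tsv$",
                   full.names = TRUE)
  if (!length(pw)) stop("stage 'cluster' requires pairwise DE tables; ",
                        "run stage 'de' first")
  deList <- lapply(pw, .readTsv)
  genes <- selectClusterInput(ce, deList)
  z <- zscoreRows(log2(tpm(ce)[genes, , drop = FALSE] + 1))
  model <- fuzzyCMeans(z, c = nClusters, seed = config@seed,
                       membershipMin = membershipMin)
  labels <- labelClusterDirection(model, sheet)
  merged <- mergeRedundantClusters(model)
  frdegs <- defineFrDegs(model, labels)
  .writeTsv(data.frame(gene_id = rownames(memberships(model)),
                       memberships(model), check.names = FALSE),
            file.path(dir, "membership.tsv"))
  .writeTsv(data.frame(cluster = seq_len(nrow(centroids(model))),
                       centroids(model), check.names = FALSE),
            file.path(dir, "centroids.tsv"))
  .writeTsv(clusterAssignments(model), file.path(dir, "assignments.tsv"))
  .writeTsv(frdegs, file.path(dir, "frdegs.tsv"))
  writeLines(jsonlite::toJSON(list(labels = as.list(labels),
                                   merged_groups = as.list(merged),
                                   m = model@m),
                              auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "labels.json"))
  .provenance(dir, "cluster", config@seed,
              list(c = nClusters, membershipMin = membershipMin), pw)
  invisible(frdegs)
}

.stageNetwork <- function(outdir, config, quantile = 0.945,
                          pccFloor = c(up = 0.98, down = 0.97)) {
  dir <- file.path(outdir, "network")
  dir.create(dir, showWarnings = FALSE)
  ce <- .loadCounts(outdir, "network")
  frdegs <- .readTsv(.need(file.path(outdir, "cluster", "frdegs.tsv"),
                           "network", "cluster"))
  hubsFile <- file.path(outdir, "simulate", "hubs.txt")
  hubs <- if (file.exists(hubsFile)) readLines(hubsFile) else character()
  logT <- log2(tpm(ce) + 1)
  params <- list(quantile = quantile, pccFloor = as.list(pccFloor))
  for (d in c("up", "down")) {
    genes <- frdegs$gene_id[frdegs$direction == d]
    if (length(genes) < 5) {
      warning("fewer than 5 ", d, "-regulated FR-DEGs; network skipped")
      next
    }
    net <- buildAdjacency(logT[genes, , drop = FALSE], quantile = quantile,
                          pccFloor = pccFloor[[d]],
                          hubs = intersect(hubs, genes))
    .writeTsv(networkEdges(net), file.path(dir, paste0("edges_", d, ".tsv")))
    lev <- nodeLevels(net)
    .writeTsv(data.frame(gene_id = names(lev), level = unname(lev)),
              file.path(dir, paste0("levels_", d, ".tsv")))
    igraph::write_graph(net@graph,
                        file.path(dir, paste0("network_", d, ".graphml")),
                        format = "graphml")
    params[[paste0("retained_", d)]] <- net@params$fracRetained
    params[[paste0("effective_pcc_", d)]] <-
      net@params$effectivePccFromQuantile
  }
  .provenance(dir, "network", config@seed, params,
              file.path(outdir, "cluster", "frdegs.tsv"))
  invisible(params)
}

.stageEnrich <- function(outdir, config) {
  dir <- file.path(outdir, "enrich")
  dir.create(dir, showWarnings = FALSE)
  binMap <- .readTsv(.need(file.path(outdir, "simulate", "bin_map.tsv"),
                           "enrich", "simulate"))
  frdegs <- .readTsv(.need(file.path(outdir, "cluster", "frdegs.tsv"),
                           "enrich", "cluster"))
  for (d in c("up", "down")) {
    set <- intersect(frdegs$gene_id[frdegs$direction == d],
                     unique(binMap$gene_id))
    res <- enrich(set, binMap)
    .writeTsv(res, file.path(dir, paste0("enrichment_", d, ".tsv")))
  }
  .provenance(dir, "enrich", config@seed, list(alpha = 0.05),
              file.path(outdir, "simulate", "bin_map.tsv"))
  invisible(dir)
}

.loadSrnaProfile <- function(outdir, stage) {
  simdir <- file.path(outdir, "simulate")
  bed <- .readTsv(.need(file.path(simdir, "srna_loci.bed"), stage,
                        "simulate"), header = FALSE)
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand")
  loci <- GenomicRanges::GRanges(bed$chrom,
                                 IRanges(bed$start + 1L, bed$end))
  names(loci) <- bed$name
  long <- .readTsv(.need(file.path(simdir, "srna_counts.tsv"), stage,
                         "simulate"))
  libs <- .readTsv(.need(file.path(simdir, "srna_libsizes.tsv"), stage,
                         "simulate"))
  sheet <- readSampleSheet(file.path(simdir, "srna_sample_sheet.tsv"))
  samples <- sheet$sample_id
  sizes <- sort(unique(long$size))
  cnt <- array(0L, dim = c(length(loci), length(sizes), length(samples)),
               dimnames = list(names(loci), sizes, samples))
  cnt[cbind(match(long$locus, names(loci)), match(long$size, sizes),
            match(long$sample, samples))] <- long$count
  srnaProfile(cnt, loci, stats::setNames(libs$library_total, libs$sample_id),
              sheet)
}

.stageSrna <- function(outdir, config) {
  dir <- file.path(outdir, "srna")
  dir.create(dir, showWarnings = FALSE)
  simdir <- file.path(outdir, "simulate")
  profile <- rpmNormalize(.loadSrnaProfile(outdir, "srna"))
  .writeTsv(sizeDistribution(profile), file.path(dir, "size_distribution.tsv"))
  # locus-level categorization against the annotation
  ann <- readGff3(.need(file.path(simdir, "annotation.gff3"), "srna",
                        "simulate"))
  loci <- srnaRegions(profile)
  ov <- function(type) GenomicRanges::countOverlaps(
    loci, ann[mcols(ann)$type == type], ignore.strand = TRUE) > 0
  asg <- data.frame(genes = ov("gene"), miRNAs = FALSE, TEs = ov("TE"),
                    rRNA = FALSE, tRNA = FALSE,
                    count = apply(srnaCounts(profile), 1, sum))
  cat1 <- categorizeReads(asg)
  .writeTsv(data.frame(category = names(cat1), reads = as.numeric(cat1),
                       fraction = as.numeric(attr(cat1, "fraction"))),
            file.path(dir, "categories.tsv"))
  fam <- .readTsv(file.path(simdir, "mirna_family_counts.tsv"))
  famCnt <- as.matrix(fam[, -1, drop = FALSE])
  rownames(famCnt) <- fam$family
  sheet <- readSampleSheet(file.path(simdir, "srna_sample_sheet.tsv"))
  famDe <- mirnaFamilyDe(famCnt, sheet, c("FR_71", "R_71"),
                         libSizes(profile))
  .writeTsv(famDe, file.path(dir, "mirna_family_de.tsv"))
  frdegsPath <- file.path(outdir, "cluster", "frdegs.tsv")
  if (file.exists(frdegsPath)) {
    frdegs <- .readTsv(frdegsPath)
    targets <- .readTsv(file.path(simdir, "mirna_targets.tsv"))
    .writeTsv(crossrefMirnaTargets(famDe, frdegs, targets),
              file.path(dir, "mirna_target_crossref.tsv"))
  }
  .provenance(dir, "srna", config@seed, list(contrast = c("FR_71", "R_71")),
              file.path(simdir, "srna_counts.tsv"))
  invisible(dir)
}

.stageMethylome <- function(outdir, config, maxGap = 300, minC = 6,
                            minDiff = 0.1, alpha = 0.05) {
  dir <- file.path(outdir, "methylome")
  dir.create(dir, showWarnings = FALSE)
  simdir <- file.path(outdir, "simulate")
  repR <- readCytosineReport(.need(
    file.path(simdir, "cytosine_report_R.tsv"), "methylome", "simulate"))
  repFR <- readCytosineReport(.need(
    file.path(simdir, "cytosine_report_FR.tsv"), "methylome", "simulate"))
  glob <- rbind(data.frame(condition = "R", context = c("CG", "CHG", "CHH"),
                           level = unname(globalMethylation(repR))),
                data.frame(condition = "FR", context = c("CG", "CHG", "CHH"),
                           level = unname(globalMethylation(repFR))))
  .writeTsv(glob, file.path(dir, "global_methylation.tsv"))
  ann <- readGff3(.need(file.path(simdir, "annotation.gff3"), "methylome",
                        "simulate"))
  genes <- ann[mcols(ann)$type == "gene"]
  mg <- rbind(cbind(condition = "R", metageneProfile(repR, genes)),
              cbind(condition = "FR", metageneProfile(repFR, genes)))
  .writeTsv(mg, file.path(dir, "metagene.tsv"))
  dmrs <- suppressWarnings(do.call(c, lapply(c("CG", "CHG", "CHH"),
    function(ctx) callDmrs(repR, repFR, ctx, maxGap = maxGap, minC = minC,
                           minDiff = minDiff, alpha = alpha))))
  dmrDf <- data.frame(dmr_id = names(dmrs),
                      chrom = as.character(seqnames(dmrs)),
                      start = start(dmrs), end = end(dmrs),
                      as.data.frame(mcols(dmrs)))
  .writeTsv(dmrDf, file.path(dir, "dmrs.tsv"))
  .writeTsv(data.frame(chrom = dmrDf$chrom, start = dmrDf$start - 1L,
                       end = dmrDf$end, name = dmrDf$dmr_id, score = 0,
                       strand = "."),
            file.path(dir, "dmrs.bed"), col.names = FALSE)
  ovl <- overlapFeatures(dmrs, ann)
  .writeTsv(ovl$assignments, file.path(dir, "dmr_features.tsv"))
  .writeTsv(data.frame(dmr_id = names(ovl$classes),
                       class = unname(ovl$classes)),
            file.path(dir, "dmr_classes.tsv"))
  for (cond in c("R", "FR")) {
    rep <- if (cond == "R") repR else repFR
    cov <- rep[(mcols(rep)$M + mcols(rep)$U) > 0]
    for (ctx in c("CG", "CHG", "CHH")) {
      sub <- sort(cov[mcols(cov)$context == ctx], ignore.strand = TRUE)
      bg <- GenomicRanges::GRanges(seqnames(sub),
                                   IRanges(start(sub), end(sub)))
      mcols(bg)$score <- methylationLevel(mcols(sub)$M, mcols(sub)$U)
      rtracklayer::export(bg, file.path(dir, paste0("meth_", cond, "_",
                                                    ctx, ".bedGraph")),
                          format = "bedGraph")
    }
  }
  .provenance(dir, "methylome", config@seed,
              list(maxGap = maxGap, minC = minC, minDiff = minDiff,
                   alpha = alpha),
              file.path(simdir, c("cytosine_report_R.tsv",
                                  "cytosine_report_FR.tsv")))
  invisible(dmrs)
}

.stageIntegrate <- function(outdir, config, alpha = 0.05) {
  dir <- file.path(outdir, "integrate")
  dir.create(dir, showWarnings = FALSE)
  simdir <- file.path(outdir, "simulate")
  dmrDf <- .readTsv(.need(file.path(outdir, "methylome", "dmrs.tsv"),
                          "integrate", "methylome"))
  dmrs <- GenomicRanges::GRanges(dmrDf$chrom,
                                 IRanges(dmrDf$start, dmrDf$end))
  names(dmrs) <- dmrDf$dmr_id
  mcols(dmrs) <- S4Vectors::DataFrame(
    dmrDf[setdiff(names(dmrDf), c("dmr_id", "chrom", "start", "end"))])
  frdegs <- .readTsv(.need(file.path(outdir, "cluster", "frdegs.tsv"),
                           "integrate", "cluster"))
  ann <- readGff3(.need(file.path(simdir, "annotation.gff3"), "integrate",
                        "simulate"))
  profile <- .loadSrnaProfile(outdir, "integrate")
  srnaRes <- srnaAtRegions(profile, dmrs, c("FR_71", "R_71"),
                           alpha = alpha)
  .writeTsv(srnaRes, file.path(dir, "srna_at_dmrs.tsv"))
  records <- associateDmrsWithDegs(dmrs, frdegs, ann)
  records <- suppressWarnings(attachSrna(records, srnaRes))
  .writeTsv(records, file.path(dir, "integration.tsv"))
  sankey <- tallySankey(records)
  writeLines(jsonlite::toJSON(sankey, pretty = TRUE),
             file.path(dir, "sankey.json"))
  levels <- integer()
  for (d in c("up", "down")) {
    lf <- file.path(outdir, "network", paste0("levels_", d, ".tsv"))
    if (file.exists(lf)) {
      lt <- .readTsv(lf)
      levels <- c(levels, stats::setNames(lt$level, lt$gene_id))
    }
  }
  report <- candidateReport(records,
                            if (length(levels)) levels else NULL)
  .writeTsv(report, file.path(dir, "candidate_report.tsv"))
  .provenance(dir, "integrate", config@seed, list(alpha = alpha),
              file.path(outdir, "methylome", "dmrs.tsv"))
  invisible(records)
}

#' Run the integrative pipeline end to end
#'
#' Executes the requested stages in dependency order: `simulate` writes
#' every input; `de` runs all group-vs-control and pairwise light
#' contrasts; `cluster` soft-clusters the DEGs and defines the FR-DEG set;
#' `network` builds the up- and down-regulated co-expression networks
#' around the designated hubs; `enrich` tests functional bins; `srna`
#' profiles small RNAs and miRNA families; `methylome` computes global and
#' metagene methylation and calls DMRs; `integrate` joins DMRs, FR-DEGs
#' and sRNA shifts into RdDM-consistency records. Each stage writes TSV
#' outputs plus a `provenance.json` (stage, seed, parameters, input
#' checksums) into its own subdirectory of `outdir`, and a stage run later
#' than its dependencies reads their files from disk, so stage subsets
#' re-use previous outputs. All randomness is derived from the
#' configuration seed: two runs with the same configuration produce
#' byte-identical outputs.
#'
#' @param config a [SimulationConfig-class].
#' @param outdir output directory.
#' @param stages subset of stages to run (default all, in order).
#' @return invisibly, `outdir`.
#' @export
runPipeline <- function(config = simConfig(), outdir,
                        stages = .ALL_STAGES) {
  stopifnot(all(stages %in% .ALL_STAGES))
  stages <- .ALL_STAGES[.ALL_STAGES %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (stage in stages) {
    switch(stage,
           simulate = writeExperiment(simulateExperiment(config),
                                      file.path(outdir, "simulate")),
           de = .stageDe(outdir, config),
           cluster = .stageCluster(outdir, config),
           network = .stageNetwork(outdir, config),
           enrich = .stageEnrich(outdir, config),
           srna = .stageSrna(outdir, config),
           methylome = .stageMethylome(outdir, config),
           integrate = .stageIntegrate(outdir, config))
  }
  invisible(outdir)
}
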