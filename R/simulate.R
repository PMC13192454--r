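#' @importFrom GenomicRanges GRangesList
NULL

# fixed seed offsets: one RNG stream per generator so adding a generator
# never perturbs the others
.SEED_OFFSETS <- c(annotation = 11L, truth = 23L, counts = 37L,
                   methylome = 53L, srna = 71L, maps = 89L)

# ten temporal archetypes over (Ctrl_0, R_23, FR_23, R_71, FR_71):
# up/down under FR at day 1, day 3 or both; R-specific; shared
.ARCHETYPES <- rbind(
  c(0, 0,  1, 0,  0),  # 1  FR-up day 1
  c(0, 0,  0, 0,  1),  # 2  FR-up day 3
  c(0, 0,  1, 0,  1),  # 3  FR-up both days
  c(0, 0, -1, 0,  0),  # 4  FR-down day 1
  c(0, 0,  0, 0, -1),  # 5  FR-down day 3
  c(0, 0, -1, 0, -1),  # 6  FR-down both days
  c(0, 1,  0, 1,  0),  # 7  R-up both days
  c(0, -1, 0, -1, 0),  # 8  R-down both days
  c(0, 1,  1, 1,  1),  # 9  up under both lights
  c(0, -1, -1, -1, -1)) # 10 down under both lights

# FR-vs-R direction implied by each archetype under the labeling rule
.ARCHETYPE_FR_DIR <- c("up", "up", "up", "down", "down", "down",
                       "down", "up", NA, NA)

#' Build a simulation configuration
#'
#' All defaults together define the study conditions of the synthetic
#' experiment; see [SimulationConfig-class] for the meaning of each
#' parameter.
#'
#' @param seed master seed.
#' @param nGenes,nTE,chromLength annotation geometry.
#' @param nSamplesPerGroup replicates per group.
#' @param groups condition x timepoint layout.
#' @param nbDispersion NB dispersion of counts.
#' @param baseMeth baseline methylation per context (plumbing defaults,
#'   not estimates).
#' @param methCoverage mean pooled coverage per cytosine.
#' @param plantedDegFrac,plantedLog2fcRange planted DEG design.
#' @param nPlantedDmrs,nNullMethWindows,dmrEffect,methWindowWidth planted
#'   methylome design.
#' @param nRddmGenes,srnaShiftFold planted RdDM design.
#' @return a validated [SimulationConfig-class].
#' @export
simConfig <- function(seed = 1, nGenes = 300, nTE = 80,
                      chromLength = 1600000, nSamplesPerGroup = 4,
                      groups = data.frame(
                        condition = c("Ctrl", "R", "FR", "R", "FR"),
                        timepoint = c(0, 23, 23, 71, 71)),
                      nbDispersion = 0.05,
                      baseMeth = c(CG = 0.7, CHG = 0.5, CHH = 0.1),
                      methCoverage = 20, plantedDegFrac = 0.3,
                      plantedLog2fcRange = c(2, 3), nPlantedDmrs = 200,
                      nNullMethWindows = 2000, dmrEffect = 0.4,
                      nRddmGenes = 12, srnaShiftFold = 4,
                      methWindowWidth = 200) {
  new("SimulationConfig", seed = as.integer(seed),
      nGenes = as.integer(nGenes), nTE = as.integer(nTE),
      chromLength = as.integer(chromLength),
      nSamplesPerGroup = as.integer(nSamplesPerGroup), groups = groups,
      nbDispersion = nbDispersion, baseMeth = baseMeth,
      methCoverage = methCoverage, plantedDegFrac = plantedDegFrac,
      plantedLog2fcRange = plantedLog2fcRange,
      nPlantedDmrs = as.integer(nPlantedDmrs),
      nNullMethWindows = as.integer(nNullMethWindows),
      dmrEffect = dmrEffect, nRddmGenes = as.integer(nRddmGenes),
      srnaShiftFold = srnaShiftFold,
      methWindowWidth = as.integer(methWindowWidth))
}

.deriveGeneFeatures <- function(genes, exons, seqlen = NA) {
  exByGene <- S4Vectors::split(exons, mcols(exons)$gene_id)[mcols(genes)$gene_id]
  introns <- GenomicRanges::psetdiff(GenomicRanges::granges(genes), exByGene)
  intr <- unlist(introns)
  if (length(intr)) {
    gid <- rep(mcols(genes)$gene_id, lengths(introns))
    mcols(intr) <- S4Vectors::DataFrame(type = rep("intron", length(intr)),
                                        gene_id = gid)
  } else {
    mcols(intr) <- S4Vectors::DataFrame(type = character(),
                                        gene_id = character())
  }
  minus <- as.character(strand(genes)) == "-"
  ps <- ifelse(minus, end(genes) + 1L, start(genes) - 2000L)
  pe <- ifelse(minus, end(genes) + 2000L, start(genes) - 1L)
  ps <- pmax(ps, 1L)
  if (!is.na(seqlen)) pe <- pmin(pe, seqlen)
  ok <- pe >= ps
  prom <- GenomicRanges::GRanges(as.character(seqnames(genes))[ok],
                                 IRanges(ps[ok], pe[ok]),
                                 strand = strand(genes)[ok])
  mcols(prom) <- S4Vectors::DataFrame(
    type = rep("promoter", sum(ok)), gene_id = mcols(genes)$gene_id[ok])
  list(introns = intr, promoters = prom)
}

#' Simulate a gene/TE annotation and a random genome
#'
#' Places `nGenes` non-overlapping genes (1--4 exons each, introns derived
#' as the gaps) along one chromosome with strand-aware 2-kb promoters, and
#' `nTE` transposable-element intervals that may overlap gene bodies. The
#' genome is uniform random DNA, which contains all three cytosine contexts
#' on both strands.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `annotation` (feature `GRanges`: gene, exon, intron,
#'   promoter, TE) and `genome` (a `DNAStringSet` of one chromosome,
#'   `chr1`).
#' @export
simulateAnnotation <- function(config) {
  set.seed(config@seed + .SEED_OFFSETS[["annotation"]])
  n <- config@nGenes
  L <- config@chromLength
  lens <- sample(900:3000, n, replace = TRUE)
  gaps <- sample(2200:3200, n, replace = TRUE)
  starts <- 2000L + cumsum(gaps) + c(0L, cumsum(lens))[seq_len(n)]
  ends <- starts + lens - 1L
  if (ends[n] + 2000L > L)
    stop("infeasible packing: ", n, " genes need more than ", L,
         " bp; increase chromLength")
  std <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("g%04d", seq_len(n))
  genes <- GenomicRanges::GRanges("chr1", IRanges(starts, ends), strand = std)
  mcols(genes) <- S4Vectors::DataFrame(type = "gene", gene_id = ids)
  exList <- lapply(seq_len(n), function(i) {
    k <- sample(1:4, 1)
    if (k == 1) return(cbind(starts[i], ends[i]))
    ints <- sample(60:150, k - 1, replace = TRUE)
    rem <- lens[i] - sum(ints)
    extra <- rem - 60L * k
    add <- if (extra > 0) tabulate(sample.int(k, extra, replace = TRUE), k)
           else integer(k)
    el <- 60L + add
    es <- starts[i] + c(0L, cumsum(el + c(ints, 0L)))[seq_len(k)]
    cbind(es, es + el - 1L)
  })
  exm <- do.call(rbind, exList)
  exons <- GenomicRanges::GRanges("chr1", IRanges(exm[, 1], exm[, 2]),
                                  strand = rep(std, vapply(exList, nrow, 1L)))
  mcols(exons) <- S4Vectors::DataFrame(
    type = "exon", gene_id = rep(ids, vapply(exList, nrow, 1L)))
  teLen <- sample(300:2000, config@nTE, replace = TRUE)
  teStart <- vapply(teLen, function(l) sample.int(L - l, 1), 1L)
  tes <- GenomicRanges::GRanges("chr1", IRanges(teStart, teStart + teLen - 1L),
                                strand = sample(c("+", "-"), config@nTE,
                                                replace = TRUE))
  mcols(tes) <- S4Vectors::DataFrame(type = "TE", gene_id = NA_character_)
  der <- .deriveGeneFeatures(genes, exons, seqlen = L)
  ann <- suppressWarnings(c(genes, exons, der$introns, der$promoters, tes))
  GenomeInfoDb::seqlengths(ann) <- L
  genome <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  names(genome) <- "chr1"
  list(annotation = sort(ann), genome = genome)
}

#' Plan the planted ground truth
#'
#' Chooses the planted DEGs (archetype and effect size per gene), the
#' methylation windows (planted DMRs and null candidate regions, mutually
#' separated by more than the DMR caller's gap), the sRNA shift labels, the
#' RdDM-consistent genes whose triples satisfy the consistency rule by
#' construction, and two designated hub genes (one FR-up, one FR-down).
#'
#' @param config a [SimulationConfig-class].
#' @param annotation annotation `GRanges` from [simulateAnnotation()].
#' @return list of ground-truth components (`degLabels`, `frDegs`,
#'   `methWindows`, `srnaShifts`, `rddmGenes`, `hubGenes`).
#' @export
planTruth <- function(config, annotation) {
  set.seed(config@seed + .SEED_OFFSETS[["truth"]])
  genes <- annotation[mcols(annotation)$type == "gene"]
  ids <- mcols(genes)$gene_id
  nDeg <- round(config@plantedDegFrac * config@nGenes)
  degIds <- sort(sample(ids, nDeg))
  arch <- rep_len(1:10, nDeg)[sample.int(nDeg)]
  lfc <- stats::runif(nDeg, config@plantedLog2fcRange[1],
                      config@plantedLog2fcRange[2])
  degLabels <- data.frame(gene_id = degIds, archetype = arch, log2fc = lfc,
                          fr_direction = .ARCHETYPE_FR_DIR[arch])
  frDegs <- degLabels[!is.na(degLabels$fr_direction),
                      c("gene_id", "fr_direction")]
  names(frDegs) <- c("gene_id", "direction")

  # RdDM genes: expression direction at day 3 paired with the opposite
  # methylation direction and a matching sRNA shift
  upPool <- degLabels$gene_id[degLabels$archetype %in% c(2, 3)]
  downPool <- degLabels$gene_id[degLabels$archetype %in% c(5, 6)]
  nUp <- config@nRddmGenes %/% 2
  nDown <- config@nRddmGenes - nUp
  rddmUp <- sort(sample(upPool, nUp))      # expr up -> hypo DMR, sRNA down
  rddmDown <- sort(sample(downPool, nDown)) # expr down -> hyper DMR, sRNA up
  rddm <- data.frame(
    gene_id = c(rddmUp, rddmDown),
    expr_direction = c(rep("up", nUp), rep("down", nDown)),
    meth_direction = c(rep("hypo", nUp), rep("hyper", nDown)),
    srna_direction = c(rep("down", nUp), rep("up", nDown)))

  w <- config@methWindowWidth
  # place the RdDM DMR window inside the promoter or gene body
  feats <- annotation[mcols(annotation)$type %in% c("promoter", "exon",
                                                    "intron")]
  rddmStart <- integer(nrow(rddm))
  rddmFeat <- character(nrow(rddm))
  for (i in seq_len(nrow(rddm))) {
    cand <- feats[mcols(feats)$gene_id == rddm$gene_id[i] &
                    width(feats) >= w + 2L]
    pick <- cand[sample.int(length(cand), 1)]
    rddmStart[i] <- start(pick) + sample.int(width(pick) - w, 1)
    rddmFeat[i] <- as.character(mcols(pick)$type)
  }
  # remaining windows on a grid whose spacing exceeds the caller's max gap
  grid <- seq(2001L, config@chromLength - w - 2000L, by = 650L)
  far <- vapply(grid, function(g) all(abs(g - rddmStart) > w + 400L), TRUE)
  grid <- grid[far]
  nOther <- config@nPlantedDmrs - nrow(rddm)
  pick <- sort(sample(grid, nOther + config@nNullMethWindows))
  otherStart <- pick[seq_len(nOther)]
  nullStart <- pick[-seq_len(nOther)]
  otherCtx <- sample(c("CHH", "CG", "CHG"), nOther, replace = TRUE,
                     prob = c(0.8, 0.1, 0.1))
  otherDir <- sample(c("hyper", "hypo"), nOther, replace = TRUE)
  allStart <- c(rddmStart, otherStart, nullStart)
  ord <- order(allStart)
  windows <- GenomicRanges::GRanges("chr1",
                                    IRanges(allStart, allStart + w - 1L))
  mcols(windows) <- S4Vectors::DataFrame(
    planted = c(rep(TRUE, config@nPlantedDmrs),
                rep(FALSE, config@nNullMethWindows)),
    context = c(rep("CHH", nrow(rddm)), otherCtx,
                rep(NA_character_, config@nNullMethWindows)),
    direction = c(rddm$meth_direction, otherDir,
                  rep(NA_character_, config@nNullMethWindows)),
    rddm_gene = c(rddm$gene_id,
                  rep(NA_character_, nOther + config@nNullMethWindows)),
    feature = c(rddmFeat,
                rep(NA_character_, nOther + config@nNullMethWindows)))
  windows <- windows[ord]
  names(windows) <- sprintf("w%04d", seq_along(windows))
  rddm$window_id <- names(windows)[match(rddm$gene_id,
                                         mcols(windows)$rddm_gene)]
  srnaShifts <- data.frame(region_id = rddm$window_id,
                           direction = rddm$srna_direction,
                           sizes = rep("21,22,24", nrow(rddm)),
                           fold = rep(config@srnaShiftFold, nrow(rddm)))
  pickHub <- function(arch, dir) {
    pool <- setdiff(degLabels$gene_id[degLabels$archetype %in% arch],
                    rddm$gene_id)
    if (!length(pool))
      pool <- frDegs$gene_id[frDegs$direction == dir]
    if (!length(pool)) return(character())
    sample(pool, 1)
  }
  hubs <- c(pickHub(3, "up"), pickHub(6, "down"))
  list(degLabels = degLabels, frDegs = frDegs, methWindows = windows,
       srnaShifts = srnaShifts, rddmGenes = rddm, hubGenes = hubs)
}

#' Simulate the gene-level count matrix
#'
#' Negative-binomial counts per gene and sample. Planted DEGs have their
#' group means scaled by `2^(+-log2fc)` following the gene's temporal
#' archetype; all other genes share one mean across groups. Gene lengths
#' are the summed exon widths.
#'
#' @param config a [SimulationConfig-class].
#' @param annotation annotation `GRanges`.
#' @param truth ground truth from [planTruth()].
#' @return a [CountExperiment-class].
#' @export
simulateCounts <- function(config, annotation, truth) {
  set.seed(config@seed + .SEED_OFFSETS[["counts"]])
  genes <- annotation[mcols(annotation)$type == "gene"]
  ids <- mcols(genes)$gene_id
  exons <- annotation[mcols(annotation)$type == "exon"]
  lens <- tapply(width(exons), mcols(exons)$gene_id, sum)[ids]
  base <- stats::rlnorm(length(ids), log(100), 1)
  names(base) <- ids
  planted <- truth$degLabels$gene_id
  base[planted] <- pmax(base[planted], 50)
  grp <- config@groups
  nrep <- config@nSamplesPerGroup
  sheet <- data.frame(
    sample_id = paste(rep(grp$condition, each = nrep),
                      rep(grp$timepoint, each = nrep),
                      paste0("r", seq_len(nrep)), sep = "_"),
    condition = rep(grp$condition, each = nrep),
    timepoint = rep(grp$timepoint, each = nrep),
    replicate = rep(seq_len(nrep), nrow(grp)))
  sign <- matrix(0, length(ids), nrow(grp), dimnames = list(ids, NULL))
  sign[planted, ] <- .ARCHETYPES[truth$degLabels$archetype, , drop = FALSE]
  lfc <- stats::setNames(rep(0, length(ids)), ids)
  lfc[planted] <- truth$degLabels$log2fc
  mu <- base * 2^(sign * lfc)
  mu <- mu[, rep(seq_len(nrow(grp)), each = nrep)]
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = 1 / config@nbDispersion),
                nrow = length(ids),
                dimnames = list(ids, sheet$sample_id))
  countExperiment(cnt, as.integer(lens), sheet)
}

.windowSites <- function(chars, windows) {
  pos <- unlist(lapply(seq_along(windows), function(i)
    start(windows)[i]:end(windows)[i]))
  win <- rep(names(windows), width(windows))
  isC <- chars[pos] == "C"
  isG <- chars[pos] == "G"
  sites <- data.frame(pos = c(pos[isC], pos[isG]),
                      strand = c(rep("+", sum(isC)), rep("-", sum(isG))),
                      window = c(win[isC], win[isG]))
  sites <- sites[order(sites$pos, sites$strand), ]
  ctx <- .contextFromChars(chars, sites$pos, sites$strand)
  sites$context <- as.character(ctx)
  sites
}

#' Simulate per-cytosine bisulfite reports for the R and FR conditions
#'
#' Cytosines inside the truth's methylation windows get coverage drawn from
#' `Poisson(methCoverage)` (replicate-pooled) and methylated counts from
#' `Binomial(coverage, level)`. Baseline levels follow `baseMeth` per
#' context; inside a planted window the window's context has baseline 0.5
#' in both conditions (an RdDM-target-like locus) and the FR level is
#' shifted by the signed `dmrEffect`, clipped to `[0, 1]`; the realized
#' (post-clipping) effect is recorded in the returned truth attribute.
#' Zero-coverage sites are emitted with 0/0 counts.
#'
#' @param config a [SimulationConfig-class].
#' @param annotation annotation `GRanges` (unused placements are taken from
#'   `truth`; kept for interface symmetry).
#' @param truth ground truth from [planTruth()].
#' @param genome `DNAStringSet` from [simulateAnnotation()].
#' @return list with elements `R` and `FR`, each a cytosine-report
#'   `GRanges` (mcols `context`, `M`, `U`), and attribute
#'   `"effectiveEffect"` (named per planted window).
#' @export
simulateMethylome <- function(config, annotation, truth, genome) {
  set.seed(config@seed + .SEED_OFFSETS[["methylome"]])
  chars <- strsplit(as.character(genome[[1]]), "")[[1]]
  w <- truth$methWindows
  sites <- .windowSites(chars, w)
  wi <- match(sites$window, names(w))
  planted <- mcols(w)$planted[wi] &
    !is.na(mcols(w)$context[wi]) & mcols(w)$context[wi] == sites$context
  baseLevel <- config@baseMeth[sites$context]
  baseLevel[planted] <- 0.5
  dirSign <- ifelse(mcols(w)$direction[wi] == "hyper", 1, -1)
  frLevel <- baseLevel
  frLevel[planted] <- pmin(pmax(
    baseLevel[planted] + dirSign[planted] * config@dmrEffect, 0), 1)
  eff <- tapply(frLevel[planted] - baseLevel[planted], sites$window[planted],
                function(x) x[1])
  mk <- function(level) {
    cov <- stats::rpois(nrow(sites), config@methCoverage)
    M <- stats::rbinom(nrow(sites), cov, level)
    gr <- GenomicRanges::GRanges("chr1", IRanges(sites$pos, sites$pos),
                                 strand = sites$strand)
    mcols(gr) <- S4Vectors::DataFrame(context = sites$context, M = M,
                                      U = cov - M)
    gr
  }
  out <- list(R = mk(baseLevel), FR = mk(frLevel))
  attr(out, "effectiveEffect") <- eff
  out
}

#' Simulate the locus-level small-RNA profile and miRNA-family table
#'
#' Per-locus per-size-class negative-binomial counts for four R and four FR
#' replicates at 71 h, with the size distribution peaking at 24 nt and
#' secondary 21/22-nt modes. Loci flagged in the truth's sRNA shift labels
#' have their FR means multiplied (divided) by the shift fold in the
#' 21/22/24-nt classes. Library totals are the assigned reads plus a
#' simulated unassigned remainder. A 15-family miRNA count table with five
#' planted differential families and a family-to-target map (biased towards
#' FR-DEGs for the planted families) is generated alongside.
#'
#' @param config a [SimulationConfig-class].
#' @param annotation annotation `GRanges`.
#' @param truth ground truth from [planTruth()].
#' @return list: `profile` ([SRNAProfile-class]), `familyCounts` (matrix),
#'   `familyInfo` (data.frame `family`, `conserved`, `planted_direction`),
#'   `targetMap` (data.frame `family`, `gene_id`).
#' @export
simulateSrna <- function(config, annotation, truth) {
  set.seed(config@seed + .SEED_OFFSETS[["srna"]])
  regions <- truth$methWindows
  nR <- length(regions)
  sizes <- 18:28
  wts <- c(1, 1, 2, 8, 6, 2, 14, 3, 2, 1, 1) / 41
  names(wts) <- sizes
  nrep <- config@nSamplesPerGroup
  sheet <- data.frame(
    sample_id = paste(rep(c("R", "FR"), each = nrep), 71,
                      paste0("r", seq_len(nrep)), sep = "_"),
    condition = rep(c("R", "FR"), each = nrep), timepoint = 71,
    replicate = rep(seq_len(nrep), 2))
  activity <- stats::rlnorm(nR, log(80), 0.8)
  shifted <- names(regions) %in% truth$srnaShifts$region_id
  activity[shifted] <- pmax(activity[shifted], 200)
  mu <- outer(activity, wts)                       # locus x size
  cnt <- array(0L, dim = c(nR, length(sizes), nrow(sheet)),
               dimnames = list(names(regions), sizes, sheet$sample_id))
  shiftDir <- truth$srnaShifts$direction[match(names(regions),
                                               truth$srnaShifts$region_id)]
  shiftSizes <- as.character(c(21, 22, 24))
  for (j in seq_len(nrow(sheet))) {
    m <- mu
    if (sheet$condition[j] == "FR" && any(shifted)) {
      fac <- ifelse(shiftDir[shifted] == "up", config@srnaShiftFold,
                    1 / config@srnaShiftFold)
      m[shifted, shiftSizes] <- m[shifted, shiftSizes] * fac
    }
    cnt[, , j] <- stats::rnbinom(length(m), mu = m,
                                 size = 1 / config@nbDispersion)
  }
  assigned <- apply(cnt, 3, sum)
  unassigned <- stats::rnbinom(nrow(sheet), mu = assigned * 1.5, size = 50)
  lib <- stats::setNames(assigned + unassigned, sheet$sample_id)
  profile <- srnaProfile(cnt, regions, lib, sheet)

  fams <- c(paste0("miR", c(156, 159, 160, 164, 166, 167, 171, 390, 396,
                            399)), paste0("ccam-sRNA", 1:5))
  conserved <- c(rep(TRUE, 10), rep(FALSE, 5))
  famBase <- stats::rlnorm(length(fams), log(300), 0.7)
  plantedFam <- c(sample(which(conserved), 3), sample(which(!conserved), 2))
  famDir <- rep(NA_character_, length(fams))
  famDir[plantedFam] <- sample(c("up", "down"), 5, replace = TRUE)
  famMu <- matrix(famBase, length(fams), nrow(sheet),
                  dimnames = list(fams, sheet$sample_id))
  fr <- sheet$condition == "FR"
  fac <- ifelse(is.na(famDir), 1, ifelse(famDir == "up", 4, 0.25))
  famMu[, fr] <- famMu[, fr] * fac
  famCnt <- matrix(stats::rnbinom(length(famMu), mu = famMu,
                                  size = 1 / config@nbDispersion),
                   nrow = length(fams), dimnames = dimnames(famMu))
  genes <- mcols(annotation)$gene_id[mcols(annotation)$type == "gene"]
  targetMap <- do.call(rbind, lapply(seq_along(fams), function(i) {
    k <- sample(2:4, 1)
    tg <- sample(genes, k)
    if (i %in% plantedFam)
      tg[1] <- sample(truth$frDegs$gene_id, 1)
    data.frame(family = fams[i], gene_id = tg)
  }))
  list(profile = profile, familyCounts = famCnt,
       familyInfo = data.frame(family = fams, conserved = conserved,
                               planted_direction = famDir),
       targetMap = targetMap)
}

.simulateBinMap <- function(config, truth, annotation) {
  set.seed(config@seed + .SEED_OFFSETS[["maps"]])
  genes <- mcols(annotation)$gene_id[mcols(annotation)$type == "gene"]
  bins <- sprintf("B%02d", 1:20)
  rows <- lapply(genes, function(g)
    data.frame(gene_id = g, bin_id = sample(bins[-1], sample(1:3, 1))))
  map <- do.call(rbind, rows)
  # one bin planted as enriched among FR-upregulated genes
  up <- truth$frDegs$gene_id[truth$frDegs$direction == "up"]
  inBin <- c(up[stats::runif(length(up)) < 0.6],
             sample(setdiff(genes, up), max(1, round(0.05 * length(genes)))))
  map <- rbind(map, data.frame(gene_id = unique(inBin), bin_id = "B01"))
  map <- unique(map)
  map$bin_name <- paste0("bin ", map$bin_id)
  map[order(map$gene_id, map$bin_id), ]
}

#' Simulate the complete in-silico light-response experiment
#'
#' Runs annotation, truth planning, count, methylome and sRNA generation in
#' order, each on its own seed-derived RNG stream, and adds a functional
#' bin map. All outputs are reproduced bit-for-bit under the same
#' configuration.
#'
#' @param config a [SimulationConfig-class].
#' @return list: `config`, `annotation`, `genome`, `truth`, `counts`
#'   ([CountExperiment-class]), `methylome` (list R/FR `GRanges`), `srna`
#'   (list from [simulateSrna()]), `binMap`.
#' @export
simulateExperiment <- function(config = simConfig()) {
  ann <- simulateAnnotation(config)
  truth <- planTruth(config, ann$annotation)
  counts <- simulateCounts(config, ann$annotation, truth)
  meth <- simulateMethylome(config, ann$annotation, truth, ann$genome)
  truth$effectiveEffect <- attr(meth, "effectiveEffect")
  srna <- simulateSrna(config, ann$annotation, truth)
  binMap <- .simulateBinMap(config, truth, ann$annotation)
  list(config = config, annotation = ann$annotation, genome = ann$genome,
       truth = truth, counts = counts, methylome = meth, srna = srna,
       binMap = binMap)
}
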