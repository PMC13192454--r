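#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' Simulation configuration for the synthetic light-response experiment
#'
#' Holds every tunable of the synthetic-data module: genome and annotation
#' geometry, the sample layout (condition x timepoint groups), the
#' negative-binomial expression model, the per-context binomial methylation
#' model, and the planted-signal design (DEG archetypes, DMRs, sRNA shifts,
#' RdDM-consistent genes). A fixed `seed` makes all four generators
#' bit-reproducible; each generator draws from its own stream derived from
#' the master seed by a fixed offset so that adding one generator never
#' perturbs another.
#'
#' Default base methylation levels (CG 0.7, CHG 0.5, CHH 0.1) are arbitrary
#' configuration defaults chosen to span the dynamic range of plant
#' methylomes; they are plumbing values, not estimates of any real genome.
#'
#' @slot seed master RNG seed (integer).
#' @slot nGenes,nTE number of genes and transposable-element intervals.
#' @slot chromLength chromosome length in bp.
#' @slot nSamplesPerGroup replicates per condition x timepoint group.
#' @slot groups data.frame with columns `condition` (Ctrl/R/FR) and
#'   `timepoint` (hours: 0, 23, 71).
#' @slot nbDispersion negative-binomial dispersion of counts.
#' @slot baseMeth named numeric, baseline methylation fraction per context.
#' @slot methCoverage mean pooled read coverage per cytosine.
#' @slot plantedDegFrac fraction of genes planted as DEGs.
#' @slot plantedLog2fcRange interval of planted |log2 fold changes|;
#'   the lower bound must be at least the 1.5 DE gate so planted DEGs are
#'   recoverable by construction.
#' @slot nPlantedDmrs,nNullMethWindows planted DMR windows and additional
#'   unshifted methylation windows (candidate-region nulls).
#' @slot dmrEffect methylation-level difference planted inside DMR windows.
#' @slot nRddmGenes number of genes planted to satisfy the RdDM-consistency
#'   rule (DMR in promoter/gene body + sRNA shift + opposite expression).
#' @slot srnaShiftFold fold change planted at shifted sRNA loci (21/22/24 nt).
#' @slot methWindowWidth width in bp of each methylation window.
#' @export
setClass("SimulationConfig", representation(
  seed = "integer", nGenes = "integer", nTE = "integer",
  chromLength = "integer", nSamplesPerGroup = "integer",
  groups = "data.frame", nbDispersion = "numeric", baseMeth = "numeric",
  methCoverage = "numeric", plantedDegFrac = "numeric",
  plantedLog2fcRange = "numeric", nPlantedDmrs = "integer",
  nNullMethWindows = "integer", dmrEffect = "numeric",
  nRddmGenes = "integer", srnaShiftFold = "numeric",
  methWindowWidth = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  frac01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (length(object@seed) != 1L) msg <- c(msg, "seed must be a single integer")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
  if (!frac01(object@plantedDegFrac)) msg <- c(msg, "plantedDegFrac must be in [0,1]")
  if (!frac01(object@baseMeth) ||
      !all(c("CG", "CHG", "CHH") %in% names(object@baseMeth)))
    msg <- c(msg, "baseMeth must give a fraction in [0,1] for CG, CHG and CHH")
  if (length(object@plantedLog2fcRange) != 2L ||
      object@plantedLog2fcRange[1] < 1.5)
    msg <- c(msg, "plantedLog2fcRange lower bound must be >= 1.5 (the DE gate)")
  if (object@dmrEffect <= 0 || object@dmrEffect > 1)
    msg <- c(msg, "dmrEffect must be in (0, 1]")
  if (!all(object@groups$condition %in% c("Ctrl", "R", "FR")))
    msg <- c(msg, "groups$condition must be Ctrl, R or FR")
  if (length(msg)) msg else TRUE
})

#' Small-RNA profile: loci x size class x sample counts
#'
#' Container for locus-level small-RNA counts stratified by read length
#' (size classes 18--28 nt inclusive), together with per-sample library
#' totals of genome-matching 18--28 nt reads used for RPM normalization.
#'
#' @slot counts 3-d integer array, loci x size classes x samples.
#' @slot regions `GRanges` of the sRNA loci (one per count row).
#' @slot libSizes named numeric, genome-matching 18--28 nt reads per sample.
#' @slot sampleSheet data.frame with `sample_id`, `condition`, `timepoint`,
#'   `replicate` rows matching the sample dimension.
#' @slot rpm numeric array of the same shape as `counts`, filled by
#'   [rpmNormalize()]; empty until then.
#' @export
setClass("SRNAProfile", representation(
  counts = "array", regions = "GRanges", libSizes = "numeric",
  sampleSheet = "data.frame", rpm = "array"))

setValidity("SRNAProfile", function(object) {
  d <- dim(object@counts)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "counts must be a 3-d array")
  sizes <- as.integer(dimnames(object@counts)[[2]])
  if (!identical(sizes, 18:28))
    msg <- c(msg, "size classes must be 18..28 nt inclusive")
  if (d[1] != length(object@regions))
    msg <- c(msg, "one region per count row required")
  if (d[3] != length(object@libSizes))
    msg <- c(msg, "one library total per sample required")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (length(object@rpm) && !identical(dim(object@rpm), d))
    msg <- c(msg, "rpm must match the shape of counts")
  if (length(msg)) msg else TRUE
})

#' Fuzzy c-means soft clustering model
#'
#' @slot centroids c x T matrix of cluster centres in z-score space.
#' @slot membership N x c matrix; each row sums to 1.
#' @slot m fuzzifier (> 1).
#' @slot objective value of the fuzzy c-means objective at each iteration of
#'   the winning restart (non-increasing by construction).
#' @slot assignments data.frame of retained genes (`gene_id`, `cluster`,
#'   `membership`): argmax membership where the maximum is at least
#'   `membershipMin`, ties broken by lowest cluster index.
#' @slot membershipMin retention threshold (default 0.7).
#' @export
setClass("ClusterModel", representation(
  centroids = "matrix", membership = "matrix", m = "numeric",
  objective = "numeric", assignments = "data.frame",
  membershipMin = "numeric"))

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (nrow(object@membership) &&
      max(abs(rowSums(object@membership) - 1)) > 1e-6)
    msg <- c(msg, "membership rows must sum to 1")
  if (object@m <= 1) msg <- c(msg, "fuzzifier m must be > 1")
  if (nrow(object@assignments) &&
      any(object@assignments$membership < object@membershipMin))
    msg <- c(msg, "retained genes must have membership >= membershipMin")
  if (anyDuplicated(object@assignments$gene_id))
    msg <- c(msg, "each retained gene is assigned to exactly one cluster")
  if (length(msg)) msg else TRUE
})

#' Thresholded co-expression network
#'
#' An undirected graph over genes whose pairwise Pearson correlations,
#' Fisher-Z transformed and standardized over all pairs, exceed the normal
#' quantile cutoff, and whose raw correlation exceeds the PCC floor.
#'
#' @slot graph the underlying `igraph` object.
#' @slot edges data.frame (`gene_a`, `gene_b`, `pcc`, `z`, `std_z`).
#' @slot hubs designated hub gene ids (possibly absent from the graph).
#' @slot levels named integer: BFS depth of each node from its nearest hub
#'   (0 = hub); `NA` when unreachable or no hubs set.
#' @slot params list recording `quantile`, `pccFloor`, the implied effective
#'   PCC threshold, and the retained-edge fractions of each filter step.
#' @export
setClass("CoexprNetwork", representation(
  graph = "ANY", edges = "data.frame", hubs = "character",
  levels = "integer", params = "list"))

setValidity("CoexprNetwork", function(object) {
  msg <- character()
  if (nrow(object@edges)) {
    if (any(object@edges$gene_a == object@edges$gene_b))
      msg <- c(msg, "self-loops are not allowed")
    if (any(abs(object@edges$pcc) >= 1))
      msg <- c(msg, "edge pcc must lie in (-1, 1)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, "|", object@nGenes, "genes,",
      object@nTE, "TEs on", object@chromLength, "bp\n")
  cat("  groups:", paste(object@groups$condition, object@groups$timepoint,
                         sep = "_", collapse = ", "),
      "x", object@nSamplesPerGroup, "reps\n")
  cat("  planted:", round(object@plantedDegFrac * object@nGenes), "DEGs,",
      object@nPlantedDmrs, "DMRs (+", object@nNullMethWindows, "null windows),",
      object@nRddmGenes, "RdDM genes\n")
})

setMethod("show", "SRNAProfile", function(object) {
  d <- dim(object@counts)
  cat("SRNAProfile:", d[1], "loci x", d[2], "size classes (18-28 nt) x",
      d[3], "samples;", if (length(object@rpm)) "RPM computed" else "raw only",
      "\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel:", nrow(object@membership), "genes,",
      nrow(object@centroids), "clusters, m =", round(object@m, 3), "|",
      nrow(object@assignments), "retained at membership >=",
      object@membershipMin, "\n")
})

setMethod("show", "CoexprNetwork", function(object) {
  cat("CoexprNetwork:", length(igraph::V(object@graph)), "nodes,",
      nrow(object@edges), "edges;", length(object@hubs), "hub(s)\n")
})
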