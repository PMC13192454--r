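#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqnames
NULL

.writeTsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

.readTsv <- function(path, header = TRUE, colClasses = NA) {
  utils::read.delim(path, header = header, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = colClasses)
}

#' Read a GFF3 annotation and derive introns and promoters
#'
#' Imports gene, exon and TE features (1-based closed GFF3 coordinates,
#' which are the native `GRanges` convention), checks that every exon lies
#' inside its parent gene's span, then derives introns as the gaps between
#' the sorted exons of each gene and strand-aware 2-kb promoters upstream
#' of the TSS, clipped at contig ends when sequence lengths are known
#' (from `##sequence-region` directives or `seqlengths`).
#'
#' @param path GFF3 file; exon rows must carry `Parent` attributes.
#' @param promoterWidth promoter size in bp (default 2000).
#' @return feature `GRanges` with mcols `type` (gene, exon, intron,
#'   promoter, TE) and `gene_id`.
#' @export
readGff3 <- function(path, promoterWidth = 2000) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(mcols(gff)$type)
  type[type %in% c("transposable_element", "TE")] <- "TE"
  if (any(as.character(strand(gff)) == "*" & type %in% c("gene", "exon")))
    stop("unknown strand on gene/exon feature(s)")
  genes <- gff[type == "gene"]
  mcols(genes) <- S4Vectors::DataFrame(type = "gene",
                                       gene_id = mcols(genes)$ID)
  exons <- gff[type == "exon"]
  parent <- vapply(mcols(exons)$Parent, `[`, "", 1)
  gi <- match(parent, mcols(genes)$gene_id)
  if (anyNA(gi)) stop("exon(s) with unknown Parent: ",
                      paste(utils::head(parent[is.na(gi)], 3), collapse = ", "))
  bad <- start(exons) < start(genes)[gi] | end(exons) > end(genes)[gi]
  if (any(bad))
    stop("exon outside its gene span: ",
         paste(utils::head(paste0(parent[bad], ":", start(exons)[bad], "-",
                                  end(exons)[bad]), 3), collapse = ", "))
  mcols(exons) <- S4Vectors::DataFrame(type = "exon", gene_id = parent)
  tes <- gff[type == "TE"]
  teId <- mcols(tes)$ID
  mcols(tes) <- S4Vectors::DataFrame(type = "TE", gene_id = NA_character_)
  sl <- seqlengths(gff)
  der <- .deriveGeneFeatures(genes, exons,
                             seqlen = if (all(is.na(sl))) NA else
                               max(sl, na.rm = TRUE))
  if (promoterWidth != 2000) {
    # rederive with the requested width
    minus <- as.character(strand(genes)) == "-"
    ps <- ifelse(minus, end(genes) + 1L, start(genes) - promoterWidth)
    pe <- ifelse(minus, end(genes) + promoterWidth, start(genes) - 1L)
    ps <- pmax(ps, 1L)
    if (!all(is.na(sl))) pe <- pmin(pe, max(sl, na.rm = TRUE))
    prom <- GenomicRanges::GRanges(seqnames(genes), IRanges(ps, pe),
                                   strand = strand(genes))
    mcols(prom) <- S4Vectors::DataFrame(type = "promoter",
                                        gene_id = mcols(genes)$gene_id)
    der$promoters <- prom
  }
  ann <- suppressWarnings(c(genes, exons, der$introns, der$promoters, tes))
  if (!all(is.na(sl))) suppressWarnings(seqlengths(ann) <- sl)
  sort(ann)
}

#' Write gene/exon/TE features as GFF3
#'
#' Only primary features are written; introns and promoters are derived
#' quantities recomputed by [readGff3()].
#'
#' @param annotation feature `GRanges` with mcols `type`, `gene_id`.
#' @param path output file.
#' @export
writeGff3 <- function(annotation, path) {
  keep <- annotation[mcols(annotation)$type %in% c("gene", "exon", "TE")]
  type <- as.character(mcols(keep)$type)
  out <- GenomicRanges::granges(keep)
  teId <- rep(NA_character_, length(keep))
  teId[type == "TE"] <- sprintf("te%04d", seq_len(sum(type == "TE")))
  mcols(out)$type <- ifelse(type == "TE", "transposable_element", type)
  mcols(out)$ID <- ifelse(type == "gene", mcols(keep)$gene_id, teId)
  mcols(out)$Parent <- ifelse(type == "exon", mcols(keep)$gene_id, NA)
  mcols(out)$source <- "lightomics"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a per-cytosine methylation report
#'
#' Seven-column cytosine report (chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide), the
#' dialect written by standard bisulfite callers. Zero-coverage rows are
#' retained; they carry no level but downstream filters need to see them.
#'
#' @param path TSV file without header; empty files give an empty record
#'   set.
#' @return cytosine-report `GRanges` (mcols `context`, `M`, `U`,
#'   `trinucleotide`).
#' @export
readCytosineReport <- function(path) {
  empty <- GenomicRanges::GRanges()
  mcols(empty) <- S4Vectors::DataFrame(context = character(), M = integer(),
                                       U = integer(),
                                       trinucleotide = character())
  info <- file.info(path)
  if (is.na(info$size)) stop("file not found: ", path)
  if (info$size == 0) return(empty)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "strand", "M", "U",
                                        "context", "tri"))
  if (!nrow(df)) return(empty)
  bad <- which(df$M < 0 | df$U < 0)
  if (length(bad)) stop("negative count at line ", bad[1])
  badCtx <- which(!df$context %in% c("CG", "CHG", "CHH"))
  if (length(badCtx)) stop("unknown context token '", df$context[badCtx[1]],
                           "' at line ", badCtx[1])
  gr <- GenomicRanges::GRanges(df$chrom, IRanges(df$pos, df$pos),
                               strand = df$strand)
  mcols(gr) <- S4Vectors::DataFrame(context = df$context,
                                    M = as.integer(df$M),
                                    U = as.integer(df$U),
                                    trinucleotide = df$tri)
  gr
}

#' Write a per-cytosine methylation report
#'
#' @param records cytosine-report `GRanges` (mcols `context`, `M`, `U` and
#'   optionally `trinucleotide`).
#' @param path output TSV (no header, 7 columns).
#' @export
writeCytosineReport <- function(records, path) {
  tri <- if ("trinucleotide" %in% names(mcols(records)))
    mcols(records)$trinucleotide else rep("NNN", length(records))
  df <- data.frame(chrom = as.character(seqnames(records)),
                   pos = start(records),
                   strand = as.character(strand(records)),
                   M = mcols(records)$M, U = mcols(records)$U,
                   context = mcols(records)$context, tri = tri)
  df <- df[order(df$chrom, df$pos, df$strand), ]
  .writeTsv(df, path, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Columns `sample_id`, `condition` (Ctrl/R/FR), `timepoint` (hours),
#' `replicate`; sample ids must be unique.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readSampleSheet <- function(path) {
  df <- .readTsv(path)
  need <- c("sample_id", "condition", "timepoint", "replicate")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (!all(df$condition %in% c("Ctrl", "R", "FR")))
    stop("condition must be Ctrl, R or FR")
  df
}

#' Read a counts TSV (gene_id, length, one column per sample)
#'
#' @param path counts TSV.
#' @param sampleSheet sample sheet data.frame matching the count columns.
#' @return a [CountExperiment-class].
#' @export
readCounts <- function(path, sampleSheet) {
  df <- .readTsv(path)
  cnt <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(cnt) <- df$gene_id
  countExperiment(cnt, df$length, sampleSheet)
}

#' Write the synthetic experiment to disk
#'
#' Emits every input the pipeline consumes: GFF3 annotation, FASTA genome,
#' counts and sample sheet TSVs, per-condition cytosine reports, sRNA locus
#' BED6 and long-format count TSV with library totals, miRNA family
#' tables, functional bin map, designated hub genes, and the machine-
#' readable ground truth as JSON.
#'
#' @param sim list from [simulateExperiment()].
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
writeExperiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  writeGff3(sim$annotation, p("annotation.gff3"))
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  cnt <- SummarizedExperiment::assay(sim$counts, "counts")
  .writeTsv(data.frame(gene_id = rownames(cnt),
                       length = geneLengths(sim$counts), cnt,
                       check.names = FALSE), p("counts.tsv"))
  .writeTsv(as.data.frame(SummarizedExperiment::colData(sim$counts)),
            p("sample_sheet.tsv"))
  writeCytosineReport(sim$methylome$R, p("cytosine_report_R.tsv"))
  writeCytosineReport(sim$methylome$FR, p("cytosine_report_FR.tsv"))
  loci <- srnaRegions(sim$srna$profile)
  bed <- data.frame(chrom = as.character(seqnames(loci)),
                    start = start(loci) - 1L, end = end(loci),
                    name = names(loci), score = 0, strand = ".")
  .writeTsv(bed, p("srna_loci.bed"), col.names = FALSE)
  cnt3 <- srnaCounts(sim$srna$profile)
  long <- expand.grid(locus = dimnames(cnt3)[[1]],
                      size = as.integer(dimnames(cnt3)[[2]]),
                      sample = dimnames(cnt3)[[3]],
                      stringsAsFactors = FALSE)
  long$count <- as.vector(cnt3)
  .writeTsv(long, p("srna_counts.tsv"))
  .writeTsv(data.frame(sample_id = names(libSizes(sim$srna$profile)),
                       library_total = libSizes(sim$srna$profile)),
            p("srna_libsizes.tsv"))
  .writeTsv(sim$srna$profile@sampleSheet, p("srna_sample_sheet.tsv"))
  fam <- sim$srna$familyCounts
  .writeTsv(data.frame(family = rownames(fam), fam, check.names = FALSE),
            p("mirna_family_counts.tsv"))
  .writeTsv(sim$srna$familyInfo, p("mirna_family_info.tsv"))
  .writeTsv(sim$srna$targetMap, p("mirna_targets.tsv"))
  .writeTsv(sim$binMap, p("bin_map.tsv"))
  writeLines(sim$truth$hubGenes, p("hubs.txt"))
  tw <- sim$truth$methWindows
  truthJson <- list(
    degLabels = sim$truth$degLabels, frDegs = sim$truth$frDegs,
    methWindows = data.frame(window_id = names(tw),
                             chrom = as.character(seqnames(tw)),
                             start = start(tw), end = end(tw),
                             as.data.frame(mcols(tw))),
    srnaShifts = sim$truth$srnaShifts, rddmGenes = sim$truth$rddmGenes,
    hubGenes = sim$truth$hubGenes,
    effectiveEffect = as.list(sim$truth$effectiveEffect))
  writeLines(jsonlite::toJSON(truthJson, auto_unbox = TRUE, digits = NA,
                              na = "null", pretty = TRUE), p("truth.json"))
  invisible(dir)
}

#' Read a ground-truth JSON back into R structures
#'
#' @param path `truth.json` written by [writeExperiment()].
#' @return list mirroring the truth component of [simulateExperiment()].
#' @export
readTruth <- function(path) {
  tr <- jsonlite::fromJSON(path)
  mw <- tr$methWindows
  gr <- GenomicRanges::GRanges(mw$chrom, IRanges(mw$start, mw$end))
  names(gr) <- mw$window_id
  mcols(gr) <- S4Vectors::DataFrame(
    mw[setdiff(names(mw), c("window_id", "chrom", "start", "end"))])
  tr$methWindows <- gr
  tr
}
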