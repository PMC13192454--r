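test_that("context assignment reads the strand-aware trinucleotide", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTT"))
  expect_equal(as.character(assignContext(g, "chr1", 2, "+")), "CG")
  g2 <- Biostrings::DNAStringSet(c(chr1 = "CAGTT"))
  expect_equal(as.character(assignContext(g2, "chr1", 1, "+")), "CHG")
  # G at position 3 of ACGTT read on the minus strand: C then G -> CG
  expect_equal(as.character(assignContext(g, "chr1", 3, "-")), "CG")
  g3 <- Biostrings::DNAStringSet(c(chr1 = "CTTGG"))
  expect_equal(as.character(assignContext(g3, "chr1", 1, "+")), "CHH")
  # near the contig end CG stays decidable, everything else is flagged
  g4 <- Biostrings::DNAStringSet(c(chr1 = "ACG"))
  ctx <- assignContext(g4, "chr1", 2, "+")
  expect_equal(as.character(ctx), "CG")
  expect_false(attr(ctx, "ambiguous"))
  g5 <- Biostrings::DNAStringSet(c(chr1 = "ACT"))
  ctx5 <- assignContext(g5, "chr1", 2, "+")
  expect_equal(as.character(ctx5), "CHH")
  expect_true(attr(ctx5, "ambiguous"))
  expect_error(assignContext(g, "chr1", 1, "+"), "cytosine")
})

test_that("methylation level handles zero coverage as missing", {
  expect_equal(methylationLevel(3, 7), 0.3)
  expect_equal(methylationLevel(5, 0), 1)
  expect_true(is.na(methylationLevel(0, 0)))
})

test_that("global methylation pools counts rather than averaging levels", {
  rep1 <- makeReport(c(10, 20), M = c(1, 9), U = c(9, 1), context = "CG")
  expect_equal(unname(globalMethylation(rep1, "CG")), 0.5)
  rep2 <- makeReport(c(10, 20), M = c(1, 90), U = c(9, 10), context = "CHH")
  expect_equal(unname(globalMethylation(rep2, "CHH")), 91 / 110)
  set.seed(81)
  n <- 20000
  rep3 <- makeReport(seq_len(n) * 3, M = rbinom(n, 10, 0.3),
                     U = NA, context = "CHH")
  S4Vectors::mcols(rep3)$U <- 10L - S4Vectors::mcols(rep3)$M
  se <- sqrt(0.3 * 0.7 / (n * 10))
  expect_lt(abs(globalMethylation(rep3, "CHH") - 0.3), 3 * se)
})

test_that("metagene profile is flat under uniform methylation", {
  set.seed(83)
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(3000, 93000, by = 10000), width = 4000),
    strand = rep(c("+", "-"), 5))
  pos <- sort(sample(1:100000, 40000))
  rep <- makeReport(pos, M = rbinom(40000, 20, 0.3),
                    U = NA, context = "CHH")
  S4Vectors::mcols(rep)$U <- 20L - S4Vectors::mcols(rep)$M
  prof <- metageneProfile(rep, genes, bins = 10)
  expect_equal(nrow(prof), 30)
  expect_true(all(abs(prof$level - 0.3) < 0.02))
})

test_that("metagene profiles mirror exactly under strand reversal", {
  set.seed(85)
  gPlus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 9000),
                                  strand = "+")
  gMinus <- GenomicRanges::GRanges("chr2", IRanges::IRanges(5001, 9000),
                                   strand = "-")
  pos <- seq(3001, 11000, by = 7)
  lv <- seq(0.05, 0.95, length.out = length(pos))  # 5'-biased gradient
  M <- rbinom(length(pos), 30, lv)
  repPlus <- makeReport(pos, M = M, U = 30L - M, context = "CG")
  # same biology on the minus strand: mirror positions within the window
  repMinus <- makeReport(3001 + 11000 - pos, M = M, U = 30L - M,
                         context = "CG", chrom = "chr2")
  pPlus <- metageneProfile(repPlus, gPlus, bins = 8)
  pMinus <- metageneProfile(repMinus, gMinus, bins = 8)
  expect_equal(pPlus$level, pMinus$level)
})

test_that("short genes are skipped with a count", {
  rep <- makeReport(1:50, M = 1, U = 1, context = "CG")
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 30),
                                                           c(14, 45)),
                                  strand = "+")
  prof <- metageneProfile(rep, genes, flank = 5, bins = 10)
  expect_equal(attr(prof, "skipped"), 1)
})

test_that("a clear six-cytosine shift is called as one hyper DMR", {
  pos <- c(100, 140, 180, 220, 260, 300)
  repR <- makeReport(pos, M = 1, U = 9, context = "CHH")
  repFR <- makeReport(pos, M = 5, U = 5, context = "CHH")
  dmrs <- callDmrs(repR, repFR, "CHH")
  expect_length(dmrs, 1)
  expect_equal(S4Vectors::mcols(dmrs)$direction, "hyper")
  expect_equal(S4Vectors::mcols(dmrs)$n_cytosines, 6L)
  expect_equal(S4Vectors::mcols(dmrs)$diff, 0.4)
})

test_that("five cytosines never make a DMR regardless of effect", {
  pos <- c(100, 140, 180, 220, 260)
  repR <- makeReport(pos, M = 0, U = 20, context = "CHH")
  repFR <- makeReport(pos, M = 20, U = 0, context = "CHH")
  expect_length(callDmrs(repR, repFR, "CHH"), 0)
})

test_that("identical conditions yield no DMRs and candidates stay null", {
  set.seed(87)
  pos <- sort(sample(1:200000, 3000))
  M <- rbinom(3000, 20, 0.3)
  repR <- makeReport(pos, M = M, U = 20L - M, context = "CHH")
  M2 <- rbinom(3000, 20, 0.3)
  repFR <- makeReport(pos, M = M2, U = 20L - M2, context = "CHH")
  dmrs <- callDmrs(repR, repFR, "CHH", maxGap = 100)
  expect_length(dmrs, 0)
})

test_that("every called DMR satisfies the three printed filters", {
  sim <- cachedSim()
  dmrs <- callDmrs(sim$methylome$R, sim$methylome$FR, "CHH")
  expect_gt(length(dmrs), 0)
  mc <- S4Vectors::mcols(dmrs)
  expect_true(all(mc$n_cytosines > 5))
  expect_true(all(abs(mc$diff) > 0.1))
  expect_true(all(mc$q < 0.05))
  expect_equal(mc$direction, ifelse(mc$diff > 0, "hyper", "hypo"))
})

test_that("feature overlap equals an O(n^2) interval scan", {
  ann <- tinyAnnotation()
  dmr1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3050, 3149))
  names(dmr1) <- "d1"
  ov <- overlapFeatures(dmr1, ann)
  expect_setequal(ov$assignments$feature_type,
                  c("gene", "exon", "intron"))
  # half-open abutment: a feature starting where the DMR ends + 1 never hits
  dmr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2901, 3000))
  names(dmr2) <- "d2"
  ov2 <- overlapFeatures(dmr2, ann)
  expect_false("gene" %in% ov2$assignments$feature_type)
  expect_true("promoter" %in% ov2$assignments$feature_type)
  set.seed(91)
  s1 <- sample(1:5000, 60); e1 <- s1 + sample(10:400, 60, TRUE)
  s2 <- sample(1:5000, 60); e2 <- s2 + sample(10:400, 60, TRUE)
  dmrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s1, e1))
  names(dmrs) <- sprintf("d%02d", 1:60)
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s2, e2))
  S4Vectors::mcols(feats) <- S4Vectors::DataFrame(
    type = sample(c("gene", "TE", "exon"), 60, TRUE),
    gene_id = sprintf("g%02d", 1:60))
  got <- overlapFeatures(dmrs, feats)$assignments
  ref <- bruteOverlap(s1, e1, s2, e2)
  gotPairs <- paste(got$dmr_id, got$gene_id)
  refPairs <- paste(names(dmrs)[ref[, 1]],
                    S4Vectors::mcols(feats)$gene_id[ref[, 2]])
  expect_setequal(gotPairs, refPairs)
  # class derivation
  cls <- overlapFeatures(dmrs, feats)$classes
  expect_true(all(cls %in% c("gene-only", "TE-only", "both", "neither")))
})
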