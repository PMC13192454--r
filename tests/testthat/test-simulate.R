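test_that("the same seed reproduces every generated artifact exactly", {
  cfg <- tinyConfig(seed = 3)
  s1 <- simulateExperiment(cfg)
  s2 <- simulateExperiment(cfg)
  expect_identical(as.character(s1$genome[[1]]), as.character(s2$genome[[1]]))
  expect_identical(SummarizedExperiment::assay(s1$counts),
                   SummarizedExperiment::assay(s2$counts))
  expect_identical(S4Vectors::mcols(s1$methylome$FR)$M,
                   S4Vectors::mcols(s2$methylome$FR)$M)
  expect_identical(srnaCounts(s1$srna$profile), srnaCounts(s2$srna$profile))
  expect_identical(s1$truth$rddmGenes, s2$truth$rddmGenes)
  d1 <- tempfile(); d2 <- tempfile()
  writeExperiment(s1, d1)
  writeExperiment(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("annotation geometry respects the packing contract", {
  sim <- cachedSim()
  ann <- sim$annotation
  genes <- ann[S4Vectors::mcols(ann)$type == "gene"]
  expect_length(genes, 80)
  # gene bodies never overlap
  expect_equal(sum(GenomicRanges::countOverlaps(genes, genes) > 1), 0)
  # single-exon genes have no introns; exon+intron widths tile the gene
  for (g in S4Vectors::mcols(genes)$gene_id[1:20]) {
    ex <- ann[S4Vectors::mcols(ann)$type == "exon" &
                S4Vectors::mcols(ann)$gene_id == g]
    intr <- ann[S4Vectors::mcols(ann)$type == "intron" &
                  S4Vectors::mcols(ann)$gene_id == g]
    expect_equal(length(intr), length(ex) - 1)
    gene <- genes[S4Vectors::mcols(genes)$gene_id == g]
    expect_equal(sum(GenomicRanges::width(ex)) +
                   sum(GenomicRanges::width(intr)),
                 GenomicRanges::width(gene))
  }
  # strand-aware promoters: minus-strand promoter extends right of the gene
  prom <- ann[S4Vectors::mcols(ann)$type == "promoter"]
  for (i in seq_len(10)) {
    g <- genes[i]
    p <- prom[S4Vectors::mcols(prom)$gene_id ==
                S4Vectors::mcols(g)$gene_id]
    if (as.character(GenomicRanges::strand(g)) == "-") {
      expect_equal(GenomicRanges::start(p), GenomicRanges::end(g) + 1)
      expect_equal(GenomicRanges::width(p), 2000)
    } else {
      expect_equal(GenomicRanges::end(p), GenomicRanges::start(g) - 1)
    }
  }
  expect_error(simulateAnnotation(simConfig(nGenes = 500,
                                            chromLength = 100000)),
               "infeasible packing")
})

test_that("planted expression effects land at the configured fold change", {
  sim <- cachedSim()
  cnt <- SummarizedExperiment::assay(sim$counts)
  grp <- sampleGroups(sim$counts)
  lab <- sim$truth$degLabels
  # archetype 2: shifted in FR at day 3 only
  g2 <- lab[lab$archetype == 2, ]
  for (i in seq_len(min(4, nrow(g2)))) {
    mFR <- mean(cnt[g2$gene_id[i], grp == "FR_71"])
    mC <- mean(cnt[g2$gene_id[i], grp == "Ctrl_0"])
    want <- 2^g2$log2fc[i]
    se <- want * sqrt(2 * (1 / (4 * mC) + 0.05) )
    expect_lt(abs(mFR / mC - want), 3 * se + 0.5 * want)
  }
  # unplanted genes share means across groups (3 SE band)
  null <- setdiff(rownames(cnt), lab$gene_id)[1:20]
  for (g in null) {
    m1 <- mean(cnt[g, grp == "FR_71"]); m2 <- mean(cnt[g, grp == "Ctrl_0"])
    pooled <- sd(cnt[g, ]) / sqrt(4)
    expect_lt(abs(m1 - m2), 6 * pooled + 1)
  }
})

test_that("zero planted fraction leaves all group means equal", {
  cfg <- simConfig(seed = 5, nGenes = 40, nTE = 5, chromLength = 400000,
                   plantedDegFrac = 0, nPlantedDmrs = 10,
                   nNullMethWindows = 20, nRddmGenes = 0)
  ann <- simulateAnnotation(cfg)
  tr <- planTruth(cfg, ann$annotation)
  expect_equal(nrow(tr$degLabels), 0)
  ce <- simulateCounts(cfg, ann$annotation, tr)
  cnt <- SummarizedExperiment::assay(ce)
  grp <- sampleGroups(ce)
  for (g in rownames(cnt)[1:10]) {
    ms <- tapply(cnt[g, ], grp, mean)
    expect_lt(diff(range(ms)), 8 * sd(cnt[g, ]))
  }
})

test_that("planted methylome shifts hit the binomial expectation", {
  sim <- cachedSim()
  w <- sim$truth$methWindows
  repR <- sim$methylome$R; repFR <- sim$methylome$FR
  planted <- w[w$planted & w$context == "CHH" & w$direction == "hyper"]
  hits <- GenomicRanges::findOverlaps(repFR, planted)
  sel <- S4Vectors::queryHits(hits)[
    S4Vectors::mcols(repFR)$context[S4Vectors::queryHits(hits)] == "CHH"]
  lv <- methylationLevel(S4Vectors::mcols(repFR)$M[sel],
                         S4Vectors::mcols(repFR)$U[sel])
  lv <- lv[!is.na(lv)]
  se <- sqrt(0.9 * 0.1 / (length(lv) * 20))
  expect_lt(abs(mean(lv) - 0.9), 3 * se + 0.01)
  # outside all planted windows the two conditions agree
  nullw <- w[!w$planted]
  hN <- GenomicRanges::findOverlaps(repR, nullw)
  selN <- S4Vectors::queryHits(hN)
  lvR <- methylationLevel(S4Vectors::mcols(repR)$M[selN],
                          S4Vectors::mcols(repR)$U[selN])
  lvF <- methylationLevel(S4Vectors::mcols(repFR)$M[selN],
                          S4Vectors::mcols(repFR)$U[selN])
  expect_lt(abs(mean(lvR, na.rm = TRUE) - mean(lvF, na.rm = TRUE)), 0.01)
  # zero-coverage sites are preserved as 0/0 rows (visible at low depth)
  cfgLow <- tinyConfig()
  cfgLow@methCoverage <- 1
  low <- simulateMethylome(cfgLow, sim$annotation, sim$truth, sim$genome)
  zero <- (S4Vectors::mcols(low$R)$M + S4Vectors::mcols(low$R)$U) == 0
  expect_gt(sum(zero), 0)
  expect_equal(length(low$R), length(repR))
})

test_that("planted sRNA shifts reach the configured RPM ratio at 24 nt", {
  sim <- cachedSim()
  p <- rpmNormalize(sim$srna$profile)
  rpm <- srnaRpm(p)
  grp <- sim$srna$profile@sampleSheet$condition
  sh <- sim$truth$srnaShifts
  up <- sh$region_id[sh$direction == "up"]
  for (r in up) {
    fr <- mean(rpm[r, "24", grp == "FR"])
    rr <- mean(rpm[r, "24", grp == "R"])
    expect_gt(fr / rr, 2)   # planted fourfold, generous sampling margin
  }
  unshifted <- setdiff(rownames(rpm), sh$region_id)[1:30]
  ratios <- vapply(unshifted, function(r)
    mean(rpm[r, "24", grp == "FR"]) / mean(rpm[r, "24", grp == "R"]),
    1)
  expect_lt(abs(median(ratios, na.rm = TRUE) - 1), 0.3)
})

test_that("planted RdDM triples satisfy the consistency rule", {
  sim <- cachedSim()
  rd <- sim$truth$rddmGenes
  verdict <- rddmVerdict(rd$meth_direction,
                         matrix(rd$srna_direction, ncol = 1),
                         rd$expr_direction)
  expect_true(all(verdict))
  # their DMR windows overlap the gene's promoter or body
  ann <- sim$annotation
  for (i in seq_len(nrow(rd))) {
    w <- sim$truth$methWindows[rd$window_id[i]]
    feats <- ann[S4Vectors::mcols(ann)$gene_id %in% rd$gene_id[i] &
                   S4Vectors::mcols(ann)$type %in%
                     c("promoter", "exon", "intron")]
    expect_gt(sum(GenomicRanges::countOverlaps(w, feats,
                                               ignore.strand = TRUE)), 0)
  }
  # every planted log2fc clears the DE gate by construction
  expect_true(all(sim$truth$degLabels$log2fc >= 1.5))
})
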