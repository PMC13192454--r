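mkProfile <- function(counts3, libs = NULL) {
  nR <- dim(counts3)[1]
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 1000, length.out = nR), width = 200))
  names(regions) <- dimnames(counts3)[[1]]
  samples <- dimnames(counts3)[[3]]
  sheet <- data.frame(sample_id = samples,
                      condition = sub("_.*", "", samples), timepoint = 71,
                      replicate = seq_along(samples))
  if (is.null(libs)) libs <- setNames(apply(counts3, 3, sum), samples)
  srnaProfile(counts3, regions, libs, sheet)
}

rndCounts <- function(nR, samples, mu = 20) {
  a <- array(rnbinom(nR * 11 * length(samples), mu = mu, size = 10),
             dim = c(nR, 11, length(samples)),
             dimnames = list(sprintf("w%02d", 1:nR), 18:28, samples))
  a
}

test_that("RPM normalization scales by library totals and keeps raw", {
  set.seed(101)
  cnt <- rndCounts(4, c("R_r1", "FR_r1"))
  cnt[1, "24", 1] <- 50L
  p <- mkProfile(cnt, libs = c(R_r1 = 2e6, FR_r1 = 1e6))
  p <- rpmNormalize(p)
  expect_equal(srnaRpm(p)[1, "24", 1], 25)
  expect_identical(srnaCounts(p), cnt)
  # library total of exactly one million leaves counts unchanged
  p2 <- rpmNormalize(mkProfile(cnt, libs = c(R_r1 = 1e6, FR_r1 = 1e6)))
  expect_equal(srnaRpm(p2)[, , 1], cnt[, , 1] + 0)
  expect_error(rpmNormalize(mkProfile(cnt, libs = c(R_r1 = 0, FR_r1 = 1))),
               "positive")
})

test_that("rescaling library totals rescales RPM inversely", {
  set.seed(102)
  cnt <- rndCounts(6, c("R_r1", "R_r2"))
  libs <- c(R_r1 = 3e5, R_r2 = 5e5)
  p1 <- rpmNormalize(mkProfile(cnt, libs))
  p2 <- rpmNormalize(mkProfile(cnt, libs * 4))
  expect_equal(srnaRpm(p1), srnaRpm(p2) * 4)
  # per-sample RPM totals obey the assigned/library identity
  tot <- apply(srnaRpm(p1), 3, sum)
  expect_equal(unname(tot), unname(1e6 * apply(cnt, 3, sum) / libs))
})

test_that("size distribution equals brute-force group aggregation", {
  set.seed(103)
  cnt <- rndCounts(5, c("R_r1", "R_r2", "FR_r1", "FR_r2"))
  p <- rpmNormalize(mkProfile(cnt))
  sd1 <- sizeDistribution(p, groups = c("R", "R", "FR", "FR"))
  rpm <- srnaRpm(p)
  for (s in c(18, 24, 28)) for (g in c("R", "FR")) {
    cols <- which(c("R", "R", "FR", "FR") == g)
    vals <- colSums(rpm[, as.character(s), cols])
    row <- sd1[sd1$size == s & sd1$group == g, ]
    expect_equal(row$mean_rpm, mean(vals))
    expect_equal(row$sd_rpm, sd(vals))
  }
  # duplicated sample gives zero spread
  dup <- sizeDistribution(rpmNormalize(mkProfile(cnt[, , c(1, 1)],
                                                 libs = c(R_r1 = 1e6, R_r2 = 1e6))),
                          groups = c("R", "R"))
  expect_equal(dup$sd_rpm, rep(0, 11))
})

test_that("single concentrated size class shows up alone", {
  cnt <- array(0L, c(1, 11, 1), dimnames = list("w1", 18:28, "R_r1"))
  cnt[1, "24", 1] <- 100L
  p <- rpmNormalize(mkProfile(cnt, libs = c(R_r1 = 1e6)))
  d <- sizeDistribution(p, groups = "R")
  expect_equal(d$mean_rpm[d$size == 24], 100)
  expect_equal(sum(d$mean_rpm[d$size != 24]), 0)
})

test_that("read categorization follows priority and partitions totals", {
  asg <- data.frame(genes = c(TRUE, FALSE, FALSE, TRUE),
                    miRNAs = c(FALSE, TRUE, FALSE, FALSE),
                    TEs = c(TRUE, TRUE, FALSE, FALSE),
                    rRNA = FALSE, tRNA = FALSE,
                    count = c(10, 5, 3, 2))
  res <- categorizeReads(asg)
  expect_equal(unname(res["genes"]), 12)  # gene beats TE
  expect_equal(unname(res["miRNAs"]), 5)
  expect_equal(unname(res["TEs"]), 0)
  expect_equal(unname(res["other"]), 3)
  expect_equal(sum(res), sum(asg$count))
  ind <- categorizeReads(asg, independent = TRUE)
  expect_equal(unname(ind["TEs"]), 15)    # overlapping totals
  set.seed(104)
  big <- data.frame(genes = runif(300) < 0.4, miRNAs = runif(300) < 0.1,
                    TEs = runif(300) < 0.5, rRNA = runif(300) < 0.05,
                    tRNA = runif(300) < 0.05, count = rpois(300, 4))
  resB <- categorizeReads(big)
  expect_equal(sum(resB), sum(big$count))
})

test_that("planted miRNA family shifts are detected with matching sign", {
  set.seed(105)
  samples <- c(paste0("R_71_r", 1:4), paste0("FR_71_r", 1:4))
  sheet <- data.frame(sample_id = samples,
                      condition = rep(c("R", "FR"), each = 4),
                      timepoint = 71, replicate = rep(1:4, 2))
  mu <- matrix(200, 20, 8, dimnames = list(sprintf("fam%02d", 1:20),
                                           samples))
  mu[1, 5:8] <- 800   # planted up in FR
  mu[2, 5:8] <- 50    # planted down
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 20), 20,
                dimnames = dimnames(mu))
  libs <- setNames(rep(1e6, 8), samples)
  de <- mirnaFamilyDe(cnt, sheet, c("FR_71", "R_71"), libs)
  expect_lte(de$q[de$family == "fam01"], 0.05)
  expect_gt(de$log2fc[de$family == "fam01"], 0)
  expect_equal(de$status[de$family == "fam02"], "down")
  expect_lt(sum(de$q[-(1:2)] <= 0.05), 3)
  # all-zero family is never called
  cnt["fam03", ] <- 0L
  de0 <- mirnaFamilyDe(cnt, sheet, c("FR_71", "R_71"), libs)
  expect_equal(de0$status[de0$family == "fam03"], "ns")
})

test_that("miRNA target cross-reference equals set intersection", {
  famDe <- data.frame(family = c("miR166", "miR171", "miR390"),
                      status = c("down", "up", "ns"))
  frDegs <- data.frame(gene_id = c("g1", "g2", "g3"),
                       direction = c("up", "down", "up"))
  targets <- data.frame(family = c("miR166", "miR166", "miR171", "miR390"),
                        gene_id = c("g1", "g9", "g2", "g3"))
  x <- crossrefMirnaTargets(famDe, frDegs, targets)
  expect_equal(nrow(x), 2)   # ns family and non-DEG target dropped
  expect_true(x$inverse[x$family == "miR166"])  # down miRNA, up target
  expect_true(x$inverse[x$family == "miR171"])  # up miRNA, down target
  none <- crossrefMirnaTargets(famDe[3, , drop = FALSE], frDegs, targets)
  expect_equal(nrow(none), 0)
})

test_that("sRNA shifts at regions are found where planted and only there", {
  set.seed(106)
  samples <- c(paste0("R_71_r", 1:4), paste0("FR_71_r", 1:4))
  cnt <- rndCounts(30, samples, mu = 40)
  cnt[5, "24", 5:8] <- rnbinom(4, mu = 640, size = 10)
  p <- mkProfile(cnt, libs = setNames(rep(1e6, 8), samples))
  regions <- srnaRegions(p)
  res <- srnaAtRegions(p, regions, c("FR_71", "R_71"))
  hit <- res[res$region_id == "w05" & res$size == 24, ]
  expect_equal(hit$direction, "up")
  others <- res[!(res$region_id == "w05" & res$size == 24), ]
  expect_lt(mean(others$direction != "ns"), 0.05)
  # aggregation equals brute-force interval-overlap counting
  shifted <- GenomicRanges::shift(regions, 50)  # still >=1 bp overlap
  res2 <- srnaAtRegions(p, shifted, c("FR_71", "R_71"), sizes = 24)
  expect_equal(res2$log2fc, res$log2fc[res$size == 24])
})
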