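test_that("cluster input selection equals brute-force rule evaluation", {
  set.seed(31)
  n <- 200
  cnt <- matrix(rnbinom(n * 6, mu = 8, size = 2), n,
                dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:6)))
  sf <- setNames(rep(1, 6), paste0("s", 1:6))
  de1 <- data.frame(gene_id = rownames(cnt),
                    status = sample(c("up", "ns"), n, TRUE, c(0.2, 0.8)))
  de2 <- data.frame(gene_id = rownames(cnt),
                    status = sample(c("down", "ns"), n, TRUE, c(0.1, 0.9)))
  got <- selectClusterInput(cnt, list(de1, de2), sizeFactors = sf)
  want <- rownames(cnt)[(de1$status != "ns" | de2$status != "ns") &
                          rowSums(cnt >= 5) >= 3]
  expect_setequal(got, want)
  # a gene DE nowhere is excluded even when well expressed
  deNone <- data.frame(gene_id = rownames(cnt), status = "ns")
  expect_length(selectClusterInput(cnt, list(deNone), sizeFactors = sf), 0)
})

test_that("borderline expression criterion counts exactly three samples", {
  cnt <- rbind(g1 = c(6, 6, 6, 0, 0, 0), g2 = c(6, 6, 0, 0, 0, 0))
  colnames(cnt) <- paste0("s", 1:6)
  de <- data.frame(gene_id = c("g1", "g2"), status = "up")
  sel <- selectClusterInput(cnt, list(de),
                            sizeFactors = setNames(rep(1, 6), colnames(cnt)))
  expect_true("g1" %in% sel)   # three samples at the minimum count
  expect_false("g2" %in% sel)  # only two
})

test_that("z-scoring centres and scales every retained row", {
  expect_equal(unname(zscoreRows(rbind(c(1, 2, 3)))[1, ]), c(-1, 0, 1))
  set.seed(5)
  m <- matrix(rnorm(50 * 8, sd = 3), 50)
  m <- rbind(m, 7)  # constant row
  rownames(m) <- sprintf("g%02d", 1:51)
  expect_warning(z <- zscoreRows(m), "constant")
  expect_equal(nrow(z), 50)
  expect_equal(unname(rowMeans(z)), rep(0, 50), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 50), tolerance = 1e-9)
})

test_that("fuzzy c-means separates tight groups and respects symmetry", {
  set.seed(17)
  x <- rbind(matrix(rnorm(20 * 4, mean = 0, sd = 0.05), 20),
             matrix(rnorm(20 * 4, mean = 10, sd = 0.05), 20))
  rownames(x) <- sprintf("g%02d", 1:40)
  fit <- fuzzyCMeans(x, c = 2, m = 2, seed = 3, nstart = 3)
  own <- apply(memberships(fit), 1, max)
  expect_true(all(own > 0.99))
  expect_true(all(diff(fit@objective) <= 1e-8))
  expect_equal(unname(rowSums(memberships(fit))), rep(1, 40),
               tolerance = 1e-9)
  # a point equidistant from both centroids gets memberships (0.5, 0.5)
  u <- lightomics:::.fcmMembership(matrix(c(12.5, 12.5), 1, 2), m = 2)
  expect_equal(unname(u[1, ]), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("a point coincident with a centroid takes membership one", {
  u <- lightomics:::.fcmMembership(matrix(c(0, 4), 1, 2), m = 2)
  expect_equal(unname(u[1, ]), c(1, 0))
})

test_that("planted archetypes are recovered and input order is immaterial", {
  set.seed(23)
  arch <- rbind(c(2, -2, 0, 0), c(-2, 2, 0, 0), c(0, 0, 2, -2))
  x <- arch[rep(1:3, each = 30), ] + matrix(rnorm(90 * 4, sd = 0.2), 90)
  rownames(x) <- sprintf("g%02d", 1:90)
  fit <- fuzzyCMeans(x, c = 3, m = NULL, seed = 9)
  asg <- clusterAssignments(fit)
  truth <- rep(1:3, each = 30)[match(asg$gene_id, rownames(x))]
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(truth, asg$cluster)
  expect_gte(ari, 0.95)
  perm <- sample(nrow(x))
  fit2 <- fuzzyCMeans(x[perm, ], c = 3, m = fit@m, seed = 9)
  expect_equal(memberships(fit2), memberships(fit)[perm, ],
               tolerance = 1e-8)
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(41)
  x <- rbind(matrix(rnorm(25 * 5, 0, 0.3), 25),
             matrix(rnorm(25 * 5, 5, 0.3), 25),
             matrix(rnorm(25 * 5, -5, 0.3), 25))
  rownames(x) <- sprintf("g%02d", 1:75)
  fit <- fuzzyCMeans(x, c = 3, m = 2, seed = 2)
  ref <- e1071::cmeans(x, centers = 3, m = 2)
  # same hard partition up to label switching
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(
    apply(memberships(fit), 1, which.max), ref$cluster), 0.99)
})

test_that("cluster direction labels equal the brute-force rule", {
  sheet <- data.frame(sample_id = paste0("s", 1:10),
                      condition = rep(c("Ctrl", "R", "FR", "R", "FR"),
                                      each = 2),
                      timepoint = rep(c(0, 23, 23, 71, 71), each = 2),
                      replicate = rep(1:2, 5))
  mkModel <- function(v) new("ClusterModel", centroids = v,
                             membership = matrix(1, 1, nrow(v)), m = 2,
                             objective = 1,
                             assignments = data.frame(gene_id = character(),
                                                      cluster = integer(),
                                                      membership = numeric()),
                             membershipMin = 0.7)
  up <- matrix(rep(c(0, -1, 1, -1, 1), each = 2), 1, byrow = TRUE)
  expect_equal(unname(labelClusterDirection(mkModel(up), sheet)), "FR-up")
  flat <- matrix(0, 1, 10)
  expect_equal(unname(labelClusterDirection(mkModel(flat), sheet)), "other")
  set.seed(19)
  grp <- sampleGroups(sheet)
  for (i in 1:50) {
    v <- matrix(rnorm(10), 1)
    lab <- unname(labelClusterDirection(mkModel(v), sheet, delta = 0.5))
    d1 <- mean(v[grp == "FR_23"]) - mean(v[grp == "R_23"])
    d3 <- mean(v[grp == "FR_71"]) - mean(v[grp == "R_71"])
    upHit <- d1 > 0.5 | d3 > 0.5
    dnHit <- d1 < -0.5 | d3 < -0.5
    want <- if (upHit && !dnHit) "FR-up" else
      if (dnHit && !upHit) "FR-down" else "other"
    expect_equal(lab, want)
  }
})

test_that("redundant-cluster grouping is the transitive closure", {
  mk <- function(v) new("ClusterModel", centroids = v,
                        membership = matrix(1 / nrow(v), 2, nrow(v)), m = 2,
                        objective = 1,
                        assignments = data.frame(gene_id = character(),
                                                 cluster = integer(),
                                                 membership = numeric()),
                        membershipMin = 0.7)
  a <- c(1, 2, 3, 4, 5)
  same <- mk(rbind(a, a + 1))            # r = 1
  expect_equal(unname(mergeRedundantClusters(same)), c(1, 1))
  anti <- mk(rbind(a, rev(a)))           # r = -1
  expect_equal(unname(mergeRedundantClusters(anti)), c(1, 2))
  set.seed(29)
  for (i in 1:20) {
    v <- matrix(rnorm(4 * 6), 4)
    got <- mergeRedundantClusters(mk(v), rMin = 0.8)
    adj <- diag(4) == 1
    for (p in 1:3) for (q in (p + 1):4) {
      r <- cor(v[p, ], v[q, ])
      pv <- cor.test(v[p, ], v[q, ])$p.value
      if (r >= 0.8 && pv < 0.05) adj[p, q] <- adj[q, p] <- TRUE
    }
    # transitive closure by repeated boolean multiplication
    reach <- adj
    for (k in 1:4) reach <- reach | (reach %*% reach > 0)
    same <- outer(got, got, "==")
    expect_equal(unname(same), unname(reach))
  }
})

test_that("the fuzzifier rule shrinks towards one for large data", {
  expect_gt(estimateFuzzifier(50, 10), estimateFuzzifier(5000, 10))
  expect_gt(estimateFuzzifier(100, 4), 1)
})
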