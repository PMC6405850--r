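test_that("loop matrix has the canonical dimensionality and ordering", {
  out <- sampleEnsemble(threeBasinSpec(nFrames = 10, seed = 1))
  lm <- loopMatrix(out$ensemble, loop = c(342, 359))
  expect_equal(dim(lm$matrix), c(10L, 216L))  # 72 atoms x 3
  expect_equal(nrow(lm$atoms), 72L)
  expect_equal(lm$source, rep("synthetic", 10))

  # multiple sources concatenate in order
  a <- sampleEnsemble(threeBasinSpec(nFrames = 5, seed = 2))$ensemble
  b <- sampleEnsemble(threeBasinSpec(nFrames = 7, seed = 3))$ensemble
  a@sourceId <- "sysA"
  b@sourceId <- "sysB"
  lm2 <- loopMatrix(list(a, b))
  expect_equal(dim(lm2$matrix), c(12L, 216L))
  expect_equal(table(lm2$source), table(rep(c("sysA", "sysB"), c(5, 7))))
  # single frame still yields a 1 x 216 matrix
  single <- selectFrames(a, 1)
  expect_equal(dim(loopMatrix(single)$matrix), c(1L, 216L))
  # mismatched layouts are refused with the source named
  short <- sampleEnsemble(ensembleSpec(nRes = 10, nFrames = 3,
                                       seed = 4))$ensemble
  short@sourceId <- "shortLoop"
  expect_error(loopMatrix(list(a, short)), "shortLoop")
})

test_that("PCA satisfies orthonormality, variance-sum and reconstruction", {
  out <- sampleEnsemble(threeBasinSpec(nFrames = 80, seed = 5))
  x <- loopMatrix(out$ensemble)$matrix
  model <- fitPCA(x)
  p <- length(model@mean)
  expect_lt(max(abs(tcrossprod(model@components) - diag(p))), 1e-8)
  expect_equal(sum(model@varianceFraction), 1, tolerance = 1e-8)
  expect_true(all(diff(model@eigenvalues) < 1e-10))
  # full reconstruction
  scores <- projectPCA(model, x)
  back <- reconstructPCA(model, scores)
  expect_lt(max(abs(back - x)), 1e-6)
  expect_error(fitPCA(x[1, , drop = FALSE]), "2 frames")
})

test_that("PCA spectra behave on exact-line and isotropic data", {
  t_ <- seq(-1, 1, length.out = 50)
  line <- outer(t_, c(1, 2, -1, 0.5))
  model <- fitPCA(line)
  expect_equal(model@varianceFraction[1], 1, tolerance = 1e-12)
  expect_equal(sum(model@varianceFraction[-1]), 0, tolerance = 1e-9)

  set.seed(19)
  iso <- matrix(rnorm(10000 * 6), ncol = 6)
  vf <- fitPCA(iso)@varianceFraction
  expect_true(all(abs(vf - 1 / 6) < 0.05))
})

test_that("the 1 percent minimum-cluster-size rule reproduces its anchors", {
  expect_identical(minClusterSize(8993, 0.01), 90L)
  expect_identical(minClusterSize(100, 0.01), 2L)
  expect_identical(minClusterSize(200, 0.01), 2L)
  expect_identical(minClusterSize(250, 0.01), 3L)  # round-half-up of 2.5
  expect_error(minClusterSize(100, 0), "fraction")
})

test_that("clustering recovers three planted basins across seeds", {
  aris <- vapply(1:10, function(s) {
    out <- sampleEnsemble(threeBasinSpec(nFrames = 300, seed = 100 + s))
    lm <- loopMatrix(out$ensemble)
    proj <- projectPCA(fitPCA(lm$matrix), lm$matrix)
    asg <- clusterConformations(proj, minClusterSize(300))
    ari(clusterLabels(asg), out$labels)
  }, numeric(1))
  expect_true(all(aris >= 0.95))
})

test_that("full-PC-space clustering equals clustering the centred raw matrix", {
  out <- sampleEnsemble(threeBasinSpec(nFrames = 200, seed = 55))
  lm <- loopMatrix(out$ensemble)
  x <- lm$matrix
  xc <- sweep(x, 2, colMeans(x))
  proj <- projectPCA(fitPCA(x), x)
  m <- minClusterSize(200)
  a1 <- clusterConformations(proj, m)
  a2 <- clusterConformations(xc, m)
  expect_equal(ari(clusterLabels(a1), clusterLabels(a2)), 1)
})

test_that("cluster partitions are stable under row permutation", {
  out <- sampleEnsemble(threeBasinSpec(nFrames = 200, seed = 66))
  lm <- loopMatrix(out$ensemble)
  proj <- projectPCA(fitPCA(lm$matrix), lm$matrix)
  m <- minClusterSize(200)
  base <- clusterConformations(proj, m)
  set.seed(77)
  perm <- sample(nrow(proj))
  shuf <- clusterConformations(proj[perm, ], m)
  expect_equal(ari(clusterLabels(base)[perm], clusterLabels(shuf)), 1)
})

test_that("scaffold superposition rescues clustering under pose noise", {
  spec <- ensembleSpec(nRes = 18, nFrames = 250, stayProb = 0.9, seed = 2,
                       poseRotSd = 25, poseTransSd = 4)
  out <- sampleEnsemble(spec)
  ariOf <- function(lm) {
    proj <- projectPCA(fitPCA(lm$matrix), lm$matrix)
    ari(clusterLabels(clusterConformations(proj, minClusterSize(250))),
        out$labels)
  }
  superposed <- ariOf(loopMatrix(out$ensemble, fitResidues = c(342, 359)))
  raw <- ariOf(loopMatrix(out$ensemble))
  expect_gte(superposed, 0.95)
  expect_gt(superposed, raw)
})

test_that("degenerate clustering inputs behave per contract", {
  # one tight blob: exactly one cluster when a single cluster is allowed
  set.seed(8)
  blob <- matrix(rnorm(300 * 2, 0, 0.1), 300, 2)
  a <- clusterConformations(blob, 30, allowSingleCluster = TRUE)
  expect_equal(nClusters(a), 1L)
  expect_equal(sum(clusterLabels(a) == -1L), 0L)
  # structureless input under the default: everything is noise
  unif <- matrix(runif(200 * 2, 0, 10), 200, 2)
  a2 <- clusterConformations(unif, 80)
  expect_equal(nClusters(a2), 0L)
  expect_true(all(clusterLabels(a2) == -1L))
  # fewer frames than the minimum size: warning + all-noise
  expect_warning(a3 <- clusterConformations(blob[1:5, ], 10), "noise")
  expect_true(all(clusterLabels(a3) == -1L))
})

test_that("medoids match exhaustive search and break ties low", {
  # collinear toy: medoid of {0, 1, 10} is the middle point
  x <- matrix(c(0, 1, 10), ncol = 1)
  expect_equal(clusterMedoid(c(0L, 0L, 0L), x), 2L)
  # symmetric pair: lower frame index wins
  expect_equal(clusterMedoid(c(0L, 0L), matrix(c(0, 2), ncol = 1)), 1L)
  # brute-force oracle on random clusters
  set.seed(91)
  for (rep in 1:3) {
    y <- matrix(rnorm(200 * 3), 200, 3)
    lab <- rep(0:1, each = 100)
    med <- clusterMedoid(lab, y)
    for (c in 0:1) {
      idx <- which(lab == c)
      d <- as.matrix(dist(y[idx, ]))
      expect_equal(med[c + 1], idx[which.min(colSums(d))])
    }
  }
})

test_that("occupancy tables expose source-exclusive and shared clusters", {
  # source A visits basins 1+2, source B only basin 2 (shared)
  basins12 <- list(basinSpec(-120, 130, jitterSigma = 0.1, weight = 0.5),
                   basinSpec(-60, -45, jitterSigma = 0.1, weight = 0.5))
  specA <- ensembleSpec(nRes = 18, basins = basins12, stayProb = 0.8,
                        nFrames = 150, seed = 7)
  specB <- ensembleSpec(nRes = 18,
                        basins = list(basins12[[2]]),
                        nFrames = 150, seed = 8)
  a <- sampleEnsemble(specA)$ensemble
  b <- sampleEnsemble(specB)$ensemble
  a@sourceId <- "A"
  b@sourceId <- "B"
  lm <- loopMatrix(list(a, b))
  proj <- projectPCA(fitPCA(lm$matrix), lm$matrix)
  asg <- clusterConformations(proj, minClusterSize(300),
                              sourceLabels = lm$source)
  expect_equal(nClusters(asg), 2L)
  tab <- clusterOccupancyTable(asg)
  counts <- asg@sourceOccupancy
  # row sums = per-source frame counts
  expect_equal(unname(rowSums(counts)), c(150L, 150L))
  # B never visits A's exclusive basin; both sources share one cluster
  exclusive <- which(counts["B", seq_len(2)] == 0)
  expect_length(exclusive, 1L)
  shared <- which(counts["A", seq_len(2)] > 0 & counts["B", seq_len(2)] > 0)
  expect_length(shared, 1L)
  expect_equal(sum(tab$fraction[tab$source == "A"]), 1)
})
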