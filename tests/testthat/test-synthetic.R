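test_that("the chain builder produces ideal geometry", {
  h <- buildBackbone(basinSpec(phi = -60, psi = -45), nRes = 3)
  expect_equal(nAtoms(h), 12)
  co <- coords(h)[1, , ]
  at <- atoms(h)
  idx <- function(res, name) which(at$resSeq == res & at$atomName == name)
  bond <- function(i, j) sqrt(sum((co[i, ] - co[j, ])^2))
  for (r in 342:344) {
    expect_equal(bond(idx(r, "N"), idx(r, "CA")), 1.458, tolerance = 1e-9)
    expect_equal(bond(idx(r, "CA"), idx(r, "C")), 1.525, tolerance = 1e-9)
    expect_equal(bond(idx(r, "C"), idx(r, "O")), 1.231, tolerance = 1e-9)
  }
  for (r in 342:343)
    expect_equal(bond(idx(r, "C"), idx(r + 1, "N")), 1.329, tolerance = 1e-9)
  # consecutive CA-CA distance of a trans chain is ~3.8 A
  caca <- vapply(342:343, function(r)
    bond(idx(r, "CA"), idx(r + 1, "CA")), numeric(1))
  expect_true(all(abs(caca - 3.8) < 0.05))

  expect_equal(nAtoms(buildBackbone(basinSpec(-120, 130), nRes = 2)), 8)
})

test_that("built dihedrals round-trip through the template within 1e-3 deg", {
  template <- cbind(phi = c(-120, -60, -75, 60, -100),
                    psi = c(130, -45, 150, 40, 120),
                    omega = c(180, 175, -170, 180, 178))
  ens <- buildBackbone(template)
  d <- backboneDihedrals(ens)
  angDiff <- function(a, b) {
    x <- (a - b) %% 360
    pmin(x, 360 - x)
  }
  expect_lt(max(angDiff(d$phi[1, -1], template[-1, "phi"])), 1e-3)
  expect_lt(max(angDiff(d$psi[1, -5], template[-5, "psi"])), 1e-3)
  expect_lt(max(angDiff(d$omega[1, -1], template[-1, "omega"])), 1e-3)
})

test_that("built dihedrals agree with the bio3d torsion oracle", {
  skip_if_not_installed("bio3d")
  template <- cbind(phi = c(-120, -65, 55, -80),
                    psi = c(140, -40, 45, 100),
                    omega = c(180, 180, 180, 180))
  ens <- buildBackbone(template)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeMultimodelPDB(ens, path)
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  tor <- suppressWarnings(bio3d::torsion.pdb(pdb))
  d <- backboneDihedrals(readMultimodelPDB(path))
  # coordinates written at 3 decimals: allow a small angular tolerance
  expect_equal(unname(tor$phi[-1]), unname(d$phi[1, -1]), tolerance = 1e-2)
  expect_equal(unname(tor$psi[-4]), unname(d$psi[1, -4]), tolerance = 1e-2)
})

test_that("basin Markov sampling matches its stationary distribution", {
  spec <- ensembleSpec(
    nRes = 4,
    basins = list(basinSpec(-120, 130, jitterSigma = 0, weight = 0.5),
                  basinSpec(-60, -45, jitterSigma = 0, weight = 0.5)),
    stayProb = 0.5, nFrames = 10000, seed = 11)
  out <- sampleEnsemble(spec)
  freq <- as.numeric(table(out$labels)) / spec$nFrames
  expect_true(all(abs(freq - 0.5) < 0.02))
})

test_that("degenerate and seeded ensemble contracts hold", {
  one <- ensembleSpec(nRes = 4,
                      basins = list(basinSpec(-60, -45, jitterSigma = 0)),
                      nFrames = 20, seed = 9)
  out <- sampleEnsemble(one)
  expect_true(all(out$labels == 1))
  ref <- out$ensemble@coords[1, , ]
  for (f in 2:20)
    expect_equal(out$ensemble@coords[f, , ], ref)
  expect_equal(max(rmsfPerResidue(out$ensemble, fitSelection = NA)$rmsf), 0)

  # bit-identical under the same seed
  a <- sampleEnsemble(threeBasinSpec(nFrames = 50, seed = 123))
  b <- sampleEnsemble(threeBasinSpec(nFrames = 50, seed = 123))
  expect_identical(a$ensemble@coords, b$ensemble@coords)
  expect_identical(a$labels, b$labels)
  expect_error(sampleEnsemble(ensembleSpec(basins = list())), "zero basins")
})

test_that("salt-bridge series hits its stationary occupancy", {
  s <- simulateSaltBridgeSeries(pFormed = 0.91, dOn = 3, dOff = 6,
                                noiseSd = 0.1, n = 1e5, seed = 21)
  expect_lt(abs(occupancyFromDistances(s$distance, 4.0) - 0.91), 0.02)

  s0 <- simulateSaltBridgeSeries(pFormed = 0, n = 1000, seed = 1)
  expect_equal(occupancyFromDistances(s0$distance, 4.0), 0)
  expect_true(all(abs(s0$distance - 6) < 1))

  s1 <- simulateSaltBridgeSeries(pFormed = 1, noiseSd = 0, n = 500, seed = 1)
  expect_equal(occupancyFromDistances(s1$distance, 4.0), 1)
  expect_error(simulateSaltBridgeSeries(pFormed = 1.2), "pFormed")
})

test_that("melt simulation honours the sigmoid midpoint and refits", {
  m <- simulateMelt(tm = 72.2, slope = 2, baseFolded = -10,
                    baseUnfolded = -2, temps = seq(35, 95, by = 0.1))
  mid <- m$signal[which.min(abs(m$temperature - 72.2))]
  expect_equal(mid, (-10 + -2) / 2, tolerance = 1e-6)
  fit <- fitBoltzmannMelt(simulateMelt(72.2, 2, -10, -2,
                                       temps = seq(35, 95)))
  expect_equal(unname(fit@parameters["tm"]), 72.2, tolerance = 1e-6)
  expect_error(simulateMelt(70, 0), "slope")
})

test_that("inhibition assay has the SI as x-intercept and refits", {
  a <- simulateInhibitionAssay(si = 1.64, ratios = seq(0, 2, 0.01))
  expect_true(all(a$residualActivity[abs(a$ratio - 1.64) < 1e-9] == 0))
  a2 <- simulateInhibitionAssay(si = 1)
  expect_true(all(a2$residualActivity[a2$ratio == 0.5] == 0.5))
  fit <- fitSI(simulateInhibitionAssay(si = 1.64))
  expect_equal(unname(fit@parameters["si"]), 1.64, tolerance = 1e-6)
  expect_error(simulateInhibitionAssay(si = 0), "si")
})

test_that("simulated MSAs plant conservation and reject overlaps", {
  msa <- simulateMsa(60, 8, conservedCols = c("3" = "C"), seed = 5)
  expect_true(all(msaMatrix(msa)[, 3] == "C"))
  prof <- conservationProfile(msa)
  expect_equal(prof$score[3], 1)
  expect_equal(prof$grade[3], 9L)
  expect_error(
    simulateMsa(10, 8, conservedCols = c("2" = "A"),
                covaryPairs = list(list(i = 2, j = 5, coupling = 1))),
    "overlapping")
  # same seed -> identical alignment
  expect_identical(msaMatrix(simulateMsa(20, 6, seed = 2)),
                   msaMatrix(simulateMsa(20, 6, seed = 2)))
})
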