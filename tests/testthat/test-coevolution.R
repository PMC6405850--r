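test_that("percent identity follows the gap-inclusive formula", {
  expect_equal(percentIdentity("ACDEF", "ACDEF"), 100)
  expect_equal(percentIdentity("ACDEF", "ACDEG"), 80)
  # gap-gap columns add to length, not identity, under the default
  expect_equal(percentIdentity("AC-A", "AC-G"), 50)
  expect_equal(percentIdentity("AC-A", "AC-G", gapGapIdentity = TRUE), 75)
  expect_error(percentIdentity("ACD", "AC"), "different aligned lengths")
  # symmetry and bounds on random pairs
  set.seed(3)
  aa <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-")
  for (rep in 1:5) {
    a <- sample(aa, 40, replace = TRUE)
    b <- sample(aa, 40, replace = TRUE)
    pid <- percentIdentity(a, b)
    expect_equal(pid, percentIdentity(b, a))
    expect_gte(pid, 0)
    expect_lte(pid, 100)
  }
  expect_lt(percentIdentity(c("A", "-"), c("A", "-")), 100)
})

test_that("an alignment with 379 positions and 148 differences is 61 percent
           identical", {
  n <- 379
  diffs <- 148
  a <- rep("A", n)
  b <- a
  b[seq_len(diffs)] <- "G"
  pid <- percentIdentity(a, b)
  expect_equal(pid, 100 * (379 - 148) / 379)
  expect_equal(round(pid), 61)
})

test_that("conservation scores span invariant to uniform columns", {
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  m <- cbind(rep("W", 20), aa20, rep(c("A", "V"), each = 10), rep("-", 20))
  msa <- Msa(sprintf("s%02d", 1:20), m)
  prof <- conservationProfile(msa)
  expect_equal(prof$score[1], 1)
  expect_equal(prof$grade[1], 9L)
  expect_equal(prof$score[2], 0, tolerance = 1e-12)
  # 50/50 two-residue column: 1 - log(2)/log(20)
  expect_equal(prof$score[3], 1 - log(2) / log(20), tolerance = 1e-12)
  # all-gap column masked
  expect_true(is.na(prof$score[4]))
  expect_true(is.na(prof$grade[4]))
})

test_that("OMES equals the brute-force contingency oracle exactly", {
  for (s in 1:5) {
    msa <- simulateMsa(40, 5, seed = 500 + s)
    mine <- covariationScores(omes(msa))
    oracle <- omesOracle(msaMatrix(msa))
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("a deterministic binary association gives chi-squared = N", {
  m <- cbind(rep(c("A", "V"), each = 50), rep(c("L", "F"), each = 50))
  msa <- Msa(sprintf("s%03d", 1:100), m)
  expect_equal(covariationScores(omes(msa))[1, 2], 100, tolerance = 1e-12)
})

test_that("OMES p-values are calibrated on independent columns", {
  msa <- simulateMsa(500, 8, seed = 17)
  sig <- covariationSignificance(msa, "omes", nPermutations = 99, seed = 5)
  p <- sig$p[upper.tri(sig$p)]
  # permutation p-values under the null are near-uniform: KS against U(0,1)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ELSC matches hand-computed binomial arithmetic on a toy", {
  # 6 sequences, 2 columns; consensus at column 1 is A (4 of 6)
  m <- cbind(c("A", "A", "A", "A", "V", "V"),
             c("L", "L", "L", "F", "F", "F"))
  msa <- Msa(sprintf("s%d", 1:6), m)
  # subset = rows 1:4; column 2 within subset: L = 3, F = 1; full: L = 3,
  # F = 3; expected subset counts m = round(3 * 4/6) each = 2
  hand <- (lchoose(3, 2) - lchoose(3, 3)) + (lchoose(3, 2) - lchoose(3, 1))
  val <- covariationScores(elsc(msa, minSubset = 2))[1, 2]
  # directional j -> i: consensus at col 2 is a tie (L = F = 3) -> "F"
  # alphabetically; subset rows 4:6; col 1 in subset: A = 1, V = 2; full:
  # A = 4, V = 2; expected m: A = 2, V = 1
  hand_ji <- (lchoose(4, 2) - lchoose(4, 1)) + (lchoose(2, 1) - lchoose(2, 2))
  expect_equal(val, max(hand, hand_ji), tolerance = 1e-12)
})

test_that("planted covariation is the ELSC and SCA argmax", {
  msa <- simulateMsa(150, 8, covaryPairs = list(list(i = 2, j = 6,
                                                     coupling = 0.9)),
                     seed = 23)
  for (fn in list(elsc, sca)) {
    s <- covariationScores(fn(msa))
    am <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, ]
    expect_equal(sort(unname(am)), c(2L, 6L))
  }
})

test_that("SCA vanishes when subset frequencies equal the full alignment", {
  # both columns invariant -> each perturbation subset is the whole
  # alignment, so subset and full frequencies coincide in both directions
  m <- cbind(rep("A", 30), rep("L", 30))
  msa <- Msa(sprintf("s%02d", 1:30), m)
  s <- covariationScores(sca(msa, minSubset = 5))
  expect_equal(s[1, 2], 0, tolerance = 1e-12)
})

test_that("independent columns score near zero relative to a planted pair", {
  msa <- simulateMsa(500, 8, covaryPairs = list(list(i = 1, j = 5,
                                                     coupling = 0.8)),
                     seed = 29)
  s <- covariationScores(sca(msa))
  planted <- s[1, 5]
  others <- s[upper.tri(s)]
  others <- others[others != planted]
  expect_gt(planted, max(others, na.rm = TRUE))
})

test_that("covariation scores are invariant to sequence reordering", {
  msa <- simulateMsa(80, 6, covaryPairs = list(list(i = 1, j = 4,
                                                    coupling = 0.7)),
                     seed = 31)
  set.seed(7)
  perm <- sample(80)
  shuffled <- Msa(msaIds(msa)[perm], msaMatrix(msa)[perm, ])
  for (fn in list(omes, elsc, sca)) {
    expect_equal(covariationScores(fn(msa)),
                 covariationScores(fn(shuffled)), tolerance = 1e-12)
  }
})

test_that("gap-heavy columns and tiny subsets are masked", {
  m <- cbind(c(rep("-", 20), rep("A", 10)),  # 66% gaps -> masked
             sample(c("A", "V"), 30, replace = TRUE),
             sample(c("L", "F"), 30, replace = TRUE))
  msa <- Msa(sprintf("s%02d", 1:30), m)
  o <- omes(msa)
  expect_false(o@validColumns[1])
  expect_true(all(is.na(covariationScores(o)[1, ])))
})

test_that("permutation significance flags a deterministic pair at 1/(B+1)", {
  msa <- simulateMsa(60, 6, covaryPairs = list(list(i = 1, j = 4,
                                                    coupling = 1)),
                     seed = 37)
  sig <- covariationSignificance(msa, "omes", nPermutations = 199, seed = 3)
  expect_equal(sig$p[1, 4], 1 / 200)
  # reproducible under the same seed
  sig2 <- covariationSignificance(msa, "omes", nPermutations = 199, seed = 3)
  expect_identical(sig$p, sig2$p)
  expect_error(covariationSignificance(msa, "omes", nPermutations = 10),
               "19")
  # BH-adjusted values are present and >= raw p
  ut <- upper.tri(sig$p)
  expect_true(all(sig$padj[ut] >= sig$p[ut] - 1e-12))
})
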