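# Shared fixture builders; everything is generated in code at test time.

# Three well-separated basins with small jitter: separation >> 5 x jitter.
threeBasinSpec <- function(nFrames = 400, seed = 1, jitter = 0.15,
                           poseRotSd = 0, poseTransSd = 0) {
  ensembleSpec(
    nRes = 18,
    basins = list(
      basinSpec(phi = -120, psi = 130, jitterSigma = jitter, weight = 1 / 3),
      basinSpec(phi = -60, psi = -45, jitterSigma = jitter, weight = 1 / 3),
      basinSpec(phi = -75, psi = 150, jitterSigma = jitter, weight = 1 / 3)
    ),
    stayProb = 0.9, nFrames = nFrames, seed = seed,
    poseRotSd = poseRotSd, poseTransSd = poseTransSd
  )
}

# A toy chain, mostly hydrophobic, with one E and one K, CB placeholders.
chargedToyChain <- function() {
  buildBackbone(basinSpec(phi = -120, psi = 130), nRes = 6, cbeta = TRUE,
                resNames = c("LEU", "GLU", "ALA", "ILE", "LYS", "VAL"))
}

# Subset frames of an ensemble.
selectFrames <- function(ens, idx) {
  methods::new("ConformationEnsemble",
               coords = ens@coords[idx, , , drop = FALSE],
               atoms = atoms(ens), frameInterval = frameInterval(ens),
               sourceId = sourceId(ens))
}

selectFirstFrame <- function(ens) selectFrames(ens, 1)

# Adjusted Rand index oracle (mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Independent brute-force OMES oracle: explicit contingency arithmetic.
omesOracle <- function(m) {
  nCol <- ncol(m)
  aaOK <- function(x) x %in% strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  s <- matrix(NA_real_, nCol, nCol)
  for (i in seq_len(nCol - 1)) for (j in (i + 1):nCol) {
    use <- aaOK(m[, i]) & aaOK(m[, j])
    n <- sum(use)
    if (n < 2) next
    ai <- m[use, i]; aj <- m[use, j]
    tot <- 0
    for (a in unique(ai)) for (b in unique(aj)) {
      obs <- sum(ai == a & aj == b)
      expd <- n * (sum(ai == a) / n) * (sum(aj == b) / n)
      if (expd > 0) tot <- tot + (obs - expd)^2 / expd
    }
    s[i, j] <- s[j, i] <- tot
  }
  s
}

# Exhaustive decoy oracle for one contact: direct weighted enumeration of
# all residue-type pairs from a composition table.
frustrationOracle <- function(aNative, bNative, r, comp, model) {
  types <- names(comp)
  eN <- pairEnergy(aNative, bNative, r, model)
  es <- c(); ws <- c()
  for (a in types) for (b in types) {
    es <- c(es, pairEnergy(a, b, r, model))
    ws <- c(ws, comp[[a]] * comp[[b]])
  }
  mu <- sum(ws * es)
  sd_ <- sqrt(sum(ws * (es - mu)^2))
  if (sd_ < 1e-12) return(0)
  (mu - eN) / sd_
}
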