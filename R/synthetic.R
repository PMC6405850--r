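#' @include structure_io.R
NULL

# Ideal backbone geometry (Engh-Huber-like constants, Angstrom / degrees).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
BOND_CA_CB <- 1.521
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
ANGLE_N_CA_CB <- 110.5

#' Specify one conformational basin of a loop ensemble
#'
#' A basin is defined by a per-residue backbone dihedral template plus an
#' isotropic Gaussian jitter and a stationary weight. Uniform templates can
#' be given as scalar `phi`/`psi`/`omega`.
#'
#' @param phi,psi,omega backbone dihedrals in degrees; scalars are recycled
#'   over residues when the basin is used.
#' @param jitterSigma per-coordinate Gaussian jitter sd (Angstrom, >= 0).
#' @param weight stationary probability of the basin (weights of a basin set
#'   are normalised to sum to 1).
#' @return list of class `basinSpec`.
#' @export
basinSpec <- function(phi, psi, omega = 180, jitterSigma = 0.3, weight = 1) {
  if (jitterSigma < 0) stop("jitterSigma must be >= 0", call. = FALSE)
  structure(list(phi = phi, psi = psi, omega = omega,
                 jitterSigma = jitterSigma, weight = weight),
            class = "basinSpec")
}

#' Specify a multi-basin loop ensemble
#'
#' The generator emulates a loop hopping between metastable backbone
#' conformations: a first-order Markov chain over basins (self-transition
#' probability `stayProb`, jumps distributed according to the basin weights),
#' per-coordinate Gaussian jitter about each basin's ideal-geometry backbone
#' and, optionally, a global rigid-body pose noise per frame. The default
#' three-basin set (extended, alpha-helical and polyproline-II-like
#' templates, equal weights) mimics a reactive-centre loop exchanging between
#' extended-hinge and bent-hinge conformations.
#'
#' @param nRes loop length in residues (default 18, an RCL-length loop).
#' @param basins list of [basinSpec()] objects; default 3 well-separated
#'   basins with equal weights.
#' @param stayProb Markov self-transition probability in `[0, 1]`
#'   (default 0.95).
#' @param nFrames number of frames (default 1000).
#' @param seed RNG seed.
#' @param poseRotSd per-frame random rotation angle sd (degrees; default 0).
#' @param poseTransSd per-frame random translation sd (Angstrom; default 0).
#' @param startRes author number of the first residue (default 342, the
#'   P17 position in alpha-1-antitrypsin numbering).
#' @param chain chain identifier (default "A").
#' @param resNames per-residue 3-letter codes (default poly-alanine).
#' @return list of class `ensembleSpec`.
#' @export
ensembleSpec <- function(nRes = 18, basins = NULL, stayProb = 0.95,
                         nFrames = 1000, seed = 1, poseRotSd = 0,
                         poseTransSd = 0, startRes = 342, chain = "A",
                         resNames = NULL) {
  if (is.null(basins))
    basins <- list(
      basinSpec(phi = -120, psi = 130, weight = 1 / 3),   # extended
      basinSpec(phi = -60, psi = -45, weight = 1 / 3),    # helical
      basinSpec(phi = -75, psi = 150, weight = 1 / 3)     # PPII-like
    )
  if (stayProb < 0 || stayProb > 1)
    stop("stayProb must lie in [0, 1]", call. = FALSE)
  if (nFrames < 1) stop("nFrames must be >= 1", call. = FALSE)
  if (is.null(resNames)) resNames <- rep("ALA", nRes)
  structure(list(nRes = nRes, basins = basins, stayProb = stayProb,
                 nFrames = nFrames, seed = seed, poseRotSd = poseRotSd,
                 poseTransSd = poseTransSd, startRes = startRes,
                 chain = chain, resNames = resNames),
            class = "ensembleSpec")
}

# Expand a basin's dihedral template to an nRes x 3 matrix.
basinTemplate <- function(basin, nRes) {
  cbind(phi = rep_len(basin$phi, nRes),
        psi = rep_len(basin$psi, nRes),
        omega = rep_len(basin$omega, nRes))
}

# Deterministic internal-coordinate chain build; returns a (4*nRes) x 3
# matrix in N, CA, C, O order per residue (+ CB appended per residue when
# requested).
buildBackboneCoords <- function(template, cbeta = FALSE) {
  nRes <- nrow(template)
  co <- matrix(NA_real_, nRes * 4L, 3L)
  rowOf <- function(i, what) (i - 1L) * 4L + match(what, c("N", "CA", "C", "O"))
  # residue 1 placed canonically: N at origin, CA on +x, C in the xy-plane
  co[rowOf(1, "N"), ] <- c(0, 0, 0)
  co[rowOf(1, "CA"), ] <- c(BOND_N_CA, 0, 0)
  ang <- ANGLE_N_CA_C * pi / 180
  co[rowOf(1, "C"), ] <- co[rowOf(1, "CA"), ] +
    BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(nRes)[-1]) {
    co[rowOf(i, "N"), ] <- placeAtom(
      co[rowOf(i - 1, "N"), ], co[rowOf(i - 1, "CA"), ],
      co[rowOf(i - 1, "C"), ],
      BOND_C_N, ANGLE_CA_C_N, template[i - 1, "psi"])
    co[rowOf(i, "CA"), ] <- placeAtom(
      co[rowOf(i - 1, "CA"), ], co[rowOf(i - 1, "C"), ], co[rowOf(i, "N"), ],
      BOND_N_CA, ANGLE_C_N_CA, template[i, "omega"])
    co[rowOf(i, "C"), ] <- placeAtom(
      co[rowOf(i - 1, "C"), ], co[rowOf(i, "N"), ], co[rowOf(i, "CA"), ],
      BOND_CA_C, ANGLE_N_CA_C, template[i, "phi"])
  }
  # carbonyl O from the psi torsion (psi + 180 places O trans to N(i+1));
  # the template psi is used for the final residue too.
  for (i in seq_len(nRes)) {
    co[rowOf(i, "O"), ] <- placeAtom(
      co[rowOf(i, "N"), ], co[rowOf(i, "CA"), ], co[rowOf(i, "C"), ],
      BOND_C_O, ANGLE_CA_C_O, template[i, "psi"] + 180)
  }
  if (!cbeta) return(co)
  cb <- matrix(NA_real_, nRes, 3L)
  for (i in seq_len(nRes)) {
    # CB placed off the backbone plane at the canonical -122 deg branch
    cb[i, ] <- placeAtom(
      co[rowOf(i, "C"), ], co[rowOf(i, "N"), ], co[rowOf(i, "CA"), ],
      BOND_CA_CB, ANGLE_N_CA_CB, -122)
  }
  list(backbone = co, cbeta = cb)
}

backboneAtomTable <- function(nRes, startRes, chain, resNames,
                              cbeta = FALSE) {
  names4 <- c("N", "CA", "C", "O")
  nms <- if (cbeta) c(names4, "CB") else names4
  k <- length(nms)
  data.frame(
    chain = rep(chain, nRes * k),
    resSeq = rep(as.integer(startRes) + seq_len(nRes) - 1L, each = k),
    resName = rep(resNames, each = k),
    atomName = rep(nms, nRes),
    element = rep(substr(nms, 1, 1), nRes),
    nonstandard = rep(!(resNames %in% STANDARD_AA3), each = k),
    stringsAsFactors = FALSE
  )
}

#' Build an ideal-geometry backbone from a dihedral template
#'
#' Deterministic internal-coordinate (NeRF) chain construction with ideal
#' bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom) and
#' tetrahedral-like angles; `omega` is honoured as given. Atoms per residue
#' are N, CA, C, O (plus an optional CB placeholder). Recomputing phi/psi
#' from the built coordinates with [backboneDihedrals()] returns the
#' template.
#'
#' @param template `nRes x 3` matrix (columns `phi`, `psi`, `omega`,
#'   degrees), or a [basinSpec()] together with `nRes`.
#' @param nRes number of residues (required when `template` is a basinSpec).
#' @param startRes,chain,resNames residue labelling, see [ensembleSpec()].
#' @param cbeta also place a CB placeholder atom per residue (default FALSE).
#' @return a single-frame [ConformationEnsemble-class].
#' @examples
#' helix <- buildBackbone(basinSpec(phi = -60, psi = -45), nRes = 3)
#' nAtoms(helix)  # 12 atoms: N, CA, C, O per residue
#' @export
buildBackbone <- function(template, nRes = NULL, startRes = 342,
                          chain = "A", resNames = NULL, cbeta = FALSE) {
  if (inherits(template, "basinSpec")) {
    if (is.null(nRes)) stop("nRes required with a basinSpec", call. = FALSE)
    template <- basinTemplate(template, nRes)
  }
  template <- as.matrix(template)
  if (is.null(colnames(template))) colnames(template) <- c("phi", "psi", "omega")
  nRes <- nrow(template)
  if (is.null(resNames)) resNames <- rep("ALA", nRes)
  built <- buildBackboneCoords(template, cbeta = cbeta)
  if (cbeta) {
    bb <- built$backbone
    cb <- built$cbeta
    co <- matrix(NA_real_, nRes * 5L, 3L)
    for (i in seq_len(nRes)) {
      co[(i - 1L) * 5L + 1:4, ] <- bb[(i - 1L) * 4L + 1:4, ]
      co[(i - 1L) * 5L + 5L, ] <- cb[i, ]
    }
  } else {
    co <- built
  }
  at <- backboneAtomTable(nRes, startRes, chain, resNames, cbeta = cbeta)
  arr <- array(co, dim = c(1L, nrow(co), 3L))
  arr[1, , ] <- co
  new("ConformationEnsemble", coords = arr, atoms = at,
      frameInterval = NA_real_, sourceId = "built")
}

#' Sample a multi-basin loop ensemble with known basin labels
#'
#' Frame `t`'s basin follows a Markov chain whose transition matrix is
#' `stayProb * I + (1 - stayProb) * 1 w'` (off-diagonal mass proportional to
#' the basin weights `w`); its stationary distribution is exactly `w`. The
#' initial basin is drawn from `w`. Coordinates are the basin's
#' ideal-geometry backbone plus i.i.d. Gaussian jitter, plus an optional
#' per-frame rigid-body pose perturbation. Fully reproducible from
#' `(spec, seed)`.
#'
#' @param spec an [ensembleSpec()].
#' @return list with elements `ensemble` (a
#'   [ConformationEnsemble-class]) and `labels` (integer per-frame basin
#'   index, 1-based).
#' @examples
#' out <- sampleEnsemble(ensembleSpec(nFrames = 50, seed = 7))
#' table(out$labels)
#' @export
sampleEnsemble <- function(spec) {
  stopifnot(inherits(spec, "ensembleSpec"))
  nB <- length(spec$basins)
  if (nB == 0L) stop("spec contains zero basins", call. = FALSE)
  w <- vapply(spec$basins, `[[`, numeric(1), "weight")
  if (any(w < 0) || sum(w) <= 0)
    stop("basin weights must be non-negative and not all zero", call. = FALSE)
  w <- w / sum(w)
  templates <- lapply(spec$basins, function(b)
    buildBackboneCoords(basinTemplate(b, spec$nRes)))
  A <- spec$nRes * 4L
  withSeed(spec$seed, {
    labels <- integer(spec$nFrames)
    labels[1] <- sample.int(nB, 1, prob = w)
    if (spec$nFrames > 1) {
      stay <- stats::runif(spec$nFrames - 1) < spec$stayProb
      jumps <- sample.int(nB, spec$nFrames - 1, replace = TRUE, prob = w)
      for (t in 2:spec$nFrames)
        labels[t] <- if (stay[t - 1]) labels[t - 1] else jumps[t - 1]
    }
    co <- array(0, dim = c(spec$nFrames, A, 3))
    # jitter is drawn for every frame first so that switching pose noise on
    # or off leaves the underlying conformations (same seed) unchanged
    for (t in seq_len(spec$nFrames)) {
      b <- spec$basins[[labels[t]]]
      x <- templates[[labels[t]]]
      if (b$jitterSigma > 0)
        x <- x + matrix(stats::rnorm(A * 3, 0, b$jitterSigma), A, 3)
      co[t, , ] <- x
    }
    if (spec$poseRotSd > 0 || spec$poseTransSd > 0) {
      for (t in seq_len(spec$nFrames)) {
        x <- co[t, , ]
        cen <- colMeans(x)
        if (spec$poseRotSd > 0) {
          R <- randomRotation(spec$poseRotSd)
          x <- sweep(sweep(x, 2, cen) %*% t(R), 2, cen, "+")
        }
        if (spec$poseTransSd > 0)
          x <- sweep(x, 2, stats::rnorm(3, 0, spec$poseTransSd), "+")
        co[t, , ] <- x
      }
    }
    at <- backboneAtomTable(spec$nRes, spec$startRes, spec$chain,
                            spec$resNames)
    ens <- new("ConformationEnsemble", coords = co, atoms = at,
               frameInterval = NA_real_, sourceId = "synthetic")
    list(ensemble = ens, labels = labels)
  })
}

#' Simulate a two-state salt-bridge distance time series
#'
#' A formed/broken two-state Markov chain with exact stationary
#' formed-probability `pFormed` (transition matrix
#' `stayProb * I + (1 - stayProb) * 1 p'`), observed through Gaussian
#' distance noise around the formed (`dOn`) and broken (`dOff`) distance
#' levels. The caller's occupancy cutoff is intended to satisfy
#' `dOn < cutoff < dOff`.
#'
#' @param pFormed stationary probability of the formed state, in `[0, 1]`.
#' @param stayProb Markov persistence (default 0.95).
#' @param dOn formed-state distance level (Angstrom, default 3.0).
#' @param dOff broken-state distance level (Angstrom, default 6.0).
#' @param noiseSd Gaussian distance noise sd (default 0.1).
#' @param n series length.
#' @param seed RNG seed.
#' @return list with `distance` (numeric n) and `state` (logical n, TRUE =
#'   formed).
#' @examples
#' s <- simulateSaltBridgeSeries(0.91, n = 1000, seed = 1)
#' mean(s$distance <= 4.0)
#' @export
simulateSaltBridgeSeries <- function(pFormed, stayProb = 0.95, dOn = 3.0,
                                     dOff = 6.0, noiseSd = 0.1, n = 1000,
                                     seed = 1) {
  if (pFormed < 0 || pFormed > 1)
    stop("pFormed must lie in [0, 1]", call. = FALSE)
  if (stayProb < 0 || stayProb > 1)
    stop("stayProb must lie in [0, 1]", call. = FALSE)
  withSeed(seed, {
    state <- logical(n)
    state[1] <- stats::runif(1) < pFormed
    if (n > 1) {
      stay <- stats::runif(n - 1) < stayProb
      jump <- stats::runif(n - 1) < pFormed
      for (t in 2:n) state[t] <- if (stay[t - 1]) state[t - 1] else jump[t - 1]
    }
    d <- ifelse(state, dOn, dOff)
    if (noiseSd > 0) d <- d + stats::rnorm(n, 0, noiseSd)
    list(distance = d, state = state)
  })
}

#' Simulate a Boltzmann-sigmoid thermal melt curve
#'
#' `signal(T) = baseFolded + (baseUnfolded - baseFolded) /
#' (1 + exp((tm - T) / slope)) + noise`. At `T = tm` the noiseless signal is
#' the midpoint of the two baselines.
#'
#' @param tm melt midpoint (degrees C).
#' @param slope transition width parameter (degrees C, nonzero).
#' @param baseFolded,baseUnfolded folded/unfolded baselines (signal units).
#' @param noiseSd Gaussian signal noise sd (default 0).
#' @param temps temperatures (degrees C), ascending.
#' @param seed RNG seed.
#' @return `data.frame` with columns `temperature`, `signal`.
#' @examples
#' m <- simulateMelt(tm = 72.2, slope = 2, baseFolded = -10,
#'                   baseUnfolded = -2, temps = seq(35, 95))
#' @export
simulateMelt <- function(tm, slope, baseFolded = -10, baseUnfolded = -2,
                         noiseSd = 0, temps = seq(35, 95, by = 1),
                         seed = 1) {
  if (slope == 0) stop("slope must be nonzero", call. = FALSE)
  if (is.unsorted(temps))
    stop("temps must be ascending", call. = FALSE)
  withSeed(seed, {
    s <- baseFolded + (baseUnfolded - baseFolded) /
      (1 + exp((tm - temps) / slope))
    if (noiseSd > 0) s <- s + stats::rnorm(length(temps), 0, noiseSd)
    data.frame(temperature = temps, signal = s)
  })
}

#' Simulate a residual-activity inhibition assay
#'
#' Residual protease activity at serpin:protease molar ratio `r` follows
#' `a(r) = max(0, 1 - r / si) + noise`: a line from 1 at `r = 0` to its
#' x-intercept at the stoichiometry of inhibition, clamped at the zero floor
#' beyond it.
#'
#' @param si stoichiometry of inhibition (> 0).
#' @param e0 protease concentration in molar units (metadata; default
#'   105e-9, a typical constant-protease assay concentration).
#' @param ratios serpin:protease molar ratios (default 0..2 by 0.25).
#' @param replicates independent measurements per ratio (default 3, the
#'   usual triplicate protocol for SI determinations).
#' @param noiseSd Gaussian activity noise sd per measurement (default 0).
#' @param seed RNG seed.
#' @return `data.frame` with columns `ratio`, `replicate`,
#'   `residualActivity`; `e0` is attached as an attribute.
#' @examples
#' a <- simulateInhibitionAssay(si = 1.64)
#' @export
simulateInhibitionAssay <- function(si, e0 = 105e-9,
                                    ratios = seq(0, 2, by = 0.25),
                                    replicates = 3, noiseSd = 0, seed = 1) {
  if (si <= 0) stop("si must be > 0", call. = FALSE)
  withSeed(seed, {
    r <- rep(ratios, each = replicates)
    a <- pmax(0, 1 - r / si)
    if (noiseSd > 0) a <- a + stats::rnorm(length(r), 0, noiseSd)
    out <- data.frame(ratio = r,
                      replicate = rep(seq_len(replicates), length(ratios)),
                      residualActivity = a)
    attr(out, "e0") <- e0
    out
  })
}

#' Simulate an alignment with planted conservation and covariation
#'
#' Columns are drawn independently from the background amino-acid
#' frequencies, except (i) conserved columns, fixed to a single residue, and
#' (ii) covarying column pairs: with probability `coupling` the two columns
#' of a sequence receive the same background-drawn residue (a perfectly
#' coupled event), otherwise they are drawn independently. The coupling is
#' thus a mixture weight between independence and perfect coupling,
#' monotonically controlling the pair's mutual information.
#'
#' @param nSeq number of sequences.
#' @param nCol number of alignment columns.
#' @param conservedCols named character vector mapping column index to a
#'   1-letter residue, e.g. `c("3" = "C")`; or NULL.
#' @param covaryPairs list of `list(i =, j =, coupling =)`; or NULL.
#' @param backgroundFreqs named numeric vector over the 20 standard residues
#'   (default: the shipped background frequency table).
#' @param seed RNG seed.
#' @return an [Msa-class].
#' @examples
#' msa <- simulateMsa(50, 10, covaryPairs = list(list(i = 2, j = 7,
#'                    coupling = 1)), seed = 3)
#' @export
simulateMsa <- function(nSeq, nCol, conservedCols = NULL,
                        covaryPairs = NULL, backgroundFreqs = NULL,
                        seed = 1) {
  if (is.null(backgroundFreqs)) backgroundFreqs <- backgroundFrequencies()
  backgroundFreqs <- backgroundFreqs / sum(backgroundFreqs)
  aa <- names(backgroundFreqs)
  consIdx <- if (is.null(conservedCols)) integer(0) else
    as.integer(names(conservedCols))
  covIdx <- unlist(lapply(covaryPairs, function(p) c(p$i, p$j)))
  special <- c(consIdx, covIdx)
  if (anyDuplicated(special))
    stop("overlapping conserved/covarying column assignments: column(s) ",
         paste(unique(special[duplicated(special)]), collapse = ","),
         call. = FALSE)
  if (length(special) && (max(special) > nCol || min(special) < 1))
    stop("special column index outside 1..nCol", call. = FALSE)
  withSeed(seed, {
    m <- matrix(sample(aa, nSeq * nCol, replace = TRUE,
                       prob = backgroundFreqs), nSeq, nCol)
    for (k in seq_along(consIdx))
      m[, consIdx[k]] <- unname(conservedCols[k])
    for (p in covaryPairs) {
      coupled <- stats::runif(nSeq) < p$coupling
      shared <- sample(aa, nSeq, replace = TRUE, prob = backgroundFreqs)
      m[coupled, p$i] <- shared[coupled]
      m[coupled, p$j] <- shared[coupled]
    }
    Msa(ids = sprintf("seq%04d", seq_len(nSeq)), seqs = m)
  })
}

#' Background amino-acid frequencies
#'
#' The BLOSUM-style background frequency table shipped with the package
#' (inst/extdata/aa_background_freqs.tsv), used by [simulateMsa()] and as
#' the SCA pseudocount prior.
#'
#' @return named numeric vector over the 20 standard residues, summing to 1.
#' @export
backgroundFrequencies <- function() {
  path <- system.file("extdata", "aa_background_freqs.tsv",
                      package = "loopscape")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  f <- tab$freq
  names(f) <- tab$aa
  f / sum(f)
}
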