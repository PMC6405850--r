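#' @include structure_io.R
NULL

RESIDUE_CHARGE <- c(ASP = -1, GLU = -1, LYS = +1, ARG = +1, HIS = 0)

#' Energy model for local frustration analysis
#'
#' A reduced contact Hamiltonian: a 20 x 20 statistical contact potential
#' plus a Debye-screened Coulomb term between formal side-chain charges,
#' `E(a, b, r) = V[a, b] + q_a q_b exp(-r / debyeLength) / (kElec * r)`.
#' The electrostatic strength constant defaults to 4.15. The shipped default
#' potential is a hydrophobicity-derived synthetic table
#' (contact_potential_synthetic.tsv); any symmetric 20 x 20 table with
#' 1-letter row/column names can be swapped in.
#'
#' @param contactPotential symmetric 20 x 20 numeric matrix with 1-letter
#'   amino-acid dimnames, or `NULL` for the shipped table.
#' @param kElec electrostatic strength constant (> 0, default 4.15).
#' @param debyeLength screening length (Angstrom, default 10).
#' @param contactCutoff CB-CB contact cutoff (Angstrom, default 8.0; CA for
#'   glycine).
#' @param charges named per-residue-type formal charges (default: D, E = -1;
#'   K, R = +1; H = 0).
#' @return list of class `energyModel`.
#' @export
energyModel <- function(contactPotential = NULL, kElec = 4.15,
                        debyeLength = 10, contactCutoff = 8.0,
                        charges = RESIDUE_CHARGE) {
  if (kElec <= 0) stop("kElec must be > 0", call. = FALSE)
  if (is.null(contactPotential)) {
    path <- system.file("extdata", "contact_potential_synthetic.tsv",
                        package = "loopscape")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    contactPotential <- as.matrix(tab[, -1])
    rownames(contactPotential) <- tab$aa
  }
  if (max(abs(contactPotential - t(contactPotential))) > 1e-9)
    stop("contactPotential must be symmetric", call. = FALSE)
  structure(list(contactPotential = contactPotential, kElec = kElec,
                 debyeLength = debyeLength, contactCutoff = contactCutoff,
                 charges = charges),
            class = "energyModel")
}

residueCharge1 <- function(aa1, charges = RESIDUE_CHARGE) {
  q <- charges[aa1to3(aa1)]
  q[is.na(q)] <- 0
  unname(q)
}

#' Residue-residue contact map
#'
#' Unordered residue pairs with sequence separation `|i - j| >= 2` whose
#' side-chain centroids (CB; CA for glycine) lie within the cutoff. Residues
#' missing a CB that are not glycine are skipped with a warning; nonstandard
#' residues are excluded.
#'
#' @param structure single-frame [ConformationEnsemble-class].
#' @param cutoff contact distance (Angstrom; default: 8.0).
#' @param minSeqSep minimum sequence separation (default 2).
#' @return `data.frame` with columns `i`, `j` (residue order indices),
#'   `resI`, `resJ` (1-letter types), `resSeqI`, `resSeqJ`, `r` (Angstrom).
#' @export
contactMap <- function(structure, cutoff = 8.0, minSeqSep = 2) {
  at <- structure@atoms
  co <- structure@coords[1, , , drop = TRUE]
  if (is.null(dim(co))) co <- matrix(co, ncol = 3)
  resKey <- paste(at$chain, at$resSeq)
  resIds <- unique(resKey)
  pos <- matrix(NA_real_, length(resIds), 3)
  keep <- logical(length(resIds))
  aa1 <- character(length(resIds))
  resSeqs <- integer(length(resIds))
  skipped <- character(0)
  for (r in seq_along(resIds)) {
    rows <- which(resKey == resIds[r])
    rn <- at$resName[rows[1]]
    resSeqs[r] <- at$resSeq[rows[1]]
    if (!(rn %in% STANDARD_AA3)) next  # nonstandard residues excluded
    aa1[r] <- STANDARD_AA1[rn]
    anchor <- if (rn == "GLY") "CA" else "CB"
    i <- rows[at$atomName[rows] == anchor]
    if (!length(i)) {
      skipped <- c(skipped, resIds[r])
      next
    }
    pos[r, ] <- co[i[1], ]
    keep[r] <- TRUE
  }
  if (length(skipped))
    warning("residue(s) without CB skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  idx <- which(keep)
  out <- list()
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      if (abs(i - j) < minSeqSep) next
      r_ <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (r_ <= cutoff)
        out[[length(out) + 1L]] <- data.frame(
          i = i, j = j, resI = aa1[i], resJ = aa1[j],
          resSeqI = resSeqs[i], resSeqJ = resSeqs[j], r = r_,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0), resI = character(0),
                      resJ = character(0), resSeqI = integer(0),
                      resSeqJ = integer(0), r = numeric(0)))
  do.call(rbind, out)
}

#' Pairwise contact energy under an energy model
#'
#' `E = V[a, b] + q_a q_b exp(-r / debyeLength) / (kElec * r)`. Doubling
#' `kElec` halves the electrostatic term exactly; uncharged pairs reduce to
#' the contact-potential term.
#'
#' @param a,b 1-letter residue types.
#' @param r distance (Angstrom, > 0).
#' @param model an [energyModel()].
#' @return numeric energy (model units).
#' @examples
#' m <- energyModel()
#' pairEnergy("E", "K", 4, m)
#' @export
pairEnergy <- function(a, b, r, model = energyModel()) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  V <- model$contactPotential[cbind(a, b)]
  q <- residueCharge1(a, model$charges) * residueCharge1(b, model$charges)
  V + q * exp(-r / model$debyeLength) / (model$kElec * r)
}

#' Mutational frustration index of native contacts
#'
#' For every native contact, decoy energies are obtained by mutating the two
#' residue identities while keeping the geometry fixed: decoy residue pairs
#' are drawn i.i.d. from the structure's amino-acid composition (sampled
#' mode, seeded) or enumerated exhaustively over all composition-weighted
#' type pairs (`nDecoys = "exhaustive"`). The frustration index is the
#' z-score `F = (mean(E_decoy) - E_native) / sd(E_decoy)`: positive when the
#' native pair is more favourable than typical decoys (minimally
#' frustrated). Contacts with zero decoy spread (e.g. a homopolymer) get
#' `F = 0` and are flagged degenerate. The index is invariant under affine
#' rescaling `E -> aE + b` (a > 0) of the whole model.
#'
#' @param structure single-frame [ConformationEnsemble-class] with CB
#'   placeholders (see [buildBackbone()] `cbeta = TRUE`).
#' @param model an [energyModel()].
#' @param nDecoys decoy count (>= 2), or `"exhaustive"`.
#' @param seed RNG seed for sampled decoys.
#' @param contacts optional precomputed [contactMap()].
#' @return a [FrustrationMap-class].
#' @export
frustrationIndex <- function(structure, model = energyModel(),
                             nDecoys = 2000, seed = 1, contacts = NULL) {
  exhaustive <- identical(nDecoys, "exhaustive")
  if (!exhaustive && nDecoys < 2)
    stop("nDecoys must be >= 2 (or 'exhaustive')", call. = FALSE)
  if (is.null(contacts))
    contacts <- contactMap(structure, cutoff = model$contactCutoff)
  at <- structure@atoms
  compRes <- unique(at[!at$nonstandard, c("chain", "resSeq", "resName")])
  compAa <- STANDARD_AA1[compRes$resName]
  compAa <- compAa[!is.na(compAa)]
  comp <- table(compAa) / length(compAa)
  types <- names(comp)
  wts <- as.numeric(comp)
  n <- nrow(contacts)
  eNative <- decoyMean <- decoySd <- fIndex <- numeric(n)
  degenerate <- logical(n)
  withSeed(seed, {
    for (c in seq_len(n)) {
      r_ <- contacts$r[c]
      eNative[c] <- pairEnergy(contacts$resI[c], contacts$resJ[c], r_, model)
      if (exhaustive) {
        grid <- expand.grid(a = types, b = types, stringsAsFactors = FALSE)
        w <- wts[match(grid$a, types)] * wts[match(grid$b, types)]
        e <- pairEnergy(grid$a, grid$b, rep(r_, nrow(grid)), model)
        decoyMean[c] <- sum(w * e)
        decoySd[c] <- sqrt(sum(w * (e - decoyMean[c])^2))
      } else {
        da <- sample(types, nDecoys, replace = TRUE, prob = wts)
        db <- sample(types, nDecoys, replace = TRUE, prob = wts)
        e <- pairEnergy(da, db, rep(r_, nDecoys), model)
        decoyMean[c] <- mean(e)
        decoySd[c] <- stats::sd(e)
      }
      if (!is.finite(decoySd[c]) || decoySd[c] < 1e-12) {
        fIndex[c] <- 0
        degenerate[c] <- TRUE
        decoySd[c] <- 0
      } else {
        fIndex[c] <- (decoyMean[c] - eNative[c]) / decoySd[c]
      }
    }
  })
  df <- data.frame(contacts[, c("i", "j", "resI", "resJ")],
                   r = contacts$r, eNative = eNative,
                   decoyMean = decoyMean, decoySd = decoySd,
                   fIndex = fIndex,
                   class = classifyFrustration(fIndex),
                   degenerate = degenerate, stringsAsFactors = FALSE)
  new("FrustrationMap", contacts = df,
      model = list(kElec = model$kElec, debyeLength = model$debyeLength,
                   contactCutoff = model$contactCutoff,
                   nDecoys = if (exhaustive) "exhaustive" else nDecoys,
                   seed = seed))
}

#' Classify frustration indices
#'
#' Conventional z-score thresholds: minimally frustrated at `F >= 0.78`
#' (inclusive), highly frustrated at `F <= -1`, neutral between.
#'
#' @param f numeric frustration indices.
#' @param minimal,high class thresholds (defaults 0.78 and -1).
#' @return character vector in `{minimal, neutral, high}`.
#' @examples
#' classifyFrustration(c(0.78, 0, -1))
#' @export
classifyFrustration <- function(f, minimal = 0.78, high = -1) {
  ifelse(f >= minimal, "minimal", ifelse(f <= high, "high", "neutral"))
}
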