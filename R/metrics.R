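#' @include structure_io.R
NULL

# Kabsch rotation (SVD with determinant correction) aligning mobile onto
# reference; both are n x 3 matrices already reduced to the fit atoms.
kabschRotation <- function(mobile, reference) {
  h <- crossprod(mobile, reference)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Kabsch superposition of one coordinate set onto another
#'
#' Least-squares rigid-body superposition: the returned rotation is always
#' proper (determinant +1; mirror solutions are rejected), and the returned
#' RMSD over the fit selection is the global minimum over rigid motions.
#'
#' @param mobile `A x 3` coordinate matrix to transform.
#' @param reference `A x 3` coordinate matrix (same atom count).
#' @param fitSelection integer atom indices used for the fit (default: all).
#'   At least 3 non-collinear atoms are required.
#' @return list with `coords` (transformed full mobile set), `rmsd`
#'   (Angstrom, over the fit selection), `rotation` (3 x 3), `translation`.
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' rot <- randomRotationMatrix(seed = 1)
#' mob <- ref %*% t(rot) + 5
#' kabschSuperpose(mob, ref)$rmsd  # ~0
#' @export
kabschSuperpose <- function(mobile, reference, fitSelection = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have the same dimensions", call. = FALSE)
  if (is.null(fitSelection)) fitSelection <- seq_len(nrow(mobile))
  if (length(fitSelection) < 3)
    stop("at least 3 fit atoms are required", call. = FALSE)
  mFit <- mobile[fitSelection, , drop = FALSE]
  rFit <- reference[fitSelection, , drop = FALSE]
  mc <- colMeans(mFit)
  rc <- colMeans(rFit)
  mFitC <- sweep(mFit, 2, mc)
  rFitC <- sweep(rFit, 2, rc)
  if (qr(mFitC)$rank < 2)
    stop("fit atoms are collinear; superposition is underdetermined",
         call. = FALSE)
  rot <- kabschRotation(mFitC, rFitC)
  out <- sweep(mobile, 2, mc) %*% rot
  out <- sweep(out, 2, rc, "+")
  rmsd <- sqrt(mean(rowSums((out[fitSelection, , drop = FALSE] - rFit)^2)))
  list(coords = out, rmsd = rmsd, rotation = rot,
       translation = rc - as.vector(mc %*% rot))
}

#' Random proper rotation matrix
#'
#' Uniform over SO(3) (quaternion method); exported as a convenience for
#' rigid-motion invariance experiments.
#'
#' @param seed RNG seed (optional).
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
randomRotationMatrix <- function(seed = NULL) {
  withSeed(seed, randomRotation())
}

#' Per-frame RMSD series relative to a reference frame
#'
#' Each frame is superposed (over `fitSelection`) onto the reference frame
#' and the RMSD over `measureSelection` after the fit is reported. With
#' `block` > 1, block means over consecutive windows are also returned (the
#' last partial block is retained and flagged).
#'
#' @param ens a [ConformationEnsemble-class].
#' @param referenceFrame frame index of the reference (default 1).
#' @param fitSelection atom indices used for superposition (default all).
#' @param measureSelection atom indices entering the RMSD (default: the fit
#'   selection).
#' @param block frames per averaging window (default 1 = no blocking).
#' @return `data.frame` per frame (`frame`, `rmsd`) with attributes `blocks`
#'   (`data.frame` of block means, columns `block`, `rmsd`, `nFrames`,
#'   `partial`) and `blockSize`.
#' @export
rmsdSeries <- function(ens, referenceFrame = 1, fitSelection = NULL,
                       measureSelection = NULL, block = 1) {
  co <- ens@coords
  nF <- dim(co)[1]
  if (referenceFrame < 1 || referenceFrame > nF)
    stop(sprintf("reference frame %d outside 1..%d", referenceFrame, nF),
         call. = FALSE)
  if (block < 1) stop("block must be >= 1", call. = FALSE)
  if (is.null(fitSelection)) fitSelection <- seq_len(dim(co)[2])
  if (is.null(measureSelection)) measureSelection <- fitSelection
  ref <- co[referenceFrame, , ]
  vals <- vapply(seq_len(nF), function(f) {
    fit <- kabschSuperpose(co[f, , ], ref, fitSelection)
    sqrt(mean(rowSums(
      (fit$coords[measureSelection, , drop = FALSE] -
         ref[measureSelection, , drop = FALSE])^2)))
  }, numeric(1))
  out <- data.frame(frame = seq_len(nF), rmsd = vals)
  attr(out, "blocks") <- blockMeans(vals, block)
  attr(out, "blockSize") <- block
  out
}

# Block means of a per-frame series; the trailing partial block is kept and
# flagged.
blockMeans <- function(x, block) {
  n <- length(x)
  id <- ceiling(seq_len(n) / block)
  data.frame(
    block = unique(id),
    value = as.vector(tapply(x, id, mean)),
    nFrames = as.vector(tapply(x, id, length)),
    partial = as.vector(tapply(x, id, length)) < block
  )
}

#' Per-residue RMSF about the iteratively refined mean structure
#'
#' Frames are superposed over `fitSelection` onto their mean structure,
#' which is refined iteratively (superpose, re-average, repeat until the
#' mean shifts by less than `tol`, at most `maxIter` rounds). The RMSF of
#' residue `i` is `sqrt(mean_t ||x_i(t) - xbar_i||^2)` for its measured atom,
#' averaged within blocks of `block` frames and then across blocks.
#' `fitSelection = NULL` superposes on all atoms; `fitSelection = NA`
#' disables superposition (raw coordinates).
#'
#' @param ens a [ConformationEnsemble-class] with >= 2 frames.
#' @param fitSelection atom indices for the fit; `NULL` = all atoms; `NA` =
#'   no superposition. A typical choice is scaffold (non-loop) CA atoms so
#'   loop flexibility is measured relative to the body.
#' @param measureAtom atom name measured per residue (default `"CA"`).
#' @param block frames per averaging block (default: all frames in one
#'   block).
#' @return `data.frame` with columns `chain`, `resSeq`, `rmsf` (Angstrom).
#' @export
rmsfPerResidue <- function(ens, fitSelection = NULL, measureAtom = "CA",
                           block = NULL) {
  co <- ens@coords
  nF <- dim(co)[1]
  if (nF < 2) stop("RMSF requires at least 2 frames", call. = FALSE)
  noFit <- length(fitSelection) == 1L && is.na(fitSelection[1])
  if (!noFit) {
    if (is.null(fitSelection)) fitSelection <- seq_len(dim(co)[2])
    co <- superposeToMean(co, fitSelection)
  }
  at <- ens@atoms
  mi <- which(at$atomName == measureAtom)
  if (!length(mi))
    stop("no atoms named ", measureAtom, " in ensemble", call. = FALSE)
  if (is.null(block)) block <- nF
  id <- ceiling(seq_len(nF) / block)
  perBlock <- vapply(unique(id), function(b) {
    fr <- which(id == b)
    xb <- co[fr, mi, , drop = FALSE]
    mean_ <- apply(xb, c(2, 3), mean)
    dev2 <- sweep(xb, c(2, 3), mean_)^2
    sqrt(apply(dev2, 2, sum) / length(fr))
  }, numeric(length(mi)))
  rmsf <- if (is.matrix(perBlock)) rowMeans(perBlock) else perBlock
  data.frame(chain = at$chain[mi], resSeq = at$resSeq[mi], rmsf = rmsf)
}

# Iterative mean-structure superposition: superpose -> mean -> re-superpose
# until the mean shifts < tol Angstrom (RMS), max maxIter rounds.
superposeToMean <- function(co, fitSelection, tol = 1e-6, maxIter = 20) {
  nF <- dim(co)[1]
  ref <- co[1, , ]
  for (iter in seq_len(maxIter)) {
    for (f in seq_len(nF))
      co[f, , ] <- kabschSuperpose(co[f, , ], ref, fitSelection)$coords
    newMean <- apply(co, c(2, 3), mean)
    shift <- sqrt(mean((newMean - ref)^2))
    ref <- newMean
    if (shift < tol) break
  }
  co
}

#' Backbone dihedral series of an ensemble
#'
#' Phi, psi (and omega) per residue per frame, degrees in (-180, 180],
#' IUPAC sign convention. Phi is undefined for the first residue of a chain,
#' psi for the last, omega for the first; these are returned as `NA`.
#' Residues missing a backbone atom yield `NA` with a warning.
#'
#' @param ens a [ConformationEnsemble-class] containing N, CA, C atoms.
#' @return list of matrices `phi`, `psi`, `omega` (`F x nRes`), with residue
#'   numbers as column names.
#' @examples
#' helix <- buildBackbone(basinSpec(phi = -60, psi = -45), nRes = 4)
#' backboneDihedrals(helix)$phi  # -60 for residues 2..4
#' @export
backboneDihedrals <- function(ens) {
  at <- ens@atoms
  co <- ens@coords
  nF <- dim(co)[1]
  resKey <- paste(at$chain, at$resSeq)
  resIds <- unique(resKey)
  nR <- length(resIds)
  idxOf <- function(res, name) {
    i <- which(resKey == res & at$atomName == name)
    if (length(i) == 1L) i else NA_integer_
  }
  Nn <- vapply(resIds, idxOf, integer(1), name = "N")
  Ca <- vapply(resIds, idxOf, integer(1), name = "CA")
  Cc <- vapply(resIds, idxOf, integer(1), name = "C")
  missing <- is.na(Nn) | is.na(Ca) | is.na(Cc)
  if (any(missing))
    warning("missing backbone atoms for residue(s): ",
            paste(resIds[missing], collapse = ", "),
            "; dihedrals reported NA", call. = FALSE)
  phi <- psi <- omega <- matrix(NA_real_, nF, nR)
  colnames(phi) <- colnames(psi) <- colnames(omega) <- resIds
  for (f in seq_len(nF)) {
    x <- co[f, , ]
    for (r in seq_len(nR)) {
      if (missing[r]) next
      if (r > 1 && !missing[r - 1]) {
        phi[f, r] <- dihedralAngle(x[Cc[r - 1], ], x[Nn[r], ],
                                   x[Ca[r], ], x[Cc[r], ])
        omega[f, r] <- dihedralAngle(x[Ca[r - 1], ], x[Cc[r - 1], ],
                                     x[Nn[r], ], x[Ca[r], ])
      }
      if (r < nR && !missing[r + 1])
        psi[f, r] <- dihedralAngle(x[Nn[r], ], x[Ca[r], ],
                                   x[Cc[r], ], x[Nn[r + 1], ])
    }
  }
  list(phi = phi, psi = psi, omega = omega)
}

#' Matched-CA RMSD between two single structures
#'
#' Convenience for comparing two crystal structures: CA atoms are matched on
#' (chain, residue number) across the two ensembles' first frames, Kabsch
#' superposed, and the minimum RMSD reported.
#'
#' @param a,b [ConformationEnsemble-class] objects (first frame used).
#' @param matchChains match on chain id as well as residue number
#'   (default TRUE; set FALSE for renamed chains).
#' @return list with `rmsd` (Angstrom) and `nMatched` (CA pairs used).
#' @export
caRmsd <- function(a, b, matchChains = TRUE) {
  keyify <- function(ens) {
    at <- ens@atoms
    sel <- which(at$atomName == "CA")
    key <- if (matchChains) paste(at$chain[sel], at$resSeq[sel])
           else as.character(at$resSeq[sel])
    list(sel = sel, key = key)
  }
  ka <- keyify(a)
  kb <- keyify(b)
  common <- intersect(ka$key, kb$key)
  if (length(common) < 3)
    stop("fewer than 3 matched CA atoms", call. = FALSE)
  ia <- ka$sel[match(common, ka$key)]
  ib <- kb$sel[match(common, kb$key)]
  xa <- a@coords[1, ia, ]
  xb <- b@coords[1, ib, ]
  fit <- kabschSuperpose(xa, xb)
  list(rmsd = fit$rmsd, nMatched = length(common))
}
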