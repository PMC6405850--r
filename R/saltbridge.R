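#' @include structure_io.R
NULL

# Charged side-chain atoms per residue type. Histidine is
# protonation-dependent and only counted when includeHis = TRUE.
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                    HIS = c("ND1", "NE2"))

chargedResidues <- function(atoms, includeHis = FALSE) {
  basicNames <- if (includeHis) names(BASIC_ATOMS)
                else setdiff(names(BASIC_ATOMS), "HIS")
  res <- unique(atoms[, c("chain", "resSeq", "resName")])
  res$role <- ifelse(res$resName %in% names(ACIDIC_ATOMS), "acidic",
                     ifelse(res$resName %in% basicNames, "basic", NA))
  res[!is.na(res$role), , drop = FALSE]
}

# Minimum charged-atom distance per frame between two atom index sets.
minDistSeries <- function(co, iA, iB) {
  nF <- dim(co)[1]
  out <- numeric(nF)
  for (f in seq_len(nF)) {
    xa <- matrix(co[f, iA, ], ncol = 3)
    xb <- matrix(co[f, iB, ], ncol = 3)
    dmin <- Inf
    for (j in seq_len(nrow(xb))) {
      dj <- min(rowSums(sweep(xa, 2, xb[j, ])^2))
      if (dj < dmin) dmin <- dj
    }
    out[f] <- sqrt(dmin)
  }
  out
}

#' Candidate salt-bridge pairs between two residue groups
#'
#' All acidic (Asp/Glu) x basic (Lys/Arg, optionally His) cross pairs
#' between the two groups, in both orientations, pre-screened: a pair is a
#' candidate only if its minimum charged-atom distance ever falls below
#' `cutoff + 2` Angstrom in the ensemble. A residue present in both groups
#' is never paired with itself.
#'
#' @param ens a [ConformationEnsemble-class].
#' @param groupA,groupB residue-number vectors (e.g. loop and body).
#' @param chainA,chainB chain ids (default: any).
#' @param cutoff formation cutoff used downstream (Angstrom, default 4.0);
#'   the pre-screen uses `cutoff + 2`.
#' @param includeHis count histidine as basic (default FALSE; flagged as
#'   protonation-dependent when included).
#' @return `data.frame` of candidate pairs with columns `acidicChain`,
#'   `acidicRes`, `acidicName`, `basicChain`, `basicRes`, `basicName`,
#'   `minDistance` (Angstrom, over frames), `his` (logical flag).
#' @export
findCandidatePairs <- function(ens, groupA, groupB, chainA = NULL,
                               chainB = NULL, cutoff = 4.0,
                               includeHis = FALSE) {
  at <- ens@atoms
  charged <- chargedResidues(at, includeHis = includeHis)
  inGroup <- function(res, group, chain) {
    ok <- res$resSeq %in% group
    if (!is.null(chain)) ok <- ok & res$chain %in% chain
    res[ok, , drop = FALSE]
  }
  ca <- inGroup(charged, groupA, chainA)
  cb <- inGroup(charged, groupB, chainB)
  out <- list()
  addPairs <- function(acid, base) {
    for (i in seq_len(nrow(acid))) for (j in seq_len(nrow(base))) {
      if (acid$chain[i] == base$chain[j] && acid$resSeq[i] == base$resSeq[j])
        next
      iA <- which(at$chain == acid$chain[i] & at$resSeq == acid$resSeq[i] &
                    at$atomName %in% ACIDIC_ATOMS[[acid$resName[i]]])
      iB <- which(at$chain == base$chain[j] & at$resSeq == base$resSeq[j] &
                    at$atomName %in% BASIC_ATOMS[[base$resName[j]]])
      if (!length(iA) || !length(iB)) next
      d <- minDistSeries(ens@coords, iA, iB)
      if (min(d) <= cutoff + 2) {
        out[[length(out) + 1L]] <<- data.frame(
          acidicChain = acid$chain[i], acidicRes = acid$resSeq[i],
          acidicName = acid$resName[i], basicChain = base$chain[j],
          basicRes = base$resSeq[j], basicName = base$resName[j],
          minDistance = min(d), his = base$resName[j] == "HIS",
          stringsAsFactors = FALSE)
      }
    }
  }
  addPairs(ca[ca$role == "acidic", ], cb[cb$role == "basic", ])
  addPairs(cb[cb$role == "acidic", ], ca[ca$role == "basic", ])
  if (!length(out)) {
    return(data.frame(acidicChain = character(0), acidicRes = integer(0),
                      acidicName = character(0), basicChain = character(0),
                      basicRes = integer(0), basicName = character(0),
                      minDistance = numeric(0), his = logical(0)))
  }
  do.call(rbind, out)
}

#' Fractional occupancy of a salt bridge over an ensemble
#'
#' A bridge is formed in a frame when the minimum distance over charged-atom
#' pairs (carboxylate O x side-chain N) is at most `cutoff`. Frames with
#' missing atoms are excluded from the denominator and counted separately.
#' Occupancy is monotone non-decreasing in `cutoff`.
#'
#' @param ens a [ConformationEnsemble-class].
#' @param pair one row of [findCandidatePairs()] output (or a list with the
#'   same fields).
#' @param cutoff formation distance (Angstrom, default 4.0; the common
#'   literature criterion for N-O salt bridges).
#' @return list with `occupancy` (fraction), `nFrames` (frames used),
#'   `nMissing` (frames excluded for missing atoms).
#' @export
saltBridgeOccupancy <- function(ens, pair, cutoff = 4.0) {
  at <- ens@atoms
  iA <- which(at$chain == pair$acidicChain & at$resSeq == pair$acidicRes &
                at$atomName %in% ACIDIC_ATOMS[[pair$acidicName]])
  iB <- which(at$chain == pair$basicChain & at$resSeq == pair$basicRes &
                at$atomName %in% BASIC_ATOMS[[pair$basicName]])
  if (!length(iA) || !length(iB))
    stop("pair atoms absent from the ensemble", call. = FALSE)
  d <- minDistSeries(ens@coords, iA, iB)
  ok <- is.finite(d)
  if (!any(ok))
    stop("pair atoms missing in every frame", call. = FALSE)
  list(occupancy = mean(d[ok] <= cutoff), nFrames = sum(ok),
       nMissing = sum(!ok))
}

#' Occupancy of a distance series at a cutoff
#'
#' Fraction of observations at or below the cutoff; the occupancy estimator
#' applied directly to a (possibly simulated) charged-atom distance series.
#'
#' @param distance numeric distances (Angstrom); NAs are dropped.
#' @param cutoff formation distance (Angstrom, default 4.0).
#' @return fraction in `[0, 1]`.
#' @examples
#' s <- simulateSaltBridgeSeries(0.91, n = 1e4, seed = 1)
#' occupancyFromDistances(s$distance)  # ~0.91
#' @export
occupancyFromDistances <- function(distance, cutoff = 4.0) {
  distance <- distance[is.finite(distance)]
  if (!length(distance)) stop("no finite distances", call. = FALSE)
  mean(distance <= cutoff)
}

#' Salt-bridge occupancy report for one or more ensembles
#'
#' Per-pair occupancy for every candidate pair, sorted descending; pairs at
#' or below `reportThreshold` (default 0.20, the conventional reporting
#' floor) are dropped unless `all = TRUE`. With several ensembles a
#' per-source occupancy column and pairwise difference columns are included,
#' so occupancy shifts of conserved bridges between systems stand out.
#'
#' @param ensembles a [ConformationEnsemble-class] or named list of them.
#' @param pairs `data.frame` from [findCandidatePairs()]; default: candidates
#'   recomputed from `groupA`/`groupB` on the first ensemble.
#' @param cutoff formation distance (Angstrom, default 4.0).
#' @param reportThreshold occupancy floor for inclusion (default 0.20).
#' @param all include pairs at or below the threshold (default FALSE).
#' @param groupA,groupB passed to [findCandidatePairs()] when `pairs` is
#'   NULL.
#' @return `data.frame`: pair identity columns, one `occupancy.<source>`
#'   column per ensemble, `occupancyMax`, and `diff.<a>.<b>` columns for
#'   source pairs.
#' @export
occupancyReport <- function(ensembles, pairs = NULL, cutoff = 4.0,
                            reportThreshold = 0.20, all = FALSE,
                            groupA = NULL, groupB = NULL) {
  if (is(ensembles, "ConformationEnsemble")) ensembles <- list(ensembles)
  if (is.null(names(ensembles)))
    names(ensembles) <- vapply(ensembles, function(e) e@sourceId,
                               character(1))
  if (is.null(pairs)) {
    if (is.null(groupA) || is.null(groupB))
      stop("either pairs or groupA/groupB must be given", call. = FALSE)
    pairs <- findCandidatePairs(ensembles[[1]], groupA, groupB,
                                cutoff = cutoff)
  }
  if (!nrow(pairs)) return(pairs)
  occCols <- vapply(ensembles, function(e) {
    vapply(seq_len(nrow(pairs)), function(i)
      saltBridgeOccupancy(e, pairs[i, ], cutoff)$occupancy, numeric(1))
  }, numeric(nrow(pairs)))
  occCols <- matrix(occCols, nrow = nrow(pairs),
                    dimnames = list(NULL, paste0("occupancy.",
                                                 names(ensembles))))
  out <- cbind(pairs[, c("acidicChain", "acidicRes", "acidicName",
                         "basicChain", "basicRes", "basicName", "his")],
               occCols)
  out$occupancyMax <- apply(occCols, 1, max)
  nm <- names(ensembles)
  if (length(nm) > 1) {
    for (a in seq_along(nm)[-length(nm)]) for (b in (a + 1):length(nm)) {
      out[[paste0("diff.", nm[a], ".", nm[b])]] <-
        occCols[, a] - occCols[, b]
    }
  }
  out <- out[order(-out$occupancyMax), , drop = FALSE]
  if (!all) out <- out[out$occupancyMax > reportThreshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
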