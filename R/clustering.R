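#' @include metrics.R hdbscan.R
NULL

#' Concatenate loop backbone coordinates across ensembles
#'
#' Extracts the loop backbone (default atoms N, CA, C, O) from each ensemble,
#' optionally superposes every frame onto a common reference over a scaffold
#' selection, and stacks the frames into one `F_total x 3A` matrix (columns
#' atom-major: x, y, z per selected atom). An 18-residue loop with the
#' default atom set gives 72 atoms and 216 columns. All ensembles must share
#' the loop atom layout; frames keep their input order and per-frame source
#' labels are returned.
#'
#' @param ensembles a [ConformationEnsemble-class] or list of them.
#' @param loop inclusive residue-number pair (default `c(342, 359)`, the
#'   P17-P1' span in alpha-1-antitrypsin numbering).
#' @param chain chain identifier or `NULL`.
#' @param atomNames loop atoms (default backbone N, CA, C, O).
#' @param fitResidues residue-number pair(s) defining the scaffold CA
#'   selection used to superpose frames onto the first frame of the first
#'   ensemble before extraction, or `NULL` (default) for no superposition
#'   (appropriate for loop-only synthetic ensembles or pre-aligned input).
#' @return list with `matrix` (`F_total x 3A`), `source` (character per
#'   row) and `atoms` (atom table of the selection).
#' @examples
#' ens <- sampleEnsemble(ensembleSpec(nRes = 18, nFrames = 5, seed = 1))$ensemble
#' lm <- loopMatrix(ens)
#' dim(lm$matrix)  # 5 x 216
#' @export
loopMatrix <- function(ensembles, loop = c(342, 359), chain = NULL,
                       atomNames = c("N", "CA", "C", "O"),
                       fitResidues = NULL) {
  if (is(ensembles, "ConformationEnsemble")) ensembles <- list(ensembles)
  refLayout <- NULL
  refFrame <- NULL
  rows <- list()
  src <- character(0)
  atomsOut <- NULL
  for (e in seq_along(ensembles)) {
    ens <- ensembles[[e]]
    if (!is.null(fitResidues)) {
      at <- ens@atoms
      fitIdx <- which(at$atomName == "CA" &
                        at$resSeq >= fitResidues[1] &
                        at$resSeq <= fitResidues[2])
      if (length(fitIdx) < 3)
        stop("scaffold fit selection has fewer than 3 CA atoms in source ",
             ens@sourceId, call. = FALSE)
      if (is.null(refFrame)) refFrame <- ens@coords[1, , ]
      co <- ens@coords
      for (f in seq_len(dim(co)[1]))
        co[f, , ] <- kabschSuperpose(co[f, , ], refFrame, fitIdx)$coords
      ens@coords <- co
    }
    sel <- selectAtoms(ens, chain = chain, resRange = loop,
                       atomNames = atomNames)
    layout <- paste(sel@atoms$resSeq, sel@atoms$atomName)
    if (is.null(refLayout)) {
      refLayout <- layout
      atomsOut <- sel@atoms
    } else if (length(layout) != length(refLayout) ||
               any(layout != refLayout)) {
      stop("loop atom layout of source '", ens@sourceId,
           "' does not match the first ensemble", call. = FALSE)
    }
    co <- sel@coords
    nF <- dim(co)[1]
    A <- dim(co)[2]
    # columns atom-major: (atom1.x, atom1.y, atom1.z, atom2.x, ...)
    m <- matrix(0, nF, 3 * A)
    for (f in seq_len(nF)) m[f, ] <- as.vector(t(co[f, , ]))
    rows[[e]] <- m
    src <- c(src, rep(ens@sourceId, nF))
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0(rep(paste0(atomsOut$resSeq, ".",
                                     atomsOut$atomName), each = 3),
                          ".", c("x", "y", "z"))
  list(matrix = mat, source = src, atoms = atomsOut)
}

#' Fit a full-rank PCA model to a coordinate matrix
#'
#' Eigendecomposition of the covariance of the mean-centred rows. All 3A
#' components are reported; rank-deficient directions carry zero eigenvalue,
#' so the component matrix is a complete orthonormal basis and projection is
#' distance-preserving.
#'
#' @param x numeric matrix, rows = frames (>= 2), columns = coordinates.
#' @return a [PCAModel-class].
#' @export
fitPCA <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2)
    stop("PCA requires at least 2 frames", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (nrow(x) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  tot <- sum(ev)
  vf <- if (tot > 0) ev / tot else rep(1 / length(ev), length(ev))
  new("PCAModel", mean = mu, components = t(eg$vectors),
      eigenvalues = ev, varianceFraction = vf)
}

#' Project coordinates into PCA space
#'
#' @param model a [PCAModel-class].
#' @param x matrix with the model's coordinate columns.
#' @param k number of leading components (default: all).
#' @return `nrow(x) x k` score matrix.
#' @export
projectPCA <- function(model, x, k = NULL) {
  x <- as.matrix(x)
  p <- length(model@mean)
  if (ncol(x) != p)
    stop("x has ", ncol(x), " columns; model expects ", p, call. = FALSE)
  if (is.null(k)) k <- p
  sweep(x, 2, model@mean) %*% t(model@components[seq_len(k), , drop = FALSE])
}

#' Reconstruct coordinates from PCA scores
#'
#' @param model a [PCAModel-class].
#' @param scores score matrix from [projectPCA()].
#' @return coordinate matrix (mean re-added).
#' @export
reconstructPCA <- function(model, scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  sweep(scores %*% model@components[seq_len(k), , drop = FALSE],
        2, model@mean, "+")
}

#' Minimum cluster size from a frame fraction
#'
#' Round-half-up of `fraction * nFrames`, floored at 2 (a cluster of one is
#' meaningless). The conventional 1 percent fraction turns an 8993-frame
#' concatenated trajectory into a 90-frame minimum cluster size.
#'
#' @param nFrames total frame count (>= 1).
#' @param fraction minimum cluster fraction (> 0; default 0.01).
#' @return integer.
#' @examples
#' minClusterSize(8993)  # 90
#' @export
minClusterSize <- function(nFrames, fraction = 0.01) {
  if (fraction <= 0) stop("fraction must be > 0", call. = FALSE)
  if (nFrames < 1) stop("nFrames must be >= 1", call. = FALSE)
  max(2L, as.integer(floor(fraction * nFrames + 0.5)))
}

#' Density-cluster projected conformations
#'
#' HDBSCAN (Euclidean) over the rows of a projection matrix with the given
#' minimum cluster size; `minSamples` defaults to the minimum cluster size
#' (default parameters of the cited implementation otherwise). Clusters are
#' relabelled 0-based by decreasing size; noise is -1. Medoid frames are
#' computed in the clustering coordinate space. With fewer frames than
#' `minSize` the result is a single all-noise assignment with a warning.
#'
#' @param projected `F x k` matrix (e.g. PCA scores; full-dimensional scores
#'   give clustering identical to the centred raw matrix, since Euclidean
#'   HDBSCAN is rotation-invariant).
#' @param minSize minimum cluster size (>= 2).
#' @param minSamples core-distance neighbour count (default `minSize`).
#' @param allowSingleCluster permit a single root-level cluster
#'   (default FALSE).
#' @param sourceLabels optional per-frame source labels for the occupancy
#'   table.
#' @return a [ClusterAssignment-class].
#' @export
clusterConformations <- function(projected, minSize,
                                 minSamples = minSize,
                                 allowSingleCluster = FALSE,
                                 sourceLabels = NULL) {
  projected <- as.matrix(projected)
  nF <- nrow(projected)
  if (is.null(sourceLabels)) sourceLabels <- rep("all", nF)
  if (nF < minSize) {
    warning("fewer frames (", nF, ") than the minimum cluster size (",
            minSize, "); all frames labelled noise", call. = FALSE)
    res <- list(labels = rep(-1L, nF), nClusters = 0L)
  } else {
    res <- hdbscan(projected, minClusterSize = minSize,
                   minSamples = minSamples,
                   allowSingleCluster = allowSingleCluster)
  }
  buildAssignment(res$labels, projected, sourceLabels)
}

buildAssignment <- function(labels, space, sourceLabels) {
  k <- if (any(labels >= 0L)) max(labels) + 1L else 0L
  sizes <- integer(k)
  med <- integer(k)
  if (k > 0L) {
    med <- clusterMedoidFromLabels(labels, space)
    for (c in seq_len(k)) sizes[c] <- sum(labels == c - 1L)
  }
  occ <- occupancyCounts(labels, sourceLabels, k)
  new("ClusterAssignment", labels = as.integer(labels), nClusters = k,
      sizes = sizes, medoidFrame = med, sourceOccupancy = occ)
}

occupancyCounts <- function(labels, sourceLabels, k) {
  srcs <- unique(sourceLabels)
  occ <- matrix(0L, length(srcs), k + 1L,
                dimnames = list(srcs, c(if (k > 0) paste0("cluster", 0:(k - 1)),
                                        "noise")))
  for (s in seq_along(srcs)) {
    ls <- labels[sourceLabels == srcs[s]]
    if (k > 0)
      for (c in seq_len(k)) occ[s, c] <- sum(ls == c - 1L)
    occ[s, k + 1L] <- sum(ls == -1L)
  }
  occ
}

clusterMedoidFromLabels <- function(labels, space) {
  k <- max(labels) + 1L
  med <- integer(k)
  for (c in seq_len(k)) {
    idx <- which(labels == c - 1L)
    if (length(idx) == 1L) {
      med[c] <- idx
    } else {
      d <- as.matrix(stats::dist(space[idx, , drop = FALSE]))
      med[c] <- idx[which.min(colSums(d))]  # ties: lowest frame index
    }
  }
  med
}

#' Medoid frame of each cluster
#'
#' The medoid is the member frame minimising the summed Euclidean distance
#' to all co-members in the supplied coordinate space; ties break to the
#' lowest frame index. Matches exhaustive search by construction.
#'
#' @param assignment a [ClusterAssignment-class] (or integer label vector).
#' @param space the matrix the clustering was computed in.
#' @return integer frame index per cluster.
#' @export
clusterMedoid <- function(assignment, space) {
  labels <- if (is(assignment, "ClusterAssignment")) assignment@labels
            else as.integer(assignment)
  if (!any(labels >= 0L)) return(integer(0))
  clusterMedoidFromLabels(labels, as.matrix(space))
}

#' Per-source cluster exploration table
#'
#' Counts and fractions of each source's frames per cluster and in noise:
#' which conformational basins each simulated system explored, and where
#' sources overlap in a shared cluster.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param sourceLabels per-frame source labels (default: those stored in the
#'   assignment's occupancy matrix).
#' @return `data.frame` with columns `source`, `cluster` (label or
#'   `"noise"`), `count`, `fraction` (of the source's frames).
#' @export
clusterOccupancyTable <- function(assignment, sourceLabels = NULL) {
  occ <- assignment@sourceOccupancy
  if (!is.null(sourceLabels)) {
    occ <- occupancyCounts(assignment@labels, sourceLabels,
                           assignment@nClusters)
  }
  long <- expand.grid(source = rownames(occ), cluster = colnames(occ),
                      stringsAsFactors = FALSE)
  long$count <- as.vector(occ)
  tot <- rowSums(occ)
  long$fraction <- long$count / tot[long$source]
  long[order(long$source, long$cluster), , drop = FALSE]
}
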