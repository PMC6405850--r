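#' @import methods
NULL

#' ConformationEnsemble: frames of an atomic coordinate ensemble
#'
#' Container for a conformational ensemble: `F` frames of the same `A` atoms,
#' e.g. the MODELs of a multi-model PDB file or the frames of a molecular
#' dynamics trajectory. Atom metadata (chain, author residue number, residue
#' name, atom name, element) is carried alongside the coordinates; every frame
#' shares the atom order of the first.
#'
#' @slot coords numeric array `F x A x 3`, Angstrom.
#' @slot atoms `data.frame` with one row per atom and columns `chain`,
#'   `resSeq` (author numbering), `resName` (3-letter code), `atomName`,
#'   `element`, `nonstandard` (logical; residue name outside the 20 standard
#'   amino acids).
#' @slot frameInterval numeric(1), picoseconds between frames (`NA` if
#'   unknown); metadata only.
#' @slot sourceId character(1) label of the originating system.
#'
#' @seealso [readMultimodelPDB()], [selectAtoms()], [sampleEnsemble()]
#' @exportClass ConformationEnsemble
setClass("ConformationEnsemble",
  representation(
    coords = "array",
    atoms = "data.frame",
    frameInterval = "numeric",
    sourceId = "character"
  )
)

setValidity("ConformationEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be an F x A x 3 array")
  if (d[1] < 1L)
    return("ensemble must contain at least one frame")
  if (nrow(object@atoms) != d[2])
    return(sprintf("atoms table has %d rows but coords has %d atoms",
                   nrow(object@atoms), d[2]))
  need <- c("chain", "resSeq", "resName", "atomName", "element", "nonstandard")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (!all(is.finite(object@coords)))
    return("coords contains non-finite values")
  keys <- paste(object@atoms$chain, object@atoms$resSeq, object@atoms$atomName)
  if (anyDuplicated(keys))
    return("atom names must be unique within a residue")
  TRUE
})

#' PCAModel: principal components of loop coordinate space
#'
#' Full-rank eigendecomposition of the covariance of mean-centred coordinate
#' rows. Rank-deficient directions are retained with zero eigenvalue so that
#' `components` is always a complete orthonormal basis of the 3A-dimensional
#' coordinate space.
#'
#' @slot mean numeric 3A-vector, column means of the training matrix.
#' @slot components numeric `3A x 3A` orthonormal matrix, rows = principal
#'   components in order of non-increasing eigenvalue.
#' @slot eigenvalues numeric 3A-vector (Angstrom^2), non-increasing.
#' @slot varianceFraction numeric 3A-vector summing to 1.
#'
#' @seealso [fitPCA()], [projectPCA()]
#' @exportClass PCAModel
setClass("PCAModel",
  representation(
    mean = "numeric",
    components = "matrix",
    eigenvalues = "numeric",
    varianceFraction = "numeric"
  )
)

setValidity("PCAModel", function(object) {
  p <- length(object@mean)
  if (!all(dim(object@components) == c(p, p)))
    return("components must be square with dimension length(mean)")
  if (length(object@eigenvalues) != p || length(object@varianceFraction) != p)
    return("eigenvalues and varianceFraction must have length(mean) entries")
  ctc <- tcrossprod(object@components)
  if (max(abs(ctc - diag(p))) > 1e-8)
    return("components are not orthonormal within 1e-8")
  if (abs(sum(object@varianceFraction) - 1) > 1e-8)
    return("varianceFraction must sum to 1 within 1e-8")
  if (any(diff(object@eigenvalues) > 1e-10))
    return("eigenvalues must be non-increasing")
  TRUE
})

#' ClusterAssignment: density-clustering result over ensemble frames
#'
#' @slot labels integer per-frame cluster label; clusters are numbered from 0
#'   by decreasing size, noise frames carry -1.
#' @slot nClusters integer(1).
#' @slot sizes integer vector, one entry per cluster (label order).
#' @slot medoidFrame integer vector, frame index of each cluster's medoid.
#' @slot sourceOccupancy matrix of frame counts, rows = sources, columns =
#'   clusters plus a final `noise` column.
#'
#' @seealso [clusterConformations()], [clusterMedoid()],
#'   [clusterOccupancyTable()]
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(
    labels = "integer",
    nClusters = "integer",
    sizes = "integer",
    medoidFrame = "integer",
    sourceOccupancy = "matrix"
  )
)

setValidity("ClusterAssignment", function(object) {
  k <- object@nClusters
  if (length(object@sizes) != k || length(object@medoidFrame) != k)
    return("sizes and medoidFrame must have one entry per cluster")
  lab <- object@labels
  if (any(lab < -1L) || (k > 0L && max(lab) != k - 1L && any(lab >= 0L)))
    return("labels must lie in {-1, 0, ..., nClusters-1}")
  if (k > 0L) {
    for (c in seq_len(k)) {
      if (lab[object@medoidFrame[c]] != c - 1L)
        return("each medoid frame must carry its own cluster's label")
    }
  }
  TRUE
})

#' Msa: multiple sequence alignment over the amino-acid alphabet
#'
#' Aligned, equal-length rows over the 20 standard amino acids plus the gap
#' character `-`. Sequences containing other letters (e.g. `X`) are accepted
#' but flagged `nonstandard`; covariation and conservation statistics treat
#' those letters as missing.
#'
#' @slot ids character vector of sequence identifiers.
#' @slot seqs character matrix, rows = sequences, columns = alignment columns,
#'   single upper-case characters.
#' @slot nonstandard logical per sequence: contains letters outside the
#'   20 standard amino acids + gap.
#'
#' @seealso [readFastaAlignment()], [simulateMsa()]
#' @exportClass Msa
setClass("Msa",
  representation(
    ids = "character",
    seqs = "matrix",
    nonstandard = "logical"
  )
)

setValidity("Msa", function(object) {
  if (nrow(object@seqs) != length(object@ids))
    return("one id per alignment row required")
  if (length(object@nonstandard) != length(object@ids))
    return("one nonstandard flag per row required")
  if (nrow(object@seqs) > 0 && any(nchar(object@seqs) != 1L))
    return("seqs must hold single characters")
  TRUE
})

#' FrustrationMap: per-contact local energetic frustration
#'
#' @slot contacts `data.frame` with columns `i`, `j` (residue indices,
#'   `i < j`), `resI`, `resJ` (residue types), `r` (contact distance,
#'   Angstrom), `eNative`, `decoyMean`, `decoySd`, `fIndex` (z-score; positive
#'   = native more favourable than decoys), `class` (`minimal`, `neutral`,
#'   `high`) and `degenerate` (logical; decoy spread was zero and `fIndex`
#'   was defined as 0).
#' @slot model list of the energy-model parameters used.
#'
#' @seealso [frustrationIndex()], [classifyFrustration()]
#' @exportClass FrustrationMap
setClass("FrustrationMap",
  representation(contacts = "data.frame", model = "list")
)

setValidity("FrustrationMap", function(object) {
  need <- c("i", "j", "resI", "resJ", "r", "eNative", "decoyMean", "decoySd",
            "fIndex", "class", "degenerate")
  if (!all(need %in% names(object@contacts)))
    return(paste("contacts must have columns:", paste(need, collapse = ", ")))
  cl <- object@contacts$class
  if (length(cl) && !all(cl %in% c("minimal", "neutral", "high")))
    return("class must be minimal/neutral/high")
  TRUE
})

#' AssayFit: fitted curve model for a wet-lab assay
#'
#' Result of [fitBoltzmannMelt()] (`method = "boltzmann_melt"`) or [fitSI()]
#' (`method = "si_linear"`).
#'
#' @slot method character(1) model label.
#' @slot parameters named numeric vector of fitted parameters.
#' @slot se named numeric vector of standard errors (NA where unavailable).
#' @slot fitted numeric fitted values at the observed abscissae.
#' @slot residuals numeric residuals.
#' @slot data `data.frame` of the points used in the fit.
#' @slot diagnostics list: convergence flag, residual sd, identifiability
#'   flag, points excluded, etc.
#'
#' @exportClass AssayFit
setClass("AssayFit",
  representation(
    method = "character",
    parameters = "numeric",
    se = "numeric",
    fitted = "numeric",
    residuals = "numeric",
    data = "data.frame",
    diagnostics = "list"
  )
)
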