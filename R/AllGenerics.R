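#' @include AllClasses.R
NULL

#' Number of frames in an ensemble
#' @param x a [ConformationEnsemble-class]
#' @return integer(1)
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms in an ensemble
#' @param x a [ConformationEnsemble-class]
#' @return integer(1)
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom metadata table
#' @param x a [ConformationEnsemble-class]
#' @return `data.frame`, one row per atom
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Coordinate array
#' @param x a [ConformationEnsemble-class]
#' @return numeric array `F x A x 3` (Angstrom)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Frame interval metadata (picoseconds)
#' @param x a [ConformationEnsemble-class]
#' @return numeric(1)
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Source label of an ensemble
#' @param x a [ConformationEnsemble-class]
#' @return character(1)
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' Cluster labels (per frame; -1 = noise)
#' @param x a [ClusterAssignment-class]
#' @return integer vector
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Number of clusters
#' @param x a [ClusterAssignment-class]
#' @return integer(1)
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' Cluster sizes
#' @param x a [ClusterAssignment-class]
#' @return integer vector (one per cluster, label order)
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' Medoid frame indices
#' @param x a [ClusterAssignment-class]
#' @return integer vector (one per cluster)
#' @export
setGeneric("medoidFrames", function(x) standardGeneric("medoidFrames"))

#' Alignment ids
#' @param x an [Msa-class]
#' @return character vector
#' @export
setGeneric("msaIds", function(x) standardGeneric("msaIds"))

#' Alignment as a character matrix
#' @param x an [Msa-class]
#' @return character matrix (rows = sequences)
#' @export
setGeneric("msaMatrix", function(x) standardGeneric("msaMatrix"))
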