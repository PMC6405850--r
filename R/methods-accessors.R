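#' @include AllGenerics.R
NULL

#' @rdname nFrames
#' @aliases nFrames,ConformationEnsemble-method
setMethod("nFrames", "ConformationEnsemble", function(x) dim(x@coords)[1])

#' @rdname nAtoms
#' @aliases nAtoms,ConformationEnsemble-method
setMethod("nAtoms", "ConformationEnsemble", function(x) dim(x@coords)[2])

#' @rdname atoms
#' @aliases atoms,ConformationEnsemble-method
setMethod("atoms", "ConformationEnsemble", function(x) x@atoms)

#' @rdname coords
#' @aliases coords,ConformationEnsemble-method
setMethod("coords", "ConformationEnsemble", function(x) x@coords)

#' @rdname frameInterval
#' @aliases frameInterval,ConformationEnsemble-method
setMethod("frameInterval", "ConformationEnsemble", function(x) x@frameInterval)

#' @rdname sourceId
#' @aliases sourceId,ConformationEnsemble-method
setMethod("sourceId", "ConformationEnsemble", function(x) x@sourceId)

setMethod("show", "ConformationEnsemble", function(object) {
  d <- dim(object@coords)
  res <- unique(paste(object@atoms$chain, object@atoms$resSeq))
  cat("ConformationEnsemble of", d[1], "frame(s),", d[2], "atom(s),",
      length(res), "residue(s)\n")
  cat("  source:", object@sourceId,
      " frame interval:", object@frameInterval, "ps\n")
  ch <- unique(object@atoms$chain)
  rr <- range(object@atoms$resSeq)
  cat("  chains:", paste(ch, collapse = ","),
      " residues:", rr[1], "-", rr[2], "\n")
})

#' @rdname clusterLabels
#' @aliases clusterLabels,ClusterAssignment-method
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname nClusters
#' @aliases nClusters,ClusterAssignment-method
setMethod("nClusters", "ClusterAssignment", function(x) x@nClusters)

#' @rdname clusterSizes
#' @aliases clusterSizes,ClusterAssignment-method
setMethod("clusterSizes", "ClusterAssignment", function(x) x@sizes)

#' @rdname medoidFrames
#' @aliases medoidFrames,ClusterAssignment-method
setMethod("medoidFrames", "ClusterAssignment", function(x) x@medoidFrame)

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@labels), "frames,",
      object@nClusters, "cluster(s),",
      sum(object@labels == -1L), "noise frame(s)\n")
  if (object@nClusters > 0) {
    cat("  sizes:", paste(object@sizes, collapse = ", "), "\n")
    cat("  medoid frames:", paste(object@medoidFrame, collapse = ", "), "\n")
  }
})

#' @rdname msaIds
#' @aliases msaIds,Msa-method
setMethod("msaIds", "Msa", function(x) x@ids)

#' @rdname msaMatrix
#' @aliases msaMatrix,Msa-method
setMethod("msaMatrix", "Msa", function(x) x@seqs)

setMethod("show", "Msa", function(object) {
  cat("Msa:", nrow(object@seqs), "sequences x", ncol(object@seqs),
      "columns\n")
  if (any(object@nonstandard))
    cat("  nonstandard letters in:",
        paste(object@ids[object@nonstandard], collapse = ", "), "\n")
})

setMethod("show", "PCAModel", function(object) {
  p <- length(object@mean)
  cat("PCAModel over", p, "coordinates\n")
  k <- min(3L, p)
  cat("  leading variance fractions:",
      paste(sprintf("%.1f%%", 100 * object@varianceFraction[seq_len(k)]),
            collapse = ", "), "\n")
})

setMethod("show", "FrustrationMap", function(object) {
  tab <- table(factor(object@contacts$class,
                      levels = c("minimal", "neutral", "high")))
  cat("FrustrationMap:", nrow(object@contacts), "contacts (",
      tab["minimal"], "minimal /", tab["neutral"], "neutral /",
      tab["high"], "high )\n")
})

setMethod("show", "AssayFit", function(object) {
  cat("AssayFit [", object@method, "]\n", sep = "")
  print(round(object@parameters, 4))
  if (isTRUE(object@diagnostics$unidentifiable))
    cat("  ** flagged unidentifiable **\n")
})
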