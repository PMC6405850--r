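# HDBSCAN (hierarchical density-based clustering with noise), implemented
# from its published description: mutual-reachability distances, a
# single-linkage hierarchy (stats::hclust), condensation of the dendrogram
# at the minimum cluster size, and excess-of-mass cluster selection on the
# condensed-tree stabilities.

#' HDBSCAN density clustering
#'
#' Euclidean HDBSCAN over the rows of `x`. Core distance of a point is the
#' distance to its `minSamples`-th nearest neighbour (the point itself
#' counts); mutual reachability is `max(core_i, core_j, d_ij)`; the
#' single-linkage tree over mutual reachability is condensed at
#' `minClusterSize` and clusters are selected by excess of mass on the
#' condensed-tree stabilities. Points never captured by a selected cluster
#' are labelled noise (-1). The root cluster is never selected unless
#' `allowSingleCluster = TRUE`, so structureless input (no genuine density
#' split) comes back all-noise under the default.
#'
#' The result is deterministic given the input rows (there is no RNG);
#' partitions are stable under row permutation up to label renaming.
#'
#' @param x numeric matrix (rows = observations).
#' @param minClusterSize smallest cluster retained (>= 2).
#' @param minSamples neighbour count for the core distance (default:
#'   `minClusterSize`, the cited implementation's default behaviour).
#' @param allowSingleCluster permit the hierarchy root to be selected
#'   (default FALSE).
#' @return list with `labels` (integer, 0-based by decreasing cluster size,
#'   -1 = noise), `nClusters`, and `stabilities` (per selected cluster).
#' @examples
#' x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
#' table(hdbscan(x, minClusterSize = 10)$labels)
#' @export
hdbscan <- function(x, minClusterSize, minSamples = minClusterSize,
                    allowSingleCluster = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (minClusterSize < 2) stop("minClusterSize must be >= 2", call. = FALSE)
  if (n < 2 || n < minClusterSize)
    return(list(labels = rep(-1L, n), nClusters = 0L,
                stabilities = numeric(0)))
  k <- min(minSamples, n)
  d <- as.matrix(stats::dist(x))
  core <- apply(d, 1, function(r) sort(r, partial = k)[k])
  mreach <- pmax(d, outer(core, core, pmax))
  diag(mreach) <- 0
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")
  condensedLabels(hc, n, minClusterSize, allowSingleCluster)
}

# Collect leaf (point) indices of an hclust subtree, iteratively.
subtreeLeaves <- function(merge, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nd < 0) out <- c(out, -nd)
    else stack <- c(stack, merge[nd, 1], merge[nd, 2])
  }
  out
}

condensedLabels <- function(hc, n, minClusterSize, allowSingleCluster) {
  merge <- hc$merge
  heights <- hc$height
  nodeSize <- integer(nrow(merge))
  sz <- function(nd) if (nd < 0) 1L else nodeSize[nd]
  for (r in seq_len(nrow(merge)))
    nodeSize[r] <- sz(merge[r, 1]) + sz(merge[r, 2])
  hpos <- heights[heights > 0]
  hfloor <- if (length(hpos)) min(hpos) * 1e-3 else 1
  lam <- 1 / pmax(heights, hfloor)

  # condensed clusters; cluster 1 is the root
  maxC <- nrow(merge) + 1L
  birth <- numeric(maxC)
  stab <- numeric(maxC)
  parentOf <- integer(maxC)
  childrenOf <- vector("list", maxC)
  members <- vector("list", maxC)   # points falling directly out of cluster
  nC <- 1L
  birth[1] <- 0
  # stack entries: (node, clusterId)
  stack <- list(list(node = nrow(merge), cid = 1L))
  while (length(stack)) {
    it <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- it$node
    cid <- it$cid
    if (nd < 0) { # singleton reached as the continuation of a cluster
      members[[cid]] <- c(members[[cid]], -nd)
      next
    }
    l <- lam[nd]
    c1 <- merge[nd, 1]
    c2 <- merge[nd, 2]
    s1 <- sz(c1)
    s2 <- sz(c2)
    if (s1 >= minClusterSize && s2 >= minClusterSize) {
      # true split: parent cluster dies, two children are born
      stab[cid] <- stab[cid] + (s1 + s2) * (l - birth[cid])
      for (ch in list(c1, c2)) {
        nC <- nC + 1L
        birth[nC] <- l
        parentOf[nC] <- cid
        childrenOf[[cid]] <- c(childrenOf[[cid]], nC)
        stack[[length(stack) + 1L]] <- list(node = ch, cid = nC)
      }
    } else {
      for (idx in 1:2) {
        ch <- merge[nd, idx]
        schild <- sz(ch)
        if (schild >= minClusterSize) {
          # cluster continues through the large child
          stack[[length(stack) + 1L]] <- list(node = ch, cid = cid)
        } else {
          # small side falls out of the cluster at this level
          pts <- subtreeLeaves(merge, ch)
          stab[cid] <- stab[cid] + schild * (l - birth[cid])
          members[[cid]] <- c(members[[cid]], pts)
        }
      }
    }
  }
  birth <- birth[seq_len(nC)]
  stab <- stab[seq_len(nC)]

  # excess-of-mass selection, children before parents (ids increase downward)
  selected <- logical(nC)
  subScore <- numeric(nC)
  rootScore <- if (allowSingleCluster) stab[1] else -Inf
  for (cid in rev(seq_len(nC))) {
    kids <- childrenOf[[cid]]
    own <- if (cid == 1L) rootScore else stab[cid]
    if (!length(kids)) {
      selected[cid] <- is.finite(own)
      subScore[cid] <- max(own, 0)
    } else {
      kidSum <- sum(subScore[kids])
      if (own >= kidSum && is.finite(own)) {
        selected[cid] <- TRUE
        # deselect the whole subtree
        below <- kids
        while (length(below)) {
          selected[below] <- FALSE
          below <- unlist(childrenOf[below])
        }
        subScore[cid] <- own
      } else {
        subScore[cid] <- kidSum
      }
    }
  }

  labels <- rep(-1L, n)
  sel <- which(selected)
  stabSel <- numeric(length(sel))
  for (s in seq_along(sel)) {
    cid <- sel[s]
    pts <- members[[cid]]
    below <- childrenOf[[cid]]
    while (length(below)) {
      pts <- c(pts, unlist(members[below]))
      below <- unlist(childrenOf[below])
    }
    labels[pts] <- s - 1L
    stabSel[s] <- stab[cid]
  }
  relabelBySize(labels, stabSel)
}

# Renumber labels 0..k-1 by decreasing cluster size (ties: previous order).
relabelBySize <- function(labels, stabilities = NULL) {
  pos <- labels >= 0L
  if (!any(pos))
    return(list(labels = labels, nClusters = 0L, stabilities = numeric(0)))
  tab <- table(labels[pos])
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  old <- as.integer(names(tab))[ord]
  map <- integer(max(old) + 1L)
  map[old + 1L] <- seq_along(old) - 1L
  labels[pos] <- map[labels[pos] + 1L]
  stabOut <- if (is.null(stabilities)) numeric(0) else stabilities[ord]
  list(labels = labels, nClusters = length(old), stabilities = stabOut)
}
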