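#' @include structure_io.R
NULL

#' CovariationMatrix: pairwise covariation scores over alignment columns
#'
#' @slot score symmetric numeric matrix (n_col x n_col), diagonal `NA`;
#'   masked column pairs are `NA`.
#' @slot method character(1): `"omes"`, `"elsc"` or `"sca"`, with the
#'   symmetrisation convention recorded in `notes`.
#' @slot validColumns logical per column; columns failing the gap filter are
#'   masked.
#' @slot notes character, method conventions (e.g. directional scores stored
#'   as the max of the two directions).
#' @exportClass CovariationMatrix
setClass("CovariationMatrix",
  representation(score = "matrix", method = "character",
                 validColumns = "logical", notes = "character")
)

setValidity("CovariationMatrix", function(object) {
  s <- object@score
  if (nrow(s) != ncol(s)) return("score must be square")
  if (length(object@validColumns) != nrow(s))
    return("validColumns must have one entry per column")
  offdiag <- s
  diag(offdiag) <- 0
  offdiag[is.na(offdiag)] <- 0
  if (max(abs(offdiag - t(offdiag))) > 1e-9)
    return("score must be symmetric")
  TRUE
})

setMethod("show", "CovariationMatrix", function(object) {
  cat("CovariationMatrix [", object@method, "] ",
      nrow(object@score), "x", ncol(object@score), " columns (",
      sum(!object@validColumns), " masked)\n", sep = "")
})

#' Covariation scores as a matrix
#' @param x a [CovariationMatrix-class]
#' @return numeric matrix
#' @export
setGeneric("covariationScores", function(x) standardGeneric("covariationScores"))

#' @rdname covariationScores
#' @aliases covariationScores,CovariationMatrix-method
setMethod("covariationScores", "CovariationMatrix", function(x) x@score)

# Residues treated as informative: the 20 standard letters. Gaps and
# nonstandard letters are missing data.
isObservedAA <- function(m) m %in% STANDARD_AA1

#' Percent identity of two aligned sequences
#'
#' `100 * identity columns / alignment length`, the alignment length
#' including gap columns. By default a column where both sequences are
#' gapped adds to the length but not to the identity count (set
#' `gapGapIdentity = TRUE` to count it as an identity column).
#'
#' @param a,b aligned sequences (strings or character vectors), equal
#'   length.
#' @param gapGapIdentity count gap-gap columns as identities
#'   (default FALSE).
#' @return percentage in `[0, 100]`.
#' @examples
#' percentIdentity("ACDEF", "ACDEG")  # 80
#' @export
percentIdentity <- function(a, b, gapGapIdentity = FALSE) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b))
    stop("sequences have different aligned lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  a <- toupper(a)
  b <- toupper(b)
  id <- a == b
  if (!gapGapIdentity) id <- id & !(a == "-" & b == "-")
  100 * sum(id) / length(a)
}

#' Per-column conservation profile of an alignment
#'
#' Score = `1 - H(col) / log(20)` with Shannon entropy `H` over the residue
#' frequencies of the column, gaps (and nonstandard letters) excluded. An
#' invariant column scores 1; a column uniform over the 20 residues scores
#' 0. Grades 1-9 are the 9-quantile bins of the scores (9 = most
#' conserved). All-gap columns are returned `NA` and masked.
#'
#' @param msa an [Msa-class].
#' @return `data.frame` with columns `column`, `score`, `grade`, `nObserved`.
#' @export
conservationProfile <- function(msa) {
  m <- msa@seqs
  nCol <- ncol(m)
  score <- rep(NA_real_, nCol)
  nObs <- integer(nCol)
  for (j in seq_len(nCol)) {
    col <- m[, j]
    col <- col[isObservedAA(col)]
    nObs[j] <- length(col)
    if (!length(col)) next
    f <- table(col) / length(col)
    h <- -sum(f * log(f))
    score[j] <- 1 - h / log(20)
  }
  grade <- rep(NA_integer_, nCol)
  ok <- !is.na(score)
  if (any(ok)) {
    r <- rank(score[ok], ties.method = "average")
    grade[ok] <- pmin(9L, pmax(1L, ceiling(9 * r / sum(ok))))
  }
  data.frame(column = seq_len(nCol), score = score, grade = grade,
             nObserved = nObs)
}

validColumnMask <- function(m, maxGapFraction) {
  vapply(seq_len(ncol(m)), function(j)
    mean(!isObservedAA(m[, j])) <= maxGapFraction, logical(1))
}

#' OMES chi-squared covariation matrix
#'
#' Observed-minus-expected-squared residue independence test. For each
#' column pair, over the sequences observed (non-gap, standard letters) at
#' both columns: `chi2 = sum_(a,b) (N_obs(a,b) - N_exp(a,b))^2 / N_exp`
#' with `N_exp = N f_i(a) f_j(b)` from the same sequence subset; cells with
#' zero expectation are skipped. Pairs with fewer than 2 usable sequences,
#' and columns exceeding the gap filter, are masked `NA`.
#'
#' @param msa an [Msa-class].
#' @param maxGapFraction columns with a larger unobserved fraction are
#'   masked (default 0.5).
#' @return a [CovariationMatrix-class].
#' @export
omes <- function(msa, maxGapFraction = 0.5) {
  m <- msa@seqs
  nCol <- ncol(m)
  valid <- validColumnMask(m, maxGapFraction)
  s <- matrix(NA_real_, nCol, nCol)
  obsMask <- isObservedAA(m)
  dim(obsMask) <- dim(m)
  for (i in seq_len(nCol - 1)) {
    if (!valid[i]) next
    for (j in (i + 1):nCol) {
      if (!valid[j]) next
      use <- obsMask[, i] & obsMask[, j]
      n <- sum(use)
      if (n < 2) next
      tab <- table(m[use, i], m[use, j])
      fi <- rowSums(tab) / n
      fj <- colSums(tab) / n
      expd <- n * outer(fi, fj)
      nz <- expd > 0
      s[i, j] <- s[j, i] <- sum((tab[nz] - expd[nz])^2 / expd[nz])
    }
  }
  new("CovariationMatrix", score = s, method = "omes",
      validColumns = valid, notes = "chi-squared over jointly observed sequences")
}

# Most frequent observed residue of a column (ties: alphabetical).
consensusResidue <- function(col) {
  col <- col[isObservedAA(col)]
  if (!length(col)) return(NA_character_)
  tab <- sort(table(col), decreasing = TRUE)
  names(tab)[1]
}

# Largest-remainder rounding of expected subset counts: integer m_b with
# sum(m) = s, m_b <= N_b, m_b ~ N_b * s / sum(N).
roundExpectedCounts <- function(N, s) {
  raw <- N * s / sum(N)
  m <- floor(raw)
  rem <- s - sum(m)
  if (rem > 0) {
    ord <- order(raw - m, decreasing = TRUE)
    for (k in ord) {
      if (rem == 0) break
      if (m[k] < N[k]) {
        m[k] <- m[k] + 1
        rem <- rem - 1
      }
    }
  }
  m
}

# Directional ELSC score for the perturbation at column i scored at column
# j: how improbably enriched the subset's column-j composition is, relative
# to a same-size random subset. Positive = covarying.
elscDirectional <- function(m, obsMask, i, j, minSubset) {
  useI <- obsMask[, i]
  cons <- consensusResidue(m[useI, i])
  if (is.na(cons)) return(NA_real_)
  inSub <- useI & m[, i] == cons
  use <- obsMask[, j]
  N <- table(m[use, j])
  n <- table(factor(m[inSub & use, j], levels = names(N)))
  s <- sum(n)
  if (s < minSubset) return(NA_real_)
  mExp <- roundExpectedCounts(as.numeric(N), s)
  sum(lchoose(as.numeric(N), mExp) - lchoose(as.numeric(N), as.numeric(n)))
}

#' ELSC covariation matrix
#'
#' Explicit likelihood of subset covariation: the alignment is restricted to
#' the sequences carrying the most frequent residue at column `i` and column
#' `j`'s composition in that subset is scored against the composition a
#' random same-size subset would give,
#' `score = sum_b [ ln C(N_b, m_b) - ln C(N_b, n_b) ]`, where `N_b` are the
#' full-alignment counts at `j`, `n_b` the subset counts and `m_b` the
#' largest-remainder-rounded expected subset counts. Larger = more
#' covarying. The score is directional; the matrix stores
#' `max(score_ij, score_ji)`.
#'
#' @param msa an [Msa-class].
#' @param minSubset minimum perturbation subset size (default 10); smaller
#'   subsets are masked.
#' @param maxGapFraction column gap filter (default 0.5).
#' @return a [CovariationMatrix-class].
#' @export
elsc <- function(msa, minSubset = 10, maxGapFraction = 0.5) {
  m <- msa@seqs
  nCol <- ncol(m)
  valid <- validColumnMask(m, maxGapFraction)
  obsMask <- isObservedAA(m)
  dim(obsMask) <- dim(m)
  s <- matrix(NA_real_, nCol, nCol)
  for (i in seq_len(nCol - 1)) {
    if (!valid[i]) next
    for (j in (i + 1):nCol) {
      if (!valid[j]) next
      sij <- elscDirectional(m, obsMask, i, j, minSubset)
      sji <- elscDirectional(m, obsMask, j, i, minSubset)
      if (is.na(sij) && is.na(sji)) next
      s[i, j] <- s[j, i] <- max(sij, sji, na.rm = TRUE)
    }
  }
  new("CovariationMatrix", score = s, method = "elsc",
      validColumns = valid,
      notes = "directional scores symmetrised as max(score_ij, score_ji)")
}

# Pseudocounted column frequencies over the 20 standard residues.
pseudoFreq <- function(col, bg, lambda = 1) {
  col <- col[isObservedAA(col)]
  counts <- table(factor(col, levels = names(bg)))
  (as.numeric(counts) + lambda * bg) / (length(col) + lambda)
}

sca_directional <- function(m, obsMask, i, j, bg, minSubset, lambda) {
  useI <- obsMask[, i]
  cons <- consensusResidue(m[useI, i])
  if (is.na(cons)) return(NA_real_)
  inSub <- useI & m[, i] == cons
  use <- obsMask[, j]
  sub <- m[inSub & use, j]
  if (length(sub) < minSubset) return(NA_real_)
  fSub <- pseudoFreq(sub, bg, lambda)
  fFull <- pseudoFreq(m[use, j], bg, lambda)
  sqrt(sum((log(fSub) - log(fFull))^2))
}

#' SCA perturbation covariation matrix
#'
#' Statistical coupling analysis, perturbation formulation: restricting the
#' alignment to the most frequent residue at column `i`, the coupling to
#' column `j` is the Euclidean norm of the log-frequency shift,
#' `score = sqrt( sum_a [ ln f_sub_j(a) - ln f_j(a) ]^2 )` (unitless,
#' coupling constant k = 1). Frequencies are regularised with a
#' background-frequency pseudocount (the shipped BLOSUM-style table), which
#' is where the background enters; in the raw ratio it cancels. A subset
#' whose column-`j` frequencies equal the full alignment's scores 0. The
#' score is directional; the matrix stores `max(score_ij, score_ji)`.
#'
#' @param msa an [Msa-class].
#' @param minSubset minimum perturbation subset size (default 10).
#' @param maxGapFraction column gap filter (default 0.5).
#' @param backgroundFreqs pseudocount prior (default
#'   [backgroundFrequencies()]).
#' @param pseudocount pseudocount weight (default 1).
#' @return a [CovariationMatrix-class].
#' @export
sca <- function(msa, minSubset = 10, maxGapFraction = 0.5,
                backgroundFreqs = NULL, pseudocount = 1) {
  if (is.null(backgroundFreqs)) backgroundFreqs <- backgroundFrequencies()
  bg <- backgroundFreqs / sum(backgroundFreqs)
  m <- msa@seqs
  nCol <- ncol(m)
  valid <- validColumnMask(m, maxGapFraction)
  obsMask <- isObservedAA(m)
  dim(obsMask) <- dim(m)
  s <- matrix(NA_real_, nCol, nCol)
  for (i in seq_len(nCol - 1)) {
    if (!valid[i]) next
    for (j in (i + 1):nCol) {
      if (!valid[j]) next
      sij <- sca_directional(m, obsMask, i, j, bg, minSubset, pseudocount)
      sji <- sca_directional(m, obsMask, j, i, bg, minSubset, pseudocount)
      if (is.na(sij) && is.na(sji)) next
      s[i, j] <- s[j, i] <- max(sij, sji, na.rm = TRUE)
    }
  }
  new("CovariationMatrix", score = s, method = "sca",
      validColumns = valid,
      notes = "perturbation formulation, k = 1, pseudocounted frequencies; max-symmetrised")
}

#' Permutation significance of covariation scores
#'
#' Empirical per-pair p-values against the column-shuffled null: each
#' alignment column is permuted independently across sequences (destroying
#' inter-column dependence while keeping column compositions),
#' the covariation matrix is recomputed, and
#' `p = (1 + #(null >= observed)) / (1 + nPermutations)`. Benjamini-
#' Hochberg adjusted p-values across pairs accompany the raw ones.
#'
#' @param msa an [Msa-class].
#' @param method `"omes"`, `"elsc"`, `"sca"`, or a function `msa ->
#'   CovariationMatrix`.
#' @param nPermutations at least 19 (p resolution 0.05).
#' @param seed RNG seed.
#' @param ... passed to the method.
#' @return list with `observed` ([CovariationMatrix-class]), `p` and `padj`
#'   (matrices), `nPermutations`.
#' @export
covariationSignificance <- function(msa, method = "omes",
                                    nPermutations = 199, seed = 1, ...) {
  if (nPermutations < 19)
    stop("nPermutations must be >= 19 for usable p resolution",
         call. = FALSE)
  fn <- if (is.function(method)) method
        else switch(method, omes = omes, elsc = elsc, sca = sca,
                    stop("unknown method: ", method, call. = FALSE))
  obs <- fn(msa, ...)
  s <- obs@score
  geq <- matrix(0L, nrow(s), ncol(s))
  m <- msa@seqs
  withSeed(seed, {
    for (b in seq_len(nPermutations)) {
      perm <- apply(m, 2, sample)
      nullMsa <- new("Msa", ids = msa@ids, seqs = perm,
                     nonstandard = msa@nonstandard)
      ns <- fn(nullMsa, ...)@score
      geq <- geq + (!is.na(ns) & !is.na(s) & ns >= s)
    }
  })
  p <- (1 + geq) / (1 + nPermutations)
  p[is.na(s)] <- NA
  ut <- upper.tri(p)
  padj <- matrix(NA_real_, nrow(p), ncol(p))
  padj[ut] <- stats::p.adjust(p[ut], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(observed = obs, p = p, padj = padj, nPermutations = nPermutations)
}
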