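#' @include AllClasses.R
NULL

# --- PDB parsing -----------------------------------------------------------
# Fixed-column PDB ATOM records. Only ATOM records are read (the loop
# analyses are protein-only); HETATM, waters and header metadata are ignored.

parsePdbAtoms <- function(lines, lineOffset = 0L) {
  sel <- grepl("^ATOM  ", lines)
  idx <- which(sel)
  if (!length(idx)) return(NULL)
  ln <- lines[idx]
  x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop(sprintf("unreadable coordinates at line %d: '%s'",
                 idx[bad[1]] + lineOffset, ln[bad[1]]), call. = FALSE)
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[!is.finite(occ)] <- 1
  data.frame(
    atomName = trimws(substr(ln, 13, 16)),
    altLoc = substr(ln, 17, 17),
    resName = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resSeq = suppressWarnings(as.integer(substr(ln, 23, 26))),
    iCode = substr(ln, 27, 27),
    x = x, y = y, z = z,
    occupancy = occ,
    element = trimws(substr(ln, 77, 78)),
    stringsAsFactors = FALSE
  )
}

# Altloc policy: keep the highest-occupancy alternate location of each atom;
# ties resolved in favour of altloc 'A' (then alphabetically).
resolveAltloc <- function(df) {
  key <- paste(df$chain, df$resSeq, df$iCode, df$atomName)
  if (!anyDuplicated(key)) return(df)
  ord <- order(key, -df$occupancy, df$altLoc)
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  df <- df[!duplicated(key), , drop = FALSE]
  # restore file order
  df[order(as.integer(rownames(df))), , drop = FALSE]
}

modelAtomTable <- function(df) {
  el <- df$element
  noel <- !nzchar(el)
  el[noel] <- substr(df$atomName[noel], 1, 1)
  data.frame(
    chain = df$chain,
    resSeq = df$resSeq,
    resName = df$resName,
    atomName = df$atomName,
    element = el,
    nonstandard = !(df$resName %in% STANDARD_AA3),
    stringsAsFactors = FALSE
  )
}

#' Read a (multi-model) PDB file into a ConformationEnsemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a single-frame ensemble. Atom identity and order are
#' taken from the first model; every later model must present the same atoms
#' in the same order, otherwise an error names the first offending model.
#' Alternate locations are collapsed to the highest-occupancy altloc (tie
#' resolved to `A`). Nonstandard residue names are parsed and flagged in the
#' atom table.
#'
#' @param path path to a PDB file.
#' @param frameInterval picoseconds between frames (metadata; default `NA`).
#' @param sourceId label of the originating system (default: file base name).
#' @return a [ConformationEnsemble-class].
#' @examples
#' pdb <- system.file("extdata", "toy_tripeptide.pdb", package = "loopscape")
#' ens <- readMultimodelPDB(pdb)
#' nFrames(ens)
#' @export
readMultimodelPDB <- function(path, frameInterval = NA_real_,
                              sourceId = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.null(sourceId))
    sourceId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    blocks <- list(list(lines = lines, offset = 0L, id = 1L))
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts))
      ends <- c(ends, length(lines) + 1L)
    blocks <- lapply(seq_along(starts), function(i) {
      id <- suppressWarnings(as.integer(substr(lines[starts[i]], 11, 14)))
      if (!length(id) || is.na(id)) id <- i
      list(lines = lines[(starts[i] + 1L):(ends[i] - 1L)],
           offset = starts[i], id = id)
    })
  }
  frames <- vector("list", length(blocks))
  atomsTab <- NULL
  refKey <- NULL
  for (i in seq_along(blocks)) {
    df <- parsePdbAtoms(blocks[[i]]$lines, blocks[[i]]$offset)
    if (is.null(df))
      stop(sprintf("MODEL %d contains no ATOM records", blocks[[i]]$id),
           call. = FALSE)
    rownames(df) <- seq_len(nrow(df))
    df <- resolveAltloc(df)
    key <- paste(df$chain, df$resSeq, df$atomName)
    if (i == 1L) {
      atomsTab <- modelAtomTable(df)
      refKey <- key
    } else if (length(key) != length(refKey) || any(key != refKey)) {
      stop(sprintf(
        "MODEL %d atom set does not match MODEL %d (%d vs %d atoms)",
        blocks[[i]]$id, blocks[[1]]$id, length(key), length(refKey)),
        call. = FALSE)
    }
    frames[[i]] <- cbind(df$x, df$y, df$z)
  }
  A <- nrow(atomsTab)
  co <- array(0, dim = c(length(frames), A, 3))
  for (i in seq_along(frames)) co[i, , ] <- frames[[i]]
  new("ConformationEnsemble", coords = co, atoms = atomsTab,
      frameInterval = frameInterval, sourceId = sourceId)
}

#' Write a ConformationEnsemble as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame, coordinates at PDB precision
#' (3 decimals). Reading the file back reproduces the coordinates to
#' 3 decimals.
#'
#' @param ens a [ConformationEnsemble-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMultimodelPDB <- function(ens, path) {
  at <- ens@atoms
  co <- ens@coords
  nF <- dim(co)[1]
  A <- nrow(at)
  nm <- at$atomName
  # PDB atom-name column convention: names of <4 chars start in column 14
  nmFmt <- ifelse(nchar(nm) >= 4, sprintf("%-4s", nm),
                  sprintf(" %-3s", nm))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nF)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(A), nmFmt, at$resName, at$chain, at$resSeq,
      co[f, , 1], co[f, , 2], co[f, , 3], 1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms of an ensemble by chain, residue range and atom names
#'
#' The selection is returned in canonical order: residues ascending, atoms
#' within a residue ordered as in `atomNames`. Frames are preserved exactly
#' and never reordered. Residue numbers are inclusive author numbers as in
#' the PDB file.
#'
#' @param ens a [ConformationEnsemble-class].
#' @param chain chain identifier, or `NULL` for all chains.
#' @param resRange inclusive integer pair `c(first, last)`, or `NULL` for all
#'   residues.
#' @param atomNames character vector of atom names (default backbone
#'   `c("N","CA","C","O")`), or `NULL` for all atoms.
#' @return a [ConformationEnsemble-class] with the selected atoms.
#' @examples
#' ens <- sampleEnsemble(ensembleSpec(nRes = 18, nFrames = 2, seed = 1))$ensemble
#' sel <- selectAtoms(ens, resRange = c(342, 359))
#' nAtoms(sel)  # 72 backbone atoms for an 18-residue loop
#' @export
selectAtoms <- function(ens, chain = NULL, resRange = NULL,
                        atomNames = c("N", "CA", "C", "O")) {
  at <- ens@atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resRange)) {
    if (length(resRange) != 2L)
      stop("resRange must be an inclusive pair c(first, last)", call. = FALSE)
    keep <- keep & at$resSeq >= resRange[1] & at$resSeq <= resRange[2]
  }
  if (!is.null(atomNames)) keep <- keep & at$atomName %in% atomNames
  idx <- which(keep)
  if (!length(idx))
    stop(sprintf("empty atom selection (chain %s, residues %s-%s, atoms %s)",
                 if (is.null(chain)) "*" else paste(chain, collapse = ","),
                 if (is.null(resRange)) "*" else resRange[1],
                 if (is.null(resRange)) "*" else resRange[2],
                 if (is.null(atomNames)) "*" else
                   paste(atomNames, collapse = ",")), call. = FALSE)
  sub <- at[idx, , drop = FALSE]
  ord <- order(sub$chain, sub$resSeq,
               if (is.null(atomNames)) seq_along(idx)
               else match(sub$atomName, atomNames))
  idx <- idx[ord]
  new("ConformationEnsemble",
      coords = ens@coords[, idx, , drop = FALSE],
      atoms = ens@atoms[idx, , drop = FALSE],
      frameInterval = ens@frameInterval,
      sourceId = ens@sourceId)
}

# --- FASTA -----------------------------------------------------------------

#' Read an aligned FASTA file into an Msa
#'
#' All rows must have equal length (an error names the first offending id).
#' Letters outside the 20 standard amino acids + gap `-` (e.g. `X`) are
#' accepted but the sequence is flagged nonstandard; such letters are treated
#' as missing by the conservation/covariation statistics.
#'
#' @param path aligned FASTA file.
#' @return an [Msa-class].
#' @export
readFastaAlignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1L) {
    off <- which(w != w[1])[1]
    stop(sprintf("alignment rows have unequal lengths: '%s' has %d columns, expected %d",
                 ids[off], w[off], w[1]), call. = FALSE)
  }
  rows <- toupper(as.character(ss))
  Msa(ids = ids, seqs = rows)
}

#' Construct an Msa from aligned sequence strings
#'
#' @param ids sequence identifiers.
#' @param seqs character vector of equal-length aligned strings, or a
#'   character matrix of single letters (rows = sequences).
#' @return an [Msa-class].
#' @export
Msa <- function(ids, seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (length(unique(nchar(seqs))) > 1L) {
      off <- which(nchar(seqs) != nchar(seqs[1]))[1]
      stop(sprintf("alignment rows have unequal lengths: '%s'", ids[off]),
           call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (is.null(dim(m))) m <- matrix(m, nrow = length(ids))
  bad <- !(m %in% c(STANDARD_AA1, "-") | grepl("^[A-Z]$", m))
  if (any(bad))
    stop("alignment contains characters outside [A-Z-]: ",
         paste(unique(m[bad]), collapse = " "), call. = FALSE)
  nonstd <- apply(m, 1, function(r) any(!(r %in% c(STANDARD_AA1, "-"))))
  new("Msa", ids = as.character(ids), seqs = m, nonstandard = nonstd)
}

#' Write an Msa as aligned FASTA
#'
#' @param msa an [Msa-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFastaAlignment <- function(msa, path) {
  rows <- apply(msa@seqs, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", msa@ids), rows)), path)
  invisible(path)
}

# --- residue labelling -----------------------------------------------------

#' P-position labelling table for the serpin reactive-centre loop
#'
#' Named mapping between serpin P-positions and author residue numbers.
#' Positions count outward from the scissile bond: P17..P1 on the N-terminal
#' side, P1' on the C-terminal side. The default reproduces the
#' alpha-1-antitrypsin numbering of the RCL, P17 = residue 342 through
#' P1' = residue 359 (P1 = 358). The table is a plain labelling aid: supply
#' your own `p1` residue number (or a full alias table) for other numbering
#' schemes, e.g. chimeric constructs that interleave two numbering systems.
#'
#' @param p1 author residue number of the P1 residue (default 358).
#' @param nPrime number of primed positions to include (default 1).
#' @return `data.frame` with columns `position` (e.g. "P17", "P1'") and
#'   `resSeq`.
#' @examples
#' rclPositionTable()  # P17 = 342 ... P1 = 358, P1' = 359
#' @export
rclPositionTable <- function(p1 = 358, nPrime = 1) {
  pos <- c(paste0("P", 17:1), paste0("P", seq_len(nPrime), "'"))
  data.frame(position = pos,
             resSeq = c(p1 - 16:0, p1 + seq_len(nPrime)),
             stringsAsFactors = FALSE)
}
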