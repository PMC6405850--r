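#' @include clustering.R saltbridge.R frustration.R coevolution.R assays.R
NULL

# Write a run manifest next to the artifacts: subcommand, parameters,
# package version, input checksums, seed.
writeManifest <- function(outDir, subcommand, config, inputs = character(0)) {
  manifest <- list(
    subcommand = subcommand,
    package = "loopscape",
    version = as.character(utils::packageVersion("loopscape")),
    parameters = config,
    inputChecksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    seed = config$seed
  )
  path <- file.path(outDir, paste0(subcommand, ".manifest.json"))
  tmp <- tempfile(tmpdir = outDir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, path)
  path
}

cfgGet <- function(config, name, default = NULL, required = FALSE) {
  if (!is.null(config[[name]])) return(config[[name]])
  if (required)
    stop("config field '", name, "' is required", call. = FALSE)
  default
}

requireInput <- function(path) {
  if (is.null(path) || !file.exists(path))
    stop("input file not found: ",
         if (is.null(path)) "(unset)" else path, call. = FALSE)
  path
}

#' Run a named analysis stage with a configuration list
#'
#' Single programmatic entry point wiring all stages, mirroring a
#' subcommand-style interface: every stage takes a configuration list (or
#' JSON file), writes its artifacts plus a run manifest (parameters, package
#' version, input checksums, seed) into `outDir`, and is deterministic given
#' (inputs, config, seed). Outputs are written atomically. A thin shell
#' wrapper is shipped at `system.file("scripts", "loopscape.R")`.
#'
#' Subcommands: `simulate-ensemble`, `simulate-assay`, `simulate-msa`,
#' `rmsf`, `cluster`, `saltbridges`, `frustration`, `coevolve`, `conserve`,
#' `melt-fit`, `si-fit`.
#'
#' @param subcommand stage name (see above).
#' @param config named list of stage parameters, or path to a JSON config
#'   file. Common fields: `pdb` (input path or vector of paths), `loop`
#'   (residue pair), `seed`, `cutoff`, `minFrac`, `pcs`, `decoys`, `msa`,
#'   `csv`, `methods`, `perms`.
#' @param outDir output directory (created if needed; default `"."`).
#' @return invisibly, a list with `artifacts` (paths) and `result` (the
#'   stage's main in-memory result).
#' @export
runLoopscape <- function(subcommand, config = list(), outDir = ".") {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(requireInput(config), simplifyVector = TRUE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- cfgGet(config, "seed", 1L)
  config$seed <- seed
  handlers <- list(
    "simulate-ensemble" = runSimulateEnsemble,
    "simulate-assay" = runSimulateAssay,
    "simulate-msa" = runSimulateMsa,
    "rmsf" = runRmsf,
    "cluster" = runCluster,
    "saltbridges" = runSaltbridges,
    "frustration" = runFrustration,
    "coevolve" = runCoevolve,
    "conserve" = runConserve,
    "melt-fit" = runMeltFit,
    "si-fit" = runSiFit
  )
  h <- handlers[[subcommand]]
  if (is.null(h))
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(names(handlers), collapse = ", "), call. = FALSE)
  out <- h(config, outDir)
  out$artifacts <- c(out$artifacts,
                     manifest = writeManifest(outDir, subcommand, config,
                                              out$inputs %||% character(0)))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

runSimulateEnsemble <- function(config, outDir) {
  spec <- ensembleSpec(
    nRes = cfgGet(config, "nRes", 18),
    stayProb = cfgGet(config, "stayProb", 0.95),
    nFrames = cfgGet(config, "nFrames", 1000),
    seed = config$seed,
    poseRotSd = cfgGet(config, "poseRotSd", 0),
    poseTransSd = cfgGet(config, "poseTransSd", 0))
  out <- sampleEnsemble(spec)
  pdbPath <- file.path(outDir, cfgGet(config, "out", "ensemble.pdb"))
  writeMultimodelPDB(out$ensemble, pdbPath)
  labPath <- file.path(outDir, "ensemble_labels.tsv")
  writeTsvWithHeader(data.frame(frame = seq_along(out$labels),
                                basin = out$labels),
                     labPath, config)
  list(artifacts = c(pdb = pdbPath, labels = labPath), result = out)
}

runSimulateAssay <- function(config, outDir) {
  kind <- cfgGet(config, "kind", "melt")
  if (kind == "melt") {
    d <- simulateMelt(tm = cfgGet(config, "tm", 72.2),
                      slope = cfgGet(config, "slope", 2),
                      baseFolded = cfgGet(config, "baseFolded", -10),
                      baseUnfolded = cfgGet(config, "baseUnfolded", -2),
                      noiseSd = cfgGet(config, "noiseSd", 0),
                      seed = config$seed)
  } else {
    d <- simulateInhibitionAssay(si = cfgGet(config, "si", 1.64),
                                 noiseSd = cfgGet(config, "noiseSd", 0),
                                 seed = config$seed)
  }
  path <- file.path(outDir, cfgGet(config, "out", paste0(kind, ".csv")))
  tmp <- tempfile(tmpdir = outDir)
  utils::write.csv(d, tmp, row.names = FALSE)
  file.rename(tmp, path)
  list(artifacts = c(csv = path), result = d)
}

runSimulateMsa <- function(config, outDir) {
  msa <- simulateMsa(nSeq = cfgGet(config, "nSeq", 200),
                     nCol = cfgGet(config, "nCol", 50),
                     seed = config$seed)
  path <- file.path(outDir, cfgGet(config, "out", "synthetic_msa.fasta"))
  writeFastaAlignment(msa, path)
  list(artifacts = c(fasta = path), result = msa)
}

readEnsembleInputs <- function(config) {
  paths <- cfgGet(config, "pdb", required = TRUE)
  lapply(paths, function(p) readMultimodelPDB(requireInput(p)))
}

runRmsf <- function(config, outDir) {
  ens <- readEnsembleInputs(config)[[1]]
  r <- rmsfPerResidue(ens,
                      fitSelection = cfgGet(config, "fitSelection", NULL),
                      block = cfgGet(config, "block", NULL))
  path <- file.path(outDir, cfgGet(config, "out", "rmsf.tsv"))
  writeTsvWithHeader(r, path, config)
  list(artifacts = c(rmsf = path), result = r,
       inputs = unlist(config$pdb))
}

runCluster <- function(config, outDir) {
  enss <- readEnsembleInputs(config)
  loop <- cfgGet(config, "loop", c(342, 359))
  lm <- loopMatrix(enss, loop = loop,
                   fitResidues = cfgGet(config, "fitResidues", NULL))
  model <- fitPCA(lm$matrix)
  pcs <- cfgGet(config, "pcs", "all")
  k <- if (identical(pcs, "all")) ncol(lm$matrix) else as.integer(pcs)
  proj <- projectPCA(model, lm$matrix, k = k)
  minSize <- minClusterSize(nrow(lm$matrix),
                            cfgGet(config, "minFrac", 0.01))
  asg <- clusterConformations(proj, minSize, sourceLabels = lm$source)
  tab <- clusterOccupancyTable(asg)
  path <- file.path(outDir, cfgGet(config, "out", "clusters.tsv"))
  writeTsvWithHeader(data.frame(frame = seq_along(asg@labels),
                                source = lm$source,
                                cluster = asg@labels), path, config)
  occPath <- file.path(outDir, "cluster_occupancy.tsv")
  writeTsvWithHeader(tab, occPath, config)
  arts <- c(clusters = path, occupancy = occPath)
  if (asg@nClusters > 0) {
    medPath <- file.path(outDir, cfgGet(config, "medoids", "medoids.pdb"))
    frames <- asg@medoidFrame
    whichEns <- findFrameSources(enss, frames)
    medCo <- NULL
    first <- selectAtoms(enss[[1]], resRange = loop)
    co <- array(0, dim = c(length(frames), nAtoms(first), 3))
    for (i in seq_along(frames)) {
      src <- whichEns$ens[i]
      sel <- selectAtoms(enss[[src]], resRange = loop)
      co[i, , ] <- sel@coords[whichEns$frame[i], , ]
    }
    med <- new("ConformationEnsemble", coords = co, atoms = first@atoms,
               frameInterval = NA_real_, sourceId = "medoids")
    writeMultimodelPDB(med, medPath)
    arts <- c(arts, medoids = medPath)
  }
  list(artifacts = arts,
       result = list(assignment = asg, pca = model, occupancy = tab),
       inputs = unlist(config$pdb))
}

# Map concatenated frame indices back to (ensemble, local frame).
findFrameSources <- function(enss, frames) {
  sizes <- vapply(enss, nFrames, integer(1))
  ends <- cumsum(sizes)
  ensIdx <- vapply(frames, function(f) which(f <= ends)[1], integer(1))
  local <- frames - c(0, ends)[ensIdx]
  list(ens = ensIdx, frame = local)
}

runSaltbridges <- function(config, outDir) {
  enss <- readEnsembleInputs(config)
  names(enss) <- vapply(enss, sourceId, character(1))
  rep <- occupancyReport(enss,
                         cutoff = cfgGet(config, "cutoff", 4.0),
                         reportThreshold = cfgGet(config, "threshold", 0.20),
                         all = isTRUE(config$all),
                         groupA = cfgGet(config, "loopResidues",
                                         required = TRUE),
                         groupB = cfgGet(config, "bodyResidues",
                                         required = TRUE))
  path <- file.path(outDir, cfgGet(config, "out", "saltbridges.tsv"))
  writeTsvWithHeader(rep, path, config)
  list(artifacts = c(saltbridges = path), result = rep,
       inputs = unlist(config$pdb))
}

runFrustration <- function(config, outDir) {
  ens <- readEnsembleInputs(config)[[1]]
  model <- energyModel(kElec = cfgGet(config, "k", 4.15),
                       contactCutoff = cfgGet(config, "cutoff", 8.0))
  fr <- frustrationIndex(ens, model,
                         nDecoys = cfgGet(config, "decoys", 2000),
                         seed = config$seed)
  path <- file.path(outDir, cfgGet(config, "out", "frustration.tsv"))
  writeTsvWithHeader(fr@contacts, path, config)
  list(artifacts = c(frustration = path), result = fr,
       inputs = unlist(config$pdb))
}

runCoevolve <- function(config, outDir) {
  msa <- readFastaAlignment(requireInput(cfgGet(config, "msa",
                                                required = TRUE)))
  methods <- cfgGet(config, "methods", c("omes", "elsc", "sca"))
  arts <- character(0)
  results <- list()
  for (m in methods) {
    sig <- covariationSignificance(msa, method = m,
                                   nPermutations = cfgGet(config, "perms",
                                                          199),
                                   seed = config$seed)
    results[[m]] <- sig
    long <- covariationLongTable(sig)
    path <- file.path(outDir, paste0("coevolution_", m, ".tsv"))
    writeTsvWithHeader(long, path, config)
    arts[m] <- path
  }
  list(artifacts = arts, result = results, inputs = config$msa)
}

covariationLongTable <- function(sig) {
  s <- sig$observed@score
  ut <- which(upper.tri(s) & !is.na(s), arr.ind = TRUE)
  data.frame(i = ut[, 1], j = ut[, 2],
             score = s[ut], p = sig$p[ut], padj = sig$padj[ut])
}

runConserve <- function(config, outDir) {
  msa <- readFastaAlignment(requireInput(cfgGet(config, "msa",
                                                required = TRUE)))
  prof <- conservationProfile(msa)
  path <- file.path(outDir, cfgGet(config, "out", "conservation.tsv"))
  writeTsvWithHeader(prof, path, config)
  list(artifacts = c(conservation = path), result = prof,
       inputs = config$msa)
}

runMeltFit <- function(config, outDir) {
  d <- utils::read.csv(requireInput(cfgGet(config, "csv", required = TRUE)))
  names(d)[1:2] <- c("temperature", "signal")
  fit <- fitBoltzmannMelt(d)
  path <- file.path(outDir, cfgGet(config, "out", "melt_fit.json"))
  writeFitJson(fit, path)
  list(artifacts = c(fit = path), result = fit, inputs = config$csv)
}

runSiFit <- function(config, outDir) {
  d <- utils::read.csv(requireInput(cfgGet(config, "csv", required = TRUE)))
  if (!all(c("ratio", "residualActivity") %in% names(d)))
    names(d)[1:2] <- c("ratio", "residualActivity")
  fit <- fitSI(d, activityFloor = cfgGet(config, "activityFloor", 0.1))
  path <- file.path(outDir, cfgGet(config, "out", "si_fit.json"))
  writeFitJson(fit, path)
  list(artifacts = c(fit = path), result = fit, inputs = config$csv)
}

writeFitJson <- function(fit, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(list(method = fit@method,
                            parameters = as.list(fit@parameters),
                            se = as.list(fit@se),
                            diagnostics = fit@diagnostics),
                       tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  path
}
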