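test_that("multi-model PDB files round-trip through write/read", {
  out <- sampleEnsemble(ensembleSpec(nRes = 5, nFrames = 3, seed = 42,
                                     startRes = 1))
  ens <- out$ensemble
  path <- withr::local_tempfile(fileext = ".pdb")
  writeMultimodelPDB(ens, path)
  back <- readMultimodelPDB(path)
  expect_equal(nFrames(back), 3)
  expect_equal(nAtoms(back), nAtoms(ens))
  # PDB precision is 3 decimals
  expect_lt(max(abs(coords(back) - coords(ens))), 5e-4 + 1e-9)
  expect_identical(atoms(back)$atomName, atoms(ens)$atomName)
  expect_identical(atoms(back)$resSeq, atoms(ens)$resSeq)
})

test_that("the parser agrees with bio3d on the same file", {
  skip_if_not_installed("bio3d")
  ens <- sampleEnsemble(ensembleSpec(nRes = 4, nFrames = 2,
                                     seed = 5))$ensemble
  path <- withr::local_tempfile(fileext = ".pdb")
  writeMultimodelPDB(ens, path)
  ref <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  mine <- readMultimodelPDB(path)
  expect_equal(ncol(ref$xyz), 3 * nAtoms(mine))
  expect_equal(matrix(ref$xyz[2, ], ncol = 3, byrow = TRUE),
               mine@coords[2, , ], ignore_attr = TRUE)
})

test_that("single-structure files give one frame; broken models are named", {
  ens <- sampleEnsemble(ensembleSpec(nRes = 3, nFrames = 1,
                                     seed = 1))$ensemble
  path <- withr::local_tempfile(fileext = ".pdb")
  writeMultimodelPDB(ens, path)
  lines <- readLines(path)
  # strip MODEL/ENDMDL records -> plain single-structure PDB
  writeLines(lines[!grepl("^(MODEL|ENDMDL)", lines)], path)
  expect_equal(nFrames(readMultimodelPDB(path)), 1)

  # drop one atom from MODEL 2 of a 3-model file
  ens3 <- sampleEnsemble(ensembleSpec(nRes = 3, nFrames = 3,
                                      seed = 2))$ensemble
  writeMultimodelPDB(ens3, path)
  lines <- readLines(path)
  m2 <- grep("^MODEL", lines)[2]
  writeLines(lines[-(m2 + 3)], path)
  expect_error(readMultimodelPDB(path), "MODEL 2")

  # corrupt a coordinate field -> error carries the line number
  writeMultimodelPDB(ens3, path)
  lines <- readLines(path)
  atomLine <- grep("^ATOM", lines)[2]
  substr(lines[atomLine], 31, 38) <- "   xx.xx"
  writeLines(lines, path)
  expect_error(readMultimodelPDB(path), as.character(atomLine))
})

test_that("altloc records collapse to highest occupancy with tie to A", {
  path <- withr::local_tempfile(fileext = ".pdb")
  rec <- function(serial, name, alt, x, occ, el)
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, "ALA", "A", 1L, x, 0, 0, occ, 0, el)
  writeLines(c(
    rec(1, " N", " ", 0, 1.00, "N"),
    rec(2, " CA", "A", 1, 0.40, "C"),
    rec(3, " CA", "B", 2, 0.60, "C"),
    rec(4, " C", " ", 3, 1.00, "C"),
    rec(5, " O", "A", 4, 0.50, "O"),
    rec(6, " O", "B", 5, 0.50, "O"),
    "END"), path)
  ens <- readMultimodelPDB(path)
  expect_equal(nAtoms(ens), 4)
  ca <- which(atoms(ens)$atomName == "CA")
  expect_equal(unname(ens@coords[1, ca, 1]), 2.0)  # occupancy 0.60 wins
  o <- which(atoms(ens)$atomName == "O")
  expect_equal(unname(ens@coords[1, o, 1]), 4.0)   # tie -> altloc A
})

test_that("selectAtoms returns canonical backbone order and errors on empty", {
  ens <- sampleEnsemble(ensembleSpec(nRes = 18, nFrames = 4,
                                     seed = 3))$ensemble
  sel <- selectAtoms(ens, resRange = c(342, 359),
                     atomNames = c("N", "CA", "C", "O"))
  expect_equal(nAtoms(sel), 72)
  expect_equal(nFrames(sel), 4)
  expect_equal(atoms(sel)$atomName[1:8],
               rep(c("N", "CA", "C", "O"), 2))
  expect_true(!is.unsorted(atoms(sel)$resSeq))

  caOnly <- selectAtoms(ens, resRange = c(342, 359), atomNames = "CA")
  expect_equal(nAtoms(caOnly), 18)

  expect_error(selectAtoms(ens, resRange = c(342, 341)), "342-341")
  # frames preserved exactly
  expect_equal(sel@coords[3, 1, ],
               ens@coords[3, which(atoms(ens)$resSeq == 342 &
                                     atoms(ens)$atomName == "N"), ])
})

test_that("aligned FASTA reading enforces shape and flags nonstandard", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEFGHIKL", ">b", "ACDEFGHIKV", ">c", "ACDEF-HIKL"),
             path)
  msa <- readFastaAlignment(path)
  expect_s4_class(msa, "Msa")
  expect_equal(dim(msaMatrix(msa)), c(3L, 10L))
  expect_false(any(msa@nonstandard))

  writeLines(c(">a", "ACXEF", ">b", "ACDEF"), path)
  msa2 <- readFastaAlignment(path)
  expect_true(msa2@nonstandard[1])
  expect_false(msa2@nonstandard[2])

  writeLines(c(">a", "ACDEF", ">tooShort", "ACD"), path)
  expect_error(readFastaAlignment(path), "tooShort")
})

test_that("the RCL position table maps P17..P1' onto author numbering", {
  tab <- rclPositionTable()
  expect_equal(nrow(tab), 18)
  expect_equal(tab$resSeq[tab$position == "P17"], 342)
  expect_equal(tab$resSeq[tab$position == "P1"], 358)
  expect_equal(tab$resSeq[tab$position == "P1'"], 359)
  # alias numbering for a construct numbered from 1
  tab2 <- rclPositionTable(p1 = 30)
  expect_equal(range(tab2$resSeq), c(14, 31))
})
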