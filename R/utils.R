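# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
STANDARD_AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(STANDARD_AA1) <- STANDARD_AA3

aa3to1 <- function(res3) {
  out <- STANDARD_AA1[res3]
  out[is.na(out)] <- "X"
  unname(out)
}

aa1to3 <- function(res1) {
  m <- match(res1, STANDARD_AA1)
  out <- STANDARD_AA3[m]
  out[is.na(out)] <- "UNK"
  out
}

# Torsion angle (degrees, IUPAC sign, range (-180, 180]) from four points.
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi  # IUPAC sign (agrees with bio3d/biotite)
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place a fourth atom from three anchors given bond length (A), bond angle
# (deg, at `c`) and torsion (deg, about b-c); the NeRF construction.
placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, m, n)
  as.vector(rot %*% d2) + c
}

# Random proper rotation matrix (uniform over SO(3) via quaternion).
randomRotation <- function(sdDeg = NULL) {
  if (is.null(sdDeg)) {
    q <- stats::rnorm(4)
  } else {
    # small rotation: angle ~ N(0, sdDeg) about a uniform axis
    ang <- stats::rnorm(1, 0, sdDeg) * pi / 180
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    q <- c(cos(ang / 2), sin(ang / 2) * ax)
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Write a data.frame as TSV with '#'-prefixed header comments carrying the
# package version and the parameters of the producing call.
writeTsvWithHeader <- function(df, path, params = list()) {
  ver <- as.character(utils::packageVersion("loopscape"))
  hdr <- c(sprintf("# loopscape %s", ver),
           sprintf("# %s: %s", names(params),
                   vapply(params, function(p) paste(format(p), collapse = ","),
                          character(1))))
  tmp <- tempfile(tmpdir = dirname(path))
  con <- file(tmp, "w")
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

# Pairwise Euclidean distance between frame rows of a matrix (wrapper kept so
# clustering code reads clearly).
frameDist <- function(m) stats::dist(m)
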