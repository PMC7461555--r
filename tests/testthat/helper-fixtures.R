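# Shared fixtures, built in code.

# hand-written two-residue (Gly-Ala) PDB, 9 atoms, wwPDB fixed columns
glyAlaPDBLines <- function() {
  c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2       3.984   2.839   0.000  1.00  0.00           C",
    "ATOM      7  C   ALA A   2       5.496   2.696   0.172  1.00  0.00           C",
    "ATOM      8  O   ALA A   2       6.030   1.585   0.213  1.00  0.00           O",
    "ATOM      9  CB  ALA A   2       3.671   3.607  -1.286  1.00  0.00           C",
    "TER", "END")
}

writeGlyAlaPDB <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(glyAlaPDBLines(), path)
  path
}

# point-mass dummy subunit: a single CA atom at the origin
pointSubunit <- function() {
  new("MonomerStructure",
      atoms = data.frame(serial = 1L, name = "CA", resid = "ALA",
                         chain = "A", resno = 1L, insert = "",
                         x = 0, y = 0, z = 0, occ = 1, b = 0, element = "C",
                         stringsAsFactors = FALSE),
      annotations = list(missingSegments = list()))
}

# reference + uniformly displaced copy with zero net translation/rotation:
# L points on a circle, alternating +/- displacement along z
circleDisplacementPair <- function(L = 120, magnitude) {
  th <- 2 * pi * seq_len(L) / L
  ref <- cbind(30 * cos(th), 30 * sin(th), 0)
  mob <- ref + cbind(0, 0, magnitude * (-1)^seq_len(L))
  list(ref = ref, mob = mob)
}

# brute-force minimal RMSD over rotations: coarse rotation-vector grid, then
# coordinate-descent refinement with shrinking steps (independent of the
# closed-form Kabsch path)
bruteForceRMSD <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rmsdOf <- function(v) {
    ang <- sqrt(sum(v^2))
    R <- if (ang < 1e-12) diag(3) else ringswap:::.rotationAbout(v / ang, ang)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- c(0, 0, 0); bestVal <- rmsdOf(best)
  for (x in seq(-pi, pi, by = 0.4)) for (y in seq(-pi, pi, by = 0.4))
    for (z in seq(-pi, pi, by = 0.4)) {
      val <- rmsdOf(c(x, y, z))
      if (val < bestVal) { bestVal <- val; best <- c(x, y, z) }
    }
  for (step in c(0.1, 0.02, 0.004, 0.0008)) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in 1:3) for (s in c(-step, step)) {
        cand <- best; cand[i] <- cand[i] + s
        val <- rmsdOf(cand)
        if (val < bestVal - 1e-12) {
          bestVal <- val; best <- cand; improved <- TRUE
        }
      }
    }
  }
  bestVal
}

# designed-segment interior mask: drops residues within 1 position of a truth
# label change (assignment schemes disagree at element boundaries)
interiorMask <- function(truth) {
  n <- length(truth)
  boundary <- c(TRUE, truth[-1] != truth[-n])
  near <- boundary | c(boundary[-1], TRUE)
  near <- near | c(TRUE, boundary[-n])
  !near
}
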