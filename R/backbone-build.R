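# Internal backbone construction: NeRF chain building from ideal internal
# coordinates, carbonyl/CB placement, amide-hydrogen construction, and
# CA-path interpolation used both by the synthetic generators and by the
# missing-segment rebuilder.
#
# Ideal geometry: N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A; angles
# N-CA-C 111.0, CA-C-N 117.2, C-N-CA 121.7 degrees; omega 180.

.BB <- list(nca = 1.458, cac = 1.525, cn = 1.329, co = 1.229, ccb = 1.53,
            nh = 1.01,
            angNCAC = 111.0, angCACN = 117.2, angCNCA = 121.7,
            angCACO = 120.5)

# Build N/CA/C positions for a chain of n residues from torsion vectors.
# phi[1] is unused (no preceding C); omega applies between residues.
.buildBackboneFromTorsions <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(180, n)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$nca, 0, 0)
  ang <- .BB$angNCAC * pi / 180
  C[1, ] <- CA[1, ] + .BB$cac * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], .BB$cn, .BB$angCACN,
                             psi[i])
    CA[i + 1, ] <- .placeAtom(CA[i, ], C[i, ], N[i + 1, ], .BB$nca,
                              .BB$angCNCA, omega[i])
    C[i + 1, ] <- .placeAtom(C[i, ], N[i + 1, ], CA[i + 1, ], .BB$cac,
                             .BB$angNCAC, phi[i + 1])
  }
  list(N = N, CA = CA, C = C)
}

# carbonyl oxygen: in the peptide plane, anti to the next amide nitrogen
.placeO <- function(N, CA, C, psi) {
  .placeAtom(N, CA, C, .BB$co, .BB$angCACO, psi - 180)
}

# ideal tetrahedral C-beta from backbone N, CA, C (chirality constant; the
# downstream metrics are backbone-only, so handedness is not load-bearing)
.placeCB <- function(N, CA, C) {
  nh <- .unit(N - CA); ch <- .unit(C - CA)
  bis <- .unit(nh + ch)
  perp <- .unit(.cross(nh, ch))
  CA + .BB$ccb * (-0.618 * bis + 0.786 * perp)
}

# amide hydrogen on the bisector-opposed direction from N (DSSP convention);
# cPrev is the carbonyl carbon of the preceding residue
.placeAmideH <- function(N, CA, cPrev) {
  N + .BB$nh * .unit(.unit(N - cPrev) + .unit(N - CA))
}

# full-residue coordinate list (N, CA, C, O, CB) from torsion-built backbone
.residueAtomsFromBackbone <- function(bb, psi, withCB = TRUE) {
  n <- nrow(bb$N)
  lapply(seq_len(n), function(i) {
    out <- list(N = bb$N[i, ], CA = bb$CA[i, ], C = bb$C[i, ],
                O = .placeO(bb$N[i, ], bb$CA[i, ], bb$C[i, ], psi[i]))
    if (withCB) out$CB <- .placeCB(bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    out
  })
}

# assemble a list of per-residue coordinate lists into the canonical atom table
.atomTableFromResidues <- function(residues, resno, chain = "A",
                                   resid = "ALA") {
  stopifnot(length(residues) == length(resno))
  resid <- rep_len(resid, length(residues))
  rows <- list()
  serial <- 0L
  for (i in seq_along(residues)) {
    for (nm in names(residues[[i]])) {
      serial <- serial + 1L
      p <- residues[[i]][[nm]]
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, resid = resid[i], chain = chain,
        resno = resno[i], insert = "", x = p[1], y = p[2], z = p[3],
        occ = 1, b = 0, element = substr(nm, 1, 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Interpolate k CA positions between two anchor CAs so consecutive steps stay
# in the physical 2.8-4.2 A band: straight line when the implied spacing is
# already in range, otherwise a circular arc (bulging along bulgeDir) whose
# sub-chords are ~3.8 A.
.interpolateCAPath <- function(anchorA, anchorB, k, bulgeDir = NULL) {
  D <- .vnorm(anchorB - anchorA)
  nseg <- k + 1L
  step0 <- D / nseg
  if (step0 > 4.15)
    stop(sprintf("gap too wide to bridge: anchors %.1f A apart for %d residues",
                 D, k))
  if (step0 >= 2.9) {
    t <- seq_len(k) / nseg
    return(t(vapply(t, function(f) anchorA + f * (anchorB - anchorA),
                    numeric(3))))
  }
  # arc: chord D, nseg sub-chords of ~3.8 A each
  target <- 3.8
  f <- function(theta) 2 * sin(theta / (2 * nseg)) / (2 * sin(theta / 2)) -
    target / D
  # f is increasing in theta; bracket below 2*pi
  theta <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-3), tol = 1e-12)$root
  r <- D / (2 * sin(theta / 2))
  e <- .unit(anchorB - anchorA)
  p <- if (is.null(bulgeDir)) .anyPerpendicular(e)
       else .unit(bulgeDir - sum(bulgeDir * e) * e)
  m <- (anchorA + anchorB) / 2
  c0 <- m - p * (r * cos(theta / 2))
  phiA <- pi / 2 + theta / 2
  pts <- t(vapply(seq_len(k), function(j) {
    phi <- phiA - theta * j / nseg
    c0 + r * (cos(phi) * e + sin(phi) * p)
  }, numeric(3)))
  pts
}

# backbone atoms for residues given only their CA positions plus the flanking
# CAs; used for interpolated loop/gap residues (approximate local geometry:
# N toward the previous CA, C toward the next CA, O on the carbonyl bisector)
.backboneFromCATrace <- function(cas, caPrev, caNext, withCB = TRUE) {
  n <- nrow(cas)
  all <- rbind(caPrev, cas, caNext)
  lapply(seq_len(n), function(i) {
    ca <- all[i + 1, ]; prev <- all[i, ]; nxt <- all[i + 2, ]
    dirPrev <- .unit(prev - ca); dirNext <- .unit(nxt - ca)
    # off-axis component keeps N-CA-C from being collinear; the frame must be
    # stable under coordinate jitter, so near-collinear steps fall back to a
    # canonical perpendicular and bent steps get a canonical sign
    perp0 <- .cross(dirPrev, dirNext)
    if (.vnorm(perp0) < 0.3) {
      perp <- .anyPerpendicular(dirNext)
    } else {
      perp <- .unit(perp0)
      if (sum(perp * c(0.301, 0.543, 0.784)) < 0) perp <- -perp
    }
    Npos <- ca + .BB$nca * .unit(dirPrev + 0.35 * perp)
    Cpos <- ca + .BB$cac * .unit(dirNext + 0.35 * perp)
    Opos <- Cpos + .BB$co * .unit(.unit(Cpos - ca) - 0.8 * perp)
    out <- list(N = Npos, CA = ca, C = Cpos, O = Opos)
    if (withCB) out$CB <- .placeCB(Npos, ca, Cpos)
    out
  })
}
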