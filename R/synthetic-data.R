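# Seeded synthetic-structure generators. Every generator is a pure function
# of its parameters and seed (repeated invocation is bitwise identical) and
# stores its ground truth in the annotations so tests never re-derive truth
# from the fixture itself. A single root seed fans out to per-generator
# streams via .generatorSeed (documented splitting rule: stream seed =
# (root * 10007 + sum of the stream name's character codes) mod (2^31 - 1)).

#' Derive a per-generator seed from a root seed
#'
#' Splitting rule: (root * 10007 + sum(utf8(streamName))) mod (2^31 - 1), so
#' adding a fixture never perturbs the stream of an existing one.
#'
#' @param rootSeed integer root seed.
#' @param streamName generator stream label.
#' @return integer seed below 2^31.
#' @export
generatorSeed <- function(rootSeed, streamName) {
  h <- sum(utf8ToInt(streamName))
  as.integer((as.numeric(rootSeed) * 10007 + h) %% (2^31 - 1))
}

# evaluate expr under a local RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- ideal secondary-structure segment templates ---------------------------

# NeRF-built segment, principal axis aligned to +x, centred on its CA centroid
.alignedSegment <- function(n, phi, psi, rollObjective = c("none", "carbonylY")) {
  rollObjective <- match.arg(rollObjective)
  bb <- .buildBackboneFromTorsions(rep(phi, n), rep(psi, n))
  res <- .residueAtomsFromBackbone(bb, rep(psi, n))
  ca <- bb$CA
  axis <- .unit(ca[n, ] - ca[1, ])
  # rotate axis onto +x
  target <- c(1, 0, 0)
  v <- .cross(axis, target)
  if (.vnorm(v) < 1e-9) {
    R1 <- if (sum(axis * target) > 0) diag(3) else .rotationAbout(c(0, 0, 1), pi)
  } else {
    ang <- acos(max(-1, min(1, sum(axis * target))))
    R1 <- .rotationAbout(v, ang)
  }
  apply3 <- function(R, residues) lapply(residues, function(r)
    lapply(r, function(p) as.numeric(R %*% p)))
  res <- apply3(R1, res)
  if (rollObjective == "carbonylY") {
    # roll about x so carbonyl C=O vectors lie along +/- y (the hydrogen-bond
    # direction between sheet neighbours)
    score <- function(theta) {
      R <- .rotationAbout(c(1, 0, 0), theta)
      sum(vapply(res, function(r) {
        co <- as.numeric(R %*% (r$O - r$C))
        abs(co[2])
      }, numeric(1)))
    }
    thetas <- seq(0, 2 * pi, length.out = 145)[-145]
    best <- thetas[which.max(vapply(thetas, score, numeric(1)))]
    res <- apply3(.rotationAbout(c(1, 0, 0), best), res)
  }
  cas <- t(vapply(res, `[[`, numeric(3), "CA"))
  centre <- colMeans(cas)
  lapply(res, function(r) lapply(r, function(p) p - centre))
}

# rigidly place a template: optional flip (pi rotation about the given axis),
# then translation
.placeSegment <- function(template, translation, flipAxis = NULL) {
  R <- if (is.null(flipAxis)) diag(3) else .rotationAbout(flipAxis, pi)
  lapply(template, function(r) lapply(r, function(p)
    as.numeric(R %*% p) + translation))
}

# CA positions walking a polyline of legs = list(list(dir, n)); step Angstrom,
# with a small alternating zig to avoid collinear backbones
.caPathAlongLegs <- function(start, legs, step = 3.4, zig = 0.6) {
  pts <- list(); p <- start; j <- 0
  for (leg in legs) {
    d <- .unit(leg$dir)
    perp <- .anyPerpendicular(d)
    for (i in seq_len(leg$n)) {
      j <- j + 1
      p <- p + d * step
      pts[[j]] <- p + perp * zig * (-1)^j
    }
  }
  do.call(rbind, pts)
}

# ---- sheet registration constants ------------------------------------------
# Frozen from a one-off scan maximizing Kabsch-Sander bonds between adjacent
# ideal antiparallel strands (see the methods vignette): strand spacing along
# y, per-neighbour x/z offsets, and the flip axis turning a +x strand into a
# -x strand.
.SHEET <- list(spacing = 4.2, xoff = 2.75, xslide = 0.0, zoff = 0.0,
               flipAxis = c(0, 0, 1), phi = -139, psi = 135)
.HELIX <- list(phi = -57, psi = -47)
# slightly over-wound alpha torsions: the i -> i+4 bond stays strong
# (-2.6 kcal/mol) while i -> i+3 bonds are clearly absent (+0.5), so a
# 5-residue motif reads as one isolated 4-turn (T), never a 3-10 stretch
.TURNMOTIF <- list(phi = -65, psi = -50)

# ---- layout-driven builder -------------------------------------------------

# A layout is a list of segments, each list(type, n, ...):
#   coil     : legs = polyline legs (termini) or NULL (interpolated loop)
#   helix    : y, z (centre x = xc)
#   strand   : sheetRow (0-based y index), dir (+1/-1)
#   turn     : interpolated loop labelled T
#   turnmotif: short rigid alpha-torsion stretch carrying a single isolated
#              i -> i+4 hydrogen bond (a designed beta-turn-like motif)
.buildFromLayout <- function(layout, seed, jitter = 0.01, chain = "A") {
  n <- sum(vapply(layout, `[[`, numeric(1), "n"))
  truth <- character(n)
  placed <- vector("list", length(layout))   # per-segment residue lists
  resStart <- cumsum(c(1, head(vapply(layout, `[[`, numeric(1), "n"), -1)))

  # 1) rigid segments (helix, strands)
  for (k in seq_along(layout)) {
    seg <- layout[[k]]
    if (seg$type %in% c("helix", "turnmotif")) {
      tors <- if (seg$type == "helix") .HELIX else .TURNMOTIF
      tpl <- .alignedSegment(seg$n, tors$phi, tors$psi)
      flip <- if (!is.null(seg$dir) && seg$dir < 0) c(0, 0, 1) else NULL
      placed[[k]] <- .placeSegment(tpl, c(seg$xc %||% 0, seg$y, seg$z),
                                   flipAxis = flip)
    } else if (seg$type == "strand") {
      tpl <- .alignedSegment(seg$n, .SHEET$phi, .SHEET$psi,
                             rollObjective = "carbonylY")
      odd <- seg$sheetRow %% 2 == 1
      flip <- if (seg$dir < 0) .SHEET$flipAxis else NULL
      tr <- c((if (odd) .SHEET$xoff else 0) +
                seg$sheetRow * .SHEET$xslide + (seg$xc %||% 0),
              seg$sheetRow * .SHEET$spacing,
              if (odd) .SHEET$zoff else 0)
      placed[[k]] <- .placeSegment(tpl, tr, flipAxis = flip)
    }
  }

  # 2) terminal coils (explicit polylines)
  for (k in seq_along(layout)) {
    seg <- layout[[k]]
    if (seg$type == "coil" && !is.null(seg$legs)) {
      if (k == 1) {
        anchor <- placed[[2]][[1]]$CA
        cas <- .caPathAlongLegs(anchor, seg$legs)
        cas <- cas[rev(seq_len(nrow(cas))), , drop = FALSE]  # N-term runs inward
        before <- if (nrow(cas) >= 2) cas[1, ] * 2 - cas[2, ]
                  else cas[1, ] * 2 - anchor
        placed[[k]] <- .backboneFromCATrace(cas, before, anchor)
      } else if (k == length(layout)) {
        prevSeg <- placed[[k - 1]]
        anchor <- prevSeg[[length(prevSeg)]]$CA
        cas <- .caPathAlongLegs(anchor, seg$legs)
        after <- if (nrow(cas) >= 2) cas[nrow(cas), ] * 2 - cas[nrow(cas) - 1, ]
                 else cas[1, ] * 2 - anchor
        placed[[k]] <- .backboneFromCATrace(cas, anchor, after)
      } else stop("internal: polyline coil must be terminal")
    }
  }

  # 3) interpolated loops and turns between placed neighbours
  for (k in seq_along(layout)) {
    seg <- layout[[k]]
    if (seg$type %in% c("turn") ||
        (seg$type == "coil" && is.null(seg$legs))) {
      prevSeg <- placed[[k - 1]]; nextSeg <- placed[[k + 1]]
      a <- prevSeg[[length(prevSeg)]]$CA
      b <- nextSeg[[1]]$CA
      bulge <- seg$bulge %||% NULL
      cas <- .interpolateCAPath(a, b, seg$n, bulgeDir = bulge)
      placed[[k]] <- .backboneFromCATrace(cas, a, b)
    }
  }

  # 4) truth labels and atom table
  code <- c(coil = "C", helix = "H", strand = "E", turn = "T",
            turnmotif = "T")
  for (k in seq_along(layout)) {
    seg <- layout[[k]]
    truth[resStart[k]:(resStart[k] + seg$n - 1)] <- code[[seg$type]]
  }
  residues <- do.call(c, placed)
  tab <- .atomTableFromResidues(residues, resno = seq_len(n), chain = chain)
  if (jitter > 0) {
    noise <- .withSeed(seed, matrix(stats::rnorm(nrow(tab) * 3, 0, jitter),
                                    ncol = 3))
    tab[, c("x", "y", "z")] <- as.matrix(tab[, c("x", "y", "z")]) + noise
  }
  list(atoms = tab, truth = truth)
}

# cystatin-like 120-residue layout: one alpha-helix block packed above a
# five-strand antiparallel sheet, a broad appending-structure-like loop, and
# extended termini; designed composition mirrors the monomer crystal
# structure (about 17% helix, 45% sheet, 27% coil)
.monomerLayout120 <- function() {
  sp <- .SHEET$spacing
  list(
    list(type = "coil", n = 4, legs = list(list(dir = c(0.3, 1, 0.25), n = 4))),
    list(type = "helix", n = 24, y = 2 * sp, z = 10.5, dir = -1),
    list(type = "coil", n = 4),
    list(type = "strand", n = 12, sheetRow = 0, dir = +1),
    list(type = "turn", n = 3, bulge = c(0.4, 0, 1)),
    list(type = "strand", n = 12, sheetRow = 1, dir = -1),
    list(type = "turn", n = 3, bulge = c(-0.4, 0, 1)),
    list(type = "strand", n = 12, sheetRow = 2, dir = +1),
    list(type = "coil", n = 2),
    list(type = "turnmotif", n = 5, xc = 26, y = 2.5 * sp, z = -3.5),
    list(type = "coil", n = 2),
    list(type = "strand", n = 12, sheetRow = 3, dir = -1),
    list(type = "turn", n = 3, bulge = c(-0.4, 0, 1)),
    list(type = "strand", n = 12, sheetRow = 4, dir = +1),
    list(type = "coil", n = 2),
    list(type = "turnmotif", n = 5, xc = 24, y = 4.8 * sp, z = -3.5),
    list(type = "coil", n = 3,
         legs = list(list(dir = c(-0.3, -1, -0.3), n = 3)))
  )
}

# reduced fold for short chains: helix + one two-strand hairpin + termini
.smallLayout <- function(n) {
  sp <- .SHEET$spacing
  s <- max(4L, 2L * (as.integer(0.19 * n) %/% 2L))
  h <- max(4L, as.integer(round(0.22 * n)))
  # helix-to-sheet loop length from the estimated anchor separation
  # (helix C-terminal CA to first strand CA; rise 1.5 / 3.3 A per residue)
  loopFor <- function(h, s) {
    d <- sqrt((1.65 * (s - 1) - 0.75 * (h - 1))^2 + (0.5 * sp)^2 + 8^2)
    max(2L, as.integer(ceiling(d / 3.2)) - 1L)
  }
  tailN <- function() n - (2L + h + loopFor(h, s) + 2L * s + 3L)
  while (tailN() < 1L) {
    if (h > 4L) h <- h - 1L
    else if (s > 4L) s <- s - 2L
    else stop("cannot lay out ", n, " residues")
  }
  list(
    list(type = "coil", n = 2, legs = list(list(dir = c(0.3, 1, 0.25), n = 2))),
    list(type = "helix", n = h, y = 0.5 * sp, z = 8, dir = -1),
    list(type = "coil", n = loopFor(h, s)),
    list(type = "strand", n = s, sheetRow = 0, dir = +1),
    list(type = "turn", n = 3, bulge = c(0.4, 0, 1)),
    list(type = "strand", n = s, sheetRow = 1, dir = -1),
    list(type = "coil", n = tailN(),
         legs = list(list(dir = c(-0.3, -1, -0.3), n = tailN())))
  )
}

#' Synthetic compact monomer with known secondary structure
#'
#' Builds a backbone-complete (N, CA, C, O, CB) single-chain structure from
#' ideal geometry: an alpha-helix block packed above an antiparallel
#' beta-sheet assembled from hairpins, connecting loops and extended termini.
#' The designed per-residue labels are stored as ground truth in
#' annotations()$ssTruth. The default 120-residue layout is elongated and
#' flat like a cystatin-type subunit (long axis along x) so that rings built
#' from it have realistic doughnut dimensions, and its designed composition
#' follows the monomer crystal structure (~17% helix, ~45% sheet).
#'
#' @param nResidues chain length (>= 20; default 120).
#' @param seed integer seed for the small coordinate jitter.
#' @param jitter s.d. of the Gaussian coordinate jitter, Angstrom (0.01).
#' @return a [MonomerStructure-class]; annotations carry ssTruth (designed
#'   labels), the engineered disulfide pair (47, 69) and the generator spec.
#' @export
makeToyMonomer <- function(nResidues = 120, seed = 1, jitter = 0.01) {
  if (nResidues < 20) stop("nResidues must be >= 20")
  layout <- if (nResidues == 120L) .monomerLayout120()
            else .smallLayout(nResidues)
  built <- .buildFromLayout(layout, seed = generatorSeed(seed, "toy_monomer"),
                            jitter = jitter)
  ann <- list(ssTruth = built$truth,
              disulfides = list(c(47L, 69L)),
              generator = list(kind = "toy_monomer", nResidues = nResidues,
                               seed = seed, jitter = jitter),
              missingSegments = list())
  new("MonomerStructure", atoms = built$atoms, annotations = ann)
}

#' Synthetic stand-in for the monomeric cystatin C crystal structure
#'
#' A clearly synthetic surrogate: the reference crystal structures are not
#' redistributable here, so this generator provides a structure of the same
#' size and designed secondary-structure composition as the stabilized
#' monomer (about 17% helix, 45% sheet, 11% turn, 27% coil over 120
#' residues). Identical to [makeToyMonomer()] at the default length.
#'
#' @param seed integer seed.
#' @return a [MonomerStructure-class].
#' @export
makeSyntheticCystatinMonomer <- function(seed = 1) {
  makeToyMonomer(nResidues = 120, seed = seed)
}

# dimer layout per chain: shorter sheet (four strands), same helix block;
# designed composition follows the dimer crystal structure (~18% helix,
# ~36% sheet)
.dimerChainLayout <- function() {
  sp <- .SHEET$spacing
  list(
    list(type = "coil", n = 4, legs = list(list(dir = c(0.3, 1, 0.25), n = 4))),
    list(type = "helix", n = 22, y = 1.5 * sp, z = 10.5, dir = -1),
    list(type = "coil", n = 4),
    list(type = "strand", n = 12, sheetRow = 0, dir = +1),
    list(type = "turn", n = 3, bulge = c(0.4, 0, 1)),
    list(type = "strand", n = 12, sheetRow = 1, dir = -1),
    list(type = "turn", n = 3, bulge = c(-0.4, 0, 1)),
    list(type = "strand", n = 12, sheetRow = 2, dir = +1),
    list(type = "coil", n = 2),
    list(type = "turnmotif", n = 5, xc = 26, y = 1.5 * sp, z = -3.5),
    list(type = "coil", n = 2),
    list(type = "strand", n = 12, sheetRow = 3, dir = -1),
    list(type = "coil", n = 2),
    list(type = "turnmotif", n = 5, xc = -24, y = 3.8 * sp, z = -3.5),
    list(type = "coil", n = 20,
         legs = list(list(dir = c(0.35, -1, -0.25), n = 5),
                     list(dir = c(-1, -0.15, -0.1), n = 15)))
  )
}

#' Synthetic stand-in for the dimeric cystatin C crystal structure
#'
#' Two identical synthetic chains (A, B) with a designed composition
#' following the domain-swapped dimer crystal structure (~18% helix, ~36%
#' sheet per chain). The chains are placed apart; no inter-chain contacts are
#' designed. Synthetic surrogate - see [makeSyntheticCystatinMonomer()].
#'
#' @param seed integer seed.
#' @return a [RingAssembly-class] with two chains.
#' @export
makeSyntheticCystatinDimer <- function(seed = 1) {
  layout <- .dimerChainLayout()
  a <- .buildFromLayout(layout, seed = generatorSeed(seed, "dimer_chainA"),
                        chain = "A")
  b <- .buildFromLayout(layout, seed = generatorSeed(seed, "dimer_chainB"),
                        chain = "B")
  b$atoms[, "z"] <- b$atoms[, "z"] + 45
  tab <- rbind(a$atoms, b$atoms)
  tab$serial <- seq_len(nrow(tab))
  ann <- list(ssTruth = c(a$truth, b$truth),
              generator = list(kind = "synthetic_dimer", seed = seed),
              missingSegments = list())
  new("RingAssembly", atoms = tab, annotations = ann, nSubunits = 2L,
      transforms = list(), symmetryAxis = c(0, 0, 1),
      placement = list(axisKnown = FALSE))
}

#' Uniform bead filling of a hollow cylinder (annulus)
#'
#' Rejection-samples nBeads points uniformly in the annular volume
#' innerRadius <= r <= outerRadius, |z| <= height/2. The fixture emulates the
#' flattened doughnut shape used to parameterize the oligomer's radius of
#' gyration; its coordinate Rg converges to [annulusRg()] of the same
#' dimensions.
#'
#' @param outerRadius,innerRadius,height cylinder dimensions, Angstrom.
#' @param nBeads number of beads (>= 1).
#' @param seed integer seed.
#' @return a [MonomerStructure-class] of CA beads; annotations$generator
#'   stores the true dimensions.
#' @export
makeHollowCylinder <- function(outerRadius, innerRadius, height, nBeads,
                               seed = 1) {
  if (nBeads < 1) stop("nBeads must be >= 1")
  if (innerRadius < 0 || height < 0 || outerRadius < innerRadius)
    stop("require outerRadius >= innerRadius >= 0 and height >= 0")
  pts <- .withSeed(generatorSeed(seed, "hollow_cylinder"), {
    out <- matrix(NA_real_, nBeads, 3)
    got <- 0L
    while (got < nBeads) {
      m <- max(1000L, 2L * (nBeads - got))
      x <- stats::runif(m, -outerRadius, outerRadius)
      y <- stats::runif(m, -outerRadius, outerRadius)
      r2 <- x^2 + y^2
      keep <- which(r2 <= outerRadius^2 & r2 >= innerRadius^2)
      if (length(keep)) {
        keep <- keep[seq_len(min(length(keep), nBeads - got))]
        z <- if (height > 0) stats::runif(length(keep), -height / 2, height / 2)
             else rep(0, length(keep))
        out[got + seq_along(keep), ] <- cbind(x[keep], y[keep], z)
        got <- got + length(keep)
      }
    }
    out
  })
  tab <- data.frame(serial = seq_len(nBeads), name = "CA", resid = "BEA",
                    chain = "A", resno = seq_len(nBeads), insert = "",
                    x = pts[, 1], y = pts[, 2], z = pts[, 3], occ = 1, b = 0,
                    element = "C", stringsAsFactors = FALSE)
  ann <- list(generator = list(kind = "hollow_cylinder",
                               outerRadius = outerRadius,
                               innerRadius = innerRadius, height = height,
                               nBeads = nBeads, seed = seed),
              missingSegments = list())
  new("MonomerStructure", atoms = tab, annotations = ann)
}

#' Scripted synthetic trajectory
#'
#' frame i = rigidMotion(i) applied to the base coordinates plus i.i.d.
#' Gaussian noise; optionally, scheduled hydrogen-bond pairs have the
#' acceptor oxygen placed at ideal bonded geometry (2.9 A along the
#' donor N-H direction) on scheduled frames and 10 A away otherwise.
#'
#' @param base a CoordSet.
#' @param nFrames number of frames (>= 1).
#' @param rigidMotion NULL (identity) or function(i) returning list(rotation =
#'   3x3, translation = numeric(3)) applied to frame i.
#' @param noiseSigma isotropic Gaussian coordinate noise s.d., Angstrom.
#' @param hbondSchedule NULL or list of entries list(donor = c(chain, resno),
#'   acceptor = c(chain, resno), onFrames = integer vector): donor is a
#'   backbone amide N, acceptor a backbone carbonyl O.
#' @param seed integer seed.
#' @return a [Trajectory-class]; the schedule is echoed in the topology
#'   annotations as ground truth.
#' @export
makeTrajectory <- function(base, nFrames, rigidMotion = NULL, noiseSigma = 0,
                           hbondSchedule = NULL, seed = 1) {
  if (nFrames < 1) stop("nFrames must be >= 1")
  a <- atoms(base)
  xyz0 <- coords(base)
  sched <- lapply(hbondSchedule, function(e) {
    if (length(e$onFrames) && max(e$onFrames) > nFrames)
      stop("hbond schedule refers to frames beyond nFrames")
    nIdx <- which(a$chain == e$donor[1] & a$resno == as.integer(e$donor[2]) &
                  a$name == "N")
    caIdx <- which(a$chain == e$donor[1] & a$resno == as.integer(e$donor[2]) &
                   a$name == "CA")
    cPrev <- which(a$chain == e$donor[1] &
                   a$resno == as.integer(e$donor[2]) - 1L & a$name == "C")
    oIdx <- which(a$chain == e$acceptor[1] &
                  a$resno == as.integer(e$acceptor[2]) & a$name == "O")
    if (!length(nIdx) || !length(caIdx) || !length(cPrev) || !length(oIdx))
      stop("schedule pair atoms not found in topology")
    list(nIdx = nIdx[1], caIdx = caIdx[1], cPrevIdx = cPrev[1],
         oIdx = oIdx[1], on = as.integer(e$onFrames))
  })
  framesList <- .withSeed(generatorSeed(seed, "trajectory"), {
    lapply(seq_len(nFrames), function(i) {
      f <- xyz0
      if (!is.null(rigidMotion)) {
        m <- rigidMotion(i)
        f <- .applyTransform(f, m$rotation, m$translation)
      }
      if (noiseSigma > 0)
        f <- f + matrix(stats::rnorm(length(f), 0, noiseSigma), ncol = 3)
      for (e in sched) {
        H <- .placeAmideH(f[e$nIdx, ], f[e$caIdx, ], f[e$cPrevIdx, ])
        dir <- .unit(H - f[e$nIdx, ])
        d <- if (i %in% e$on) 2.9 else 10
        f[e$oIdx, ] <- f[e$nIdx, ] + d * dir
      }
      f
    })
  })
  topo <- base
  ann <- annotations(base)
  ann$hbondScheduleTruth <- hbondSchedule
  topo@annotations <- ann
  new("Trajectory", topology = topo, frames = framesList, times = numeric(0))
}

#' Synthetic Guinier scattering curve of known Rg
#'
#' I(s) = i0 * exp(-s^2 rg^2 / 3) * (1 + eps), eps ~ N(0, noiseFraction);
#' the sigma column is noiseFraction * I(true).
#'
#' @param rg true radius of gyration, nm (> 0).
#' @param i0 forward intensity.
#' @param sGrid s grid, nm^-1.
#' @param noiseFraction multiplicative Gaussian noise level (0 = exact).
#' @param seed integer seed.
#' @return a [ScatteringCurve-class].
#' @export
makeGuinierCurve <- function(rg, i0 = 1, sGrid = seq(0.02, 0.5, by = 0.005),
                             noiseFraction = 0, seed = 1) {
  if (rg <= 0) stop("rg must be > 0")
  ideal <- i0 * exp(-sGrid^2 * rg^2 / 3)
  if (noiseFraction > 0) {
    eps <- .withSeed(generatorSeed(seed, "guinier_curve"),
                     stats::rnorm(length(sGrid), 0, noiseFraction))
    scatteringCurve(sGrid, ideal * (1 + eps), noiseFraction * ideal)
  } else {
    scatteringCurve(sGrid, ideal)
  }
}

#' Analytic sphere form-factor curve
#'
#' I(s) = [3 (sin(sR) - sR cos(sR)) / (sR)^3]^2 for a homogeneous sphere of
#' radius R; I(0) = 1 and the Guinier radius of gyration is sqrt(3/5) R.
#'
#' @param radius sphere radius, nm (> 0).
#' @param sGrid s grid, nm^-1.
#' @return a [ScatteringCurve-class].
#' @export
makeSphereCurve <- function(radius, sGrid = seq(0.005, 0.4, by = 0.0025)) {
  if (radius <= 0) stop("radius must be > 0")
  x <- sGrid * radius
  amp <- ifelse(abs(x) < 1e-6, 1 - x^2 / 10,
                3 * (sin(x) - x * cos(x)) / x^3)
  scatteringCurve(sGrid, amp^2)
}
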