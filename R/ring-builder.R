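# Candidate ring generation: a deterministic parametric Cn placer standing in
# for the symmetry-docking search that originally proposed geometries. The
# selection criterion downstream is purely geometric (TEM/AFM/SAXS dimension
# ranges), so a transparent grid over radius and subunit orientation plays the
# same role.

.chainAlphabet <- c(LETTERS, letters, as.character(0:9))

#' Build a Cn-symmetric ring assembly
#'
#' Places n rigid copies of a monomer around the z axis: the subunit is
#' centred on its centroid, rotated by spin (about the local radial axis),
#' tilt (about the local tangential axis) and twist (about the vertical axis
#' through the centroid), translated to ringRadius along x, and replicated by
#' rotations of 2*pi*k/n about z. Chains are labelled A, B, C, ... in angular
#' order.
#'
#' @param monomer a [MonomerStructure-class] subunit template.
#' @param n number of subunits (>= 1); ring sizes of interest are 10 and 12.
#' @param params a [PlacementParams-class].
#' @return a [RingAssembly-class] with exact Cn symmetry.
#' @export
buildRing <- function(monomer, n, params) {
  if (n < 1) stop("ring size n must be >= 1")
  if (n > length(.chainAlphabet)) stop("ring size exceeds chain alphabet")
  a <- atoms(monomer)
  if (!nrow(a)) stop("monomer has no atoms")
  xyz <- coords(monomer)
  centroid <- colMeans(xyz)
  local <- sweep(xyz, 2, centroid)
  R0 <- .rotationAbout(c(1, 0, 0), params@spin) %*%
        .rotationAbout(c(0, 1, 0), params@tilt) %*%
        .rotZ(params@twist)
  t0 <- c(params@ringRadius, 0, 0)
  base <- .applyTransform(local, R0, t0)
  pieces <- vector("list", n)
  transforms <- vector("list", n)
  for (k in seq_len(n)) {
    Rk <- .rotZ(2 * pi * (k - 1) / n)
    xyzK <- base %*% t(Rk)
    ak <- a
    ak$chain <- .chainAlphabet[k]
    ak[, c("x", "y", "z")] <- xyzK
    pieces[[k]] <- ak
    transforms[[k]] <- list(rotation = Rk %*% R0,
                            translation = as.numeric(Rk %*% t0))
  }
  allAtoms <- do.call(rbind, pieces)
  allAtoms$serial <- seq_len(nrow(allAtoms))
  ann <- annotations(monomer)
  ann$missingSegments <- .detectMissingSegments(allAtoms)
  new("RingAssembly", atoms = allAtoms, annotations = ann,
      nSubunits = as.integer(n), transforms = transforms,
      symmetryAxis = c(0, 0, 1),
      placement = list(axisKnown = TRUE, params = params))
}

#' Enumerate candidate ring assemblies over parameter grids
#'
#' Builds the Cartesian product of ring sizes, radii and orientation triples,
#' in deterministic sorted order (by n, then radius, then orientation index).
#' Candidates with inter-subunit backbone clashes are flagged, never dropped:
#' dimensional filtering is the geometry module's job.
#'
#' @param monomer subunit template.
#' @param nValues integer vector of ring sizes (e.g. c(10, 12)).
#' @param radiusGrid numeric vector of ring radii, Angstrom.
#' @param orientationGrid list of numeric triples c(tilt, spin, twist) in
#'   radians (a single triple may be given as a bare numeric(3)).
#' @param clashCutoff inter-chain CA-CA distance (Angstrom) under which a
#'   contact counts as a clash (default 2).
#' @return list of candidates; each is list(id, assembly, params, n, clashes,
#'   clashing). The index as a data.frame is attached as attribute "index".
#' @export
enumerateCandidates <- function(monomer, nValues, radiusGrid, orientationGrid,
                                clashCutoff = 2) {
  if (!length(nValues) || !length(radiusGrid) || !length(orientationGrid))
    stop("all grids must be non-empty")
  if (is.numeric(orientationGrid) && length(orientationGrid) == 3)
    orientationGrid <- list(orientationGrid)
  nValues <- sort(unique(as.integer(nValues)))
  radiusGrid <- sort(unique(as.numeric(radiusGrid)))
  out <- list()
  idx <- list()
  id <- 0L
  for (n in nValues) for (r in radiusGrid)
    for (oi in seq_along(orientationGrid)) {
      o <- orientationGrid[[oi]]
      id <- id + 1L
      params <- placementParams(ringRadius = r, tilt = o[1], spin = o[2],
                                twist = o[3])
      asm <- buildRing(monomer, n, params)
      nclash <- clashCount(asm, cutoff = clashCutoff)
      out[[id]] <- list(id = id, assembly = asm, params = params, n = n,
                        clashes = nclash, clashing = nclash > 0L)
      idx[[id]] <- data.frame(id = id, n = n, ringRadius = r, tilt = o[1],
                              spin = o[2], twist = o[3], clashes = nclash)
    }
  attr(out, "index") <- do.call(rbind, idx)
  out
}

#' Count inter-chain CA-CA clashes
#'
#' @param assembly a [RingAssembly-class].
#' @param cutoff distance threshold, Angstrom (> 0).
#' @return integer: number of inter-chain CA pairs closer than cutoff. If the
#'   assembly has no CA atoms (bead models), all atoms are used.
#' @export
clashCount <- function(assembly, cutoff = 2) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- atoms(assembly)
  ca <- a[a$name == "CA", , drop = FALSE]
  if (!nrow(ca)) ca <- a
  if (nrow(ca) < 2 || length(unique(ca$chain)) < 2) return(0L)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  diffChain <- outer(ca$chain, ca$chain, "!=")
  sum(d < cutoff & diffChain & upper.tri(d))
}
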