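#' @import methods
NULL

# canonical atom-table columns used by every structure container
.ATOM_COLS <- c("serial", "name", "resid", "chain", "resno", "insert",
                "x", "y", "z", "occ", "b", "element")

.checkAtomTable <- function(atoms) {
  msg <- character(0)
  missing <- setdiff(.ATOM_COLS, names(atoms))
  if (length(missing))
    return(paste("atom table lacks columns:", paste(missing, collapse = ", ")))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz)))
    msg <- c(msg, "non-finite coordinates")
  if (nrow(atoms) && any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    msg <- c(msg, "occupancy outside [0, 1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

#' Virtual base class for coordinate containers
#'
#' Holds an atom table (one row per atom, PDB-style fields, coordinates in
#' Angstrom) and a free-form annotation list (engineered disulfides, missing
#' segments, designed secondary-structure labels of synthetic fixtures).
#'
#' @slot atoms data.frame with columns serial, name, resid, chain, resno,
#'   insert, x, y, z, occ, b, element.
#' @slot annotations named list.
#' @export
setClass("CoordSet", representation("VIRTUAL",
  atoms = "data.frame", annotations = "list"))

setValidity("CoordSet", function(object) .checkAtomTable(object@atoms))

#' A single-subunit protein structure
#'
#' One polypeptide chain (typically the 120-residue cystatin C monomer) in
#' author residue numbering. Annotations record the engineered disulfide
#' bridge (47-69 for the stabilized monomer) and crystallographically missing
#' segments detected as residue-number discontinuities.
#'
#' @export
setClass("MonomerStructure", contains = "CoordSet")

setValidity("MonomerStructure", function(object) {
  a <- object@atoms
  if (!nrow(a)) return("structure has no atoms")
  for (ch in unique(a$chain)) {
    r <- a$resno[a$chain == ch]
    if (is.unsorted(unique(r)))
      return(sprintf("residue numbers not increasing in chain %s", ch))
  }
  TRUE
})

#' A Cn-symmetric ring assembly
#'
#' n rigid copies of a subunit sharing one symmetry axis. Transforms store
#' the rigid placement of each subunit (rotation, translation); the chain
#' partition is mutable by the cyclic domain swap, so chain labels may no
#' longer coincide with the original rigid subunits after swapping.
#'
#' @slot nSubunits integer, number of subunits (ring sizes of interest: 10, 12).
#' @slot transforms list of length nSubunits; each element list(rotation =
#'   3x3 matrix, translation = numeric(3)).
#' @slot symmetryAxis unit 3-vector (z by construction at build time).
#' @slot placement list echoing the PlacementParams used to build the ring
#'   (empty for externally loaded assemblies).
#' @export
setClass("RingAssembly", contains = "CoordSet", representation(
  nSubunits = "integer", transforms = "list", symmetryAxis = "numeric",
  placement = "list"))

setValidity("RingAssembly", function(object) {
  if (object@nSubunits < 1L) return("nSubunits must be >= 1")
  if (length(object@symmetryAxis) != 3)
    return("symmetryAxis must be a 3-vector")
  if (abs(.vnorm(object@symmetryAxis) - 1) > 1e-6)
    return("symmetryAxis must be a unit vector")
  if (anyDuplicated(unique(object@atoms$chain)) > 0)
    return("chain ids must be unique")
  TRUE
})

#' A coordinate trajectory over a fixed topology
#'
#' @slot topology a CoordSet giving atom identities (frame atom order matches
#'   the topology atom order).
#' @slot frames list of N x 3 coordinate matrices, Angstrom.
#' @slot times optional frame times, ns (length 0 or length(frames)).
#' @export
setClass("Trajectory", representation(
  topology = "CoordSet", frames = "list", times = "numeric"))

setValidity("Trajectory", function(object) {
  n <- nrow(object@topology@atoms)
  ok <- vapply(object@frames, function(f)
    is.matrix(f) && nrow(f) == n && ncol(f) == 3, logical(1))
  if (!all(ok)) return("every frame must be an N x 3 matrix matching topology")
  if (length(object@times) && length(object@times) != length(object@frames))
    return("times must be empty or one per frame")
  TRUE
})

#' Ring placement parameters
#'
#' Parameterizes the deterministic symmetric placer that generates candidate
#' ring geometries (the role a symmetry-docking search played upstream).
#'
#' @slot ringRadius axis-to-subunit-centroid distance, Angstrom (> 0).
#' @slot tilt rotation about the local tangential axis, radians.
#' @slot spin rotation about the local radial axis, radians.
#' @slot twist rotation about the axis parallel to the symmetry axis through
#'   the subunit centroid, radians.
#' @export
setClass("PlacementParams", representation(
  ringRadius = "numeric", tilt = "numeric", spin = "numeric",
  twist = "numeric"))

setValidity("PlacementParams", function(object) {
  if (object@ringRadius <= 0) return("ringRadius must be > 0") else TRUE
})

#' @rdname PlacementParams-class
#' @param ringRadius,tilt,spin,twist see slots.
#' @return a PlacementParams object.
#' @export
placementParams <- function(ringRadius, tilt = 0, spin = 0, twist = 0) {
  new("PlacementParams", ringRadius = as.numeric(ringRadius),
      tilt = as.numeric(tilt), spin = as.numeric(spin),
      twist = as.numeric(twist))
}

#' Cyclic domain-swap specification
#'
#' The intermolecular swap transfers an N-terminal segment (residues 1-58 for
#' cystatin C, with the 58-59 peptide bond broken) from each subunit to its
#' cyclic neighbour.
#'
#' @slot junction integer pair: last residue of the donated segment and the
#'   first retained residue (default c(58, 59)); must be sequence-adjacent.
#' @slot segmentStart first residue of the donated segment (default 1).
#' @slot direction "successor" (subunit k donates to k+1) or "predecessor".
#' @export
setClass("SwapSpec", representation(
  junction = "integer", segmentStart = "integer", direction = "character"))

setValidity("SwapSpec", function(object) {
  if (length(object@junction) != 2) return("junction must be a residue pair")
  if (object@junction[2] != object@junction[1] + 1L)
    return("junction residues must be adjacent in sequence")
  if (object@segmentStart > object@junction[1])
    return("segment must end at the junction's first residue")
  if (!object@direction %in% c("successor", "predecessor"))
    return("direction must be 'successor' or 'predecessor'")
  TRUE
})

#' @rdname SwapSpec-class
#' @param junction,segmentStart,direction see slots.
#' @return a SwapSpec object.
#' @export
swapSpec <- function(junction = c(58L, 59L), segmentStart = 1L,
                     direction = "successor") {
  new("SwapSpec", junction = as.integer(junction),
      segmentStart = as.integer(segmentStart), direction = direction)
}

#' Measured doughnut geometry of a ring assembly (nm)
#'
#' @slot outerDiameter outer diameter d1, nm.
#' @slot cavityDiameter central cavity diameter, nm.
#' @slot ringWidth annulus width d2 = (outer - cavity)/2, nm.
#' @slot height extent along the symmetry axis, nm.
#' @slot rg mass-weighted coordinate radius of gyration, nm.
#' @export
setClass("RingGeometry", representation(
  outerDiameter = "numeric", cavityDiameter = "numeric",
  ringWidth = "numeric", height = "numeric", rg = "numeric"))

setValidity("RingGeometry", function(object) {
  if (object@outerDiameter < object@cavityDiameter - 1e-9)
    return("outerDiameter must be >= cavityDiameter")
  if (object@cavityDiameter < -1e-9) return("cavityDiameter must be >= 0")
  if (object@height < 0) return("height must be >= 0")
  w <- (object@outerDiameter - object@cavityDiameter) / 2
  if (abs(object@ringWidth - w) > 1e-9)
    return("ringWidth must equal (outer - cavity)/2")
  TRUE
})

#' Experimental constraint intervals for ring dimensions (nm)
#'
#' Inclusive [min, max] intervals for outerDiameter, ringWidth, height and rg;
#' each optional (NA bounds are not enforced). See [table1Constraints()] for
#' the TEM/AFM/SAXS reference ranges.
#'
#' @slot bounds named list of numeric(2) intervals.
#' @export
setClass("ConstraintSet", representation(bounds = "list"))

setValidity("ConstraintSet", function(object) {
  allowed <- c("outerDiameter", "ringWidth", "cavityDiameter", "height", "rg")
  bad <- setdiff(names(object@bounds), allowed)
  if (length(bad))
    return(paste("unknown constraint parameters:", paste(bad, collapse = ", ")))
  for (nm in names(object@bounds)) {
    b <- object@bounds[[nm]]
    if (length(b) != 2) return(sprintf("%s: interval must have two bounds", nm))
    if (all(is.finite(b)) && b[1] > b[2])
      return(sprintf("%s: min exceeds max", nm))
  }
  TRUE
})

#' @rdname ConstraintSet-class
#' @param ... named numeric(2) intervals, e.g. outerDiameter = c(16, 24).
#' @return a ConstraintSet.
#' @export
constraintSet <- function(...) {
  new("ConstraintSet", bounds = lapply(list(...), as.numeric))
}

#' Verdict of filtering a geometry against a constraint set
#'
#' @slot pass TRUE iff no parameter violates its interval.
#' @slot failed data.frame(parameter, measured, lower, upper) listing every
#'   violation (zero rows iff pass).
#' @export
setClass("FilterVerdict", representation(pass = "logical", failed = "data.frame"))

setValidity("FilterVerdict", function(object) {
  if (object@pass != (nrow(object@failed) == 0L))
    return("pass must be TRUE exactly when no parameter failed")
  TRUE
})

#' A small-angle scattering curve
#'
#' @slot s momentum transfer grid, nm^-1 (s = 4 pi sin(theta) / lambda),
#'   strictly increasing.
#' @slot intensity I(s), arbitrary units, finite.
#' @slot sigma optional per-point uncertainty (length 0 or length(s)).
#' @export
setClass("ScatteringCurve", representation(
  s = "numeric", intensity = "numeric", sigma = "numeric"))

setValidity("ScatteringCurve", function(object) {
  if (length(object@s) != length(object@intensity))
    return("s and intensity must have equal length")
  if (length(object@s) > 1 && any(diff(object@s) <= 0))
    return("s grid must be strictly increasing")
  if (!all(is.finite(object@intensity))) return("intensities must be finite")
  if (length(object@sigma) && length(object@sigma) != length(object@s))
    return("sigma must be empty or one per point")
  TRUE
})

#' @rdname ScatteringCurve-class
#' @param s,intensity,sigma see slots.
#' @return a ScatteringCurve.
#' @export
scatteringCurve <- function(s, intensity, sigma = numeric(0)) {
  new("ScatteringCurve", s = as.numeric(s), intensity = as.numeric(intensity),
      sigma = as.numeric(sigma))
}

#' Result of a Guinier fit
#'
#' @slot rg fitted radius of gyration, nm.
#' @slot rgStderr standard error of rg propagated from the slope, nm.
#' @slot i0 fitted forward scattering I(0).
#' @slot window fitted s-range c(sMin, sMax), nm^-1.
#' @slot sRgMax dimensionless product sMax * rg of the converged window.
#' @slot rSquared coefficient of determination of the ln I vs s^2 regression.
#' @slot converged FALSE if the iterative window oscillated without settling.
#' @slot nPoints number of points in the final window.
#' @export
setClass("GuinierResult", representation(
  rg = "numeric", rgStderr = "numeric", i0 = "numeric", window = "numeric",
  sRgMax = "numeric", rSquared = "numeric", converged = "logical",
  nPoints = "integer"))

#' Rigid superposition result (Kabsch)
#'
#' @slot rotation 3x3 proper rotation (det +1).
#' @slot translation 3-vector, Angstrom.
#' @slot rmsd root-mean-square deviation after superposition, Angstrom.
#' @export
setClass("SuperpositionResult", representation(
  rotation = "matrix", translation = "numeric", rmsd = "numeric"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (max(abs(t(R) %*% R - diag(3))) > 1e-9) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det +1)")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' TM-score result
#'
#' @slot score structural similarity in (0, 1].
#' @slot d0 length-dependent distance scale, Angstrom.
#' @slot lengthTarget normalization length (reference residue count).
#' @export
setClass("TMScoreResult", representation(
  score = "numeric", d0 = "numeric", lengthTarget = "integer"))

setValidity("TMScoreResult", function(object) {
  if (object@score > 1 + 1e-12 || object@score <= 0)
    return("score must lie in (0, 1]")
  TRUE
})

#' Geometric hydrogen-bond criteria
#'
#' @slot maxDistance maximum donor-acceptor heavy-atom distance, Angstrom
#'   (default 3.5).
#' @slot minAngle minimum donor-hydrogen-acceptor angle, degrees (default 120).
#' @export
setClass("HBondCriteria", representation(
  maxDistance = "numeric", minAngle = "numeric"))

setValidity("HBondCriteria", function(object) {
  if (object@maxDistance <= 0) return("maxDistance must be > 0")
  if (object@minAngle <= 0 || object@minAngle > 180)
    return("minAngle must lie in (0, 180]")
  TRUE
})

#' @rdname HBondCriteria-class
#' @param maxDistance,minAngle see slots.
#' @return an HBondCriteria object.
#' @export
hbondCriteria <- function(maxDistance = 3.5, minAngle = 120) {
  new("HBondCriteria", maxDistance = as.numeric(maxDistance),
      minAngle = as.numeric(minAngle))
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "MonomerStructure", function(object) {
  a <- object@atoms
  cat(sprintf("MonomerStructure: %d atoms, %d residues, chain(s) %s\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              paste(unique(a$chain), collapse = ",")))
  ms <- object@annotations$missingSegments
  if (length(ms))
    cat("  missing segments:",
        paste(vapply(ms, function(g) paste(g, collapse = "-"), ""),
              collapse = ", "), "\n")
})

setMethod("show", "RingAssembly", function(object) {
  cat(sprintf("RingAssembly: %d subunits, %d chains, %d atoms\n",
              object@nSubunits, length(unique(object@atoms$chain)),
              nrow(object@atoms)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n",
              length(object@frames), nrow(object@topology@atoms)))
})

setMethod("show", "RingGeometry", function(object) {
  cat(sprintf(paste0("RingGeometry (nm): outer %.2f, cavity %.2f, ",
                     "width %.2f, height %.2f, Rg %.2f\n"),
              object@outerDiameter, object@cavityDiameter, object@ringWidth,
              object@height, object@rg))
})

setMethod("show", "GuinierResult", function(object) {
  cat(sprintf("GuinierResult: Rg %.3f +/- %.3f nm, I0 %.4g, window [%.4f, %.4f] nm^-1 (s.Rg max %.3f, n %d, R^2 %.4f%s)\n",
              object@rg, object@rgStderr, object@i0, object@window[1],
              object@window[2], object@sRgMax, object@nPoints,
              object@rSquared, if (object@converged) "" else ", NOT converged"))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A\n", object@rmsd))
})

setMethod("show", "TMScoreResult", function(object) {
  cat(sprintf("TMScoreResult: %.4f (d0 %.3f A, L %d)\n",
              object@score, object@d0, object@lengthTarget))
})

setMethod("show", "FilterVerdict", function(object) {
  if (object@pass) cat("FilterVerdict: PASS\n")
  else {
    cat("FilterVerdict: FAIL\n")
    print(object@failed)
  }
})

setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf("ScatteringCurve: %d points, s in [%.4g, %.4g] nm^-1\n",
              length(object@s), min(object@s), max(object@s)))
})
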