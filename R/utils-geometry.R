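# Small geometric helpers shared across modules. Internal length unit is
# Angstrom throughout; report-level ring dimensions are converted to nm at a
# single boundary (angstromToNm).

ANGSTROM_PER_NM <- 10

#' Convert Angstrom to nanometres
#'
#' The package stores all coordinates in Angstrom; user-facing ring dimensions
#' and radii of gyration are reported in nm. This is the single conversion
#' boundary.
#'
#' @param x numeric, length in Angstrom.
#' @return numeric, length in nm.
#' @export
angstromToNm <- function(x) x / ANGSTROM_PER_NM

#' Convert nanometres to Angstrom
#'
#' @param x numeric, length in nm.
#' @return numeric, length in Angstrom.
#' @export
nmToAngstrom <- function(x) x * ANGSTROM_PER_NM

# standard atomic masses (u) for mass-weighted radius of gyration
.atomicMasses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38
)

.massOfElement <- function(element) {
  m <- .atomicMasses[toupper(element)]
  m[is.na(m)] <- 12.011  # unknown elements treated as carbon
  unname(m)
}

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotation matrix for angle theta (radians) about arbitrary unit axis
.rotationAbout <- function(axis, theta) {
  u <- .unit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),        ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),        uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

.rotZ <- function(theta) .rotationAbout(c(0, 0, 1), theta)

# apply rigid transform (R, t) to an N x 3 coordinate matrix
.applyTransform <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, translation, "+")
}

# angle at vertex b (degrees) of the a-b-c triple
.angleDeg <- function(a, b, c) {
  v1 <- .unit(a - b); v2 <- .unit(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

# place atom D given A, B, C and internal coordinates: |C-D| = bond,
# angle(B, C, D) = angleDeg, torsion(A, B, C, D) = torsionDeg.  Standard
# natural-extension (NeRF) construction used by the backbone builders.
.placeAtom <- function(a, b, c, bond, angleDeg, torsionDeg) {
  ang <- angleDeg * pi / 180
  tor <- torsionDeg * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

# deterministic unit vector orthogonal to v
.anyPerpendicular <- function(v) {
  u <- .unit(v)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(.cross(u, ref))
}
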