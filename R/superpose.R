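# Kabsch least-squares rigid superposition (proper rotations only).

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD between
#' R * mobile + t and reference, via SVD of the covariance matrix with the
#' determinant correction that excludes reflections.
#'
#' @param mobile,reference N x 3 coordinate matrices (N >= 3, paired rows,
#'   not all collinear).
#' @return a [SuperpositionResult-class] (rotation, translation, rmsd in
#'   Angstrom). Superposed mobile coordinates are obtained with
#'   [transformCoords()].
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(reference))
  if (nrow(mobile) < 3) stop("need at least 3 points for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)  # 3x3 covariance
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  if (dsign == 0) dsign <- 1
  D <- diag(c(1, 1, dsign))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cr - as.numeric(R %*% cm)
  moved <- .applyTransform(mobile, R, t)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  new("SuperpositionResult", rotation = R, translation = t, rmsd = rmsd)
}

#' Apply a superposition to coordinates
#'
#' @param coords N x 3 matrix, Angstrom.
#' @param superposition a [SuperpositionResult-class].
#' @return transformed N x 3 matrix.
#' @export
transformCoords <- function(coords, superposition) {
  .applyTransform(as.matrix(coords), superposition@rotation,
                  superposition@translation)
}
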