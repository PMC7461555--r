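# Small-angle scattering: Debye curves for bead models and Guinier analysis
# with the iterative s*Rg window rule (s = 4 pi sin(theta) / lambda, nm^-1;
# I(s) = I(0) exp(-s^2 Rg^2 / 3) in the Guinier regime, slope -Rg^2/3 of
# ln I against s^2).

# sin(x)/x with a series branch near zero to avoid 0/0
.sinc <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small]^2 / 6
  out[!small] <- sin(x[!small]) / x[!small]
  out
}

#' Debye scattering intensity of a bead model
#'
#' I(s) = sum_i sum_j f_i f_j sinc(s * r_ij), with I(0) = (sum f_i)^2.
#' Bead coordinates are in Angstrom (the package's internal unit); pair
#' distances are converted to nm so that s is in nm^-1.
#'
#' @param beads N x 3 bead coordinate matrix, Angstrom.
#' @param sGrid momentum-transfer grid, nm^-1, s >= 0.
#' @param weights per-bead form-factor weights (default 1).
#' @return a [ScatteringCurve-class].
#' @export
debyeIntensity <- function(beads, sGrid, weights = NULL) {
  beads <- as.matrix(beads)
  if (!nrow(beads)) stop("bead model is empty")
  if (any(sGrid < 0)) stop("s must be non-negative")
  if (is.null(weights)) weights <- rep(1, nrow(beads))
  stopifnot(length(weights) == nrow(beads))
  n <- nrow(beads)
  selfTerm <- sum(weights^2)
  if (n == 1L)
    return(scatteringCurve(sGrid, rep(selfTerm, length(sGrid))))
  d <- angstromToNm(as.numeric(stats::dist(beads)))  # i < j pair distances
  # pair products f_i * f_j in dist() pair ordering
  pairI <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
  pairJ <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  wprod <- weights[pairI] * weights[pairJ]
  intensity <- vapply(sGrid, function(s)
    selfTerm + 2 * sum(wprod * .sinc(s * d)), numeric(1))
  scatteringCurve(sGrid, intensity)
}

#' Guinier fit with an iterative s*Rg window
#'
#' Weighted linear regression of ln I on s^2 over a low-angle window chosen
#' iteratively so that sMax * Rg <= sRgLimit (fixed point, at most 20
#' iterations): starting from the points nearest sMin, Rg is fitted, the
#' window ceiling is set to sRgLimit / Rg, and the fit repeated until the
#' window stabilizes. Weights are 1/sigma(lnI)^2 = (I/sigma)^2 when
#' uncertainties are present, otherwise the fit is unweighted.
#'
#' @param curve a [ScatteringCurve-class].
#' @param sRgLimit dimensionless window ceiling (default 1.3).
#' @param sMin lower bound of the window, nm^-1 (default: first grid point).
#' @return a [GuinierResult-class]; rg and rgStderr in nm. A window that
#'   oscillates without settling is reported with converged = FALSE.
#' @export
guinierFit <- function(curve, sRgLimit = 1.3, sMin = NULL) {
  s <- curve@s; I <- curve@intensity
  sigma <- if (length(curve@sigma)) curve@sigma else NULL
  if (is.null(sMin)) sMin <- s[1]
  admissible <- which(s >= sMin - 1e-12)
  if (length(admissible) < 3)
    stop("need at least 3 points at or above sMin")

  fitWindow <- function(idx) {
    if (any(I[idx] <= 0))
      stop("non-positive intensity inside the Guinier window")
    x <- s[idx]^2; y <- log(I[idx])
    w <- if (is.null(sigma)) NULL else (I[idx] / sigma[idx])^2
    fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
    sm <- suppressWarnings(summary(fit))  # exact synthetic curves fit perfectly
    slope <- stats::coef(fit)[["x"]]
    if (slope >= 0)
      stop("Guinier slope is non-negative; no decaying low-angle regime")
    list(rg = sqrt(-3 * slope),
         slopeSE = sm$coefficients["x", "Std. Error"],
         i0 = exp(stats::coef(fit)[["(Intercept)"]]),
         r2 = sm$r.squared)
  }

  # initial window: points whose intensity is still within the Guinier-model
  # decay at s*Rg = sRgLimit (I/I0 >= exp(-limit^2/3)), a noise-robust start
  i0guess <- max(I[admissible][seq_len(min(5L, length(admissible)))])
  idx <- admissible[I[admissible] >= exp(-sRgLimit^2 / 3) * i0guess]
  if (length(idx) < 3) idx <- admissible[seq_len(min(10L, length(admissible)))]
  seen <- list()
  converged <- FALSE
  for (iter in seq_len(20L)) {
    res <- fitWindow(idx)
    ceiling <- sRgLimit / res$rg
    newIdx <- admissible[s[admissible] <= ceiling + 1e-12]
    if (length(newIdx) < 3) newIdx <- admissible[1:3]
    if (identical(newIdx, idx)) { converged <- TRUE; break }
    key <- paste(range(newIdx), collapse = "-")
    if (key %in% names(seen)) break  # oscillation
    seen[[key]] <- TRUE
    idx <- newIdx
  }
  res <- fitWindow(idx)
  new("GuinierResult",
      rg = res$rg,
      rgStderr = 3 * res$slopeSE / (2 * res$rg),
      i0 = res$i0,
      window = c(min(s[idx]), max(s[idx])),
      sRgMax = max(s[idx]) * res$rg,
      rSquared = res$r2,
      converged = converged,
      nPoints = length(idx))
}

#' Read a 3-column scattering curve (DAT layout)
#'
#' Whitespace- or comma-separated columns s (nm^-1), I, and optional sigma;
#' lines starting with '#' are skipped.
#'
#' @param path input file.
#' @return a [ScatteringCurve-class].
#' @export
readScatteringCurve <- function(path) {
  if (!file.exists(path)) stop("cannot read curve file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  ncols <- lengths(parts)
  if (any(ncols < 2)) stop("curve file must have at least 2 columns")
  s <- as.numeric(vapply(parts, `[`, "", 1))
  I <- as.numeric(vapply(parts, `[`, "", 2))
  sig <- if (all(ncols >= 3)) as.numeric(vapply(parts, `[`, "", 3))
         else numeric(0)
  scatteringCurve(s, I, sig)
}

#' Write a scattering curve in the 3-column DAT layout
#'
#' @param curve a [ScatteringCurve-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeScatteringCurve <- function(curve, path) {
  sig <- if (length(curve@sigma)) curve@sigma else rep(0, length(curve@s))
  writeLines(c("# s[1/nm]  I(s)  sigma",
               sprintf("%.8g %.8g %.8g", curve@s, curve@intensity, sig)),
             path)
  invisible(path)
}
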