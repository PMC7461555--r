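# Kabsch-Sander backbone hydrogen bonds and a DSSP-style secondary-structure
# assignment collapsed to four states (H helix, E strand, T turn, C coil).
# The electrostatic bond energy is
#   E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)  kcal/mol,
# with a bond assigned when E < -0.5 kcal/mol. Amide hydrogens absent from
# the coordinates are constructed at ideal geometry (1.01 A along the
# bisector-opposed direction from N). Assignment depends only on the
# backbone, so residue identity (beyond proline's missing donor) is ignored.

.KS_Q <- 0.084 * 332
.KS_CUTOFF <- -0.5

# residue-level backbone table: one row per residue, coordinates of N, CA, C,
# O and the (constructed) amide H; hasH FALSE for prolines, chain starts and
# chain breaks
.residueBackbone <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  resIdx <- match(key, unique(key))
  nres <- max(resIdx)
  get <- function(name) {
    m <- matrix(NA_real_, nres, 3)
    sel <- atoms$name == name
    m[resIdx[sel], ] <- as.matrix(atoms[sel, c("x", "y", "z")])
    m
  }
  firstRow <- match(seq_len(nres), resIdx)
  res <- data.frame(chain = atoms$chain[firstRow], resno = atoms$resno[firstRow],
                    resid = atoms$resid[firstRow], stringsAsFactors = FALSE)
  bb <- list(N = get("N"), CA = get("CA"), C = get("C"), O = get("O"),
             H = get("H"))
  # explicit amide H may be called H or HN
  hn <- get("HN")
  useHN <- is.na(bb$H[, 1]) & !is.na(hn[, 1])
  bb$H[useHN, ] <- hn[useHN, ]
  # chain-internal predecessor (positional, same chain)
  prev <- c(NA, seq_len(nres - 1))
  prev[c(TRUE, res$chain[-1] != res$chain[-nres])] <- NA
  # chain break when the peptide C(prev)-N(i) distance is unphysical
  for (i in which(!is.na(prev))) {
    p <- prev[i]
    if (any(is.na(bb$C[p, ])) || any(is.na(bb$N[i, ]))) { prev[i] <- NA; next }
    if (.vnorm(bb$C[p, ] - bb$N[i, ]) > 2.5) prev[i] <- NA
  }
  # construct missing amide hydrogens
  for (i in seq_len(nres)) {
    if (!is.na(bb$H[i, 1])) next
    if (is.na(prev[i]) || toupper(res$resid[i]) == "PRO") next
    if (any(is.na(bb$N[i, ])) || any(is.na(bb$CA[i, ]))) next
    bb$H[i, ] <- .placeAmideH(bb$N[i, ], bb$CA[i, ], bb$C[prev[i], ])
  }
  hasH <- !is.na(bb$H[, 1]) & toupper(res$resid) != "PRO"
  complete <- !is.na(bb$N[, 1]) & !is.na(bb$CA[, 1]) & !is.na(bb$C[, 1]) &
    !is.na(bb$O[, 1])
  list(res = res, bb = bb, prev = prev, hasH = hasH, complete = complete,
       nres = nres)
}

# logical matrix hb[acceptor, donor]: CO(acceptor) ... H-N(donor)
.kabschSanderBonds <- function(rb) {
  n <- rb$nres
  hb <- matrix(FALSE, n, n)
  ca <- rb$bb$CA
  ok <- which(rb$complete & !is.na(ca[, 1]))
  if (length(ok) < 2) return(hb)
  dCA <- as.matrix(stats::dist(ca[ok, , drop = FALSE]))
  cand <- which(dCA < 9, arr.ind = TRUE)
  cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
  acc <- ok[cand[, 1]]; don <- ok[cand[, 2]]
  keep <- rb$hasH[don] & rb$complete[acc]
  # exclude donors hydrogen-bonding to their own or the directly preceding
  # peptide group (same chain, |i - j| < 2)
  sameChain <- rb$res$chain[acc] == rb$res$chain[don]
  keep <- keep & !(sameChain & abs(acc - don) < 2L)
  acc <- acc[keep]; don <- don[keep]
  if (!length(acc)) return(hb)
  dvec <- function(a, b) sqrt(rowSums((a - b)^2))
  O <- rb$bb$O[acc, , drop = FALSE]; C <- rb$bb$C[acc, , drop = FALSE]
  N <- rb$bb$N[don, , drop = FALSE]; H <- rb$bb$H[don, , drop = FALSE]
  rON <- dvec(O, N); rCH <- dvec(C, H); rOH <- dvec(O, H); rCN <- dvec(C, N)
  E <- .KS_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[pmin(rON, rCH, rOH, rCN) < 0.5] <- -9.9  # clashing contact, clamp
  bonded <- E < .KS_CUTOFF
  hb[cbind(acc[bonded], don[bonded])] <- TRUE
  hb
}

#' Assign per-residue secondary structure (4-state)
#'
#' Kabsch-Sander hydrogen bonds drive a DSSP-style pattern assignment:
#' n-turns (CO(i) bonded to NH(i+n), n = 3, 4, 5) yield helices (two
#' consecutive 4-turns mark an alpha-helical stretch; 3- and 5-turn analogues
#' give 3-10 and pi helices), bridge patterns between strands yield sheet
#' residues, isolated turns yield T, everything else coil. The 8-state
#' internal alphabet collapses as {H,G,I} -> H, {E,B} -> E, {T} -> T,
#' rest -> C. Residues with incomplete backbone are labelled C (counted in
#' the "incomplete" attribute).
#'
#' @param structure a CoordSet with backbone N, CA, C, O atoms (amide
#'   hydrogens constructed if absent).
#' @return character vector of labels in {H, E, T, C}, one per residue, named
#'   chain.resno; attributes: "incomplete" (count of residues lacking
#'   backbone atoms).
#' @export
assignSecondaryStructure <- function(structure) {
  a <- atoms(structure)
  rb <- .residueBackbone(a)
  n <- rb$nres
  hb <- .kabschSanderBonds(rb)
  chain <- rb$res$chain
  turn <- function(k) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - k)) {
      if (chain[i + k] == chain[i] && hb[i, i + k]) t[i] <- TRUE
    }
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  markHelix <- function(t, k) {
    sel <- rep(FALSE, n)
    if (n >= 2) for (i in 2:n) {
      if (t[i] && t[i - 1] && chain[i] == chain[i - 1])
        sel[i:min(n, i + k - 1)] <- TRUE
    }
    sel
  }
  isH <- markHelix(t4, 4)
  isG <- markHelix(t3, 3)
  isI <- markHelix(t5, 5)

  # bridges: enumerate candidate (i, j) pairs from the sparse bond list, then
  # test the Kabsch-Sander parallel/antiparallel patterns
  isE <- rep(FALSE, n)
  nb <- function(i, d) {
    j <- i + d
    ifelse(j >= 1 & j <= n & chain[pmin(pmax(j, 1), n)] == chain[i], j, NA)
  }
  bonds <- which(hb, arr.ind = TRUE)  # (acceptor, donor)
  if (nrow(bonds)) {
    accs <- bonds[, 1]; dons <- bonds[, 2]
    cand <- rbind(cbind(accs + 1L, dons), cbind(dons - 1L, accs),
                  cbind(dons, accs + 1L), cbind(accs, dons - 1L),
                  cbind(accs, dons), cbind(accs + 1L, dons - 1L),
                  cbind(dons - 1L, accs + 1L))
    cand <- unique(cand[cand[, 1] >= 1 & cand[, 1] <= n &
                        cand[, 2] >= 1 & cand[, 2] <= n, , drop = FALSE])
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (i == j) next
      if (chain[i] == chain[j] && abs(i - j) < 3) next
      im1 <- nb(i, -1L); ip1 <- nb(i, 1L)
      jm1 <- nb(j, -1L); jp1 <- nb(j, 1L)
      par <- (!is.na(im1) && !is.na(ip1) && hb[im1, j] && hb[j, ip1]) ||
             (!is.na(jm1) && !is.na(jp1) && hb[jm1, i] && hb[i, jp1])
      anti <- (hb[i, j] && hb[j, i]) ||
              (!is.na(im1) && !is.na(jp1) && !is.na(jm1) && !is.na(ip1) &&
               hb[im1, jp1] && hb[jm1, ip1])
      if (par || anti) { isE[i] <- TRUE; isE[j] <- TRUE }
    }
  }

  isT <- rep(FALSE, n)
  for (k in 3:5) {
    t <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(k)]]
    for (i in which(t)) {
      span <- (i + 1):(i + k - 1)
      span <- span[span <= n & chain[span] == chain[i]]
      isT[span] <- TRUE
    }
  }

  lab <- rep("C", n)
  lab[isT] <- "T"
  lab[isG | isI] <- "H"
  lab[isE] <- "E"
  lab[isH] <- "H"
  lab[!rb$complete] <- "C"
  names(lab) <- paste(chain, rb$res$resno, sep = ".")
  attr(lab, "incomplete") <- sum(!rb$complete)
  lab
}

#' Secondary-structure content fractions
#'
#' @param labels character vector of per-residue labels in {H, E, T, C}
#'   (output of [assignSecondaryStructure()]).
#' @return named numeric c(helix, sheet, turn, coil); fractions sum to 1.
#' @export
ssContent <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  n <- length(labels)
  c(helix = sum(labels == "H") / n,
    sheet = sum(labels == "E") / n,
    turn = sum(labels == "T") / n,
    coil = sum(labels == "C") / n)
}
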