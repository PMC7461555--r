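# Trajectory stability metrics: RMSD series over frames, TM-score, and
# hydrogen-bond occupancy under geometric criteria.

.selectionIndices <- function(topology, selection) {
  a <- atoms(topology)
  idx <- if (is.character(selection) && length(selection) == 1) {
    if (selection == "all") seq_len(nrow(a)) else which(a$name == selection)
  } else if (is.logical(selection)) {
    which(selection)
  } else {
    as.integer(selection)
  }
  if (!length(idx)) stop("empty atom selection")
  idx
}

#' Per-frame RMSD series against a reference
#'
#' Each frame is optimally superposed (Kabsch) onto the reference over the
#' selected atoms and the RMSD recorded, the standard drift measure of a
#' simulated oligomer model against its initial structure.
#'
#' @param traj a [Trajectory-class].
#' @param reference reference coordinates: a frame index into traj (default 1)
#'   or an N x 3 matrix over the full topology.
#' @param selection atom selection: an atom name (default "CA"), "all", or a
#'   logical/integer index vector over the topology atoms.
#' @return numeric vector of per-frame RMSDs, Angstrom.
#' @export
rmsdSeries <- function(traj, reference = 1, selection = "CA") {
  idx <- .selectionIndices(traj@topology, selection)
  ref <- if (is.matrix(reference)) reference else traj@frames[[reference]]
  refSel <- ref[idx, , drop = FALSE]
  vapply(traj@frames, function(f)
    kabschSuperpose(f[idx, , drop = FALSE], refSel)@rmsd, numeric(1))
}

.tmD0 <- function(L) {
  if (L <= 15) stop("TM-score d0 is defined for L > 15")
  1.24 * (L - 15)^(1 / 3) - 1.8
}

#' TM-score of a model against a reference
#'
#' Length-normalized structural similarity in (0, 1]: the maximum over rigid
#' superpositions of mean(1 / (1 + (d_i/d0)^2)) across all L residue pairs,
#' with d0 = 1.24 (L - 15)^(1/3) - 1.8 Angstrom and L the reference length.
#' The maximization uses the conventional iterative heuristic: seed fragments
#' of lengths L, L/2 and L/4 at multiple offsets are superposed, residues
#' within a distance cutoff (starting at 8 A, halving down to d0) are
#' re-superposed to a fixed point, and the best score over all searches kept.
#'
#' @param model,reference CA coordinate matrices, equal row counts (1:1
#'   residue pairing), L > 15.
#' @param optimize if FALSE, score at the single least-squares (Kabsch)
#'   superposition instead of maximizing over superpositions. The maximized
#'   score is never smaller: the TM-optimal superposition may sacrifice a few
#'   residues to bring the rest inside d0.
#' @return a [TMScoreResult-class].
#' @export
tmScore <- function(model, reference, optimize = TRUE) {
  model <- as.matrix(model); reference <- as.matrix(reference)
  L <- nrow(reference)
  if (nrow(model) != L) stop("model and reference must pair 1:1 by residue")
  d0 <- .tmD0(L)
  scoreOf <- function(sub) {
    sup <- kabschSuperpose(model[sub, , drop = FALSE],
                           reference[sub, , drop = FALSE])
    moved <- transformCoords(model, sup)
    d <- sqrt(rowSums((moved - reference)^2))
    list(score = mean(1 / (1 + (d / d0)^2)), d = d)
  }
  best <- scoreOf(seq_len(L))$score  # global Kabsch superposition
  if (!optimize)
    return(new("TMScoreResult", score = min(1, best), d0 = d0,
               lengthTarget = as.integer(L)))
  fragLens <- unique(pmax(16L, c(L, L %/% 2L, L %/% 4L)))
  for (len in fragLens) {
    startsAt <- unique(pmax(1L, seq(1L, L - len + 1L,
                                    by = max(1L, len %/% 2L))))
    for (st in startsAt) {
      sub <- st:(st + len - 1L)
      cutoff <- 8
      for (iter in 1:60) {
        prev <- sub
        res <- scoreOf(sub)
        best <- max(best, res$score)
        newSub <- which(res$d < cutoff)
        if (length(newSub) < 3L) newSub <- order(res$d)[1:4]
        if (identical(newSub, prev)) {
          if (cutoff <= d0 + 1e-9) break
          cutoff <- max(d0, cutoff / 2)
        }
        sub <- newSub
      }
    }
  }
  new("TMScoreResult", score = min(1, best), d0 = d0,
      lengthTarget = as.integer(L))
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For each donor/acceptor pair, the fraction of frames in which the
#' donor-acceptor heavy-atom distance and the donor-hydrogen-acceptor angle
#' satisfy the criteria. The donor hydrogen is taken from the topology when
#' present; for backbone amide donors (atom N) it is constructed per frame at
#' ideal geometry from N, CA and the preceding carbonyl carbon.
#'
#' @param traj a [Trajectory-class].
#' @param pairs data.frame with columns donorChain, donorResno, donorAtom,
#'   acceptorChain, acceptorResno, acceptorAtom (and optionally hydrogenAtom
#'   naming an explicit hydrogen in the topology).
#' @param criteria an [HBondCriteria-class] (default 3.5 A, 120 degrees).
#' @return the pairs data.frame with an occupancy column in [0, 1].
#' @export
hbondOccupancy <- function(traj, pairs, criteria = hbondCriteria()) {
  a <- atoms(traj@topology)
  findAtom <- function(chain, resno, name, what) {
    i <- which(a$chain == chain & a$resno == resno & a$name == name)
    if (!length(i))
      stop(sprintf("unknown %s atom %s/%d/%s", what, chain, resno, name))
    i[1]
  }
  nfr <- length(traj@frames)
  occ <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    dIdx <- findAtom(pairs$donorChain[p], pairs$donorResno[p],
                     pairs$donorAtom[p], "donor")
    aIdx <- findAtom(pairs$acceptorChain[p], pairs$acceptorResno[p],
                     pairs$acceptorAtom[p], "acceptor")
    hIdx <- NA_integer_
    caIdx <- cPrevIdx <- NA_integer_
    if (!is.null(pairs$hydrogenAtom) && !is.na(pairs$hydrogenAtom[p])) {
      hIdx <- findAtom(pairs$donorChain[p], pairs$donorResno[p],
                       pairs$hydrogenAtom[p], "hydrogen")
    } else {
      explicit <- which(a$chain == pairs$donorChain[p] &
                        a$resno == pairs$donorResno[p] & a$name %in% c("H", "HN"))
      if (length(explicit)) hIdx <- explicit[1]
      else if (pairs$donorAtom[p] == "N") {
        caIdx <- findAtom(pairs$donorChain[p], pairs$donorResno[p], "CA",
                          "donor CA")
        cp <- which(a$chain == pairs$donorChain[p] &
                    a$resno == pairs$donorResno[p] - 1L & a$name == "C")
        if (!length(cp))
          stop(sprintf(
            "cannot construct amide hydrogen for %s/%d: no preceding carbonyl",
            pairs$donorChain[p], pairs$donorResno[p]))
        cPrevIdx <- cp[1]
      } else {
        stop(sprintf(
          "no hydrogen available for donor %s/%d/%s (give hydrogenAtom)",
          pairs$donorChain[p], pairs$donorResno[p], pairs$donorAtom[p]))
      }
    }
    hits <- 0L
    for (f in traj@frames) {
      D <- f[dIdx, ]; A <- f[aIdx, ]
      if (.vnorm(D - A) > criteria@maxDistance) next
      H <- if (!is.na(hIdx)) f[hIdx, ]
           else .placeAmideH(D, f[caIdx, ], f[cPrevIdx, ])
      if (.angleDeg(D, H, A) >= criteria@minAngle) hits <- hits + 1L
    }
    occ[p] <- hits / nfr
  }
  pairs$occupancy <- occ
  pairs
}
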