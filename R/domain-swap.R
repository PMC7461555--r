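# Intermolecular cyclic domain swap. The swap is a pure relabeling of chain
# ownership (no coordinate changes): in the source study the broken 58-59
# junction was subsequently relaxed by restrained MD, which is out of scope
# here, so the junction C-N distance is reported as a quality metric instead
# of being minimized.

#' Apply the cyclic domain swap to a ring assembly
#'
#' Transfers the N-terminal segment (residues segmentStart..junction[1],
#' default 1..58) of each subunit to its cyclic neighbour by relabeling: after
#' the swap, output chain k consists of residues 1..58 originally of chain k
#' and residues 59..end originally of chain k+1 (direction "successor").
#' Atom coordinates are untouched; the operation is the n-cycle permutation on
#' segment ownership and its n-th power is the identity.
#'
#' @param assembly a [RingAssembly-class] with >= 2 chains, each containing
#'   both junction residues.
#' @param spec a [SwapSpec-class] (default: cystatin C junction 58/59).
#' @return a RingAssembly with rewired chain partition; atoms carry an
#'   origChain column recording pre-swap ownership.
#' @export
applyCyclicSwap <- function(assembly, spec = swapSpec()) {
  validObject(spec)
  a <- atoms(assembly)
  chains <- unique(a$chain)
  n <- length(chains)
  if (n < 2) stop("cyclic swap undefined for a single-chain assembly")
  for (ch in chains) {
    r <- a$resno[a$chain == ch]
    if (!(spec@junction[1] %in% r))
      stop(sprintf("junction residue %d missing in chain %s",
                   spec@junction[1], ch))
    if (!(spec@junction[2] %in% r))
      stop(sprintf("junction residue %d missing in chain %s",
                   spec@junction[2], ch))
  }
  if (is.null(a$origChain)) a$origChain <- a$chain
  pos <- match(a$chain, chains)  # 1-based angular index
  tail <- a$resno >= spec@junction[2]
  shift <- if (spec@direction == "successor") -1L else 1L
  newPos <- ifelse(tail, ((pos - 1L + shift) %% n) + 1L, pos)
  a$chain <- chains[newPos]
  # contiguous chains, residues ascending; coordinates untouched
  ord <- order(match(a$chain, chains), a$resno, seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  ann <- annotations(assembly)
  ann$swapped <- TRUE
  ann$swapSpec <- spec
  new("RingAssembly", atoms = a, annotations = ann,
      nSubunits = assembly@nSubunits, transforms = assembly@transforms,
      symmetryAxis = assembly@symmetryAxis, placement = assembly@placement)
}

#' Report junction C-N distances of a (swapped) assembly
#'
#' For each chain, the distance between the carbonyl C of the junction's
#' first residue and the amide N of its second (C(58)-N(59) for cystatin C).
#' On an unswapped structure this is the intact peptide bond (~1.33 A); after
#' the swap it measures how far the relabeled chain pairing is from a bonded
#' geometry (relaxation of this region is deliberately not performed).
#'
#' @param assembly a CoordSet (RingAssembly or MonomerStructure).
#' @param spec a [SwapSpec-class].
#' @return list(junctions = data.frame(chain, donorChain, acceptorChain,
#'   distance), summary = c(min, mean, max)).
#' @export
junctionReport <- function(assembly, spec = swapSpec()) {
  a <- atoms(assembly)
  if (is.null(a$origChain)) a$origChain <- a$chain
  chains <- unique(a$chain)
  rows <- lapply(chains, function(ch) {
    sub <- a[a$chain == ch, , drop = FALSE]
    cAtom <- sub[sub$resno == spec@junction[1] & sub$name == "C", , drop = FALSE]
    nAtom <- sub[sub$resno == spec@junction[2] & sub$name == "N", , drop = FALSE]
    if (!nrow(cAtom) || !nrow(nAtom))
      stop(sprintf("missing backbone atoms at junction in chain %s", ch))
    d <- .vnorm(c(cAtom$x[1], cAtom$y[1], cAtom$z[1]) -
                c(nAtom$x[1], nAtom$y[1], nAtom$z[1]))
    data.frame(chain = ch, donorChain = cAtom$origChain[1],
               acceptorChain = nAtom$origChain[1], distance = d,
               stringsAsFactors = FALSE)
  })
  junctions <- do.call(rbind, rows)
  list(junctions = junctions,
       summary = c(min = min(junctions$distance),
                   mean = mean(junctions$distance),
                   max = max(junctions$distance)))
}

#' Rebuild crystallographically missing segments
#'
#' Inserts the residues of an internal gap (e.g. the unresolved Pro78-Asn79
#' stretch of the stabilized cystatin C monomer entry) with N, CA, C, O (and
#' CB) atoms. CA positions follow the straight line between the flanking
#' anchors when that gives physical 2.8-4.2 A steps, otherwise a circular-arc
#' path with ~3.8 A steps bulging away from the structure centroid.
#'
#' @param structure a [MonomerStructure-class] or [RingAssembly-class].
#' @param gap residue range c(from, to) to rebuild, or NULL to rebuild every
#'   recorded missing segment.
#' @param chain chain of the gap (default: first chain). Ignored when gap is
#'   NULL.
#' @param resid residue name(s) for the inserted residues (default "ALA";
#'   "GLY" suppresses CB).
#' @return the structure with the gap(s) filled and contiguous numbering.
#' @export
rebuildMissingSegment <- function(structure, gap = NULL,
                                  chain = chainIds(structure)[1],
                                  resid = "ALA") {
  gaps <- if (is.null(gap)) missingSegments(structure)
          else list(c(from = gap[1], to = gap[2], chain = chain))
  if (!length(gaps)) return(structure)
  a <- atoms(structure)
  for (g in gaps) {
    ch <- as.character(g[["chain"]])
    from <- as.integer(g[["from"]]); to <- as.integer(g[["to"]])
    sub <- a[a$chain == ch, , drop = FALSE]
    prevRes <- from - 1L; nextRes <- to + 1L
    caPrev <- sub[sub$resno == prevRes & sub$name == "CA", , drop = FALSE]
    caNext <- sub[sub$resno == nextRes & sub$name == "CA", , drop = FALSE]
    if (!nrow(caPrev) || !nrow(caNext))
      stop(sprintf(paste0("gap %d-%d in chain %s is not flanked by resolved ",
                          "residues on both sides (terminal extension is ",
                          "unsupported)"), from, to, ch))
    pA <- c(caPrev$x[1], caPrev$y[1], caPrev$z[1])
    pB <- c(caNext$x[1], caNext$y[1], caNext$z[1])
    k <- to - from + 1L
    centroid <- colMeans(as.matrix(a[, c("x", "y", "z")]))
    bulge <- (pA + pB) / 2 - centroid
    if (.vnorm(bulge) < 1e-6) bulge <- NULL
    cas <- .interpolateCAPath(pA, pB, k, bulgeDir = bulge)
    residues <- .backboneFromCATrace(cas, pA, pB,
                                     withCB = !all(resid == "GLY"))
    resNames <- rep_len(resid, k)
    for (i in seq_len(k)) if (resNames[i] == "GLY")
      residues[[i]]$CB <- NULL
    newRows <- .atomTableFromResidues(residues, resno = from:to, chain = ch,
                                      resid = resNames)
    if (!is.null(a$origChain)) newRows$origChain <- ch
    insertAfter <- max(which(a$chain == ch & a$resno == prevRes))
    a <- rbind(a[seq_len(insertAfter), , drop = FALSE], newRows,
               a[-seq_len(insertAfter), , drop = FALSE])
  }
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  ann <- annotations(structure)
  ann$missingSegments <- .detectMissingSegments(a)
  if (is(structure, "RingAssembly"))
    new("RingAssembly", atoms = a, annotations = ann,
        nSubunits = structure@nSubunits, transforms = structure@transforms,
        symmetryAxis = structure@symmetryAxis,
        placement = structure@placement)
  else
    new("MonomerStructure", atoms = a, annotations = ann)
}
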