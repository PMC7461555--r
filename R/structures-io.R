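# PDB input/output. Parsing and fixed-width writing are delegated to bio3d;
# this module layers the package's containers, author-numbering conventions,
# altloc policy (keep blank or 'A') and gap detection on top.

.elementFromName <- function(name) {
  # strip digits and primes, then take the leading alphabetic token;
  # two-letter elements in protein PDB files (FE, ZN, SE) keep both letters
  stripped <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(stripped, 1, 2))
  ifelse(two %in% c("FE", "ZN", "SE", "MG", "MN", "CL", "NA", "BR"),
         two, toupper(substr(stripped, 1, 1)))
}

# residue-number discontinuities per chain -> list of c(from, to) missing runs
.detectMissingSegments <- function(atoms) {
  segs <- list()
  for (ch in unique(atoms$chain)) {
    r <- unique(atoms$resno[atoms$chain == ch])
    if (length(r) < 2) next
    d <- diff(r)
    at <- which(d > 1)
    for (i in at)
      segs[[length(segs) + 1L]] <- c(from = r[i] + 1L, to = r[i + 1L] - 1L,
                                     chain = ch)
  }
  segs
}

.atomsFromBio3d <- function(pdb) {
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", " ", "A")
  a <- a[keep & a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!nrow(a)) stop("no ATOM records after altloc filtering")
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) )
    elem <- .elementFromName(a$elety)
  else
    elem[is.na(elem) | elem == ""] <- .elementFromName(a$elety[is.na(elem) | elem == ""])
  occ <- a$o; occ[is.na(occ)] <- 1
  occ <- pmin(pmax(occ, 0), 1)
  bf <- a$b; bf[is.na(bf)] <- 0
  ins <- a$insert; ins[is.na(ins)] <- ""
  ch <- a$chain; ch[is.na(ch)] <- "A"
  data.frame(serial = a$eleno, name = trimws(a$elety), resid = a$resid,
             chain = ch, resno = a$resno, insert = ins,
             x = a$x, y = a$y, z = a$z, occ = occ, b = bf,
             element = trimws(elem), stringsAsFactors = FALSE)
}

.newStructureFromAtoms <- function(atoms, annotations = list()) {
  annotations$missingSegments <- .detectMissingSegments(atoms)
  chains <- unique(atoms$chain)
  if (length(chains) > 1L)
    new("RingAssembly", atoms = atoms, annotations = annotations,
        nSubunits = length(chains), transforms = list(),
        symmetryAxis = c(0, 0, 1), placement = list(axisKnown = FALSE))
  else
    new("MonomerStructure", atoms = atoms, annotations = annotations)
}

#' Read a PDB file
#'
#' Reads ATOM/HETATM records, keeps alternate location 'A' or blank, preserves
#' author residue numbering, and records missing segments from residue-number
#' discontinuities. Single-chain files return a [MonomerStructure-class];
#' multi-chain files a [RingAssembly-class] (with unknown placement, so
#' geometry measurement recovers the symmetry axis from the coordinates).
#'
#' @param path path to a PDB file.
#' @return a MonomerStructure or RingAssembly.
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("PDB file contains no ATOM records: ", path)
  .newStructureFromAtoms(.atomsFromBio3d(pdb))
}

#' Write a structure as a fixed-width PDB file
#'
#' @param x a CoordSet (MonomerStructure or RingAssembly) or a Trajectory
#'   (written as a multi-model PDB, one MODEL per frame).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
setGeneric("writePDB", function(x, path) standardGeneric("writePDB"))

.writeAtomsPDB <- function(atoms, path, xyzFrames = NULL) {
  xyz <- if (is.null(xyzFrames)) {
    matrix(as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))), nrow = 1)
  } else {
    do.call(rbind, lapply(xyzFrames, function(f) as.numeric(t(f))))
  }
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(atoms)),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = atoms$serial, elety = atoms$name,
                   chain = atoms$chain,
                   insert = ifelse(atoms$insert == "", NA, atoms$insert),
                   o = atoms$occ, b = atoms$b, elesy = atoms$element,
                   end = TRUE)
  invisible(path)
}

#' @rdname writePDB
#' @export
setMethod("writePDB", "CoordSet", function(x, path) {
  .writeAtomsPDB(x@atoms, path)
})

#' @rdname writePDB
#' @export
setMethod("writePDB", "Trajectory", function(x, path) {
  .writeAtomsPDB(x@topology@atoms, path, xyzFrames = x@frames)
})

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks become frames, ordered by MODEL number. All models
#' must contain the same number of coordinates.
#'
#' @param path path to a (multi-model) PDB file.
#' @param topology optional CoordSet giving the atom identities; defaults to
#'   the first model of the file. Atom counts must agree.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("malformed multi-model PDB: unbalanced MODEL/ENDMDL")
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM|HETATM)", lines[s:e])), starts, ends)
    if (length(unique(counts)) > 1)
      stop("inconsistent atom count across MODEL blocks: ",
           paste(unique(counts), collapse = " vs "))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("trajectory file contains no ATOM records: ", path)
  topo <- if (is.null(topology)) .newStructureFromAtoms(.atomsFromBio3d(pdb))
          else topology
  nxyz <- ncol(pdb$xyz)
  if (nxyz != 3L * nrow(topo@atoms))
    stop(sprintf("trajectory atom count (%d) does not match topology (%d)",
                 nxyz / 3L, nrow(topo@atoms)))
  frameList <- lapply(seq_len(nrow(pdb$xyz)), function(i)
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE))
  new("Trajectory", topology = topo, frames = frameList, times = numeric(0))
}

.AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

#' One-letter sequence of a chain
#'
#' @param x a CoordSet.
#' @param chain chain identifier (default: first chain).
#' @return one-letter amino-acid string; unknown residues map to 'X'.
#' @export
sequenceOf <- function(x, chain = chainIds(x)[1]) {
  a <- atoms(x)
  if (!chain %in% a$chain) stop("no such chain: ", chain)
  a <- a[a$chain == chain, , drop = FALSE]
  res <- a$resid[!duplicated(a$resno)]
  one <- .AA321[toupper(res)]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Missing residue segments of a structure
#'
#' Segments recorded at read/construction time from residue-number
#' discontinuities (e.g. the crystallographically unresolved 78-79 stretch of
#' the stabilized cystatin C monomer entry).
#'
#' @param x a CoordSet.
#' @return list of named vectors c(from, to, chain).
#' @export
missingSegments <- function(x) {
  annotations(x)$missingSegments %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
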