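# Generics and accessors. Slot access from user code goes through these.

#' Atom table of a structure
#' @param x a CoordSet (MonomerStructure or RingAssembly).
#' @return data.frame, one row per atom.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "CoordSet", function(x) x@atoms)

#' Coordinate matrix of a structure (Angstrom)
#' @param x a CoordSet or Trajectory.
#' @param ... unused.
#' @return N x 3 numeric matrix (for a Trajectory, the first frame).
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "CoordSet", function(x, ...)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x, ...) x@frames[[1]])

#' Number of atoms
#' @param x a CoordSet or Trajectory.
#' @return integer.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "CoordSet", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))

#' Chain identifiers of a structure
#' @param x a CoordSet.
#' @return character vector of unique chain ids, in order of appearance.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname chainIds
#' @export
setMethod("chainIds", "CoordSet", function(x) unique(x@atoms$chain))

#' Annotation list of a structure
#' @param x a CoordSet.
#' @return named list (missingSegments, disulfides, ssTruth, ...).
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname annotations
#' @export
setMethod("annotations", "CoordSet", function(x) x@annotations)

#' Number of subunits of a ring assembly
#' @param x a RingAssembly.
#' @return integer.
#' @export
setGeneric("nSubunits", function(x) standardGeneric("nSubunits"))

#' @rdname nSubunits
#' @export
setMethod("nSubunits", "RingAssembly", function(x) x@nSubunits)

#' Trajectory frames
#' @param x a Trajectory.
#' @return list of N x 3 coordinate matrices.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setMethod("frames", "Trajectory", function(x) x@frames)

#' Number of frames
#' @param x a Trajectory.
#' @return integer.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@frames))
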