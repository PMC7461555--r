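# Orchestration: build -> measure -> filter -> swap -> report, and the
# trajectory analysis bundle. Configs are flat named lists (optionally read
# from YAML); unknown keys are rejected before any stage runs, and every
# report echoes the effective configuration for provenance.

.CONFIG_KEYS <- c("monomer", "nValues", "radiusGrid", "orientationGrid",
                  "constraintRows", "constraints", "clashCutoff", "swap",
                  "swapJunction", "outputDir", "seed")

.CONFIG_DEFAULTS <- list(nValues = c(10L, 12L), orientationGrid = list(c(0, 0, 0)),
                         constraintRows = c("TEM", "AFM"), constraints = NULL,
                         clashCutoff = 2, swap = TRUE,
                         swapJunction = c(58L, 59L), outputDir = NULL, seed = 1L)

#' Validate (and complete) a pipeline configuration
#'
#' @param config named list; recognized keys: monomer (path or
#'   MonomerStructure), nValues, radiusGrid (Angstrom), orientationGrid (list
#'   of tilt/spin/twist triples, radians), constraintRows (subset of
#'   TEM/AFM/SAXS), constraints (a ConstraintSet overriding constraintRows),
#'   clashCutoff, swap (logical), swapJunction, outputDir, seed. Unknown keys
#'   are an error.
#' @return the completed configuration list.
#' @export
validatePipelineConfig <- function(config) {
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (k in names(.CONFIG_DEFAULTS))
    if (is.null(config[[k]])) config[k] <- .CONFIG_DEFAULTS[k]
  if (is.null(config$monomer)) stop("configuration must name a monomer")
  if (is.null(config$radiusGrid)) stop("configuration must give a radiusGrid")
  if (any(config$nValues < 1)) stop("nValues must be >= 1")
  config
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the keys of [validatePipelineConfig()].
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$orientationGrid))
    cfg$orientationGrid <- lapply(cfg$orientationGrid, as.numeric)
  validatePipelineConfig(cfg)
}

.configEcho <- function(config) {
  cfg <- config
  if (!is.character(cfg$monomer)) cfg$monomer <- "<in-memory structure>"
  cfg$constraints <- if (is.null(cfg$constraints)) NULL
                     else cfg$constraints@bounds
  cfg
}

#' Build candidate rings, measure and filter them
#'
#' Enumerates the configured placement grid, measures each candidate's
#' doughnut geometry, filters against the experimental constraint intervals,
#' and (optionally) writes surviving models as multi-chain PDB files plus a
#' JSON/CSV report. Zero survivors is a clean result, not an error.
#'
#' @param config configuration list (see [validatePipelineConfig()]).
#' @return list(report = data.frame with one row per candidate, survivors =
#'   integer ids, candidates = candidate list, config = effective config).
#' @export
runBuildAndFilter <- function(config) {
  config <- validatePipelineConfig(config)
  monomer <- if (is.character(config$monomer)) readPDB(config$monomer)
             else config$monomer
  constraints <- if (!is.null(config$constraints)) config$constraints
                 else table1Constraints(config$constraintRows)
  cands <- enumerateCandidates(monomer, config$nValues, config$radiusGrid,
                               config$orientationGrid,
                               clashCutoff = config$clashCutoff)
  rows <- lapply(cands, function(cd) {
    g <- measureRingGeometry(cd$assembly)
    v <- filterByConstraints(g, constraints)
    data.frame(id = cd$id, n = cd$n, ringRadius = cd$params@ringRadius,
               tilt = cd$params@tilt, spin = cd$params@spin,
               twist = cd$params@twist, clashes = cd$clashes,
               outerDiameter = g@outerDiameter,
               cavityDiameter = g@cavityDiameter, ringWidth = g@ringWidth,
               height = g@height, rg = g@rg, pass = v@pass,
               failedParameters = paste(v@failed$parameter, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  survivors <- report$id[report$pass]
  if (!length(survivors))
    message("no candidate satisfied the constraint set")
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(config$outputDir, "candidates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config = .configEcho(config), report = report),
      file.path(config$outputDir, "report.json"), auto_unbox = TRUE,
      digits = NA)
    for (id in survivors)
      writePDB(cands[[id]]$assembly,
               file.path(config$outputDir, sprintf("candidate_%03d.pdb", id)))
  }
  list(report = report, survivors = survivors, candidates = cands,
       config = .configEcho(config))
}

#' Apply the cyclic domain swap to selected assemblies
#'
#' @param assemblies list of RingAssembly objects, or paths to multi-chain
#'   PDB files.
#' @param spec a [SwapSpec-class].
#' @param outputDir optional directory for swapped PDBs and the junction CSV.
#' @return list(assemblies = swapped assemblies, junctions = combined
#'   junction data.frame with an assembly column).
#' @export
runSwap <- function(assemblies, spec = swapSpec(), outputDir = NULL) {
  if (!is.list(assemblies)) assemblies <- list(assemblies)
  swapped <- vector("list", length(assemblies))
  juncRows <- list()
  for (i in seq_along(assemblies)) {
    asm <- assemblies[[i]]
    if (is.character(asm)) asm <- readPDB(asm)
    if (!is(asm, "RingAssembly") || length(chainIds(asm)) < 2)
      stop("swap requires a multi-chain ring assembly")
    sw <- applyCyclicSwap(asm, spec)
    jr <- junctionReport(sw, spec)$junctions
    jr$assembly <- i
    swapped[[i]] <- sw
    juncRows[[i]] <- jr
    if (!is.null(outputDir)) {
      dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
      writePDB(sw, file.path(outputDir, sprintf("swapped_%03d.pdb", i)))
    }
  }
  junctions <- do.call(rbind, juncRows)
  if (!is.null(outputDir))
    utils::write.csv(junctions, file.path(outputDir, "junctions.csv"),
                     row.names = FALSE)
  list(assemblies = swapped, junctions = junctions)
}

#' Trajectory stability analysis bundle
#'
#' Computes the four stability metric families on a trajectory: the CA RMSD
#' series against a reference frame, the TM-score of the final frame, the
#' occupancy of requested hydrogen-bond pairs, and the 4-state secondary
#' structure content of the final frame.
#'
#' @param traj a [Trajectory-class] or path to a multi-model PDB.
#' @param reference reference frame index (default 1) or N x 3 matrix.
#' @param hbondPairs optional pairs data.frame for [hbondOccupancy()].
#' @param criteria an [HBondCriteria-class].
#' @param outputDir optional directory for the CSV/JSON reports.
#' @return list(rmsd, tmScore, occupancy, ssContent, ssLabels).
#' @export
runAnalyzeTraj <- function(traj, reference = 1, hbondPairs = NULL,
                           criteria = hbondCriteria(), outputDir = NULL) {
  if (is.character(traj)) traj <- readTrajectory(traj)
  rmsd <- rmsdSeries(traj, reference = reference, selection = "CA")
  caIdx <- .selectionIndices(traj@topology, "CA")
  refXYZ <- if (is.matrix(reference)) reference else traj@frames[[reference]]
  tm <- tmScore(traj@frames[[nFrames(traj)]][caIdx, , drop = FALSE],
                refXYZ[caIdx, , drop = FALSE])
  occ <- if (!is.null(hbondPairs)) hbondOccupancy(traj, hbondPairs, criteria)
         else NULL
  finalStruct <- traj@topology
  finalStruct@atoms[, c("x", "y", "z")] <- traj@frames[[nFrames(traj)]]
  labels <- assignSecondaryStructure(finalStruct)
  ss <- ssContent(labels)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(frame = seq_along(rmsd), rmsd = rmsd),
                     file.path(outputDir, "rmsd.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(tmScore = tm@score, d0 = tm@d0, ssContent = as.list(ss),
           occupancy = occ),
      file.path(outputDir, "stability.json"), auto_unbox = TRUE, digits = NA)
  }
  list(rmsd = rmsd, tmScore = tm, occupancy = occ, ssContent = ss,
       ssLabels = labels)
}
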