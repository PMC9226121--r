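## Configuration I/O, presets, and run outputs.

#' Construct a full simulation configuration
#'
#' All defaults equal the reference values (41 x 41 grid, homogeneous
#' synapse/neuron tables, recovery period 12 ms).
#'
#' @param nx,ny grid dimensions
#' @param mazeKind "open", "s_maze", "blocks", "fine_structure" or "file"
#' @param mazeParams named list for [makeMaze()]
#' @param maskFile mask path when \code{mazeKind = "file"}
#' @param start,target (x, y) node coordinates
#' @param synapse,attractor,planner,heterogeneity component configurations
#' @param seed integer seed
#' @return a [SimulationConfig-class]
#' @export
simulationConfig <- function(nx = 41, ny = 41, mazeKind = "open",
                             mazeParams = list(), maskFile = NA_character_,
                             start = c(5, 5), target = c(35, 35),
                             synapse = new("SynapseConfig"),
                             attractor = new("AttractorConfig"),
                             planner = new("PlannerConfig"),
                             heterogeneity = new("HeterogeneityConfig"),
                             seed = 1L) {
  new("SimulationConfig", nx = as.integer(nx), ny = as.integer(ny),
      mazeKind = mazeKind, mazeParams = mazeParams,
      maskFile = as.character(maskFile),
      start = as.integer(start), target = as.integer(target),
      synapse = synapse, attractor = attractor, planner = planner,
      heterogeneity = heterogeneity, seed = as.integer(seed))
}

#' Named experiment presets
#'
#' \code{open}, \code{s_maze}, \code{blocks} and \code{fine_structure} are
#' the corner-to-corner planning setups on the four reference mazes with the
#' homogeneous layer; \code{heterogeneous} is the blocks setup with
#' randomized neuron parameters and 10 percent synaptic jitter.
#'
#' @param name preset name
#' @param seed integer seed
#' @return a [SimulationConfig-class]
#' @export
presetConfig <- function(name = c("open", "s_maze", "blocks",
                                  "fine_structure", "heterogeneous"),
                         seed = 1L) {
  name <- match.arg(name)
  het <- new("HeterogeneityConfig",
             enabled = identical(name, "heterogeneous"),
             seed = as.integer(seed))
  kind <- if (name == "heterogeneous") "blocks" else name
  simulationConfig(mazeKind = kind, heterogeneity = het, seed = seed)
}

## ---- serialization ----------------------------------------------------

.slotList <- function(obj)
  stats::setNames(lapply(methods::slotNames(obj), function(s)
    methods::slot(obj, s)), methods::slotNames(obj))

.configToList <- function(config) {
  list(grid = list(nx = config@nx, ny = config@ny),
       maze = list(kind = config@mazeKind, params = config@mazeParams,
                   maskFile = config@maskFile),
       start = config@start, target = config@target,
       synapse = .slotList(config@synapse),
       attractor = .slotList(config@attractor),
       planner = .slotList(config@planner),
       heterogeneity = .slotList(config@heterogeneity),
       seed = config@seed)
}

.fillS4 <- function(class, values, path) {
  obj <- new(class)
  known <- methods::slotNames(obj)
  unknown <- setdiff(names(values), known)
  if (length(unknown))
    stop(sprintf("configuration error: unknown key '%s.%s'",
                 path, unknown[1]))
  for (nm in names(values)) {
    proto <- methods::slot(obj, nm)
    v <- values[[nm]]
    v <- switch(class(proto)[1],
                integer = as.integer(v),
                numeric = as.numeric(v),
                logical = as.logical(v),
                v)
    methods::slot(obj, nm) <- v
  }
  ok <- methods::validObject(obj, test = TRUE)
  if (!isTRUE(ok))
    stop(sprintf("configuration error in '%s': %s", path, ok[1]))
  obj
}

#' Load and save simulation configurations (JSON)
#'
#' Absent fields are filled with the reference defaults, unknown keys and
#' out-of-range values raise a configuration error naming the field, and a
#' save/load round trip reproduces the configuration exactly.
#'
#' @param path JSON file path
#' @param config a [SimulationConfig-class]
#' @return \code{loadConfig}: a [SimulationConfig-class];
#'   \code{saveConfig}: invisible path
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration error: no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE)
         else list()
  known <- c("grid", "maze", "start", "target", "synapse", "attractor",
             "planner", "heterogeneity", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("configuration error: unknown key '%s'", unknown[1]))
  cfg <- simulationConfig()
  if (!is.null(raw$grid$nx)) cfg@nx <- as.integer(raw$grid$nx)
  if (!is.null(raw$grid$ny)) cfg@ny <- as.integer(raw$grid$ny)
  if (!is.null(raw$maze$kind)) cfg@mazeKind <- raw$maze$kind
  if (!is.null(raw$maze$params)) cfg@mazeParams <- as.list(raw$maze$params)
  if (!is.null(raw$maze$maskFile) && !is.na(raw$maze$maskFile))
    cfg@maskFile <- raw$maze$maskFile
  if (!is.null(raw$start)) cfg@start <- as.integer(raw$start)
  if (!is.null(raw$target)) cfg@target <- as.integer(raw$target)
  if (!is.null(raw$synapse))
    cfg@synapse <- .fillS4("SynapseConfig", raw$synapse, "synapse")
  if (!is.null(raw$attractor))
    cfg@attractor <- .fillS4("AttractorConfig", raw$attractor, "attractor")
  if (!is.null(raw$planner))
    cfg@planner <- .fillS4("PlannerConfig", raw$planner, "planner")
  if (!is.null(raw$heterogeneity))
    cfg@heterogeneity <- .fillS4("HeterogeneityConfig", raw$heterogeneity,
                                 "heterogeneity")
  if (!is.null(raw$seed)) cfg@seed <- as.integer(raw$seed)
  ok <- methods::validObject(cfg, test = TRUE)
  if (!isTRUE(ok)) stop("configuration error: ", ok[1])
  cfg
}

#' @rdname loadConfig
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  jsonlite::write_json(.configToList(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Materialize the obstacle mask of a configuration
#'
#' @param config a [SimulationConfig-class]
#' @return logical nx by ny mask
#' @export
configMask <- function(config) {
  if (config@mazeKind == "file") {
    if (is.na(config@maskFile))
      stop("configuration error: mazeKind 'file' needs 'maskFile'")
    mask <- readMask(config@maskFile)
    if (!identical(dim(mask), c(config@nx, config@ny)))
      stop("configuration error: mask file dimensions do not match the grid")
    mask
  } else if (config@mazeKind == "open") {
    matrix(FALSE, config@nx, config@ny)
  } else {
    makeMaze(config@mazeKind, config@nx, config@ny, config@mazeParams,
             start = config@start, target = config@target)
  }
}

#' Run the full planner described by a configuration
#'
#' @param config a [SimulationConfig-class]
#' @param recordRaster logical, collect the spike raster
#' @param verbose logical, print progress every 100 ms
#' @return a [PlannerRun-class]
#' @export
runSimulation <- function(config, recordRaster = TRUE, verbose = FALSE) {
  manifold <- buildManifold(config@nx, config@ny, configMask(config))
  het <- config@heterogeneity
  if (het@enabled) het@seed <- config@seed
  runPlanner(manifold, config@start, config@target,
             synapseCfg = config@synapse, attractorCfg = config@attractor,
             plannerCfg = config@planner, het = het, seed = config@seed,
             recordRaster = recordRaster, verbose = verbose)
}

#' Write the artifact files of a planner run
#'
#' Writes \code{trajectory.csv} (t_ms, center_x, center_y),
#' \code{raster.csv} (t_ms, population, node_x, node_y) and
#' \code{summary.json} (status, path_hops, bfs_hops, efficiency,
#' arrival_time_ms, seed, and the full effective configuration). Outputs are
#' a pure function of configuration and seed.
#'
#' @param run a [PlannerRun-class]
#' @param dir output directory (created if needed)
#' @return invisible character vector of the written paths
#' @export
writeRunOutputs <- function(run, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("I/O error: directory not writable")
  traj <- run@trajectory
  names(traj) <- c("t_ms", "center_x", "center_y")
  paths <- file.path(dir, c("trajectory.csv", "raster.csv", "summary.json"))
  utils::write.csv(traj, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(run@raster, paths[2], row.names = FALSE, quote = FALSE)
  summary <- list(status = run@status, path_hops = run@pathHops,
                  bfs_hops = run@bfsHops, efficiency = run@efficiency,
                  arrival_time_ms = run@arrivalTime, seed = run@seed,
                  config = list(
                    start = run@configs$start, target = run@configs$target,
                    synapse = .slotList(run@configs$synapse),
                    attractor = .slotList(run@configs$attractor),
                    planner = .slotList(run@configs$planner),
                    heterogeneity = .slotList(run@configs$heterogeneity)))
  jsonlite::write_json(summary, paths[3], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}
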