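## Layer coupling: overlap detection, direction vector, recovery period,
## and the full planning loop moving the bump from start to target.

#' Overlap between bump region and wavefront
#'
#' Exact set intersection of the active attractor nodes C_t and the
#' currently spiking excitatory wave nodes P_t (both as 0-based node ids on
#' the shared grid).
#'
#' @param cSet,pSet integer vectors of node ids
#' @return integer vector of node ids
#' @export
overlapSet <- function(cSet, pSet) intersect(cSet, pSet)

#' Direction vector from bump center to overlap centroid
#'
#' \eqn{\Delta = mean(A_t) - p_t} in grid units; an empty overlap yields the
#' zero vector (no movement, as during the recovery period).
#'
#' @param overlap integer vector of 0-based node ids (possibly empty)
#' @param center (x, y) bump center in grid units
#' @param nx grid width used to decode node ids
#' @return numeric length-2 vector in grid units
#' @examples
#' directionVector(c(nodeId(3, 4, 41), nodeId(5, 6, 41)), c(2, 2), 41) # (2,3)
#' @export
directionVector <- function(overlap, center, nx) {
  if (!length(overlap)) return(c(0, 0))
  xy <- nodeXY(overlap, nx)
  c(mean(xy[, 1]), mean(xy[, 2])) - as.numeric(center)
}

#' Convert a grid-unit direction into the attractor kernel shift
#'
#' The raw vector is normalized to unit length (direction-only) and scaled
#' by \code{deltaGain}, yielding the normalized-coordinate direction vector
#' consumed by the attractor kernel. The gain is calibrated so that one
#' incoming wavefront shifts the bump center by a few nodes, bounded by half
#' the bump width.
#'
#' @param raw numeric length-2 vector in grid units
#' @param cfg a [PlannerConfig-class]
#' @return numeric length-2 normalized-coordinate vector
#' @export
applyDirection <- function(raw, cfg) {
  nrm <- sqrt(sum(raw^2))
  if (nrm == 0) return(c(0, 0))
  cfg@deltaGain * raw / nrm
}

#' One coupled 1 ms tick of both layers
#'
#' The wave layer steps first; the bump region C_t (activity threshold
#' \code{cfg@activeFrac}) and the wavefront P_t (excitatory spikes of this
#' step) are intersected. If the recovery timer is zero and a wavefront
#' newly enters the bump region (the overlap was empty on the previous tick
#' and is nonempty now), the direction vector is set from the overlap
#' centroid and the timer restarts at \code{cfg@recoveryPeriod}; the
#' attractor then steps with the currently held direction vector, which is
#' reset after \code{cfg@holdSteps} attractor steps.
#'
#' @param wave a [WaveLayer-class]
#' @param attractor an [AttractorState-class]
#' @param timer integer recovery timer (ms remaining)
#' @param cfg a [PlannerConfig-class]
#' @param prevOverlap logical, was the overlap nonempty on the previous tick
#' @param holdLeft integer, attractor steps the held direction still applies
#' @param heldDelta numeric length-2, currently held kernel shift
#' @param attractorCfg an [AttractorConfig-class]
#' @return list with updated \code{wave}, \code{attractor}, \code{timer},
#'   \code{prevOverlap}, \code{holdLeft}, \code{heldDelta}, and the
#'   \code{overlap} ids of this tick
#' @export
plannerStep <- function(wave, attractor, timer, cfg,
                        prevOverlap = FALSE, holdLeft = 0L,
                        heldDelta = c(0, 0),
                        attractorCfg = new("AttractorConfig")) {
  wave <- stepWaveLayer(wave)
  pSet <- which(wave@spikedE) - 1L
  cSet <- activeSet(attractor, cfg@activeFrac)
  ov <- overlapSet(cSet, pSet)
  if (timer == 0L && length(ov) && !prevOverlap) {
    raw <- directionVector(ov, bumpCenter(attractor), wave@manifold@nx)
    delta <- applyDirection(raw, cfg)
    if (any(delta != 0)) {
      heldDelta <- delta
      holdLeft <- cfg@holdSteps
      timer <- cfg@recoveryPeriod
    }
  }
  attractor@delta <- if (holdLeft > 0L) heldDelta else c(0, 0)
  attractor <- attractorStep(attractor, attractorCfg, wave@manifold@blocked)
  if (holdLeft > 0L) holdLeft <- holdLeft - 1L
  if (timer > 0L) timer <- timer - 1L
  list(wave = wave, attractor = attractor, timer = timer,
       prevOverlap = length(ov) > 0L, holdLeft = holdLeft,
       heldDelta = heldDelta, overlap = ov)
}

#' Run the coupled planner from start to target
#'
#' The target node is permanently DC-stimulated in the wave layer; the bump
#' is initialized at the start node and the coupled loop runs until the bump
#' center is within \code{plannerCfg@arrivalRadius} of the target (status
#' "arrived"), the budget is exhausted, or the bump collapses.
#'
#' @param manifold a [GridManifold-class]
#' @param start,target (x, y) 0-based free nodes, distinct and mutually
#'   reachable on the range-dE connectivity graph
#' @param synapseCfg a [SynapseConfig-class]
#' @param attractorCfg an [AttractorConfig-class]
#' @param plannerCfg a [PlannerConfig-class]
#' @param het a [HeterogeneityConfig-class]
#' @param seed integer seed echoed into the run record (the simulation is
#'   deterministic given the configuration; randomness enters only through
#'   the heterogeneous setup, whose own seed defaults to this one)
#' @param recordRaster logical, collect the full spike raster (default TRUE)
#' @param verbose logical, report the bump center every 100 ms and the
#'   direction-vector updates and arrival as they happen
#' @return a [PlannerRun-class]
#' @export
runPlanner <- function(manifold, start, target,
                       synapseCfg = new("SynapseConfig"),
                       attractorCfg = new("AttractorConfig"),
                       plannerCfg = new("PlannerConfig"),
                       het = new("HeterogeneityConfig"),
                       seed = 1L, recordRaster = TRUE, verbose = FALSE) {
  start <- .checkNode(manifold, start)
  target <- .checkNode(manifold, target)
  if (all(start == target))
    stop("precondition error: start and target must differ")
  graph <- connectivityGraph(manifold, range = synapseCfg@dE)
  bd <- bfsDistances(graph, start)
  bfsHops <- bd[nodeId(target[1], target[2], manifold@nx) + 1L]
  if (is.na(bfsHops))
    stop("degenerate maze: start and target are disconnected")
  if (het@enabled && is.na(het@seed)) het@seed <- as.integer(seed)
  wave <- buildWaveLayer(manifold, synapseCfg, stimNodes = target, het = het)
  attractor <- initializeBump(manifold, start, attractorCfg)
  nx <- manifold@nx
  timer <- 0L; prevOverlap <- FALSE; holdLeft <- 0L; heldDelta <- c(0, 0)
  cur <- start
  traj <- list(data.frame(t_ms = 0, x = start[1], y = start[2]))
  rt <- list(); k <- 0L
  status <- "budget_exhausted"
  arrival <- NA_real_
  for (tick in seq_len(plannerCfg@maxSteps)) {
    stepRes <- tryCatch(
      plannerStep(wave, attractor, timer, plannerCfg, prevOverlap,
                  holdLeft, heldDelta, attractorCfg),
      error = function(e) {
        if (grepl("collapsed bump", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(stepRes)) { status <- "collapsed"; break }
    wave <- stepRes$wave; attractor <- stepRes$attractor
    prevTimer <- timer
    timer <- stepRes$timer; prevOverlap <- stepRes$prevOverlap
    holdLeft <- stepRes$holdLeft; heldDelta <- stepRes$heldDelta
    if (verbose) {
      if (prevTimer == 0L && timer > 0L)
        message(sprintf("[t=%d ms] direction update from %d overlap nodes",
                        tick, length(stepRes$overlap)))
      if (tick %% 100L == 0L)
        message(sprintf("[t=%d ms] bump center (%d, %d)", tick,
                        cur[1], cur[2]))
    }
    if (recordRaster && (any(wave@spikedE) || any(wave@spikedI))) {
      k <- k + 1L
      rt[[k]] <- list(t = wave@t, e = which(wave@spikedE) - 1L,
                      i = which(wave@spikedI) - 1L)
    }
    ctr <- bumpCenter(attractor)
    if (any(ctr != cur)) {
      cur <- ctr
      traj[[length(traj) + 1L]] <- data.frame(t_ms = wave@t, x = ctr[1],
                                              y = ctr[2])
    }
    if (sqrt(sum((cur - target)^2)) <= plannerCfg@arrivalRadius) {
      status <- "arrived"
      arrival <- wave@t
      if (verbose)
        message(sprintf("[t=%d ms] arrived at (%d, %d)", tick, cur[1], cur[2]))
      break
    }
  }
  trajectory <- do.call(rbind, traj)
  rownames(trajectory) <- NULL
  pathHops <- nrow(trajectory) - 1L
  new("PlannerRun",
      trajectory = trajectory,
      raster = .rasterFrame(rt, nx),
      status = status,
      pathHops = as.integer(pathHops),
      bfsHops = as.integer(bfsHops),
      efficiency = if (status == "arrived") pathHops / bfsHops else NA_real_,
      arrivalTime = arrival,
      seed = as.integer(seed),
      configs = list(synapse = synapseCfg, attractor = attractorCfg,
                     planner = plannerCfg, heterogeneity = het,
                     start = start, target = target))
}

#' Path efficiency of an arrived run
#'
#' Number of distinct successive bump centers minus one, divided by the BFS
#' hop distance from start to target on the range-dE connectivity graph. A
#' trajectory that follows a BFS geodesic gives 1.
#'
#' @param run a [PlannerRun-class] with status "arrived"
#' @param graph optional [ConnectivityGraph-class] to recompute the BFS
#'   distance against (defaults to the one recorded in the run)
#' @return numeric ratio
#' @export
pathEfficiency <- function(run, graph = NULL) {
  if (run@status != "arrived")
    stop("invalid input: run did not arrive (status: ", run@status, ")")
  hops <- run@bfsHops
  if (!is.null(graph)) {
    st <- run@configs$start; tg <- run@configs$target
    hops <- bfsDistances(graph, st)[nodeId(tg[1], tg[2],
                                           graph@manifold@nx) + 1L]
  }
  run@pathHops / hops
}

#' @describeIn trajectory trajectory of the bump center
#' @export
setMethod("trajectory", "PlannerRun", function(x) x@trajectory)

#' @describeIn spikeRaster spike raster of the run
#' @export
setMethod("spikeRaster", "PlannerRun", function(x) x@raster)
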