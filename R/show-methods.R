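#' @describeIn GridManifold-class compact display
#' @param object the object
#' @export
setMethod("show", "GridManifold", function(object) {
  cat(sprintf("GridManifold: %d x %d nodes, %d blocked, %d free\n",
              object@nx, object@ny, sum(object@blocked),
              sum(!object@blocked)))
})

#' @describeIn ConnectivityGraph-class compact display
#' @param object the object
#' @export
setMethod("show", "ConnectivityGraph", function(object) {
  cat(sprintf("ConnectivityGraph: range %.3g, %d undirected edges on %d x %d\n",
              object@range, nrow(object@edges), object@manifold@nx,
              object@manifold@ny))
})

#' @describeIn WaveLayer-class compact display
#' @param object the object
#' @export
setMethod("show", "WaveLayer", function(object) {
  cat(sprintf(paste0("WaveLayer: %d x %d paired exc/inh Izhikevich sheets, ",
                     "t = %g ms\n  %d stimulated node(s), %s wiring, ",
                     "%d exc / %d inh spiking\n"),
              object@manifold@nx, object@manifold@ny, object@t,
              sum(object@stim > 0),
              if (is.null(object@wEE)) "homogeneous" else "jittered",
              sum(object@spikedE), sum(object@spikedI)))
})

#' @describeIn AttractorState-class compact display
#' @param object the object
#' @export
setMethod("show", "AttractorState", function(object) {
  ctr <- tryCatch(bumpCenter(object), error = function(e) c(NA, NA))
  cat(sprintf(paste0("AttractorState: %d x %d sheet, t = %g ms, ",
                     "center (%s, %s), total activation %.4g\n"),
              nrow(object@A), ncol(object@A), object@t,
              ctr[1], ctr[2], sum(object@A)))
})

#' @describeIn PlannerRun-class compact display
#' @param object the object
#' @export
setMethod("show", "PlannerRun", function(object) {
  cat(sprintf(paste0("PlannerRun: status '%s'\n  path hops %d, BFS hops %d,",
                     " efficiency %s, arrival %s ms\n  %d trajectory points,",
                     " %d raster spikes, seed %d\n"),
              object@status, object@pathHops, object@bfsHops,
              format(object@efficiency), format(object@arrivalTime),
              nrow(object@trajectory), nrow(object@raster), object@seed))
})

#' @describeIn SimulationConfig-class compact display
#' @param object the object
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d x %d grid, maze '%s', ",
                     "(%d, %d) -> (%d, %d), %s, seed %d\n"),
              object@nx, object@ny, object@mazeKind,
              object@start[1], object@start[2], object@target[1],
              object@target[2],
              if (object@heterogeneity@enabled) "heterogeneous"
              else "homogeneous", object@seed))
})
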