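#' Number of free (traversable) nodes
#' @param x a [GridManifold-class]
#' @return integer count of non-blocked nodes
#' @export
setGeneric("freeNodes", function(x) standardGeneric("freeNodes"))

#' Bump center of an attractor state
#'
#' The node with maximal activation; ties are broken by the smallest node id
#' (deterministic).
#'
#' @param x an [AttractorState-class]
#' @return integer (x, y), 0-based node coordinates
#' @export
setGeneric("bumpCenter", function(x) standardGeneric("bumpCenter"))

#' Active node set of an attractor state
#'
#' Nodes with activation at least \code{frac} times the maximum; this defines
#' the bump region C_t used for the layer coupling.
#'
#' @param x an [AttractorState-class]
#' @param frac relative threshold in (0, 1)
#' @return integer vector of 0-based node ids
#' @export
setGeneric("activeSet", function(x, frac = 0.1) standardGeneric("activeSet"))

#' Effective bump diameter
#'
#' Maximal extent in nodes of the active set along the x axis through the
#' bump center.
#'
#' @param x an [AttractorState-class]
#' @param frac relative threshold in (0, 1)
#' @return integer diameter in nodes
#' @export
setGeneric("bumpDiameter", function(x, frac = 0.1) standardGeneric("bumpDiameter"))

#' Trajectory of a planner run
#' @param x a [PlannerRun-class]
#' @return data.frame with columns t_ms, x, y
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' Spike raster of a planner run or wave layer simulation
#' @param x a [PlannerRun-class]
#' @return data.frame with columns t_ms, population, node_x, node_y
#' @export
setGeneric("spikeRaster", function(x) standardGeneric("spikeRaster"))
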