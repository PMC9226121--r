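#' @import methods
#' @importFrom Matrix sparseMatrix crossprod Diagonal
NULL

#' Grid cognitive map with obstacle mask
#'
#' A \code{GridManifold} represents the discretized manifold of stimuli as a
#' regular quadratic grid with spacing 1, where individual nodes can be
#' blocked (not traversable). Node coordinates are 0-based \code{(x, y)} with
#' \code{x} the column and \code{y} the row; the node id is
#' \code{y * nx + x}.
#'
#' @slot nx integer, number of nodes in x (columns), at least 3.
#' @slot ny integer, number of nodes in y (rows), at least 3.
#' @slot blocked logical matrix of dimension \code{nx} by \code{ny};
#'   \code{TRUE} marks a node that cannot be traversed. Element
#'   \code{blocked[x + 1, y + 1]} corresponds to node \code{(x, y)}.
#'
#' @seealso [buildManifold()], [makeMaze()], [connectivityGraph()]
#' @export
setClass("GridManifold",
  representation(nx = "integer", ny = "integer", blocked = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@nx < 3L || object@ny < 3L)
      msg <- c(msg, "grid dimensions must be at least 3 x 3")
    if (!is.logical(object@blocked))
      msg <- c(msg, "'blocked' must be a logical matrix")
    if (!identical(dim(object@blocked), c(object@nx, object@ny)))
      msg <- c(msg, sprintf("'blocked' must be %d x %d", object@nx, object@ny))
    else if (sum(!object@blocked) < 2L)
      msg <- c(msg, "fewer than 2 free nodes: degenerate manifold")
    if (length(msg)) msg else TRUE
  })

#' Distance-resolved connectivity graph over a grid manifold
#'
#' Edges connect free (non-blocked) nodes whose Euclidean distance d
#' satisfies 0 < d <= range. Distances on the integer grid therefore take
#' values 1, sqrt(2), 2, ... Edges never touch blocked nodes and there are
#' no self edges.
#'
#' @slot manifold the [GridManifold-class] the graph was built from.
#' @slot range numeric, maximal Euclidean edge length in grid units.
#' @slot edges data.frame with columns \code{from}, \code{to} (0-based node
#'   ids, one row per undirected edge with \code{from < to}) and \code{d}
#'   (exact Euclidean length).
#' @slot graph the backing \pkg{igraph} object (vertices = all grid nodes,
#'   blocked nodes isolated).
#'
#' @seealso [connectivityGraph()], [bfsDistances()], [neighborsWithin()]
#' @export
setClass("ConnectivityGraph",
  representation(manifold = "GridManifold", range = "numeric",
                 edges = "data.frame", graph = "ANY"))

#' Izhikevich neuron parameters
#'
#' The two-variable quadratic integrate-and-fire model with membrane
#' potential v (mV) and recovery variable u, reset v <- c and u <- u + d on
#' a spike (v >= 30 mV). Slots may be scalars (homogeneous population) or
#' per-neuron vectors (heterogeneous population).
#'
#' Regular-spiking (RS) defaults: a = 0.02, b = 0.2, c = -65, d = 8.
#' Fast-spiking (FS) defaults: a = 0.1, b = 0.2, c = -65, d = 2.
#'
#' @slot a recovery timescale (dimensionless), positive.
#' @slot b recovery sensitivity (dimensionless), positive.
#' @slot c after-spike reset value of v (mV scale).
#' @slot d after-spike increment of u.
#' @export
setClass("IzhikevichParams",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric"),
  validity = function(object) {
    if (any(object@a <= 0)) return("'a' must be positive")
    if (any(object@b <= 0)) return("'b' must be positive")
    n <- vapply(list(object@a, object@b, object@c, object@d), length, 1L)
    if (length(unique(n[n > 1L])) > 1L)
      return("per-neuron parameter vectors must have equal length")
    TRUE
  })

#' Synaptic configuration of the wave propagation layer
#'
#' Distance-decaying synapse strengths between the paired excitatory and
#' inhibitory neuron sheets. Strengths follow s(d) = s_max / d within the
#' interaction range and are zero beyond it; the excitatory projections are
#' zero at d = 0 (no self-excitation) while the inhibitory-to-excitatory
#' projection has its full (negative) peak at d = 0, i.e. each inhibitory
#' neuron suppresses its co-located excitatory partner most strongly.
#'
#' @slot sEEMax peak excitatory-to-excitatory strength (default 50).
#' @slot sEIFactor e-to-i peak as a multiple of \code{sEEMax} (default 0.5).
#' @slot sIEFactor i-to-e peak as a multiple of \code{sEEMax}, negative
#'   (default -9, i.e. a peak of -450 with the default \code{sEEMax}).
#' @slot dE excitation range in grid units (default 2).
#' @slot dI e-to-i interaction range in grid units (default 1).
#' @slot dS i-to-e interaction range in grid units, beyond the d = 0 self
#'   term (default 1).
#' @slot iDC DC stimulation current applied to externally driven nodes
#'   (default 25).
#' @slot vFloor numerical lower bound on the membrane potential in the
#'   1 ms Euler step (default -90 mV); prevents the quadratic term from
#'   diverging under strong impulse inhibition.
#' @export
setClass("SynapseConfig",
  representation(sEEMax = "numeric", sEIFactor = "numeric",
                 sIEFactor = "numeric", dE = "numeric", dI = "numeric",
                 dS = "numeric", iDC = "numeric", vFloor = "numeric"),
  prototype(sEEMax = 50, sEIFactor = 0.5, sIEFactor = -9, dE = 2, dI = 1,
            dS = 1, iDC = 25, vFloor = -90),
  validity = function(object) {
    msg <- character()
    if (object@sEEMax <= 0) msg <- c(msg, "'sEEMax' must be positive")
    if (object@sIEFactor * object@sEEMax >= 0)
      msg <- c(msg, "i-to-e peak ('sIEFactor' * 'sEEMax') must be negative")
    if (object@dE <= 0) msg <- c(msg, "'dE' must be positive")
    if (object@dI <= 0) msg <- c(msg, "'dI' must be positive")
    if (object@dS <= 0) msg <- c(msg, "'dS' must be positive")
    if (length(msg)) msg else TRUE
  })

#' Heterogeneity settings for the wave propagation layer
#'
#' When enabled, per-neuron Izhikevich parameters are randomized between the
#' regular-spiking and chattering phenotypes (excitatory) and between
#' low-threshold-spiking and fast-spiking phenotypes (inhibitory), and every
#' nonzero synaptic weight is jittered multiplicatively by up to plus/minus
#' \code{jitterFraction}.
#'
#' @slot enabled logical flag.
#' @slot seed integer RNG seed making the randomization reproducible.
#' @slot jitterFraction relative synaptic jitter in [0, 1) (default 0.10).
#' @export
setClass("HeterogeneityConfig",
  representation(enabled = "logical", seed = "integer",
                 jitterFraction = "numeric"),
  prototype(enabled = FALSE, seed = 1L, jitterFraction = 0.10),
  validity = function(object) {
    if (object@jitterFraction < 0 || object@jitterFraction >= 1)
      return("'jitterFraction' must be in [0, 1)")
    TRUE
  })

#' Wave propagation layer state and wiring
#'
#' Holds the paired excitatory/inhibitory Izhikevich populations on a grid
#' manifold, their distance-resolved synaptic wiring, the DC stimulation
#' vector, and the per-neuron state (v, u, spike flags) at simulation time
#' \code{t} (ms). Blocked nodes carry zero synaptic weights and are never
#' stimulated, so they stay at the resting fixed point and never spike.
#'
#' In the homogeneous setup synaptic input is accumulated from integer
#' per-distance-class spike counts, which makes the dynamics exactly
#' symmetric under grid rotations; with synaptic jitter explicit sparse
#' weight matrices are used instead.
#'
#' @slot manifold the [GridManifold-class].
#' @slot cfg the [SynapseConfig-class].
#' @slot excParams,inhParams [IzhikevichParams-class] (scalar or per-neuron).
#' @slot adj list of sparse 0/1 adjacency matrices, one per distance class.
#' @slot adjDist numeric vector of the distance classes.
#' @slot wEE,wEI,wIE explicit sparse weight matrices (jittered setups) or
#'   \code{NULL}.
#' @slot ieSelf numeric per-node weight of the d = 0 i-to-e projection.
#' @slot stim numeric per-node DC current.
#' @slot vE,uE,vI,uI numeric per-node state variables.
#' @slot spikedE,spikedI logical per-node spike flags for the current step.
#' @slot t numeric simulation time in ms.
#' @seealso [buildWaveLayer()], [stepWaveLayer()]
#' @export
setClass("WaveLayer",
  representation(manifold = "GridManifold", cfg = "SynapseConfig",
                 excParams = "IzhikevichParams", inhParams = "IzhikevichParams",
                 adj = "list", adjDist = "numeric",
                 wEE = "ANY", wEI = "ANY", wIE = "ANY", ieSelf = "numeric",
                 stim = "numeric",
                 vE = "numeric", uE = "numeric", vI = "numeric", uI = "numeric",
                 spikedE = "logical", spikedI = "logical", t = "numeric"))

#' Continuous attractor layer configuration
#'
#' Parameters of the shifted-Gaussian recurrent kernel
#' \deqn{w_{ij} = J \exp(-\|\,((i_x-j_x)/N_x, (i_y-j_y)/N_y) + \Delta\|^2
#'   / \sigma^2) - T}
#' and of the rate update. Offsets are divided by the sheet dimensions, so
#' \code{sigma}, \code{T} and the direction vector live in normalized
#' coordinates.
#'
#' @slot J synaptic strength scale (default 12).
#' @slot sigma Gaussian width in normalized coordinates (default 0.03).
#' @slot T uniform inhibitory shift (default 0.05).
#' @slot tau stabilization mixing weight in [0, 1] (default 0.8).
#' @slot normalize logical; keep total activation at 1 after each update
#'   (default TRUE). The literal rate update is degree-1 homogeneous in the
#'   activation, so without renormalization the amplitude grows without
#'   bound; with total activation 1 the update reduces exactly to A = B.
#' @export
setClass("AttractorConfig",
  representation(J = "numeric", sigma = "numeric", T = "numeric",
                 tau = "numeric", normalize = "logical"),
  prototype(J = 12, sigma = 0.03, T = 0.05, tau = 0.8, normalize = TRUE),
  validity = function(object) {
    msg <- character()
    if (object@J <= 0) msg <- c(msg, "'J' must be positive")
    if (object@sigma <= 0) msg <- c(msg, "'sigma' must be positive")
    if (object@T < 0) msg <- c(msg, "'T' must be nonnegative")
    if (object@tau < 0 || object@tau > 1)
      msg <- c(msg, "'tau' must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Continuous attractor layer state
#'
#' @slot A nonnegative activation matrix (\code{nx} by \code{ny}); zero on
#'   clamped (blocked) nodes.
#' @slot delta current direction vector in normalized coordinates.
#' @slot t numeric simulation time in ms.
#' @seealso [initializeBump()], [attractorStep()], [bumpCenter()]
#' @export
setClass("AttractorState",
  representation(A = "matrix", delta = "numeric", t = "numeric"),
  validity = function(object) {
    if (any(object@A < 0)) return("activation must be nonnegative")
    if (length(object@delta) != 2L) return("'delta' must have length 2")
    TRUE
  })

#' Planner (layer coupling) configuration
#'
#' @slot recoveryPeriod recovery period R in ms: after the bump has been
#'   moved by a wavefront, overlaps are ignored for this long, so each front
#'   interacts with the bump at most once (default 12).
#' @slot activeFrac relative activity threshold defining the bump's active
#'   set C_t: nodes with A >= activeFrac * max(A) (default 0.1).
#' @slot deltaGain magnitude of the normalized-coordinate direction vector
#'   handed to the attractor kernel per wavefront (default 0.08, a kernel
#'   shift of about 3 nodes on a 41-grid, below half the bump width).
#' @slot holdSteps number of attractor steps the direction vector is held
#'   before being reset to zero (default 1).
#' @slot maxSteps simulation budget in ms (default 6000).
#' @slot arrivalRadius termination distance from the target in grid units
#'   (default 6, about half the bump diameter).
#' @export
setClass("PlannerConfig",
  representation(recoveryPeriod = "integer", activeFrac = "numeric",
                 deltaGain = "numeric", holdSteps = "integer",
                 maxSteps = "integer", arrivalRadius = "numeric"),
  prototype(recoveryPeriod = 12L, activeFrac = 0.1, deltaGain = 0.08,
            holdSteps = 1L, maxSteps = 6000L, arrivalRadius = 6),
  validity = function(object) {
    msg <- character()
    if (object@recoveryPeriod < 0L) msg <- c(msg, "'recoveryPeriod' must be >= 0")
    if (object@activeFrac <= 0 || object@activeFrac >= 1)
      msg <- c(msg, "'activeFrac' must be in (0, 1)")
    if (object@deltaGain <= 0) msg <- c(msg, "'deltaGain' must be positive")
    if (object@holdSteps < 1L) msg <- c(msg, "'holdSteps' must be >= 1")
    if (object@maxSteps <= 0L) msg <- c(msg, "'maxSteps' must be positive")
    if (object@arrivalRadius < 0) msg <- c(msg, "'arrivalRadius' must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Record of a coupled planning run
#'
#' @slot trajectory data.frame with columns \code{t_ms}, \code{x}, \code{y}:
#'   the bump center every time it changed (plus the initial center at t=0).
#' @slot raster data.frame with columns \code{t_ms}, \code{population}
#'   ("exc"/"inh"), \code{node_x}, \code{node_y}: all spikes of the run.
#' @slot status "arrived", "budget_exhausted" or "collapsed".
#' @slot pathHops integer, number of distinct successive bump centers minus 1.
#' @slot bfsHops integer, BFS hop distance start-to-target on the range-dE
#'   connectivity graph.
#' @slot efficiency numeric, \code{pathHops / bfsHops} (NA unless arrived).
#' @slot arrivalTime numeric, ms at arrival (NA unless arrived).
#' @slot seed integer seed used.
#' @slot configs list echoing the effective configuration.
#' @seealso [runPlanner()], [pathEfficiency()]
#' @export
setClass("PlannerRun",
  representation(trajectory = "data.frame", raster = "data.frame",
                 status = "character", pathHops = "integer",
                 bfsHops = "integer", efficiency = "numeric",
                 arrivalTime = "numeric", seed = "integer", configs = "list"))

#' Full simulation configuration
#'
#' Bundles grid, maze, endpoints, all layer configurations, heterogeneity
#' settings and the seed. Defaults reproduce the reference homogeneous
#' 41 x 41 setup. Serializes losslessly to JSON via [saveConfig()] /
#' [loadConfig()].
#'
#' @slot nx,ny grid dimensions.
#' @slot mazeKind one of "open", "s_maze", "blocks", "fine_structure",
#'   or "file" (mask read from \code{maskFile}).
#' @slot mazeParams named list of shape parameters for [makeMaze()].
#' @slot maskFile path of a plain-text mask file (only for mazeKind "file").
#' @slot start,target integer (x, y) node coordinates, 0-based.
#' @slot synapse [SynapseConfig-class].
#' @slot attractor [AttractorConfig-class].
#' @slot planner [PlannerConfig-class].
#' @slot heterogeneity [HeterogeneityConfig-class].
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(nx = "integer", ny = "integer", mazeKind = "character",
                 mazeParams = "list", maskFile = "character",
                 start = "integer", target = "integer",
                 synapse = "SynapseConfig", attractor = "AttractorConfig",
                 planner = "PlannerConfig",
                 heterogeneity = "HeterogeneityConfig", seed = "integer"),
  prototype(nx = 41L, ny = 41L, mazeKind = "open", mazeParams = list(),
            maskFile = NA_character_, start = c(5L, 5L), target = c(35L, 35L),
            seed = 1L),
  validity = function(object) {
    kinds <- c("open", "s_maze", "blocks", "fine_structure", "file")
    if (!object@mazeKind %in% kinds)
      return(sprintf("mazeKind must be one of %s",
                     paste(kinds, collapse = ", ")))
    if (length(object@start) != 2L || length(object@target) != 2L)
      return("'start' and 'target' must be (x, y) pairs")
    TRUE
  })
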