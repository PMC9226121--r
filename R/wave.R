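## Wave propagation layer: paired excitatory/inhibitory Izhikevich sheets on
## the grid, distance-decaying synapses, DC target stimulation, 1 ms stepping.

#' Reference Izhikevich phenotypes
#'
#' @param n optional number of neurons (recycles scalars to vectors)
#' @return an [IzhikevichParams-class]: regular spiking (RS, excitatory
#'   default) or fast spiking (FS, inhibitory default)
#' @export
rsParams <- function(n = 1L)
  new("IzhikevichParams", a = rep(0.02, n), b = rep(0.2, n),
      c = rep(-65, n), d = rep(8, n))

#' @rdname rsParams
#' @export
fsParams <- function(n = 1L)
  new("IzhikevichParams", a = rep(0.1, n), b = rep(0.2, n),
      c = rep(-65, n), d = rep(2, n))

#' Distance-dependent synaptic strengths
#'
#' \code{synapticStrengthEE}: excitatory-to-excitatory, \code{sEEMax / d} for
#' 0 < d <= dE, zero otherwise (in particular zero at d = 0, preventing
#' self-excitation). \code{synapticStrengthEI}: excitatory-to-inhibitory,
#' analogous with peak \code{sEIFactor * sEEMax} and range dI.
#' \code{synapticStrengthIE}: inhibitory-to-excitatory, full (negative) peak
#' \code{sIEFactor * sEEMax} at d = 0, peak / d for 0 < d <= dS, zero beyond.
#'
#' @param d Euclidean distance(s) in grid units, nonnegative
#' @param cfg a [SynapseConfig-class]
#' @return numeric strength(s)
#' @examples
#' cfg <- new("SynapseConfig")
#' synapticStrengthEE(1, cfg)  # 50
#' synapticStrengthEE(0, cfg)  # 0
#' synapticStrengthIE(0, cfg)  # -450
#' @export
synapticStrengthEE <- function(d, cfg) {
  if (any(d < 0)) stop("contract violation: negative distance")
  ifelse(d > 0 & d <= cfg@dE, cfg@sEEMax / d, 0)
}

#' @rdname synapticStrengthEE
#' @export
synapticStrengthEI <- function(d, cfg) {
  if (any(d < 0)) stop("contract violation: negative distance")
  ifelse(d > 0 & d <= cfg@dI, cfg@sEIFactor * cfg@sEEMax / d, 0)
}

#' @rdname synapticStrengthEE
#' @export
synapticStrengthIE <- function(d, cfg) {
  if (any(d < 0)) stop("contract violation: negative distance")
  peak <- cfg@sIEFactor * cfg@sEEMax
  ifelse(d == 0, peak, ifelse(d <= cfg@dS, peak / d, 0))
}

#' One forward-Euler step of the Izhikevich model
#'
#' Advances \code{dv/dt = 0.04 v^2 + 5 v + 140 - u + I} and
#' \code{du/dt = a (b v - u)} by one step of length \code{dt}, with both
#' derivatives evaluated at the incoming state. Any neuron whose updated
#' potential reaches 30 mV is flagged as spiked and reset (\code{v <- c},
#' \code{u <- u + d}). The membrane potential is floored at \code{vFloor}
#' before spike detection: with impulse synaptic currents a 1 ms Euler step
#' can otherwise push v so far negative that the quadratic term diverges.
#'
#' @param v,u numeric state vectors
#' @param params an [IzhikevichParams-class] (scalar or per-neuron)
#' @param I input current (synaptic plus DC), recycled
#' @param dt step length in ms, positive (default 1)
#' @param vFloor numeric lower bound on v (default -90)
#' @return list with elements \code{v}, \code{u}, \code{spiked}
#' @examples
#' st <- izhikevichStep(-70, -14, rsParams(), I = 0)  # resting fixed point
#' c(st$v, st$u)  # unchanged
#' @export
izhikevichStep <- function(v, u, params, I, dt = 1, vFloor = -90) {
  if (dt <= 0) stop("'dt' must be positive")
  v2 <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  u2 <- u + dt * params@a * (params@b * v - u)
  v2 <- pmax(v2, vFloor)
  if (!all(is.finite(v2)) || !all(is.finite(u2)))
    stop("numerical divergence in the Izhikevich step")
  spiked <- v2 >= 30
  if (any(spiked)) {
    cc <- if (length(params@c) > 1L) params@c[spiked] else params@c
    dd <- if (length(params@d) > 1L) params@d[spiked] else params@d
    v2[spiked] <- cc
    u2[spiked] <- u2[spiked] + dd
  }
  list(v = v2, u = u2, spiked = spiked)
}

#' Randomized per-neuron parameters (heterogeneous setup)
#'
#' Excitatory neurons interpolate between regular spiking (r = 0) and
#' chattering (r = 1) via \code{c = -65 + 15 r^2}, \code{d = 8 - 6 r^2}
#' (squaring biases the distribution towards RS); inhibitory neurons
#' interpolate between low-threshold spiking (r = 0) and fast spiking
#' (r = 1) via \code{a = 0.02 + 0.08 r}, \code{b = 0.25 - 0.05 r}.
#'
#' @param n number of neurons per population
#' @param seed integer RNG seed (reproducible)
#' @return list with [IzhikevichParams-class] elements \code{exc} and
#'   \code{inh} and the uniform draws \code{rE}, \code{rI}
#' @export
randomizeNeuronParams <- function(n, seed) {
  set.seed(as.integer(seed))
  rE <- stats::runif(n)
  rI <- stats::runif(n)
  list(
    exc = new("IzhikevichParams", a = rep(0.02, n), b = rep(0.2, n),
              c = -65 + 15 * rE^2, d = 8 - 6 * rE^2),
    inh = new("IzhikevichParams", a = 0.02 + 0.08 * rI, b = 0.25 - 0.05 * rI,
              c = rep(-65, n), d = rep(2, n)),
    rE = rE, rI = rI)
}

#' Multiplicative jitter of nonzero synaptic weights
#'
#' Each nonzero weight w is replaced by w (1 + e) with e drawn independently
#' and uniformly from [-fraction, +fraction]; zeros stay zero and signs are
#' preserved for fraction < 1.
#'
#' @param W a sparse weight matrix (\pkg{Matrix})
#' @param seed integer RNG seed
#' @param fraction relative jitter amplitude in [0, 1) (default 0.10)
#' @return the jittered matrix
#' @export
jitterSynapses <- function(W, seed, fraction = 0.10) {
  if (fraction < 0 || fraction >= 1)
    stop("'fraction' must be in [0, 1)")
  if (fraction == 0) return(W)
  set.seed(as.integer(seed))
  W@x <- W@x * (1 + stats::runif(length(W@x), -fraction, fraction))
  W
}

## distance-class adjacency between free nodes, one sparse 0/1 matrix per
## exact distance value (blocked nodes are isolated: their synapses are zero)
.distanceClassAdjacency <- function(manifold, range) {
  nx <- manifold@nx; ny <- manifold@ny; n <- nx * ny
  offs <- .latticeOffsets(range)
  classes <- sort(unique(offs$d))
  xs <- rep(0:(nx - 1L), ny)
  ys <- rep(0:(ny - 1L), each = nx)
  free <- !as.vector(manifold@blocked)
  adj <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    oo <- offs[abs(offs$d - classes[k]) < 1e-9, ]
    ii <- integer(0); jj <- integer(0)
    for (r in seq_len(nrow(oo))) {
      x2 <- xs + oo$dx[r]; y2 <- ys + oo$dy[r]
      ok <- x2 >= 0L & x2 < nx & y2 >= 0L & y2 < ny
      i0 <- which(ok)
      j0 <- nodeId(x2[ok], y2[ok], nx) + 1L
      keep <- free[i0] & free[j0]
      ii <- c(ii, i0[keep]); jj <- c(jj, j0[keep])
    }
    adj[[k]] <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  }
  list(adj = adj, d = classes)
}

#' Build the wave propagation layer
#'
#' Constructs the paired excitatory/inhibitory populations on the manifold,
#' wires the three synapse classes, and initializes all neurons at the
#' deterministic resting fixed point v = -70, u = b v (no randomized initial
#' conditions, for reproducible analyses). Blocked nodes get all incoming
#' and outgoing weights zeroed and are never stimulated.
#'
#' With \code{het@enabled}, per-neuron parameters come from
#' [randomizeNeuronParams()] (seed \code{het@seed}) and all weights are
#' jittered with [jitterSynapses()] (seeds derived from \code{het@seed}).
#'
#' @param manifold a [GridManifold-class]
#' @param cfg a [SynapseConfig-class]
#' @param stimNodes list/matrix of (x, y) nodes receiving the DC current
#'   \code{cfg@iDC} every step, or NULL
#' @param het a [HeterogeneityConfig-class]
#' @return a [WaveLayer-class]
#' @export
buildWaveLayer <- function(manifold, cfg = new("SynapseConfig"),
                           stimNodes = NULL,
                           het = new("HeterogeneityConfig")) {
  stopifnot(is(manifold, "GridManifold"), is(cfg, "SynapseConfig"))
  n <- manifold@nx * manifold@ny
  free <- !as.vector(manifold@blocked)
  dcl <- .distanceClassAdjacency(manifold, max(cfg@dE, cfg@dI, cfg@dS))
  stim <- numeric(n)
  if (!is.null(stimNodes)) {
    if (!is.list(stimNodes)) stimNodes <- list(stimNodes)
    for (nd in stimNodes) {
      nd <- .checkNode(manifold, nd)
      stim[nodeId(nd[1], nd[2], manifold@nx) + 1L] <- cfg@iDC
    }
  }
  iePeak <- cfg@sIEFactor * cfg@sEEMax
  ieSelf <- ifelse(free, iePeak, 0)
  wEE <- wEI <- wIE <- NULL
  if (het@enabled) {
    pars <- randomizeNeuronParams(n, het@seed)
    excParams <- pars$exc; inhParams <- pars$inh
    mk <- function(strengths) {
      keep <- which(strengths != 0)
      Reduce(`+`, Map(function(a, s) s * a, dcl$adj[keep], strengths[keep]))
    }
    wEE <- jitterSynapses(mk(synapticStrengthEE(dcl$d, cfg)),
                          het@seed + 1L, het@jitterFraction)
    wEI <- jitterSynapses(mk(synapticStrengthEI(dcl$d, cfg)),
                          het@seed + 2L, het@jitterFraction)
    wIE <- mk(synapticStrengthIE(dcl$d, cfg)) +
      Matrix::Diagonal(n, x = ieSelf)
    wIE <- jitterSynapses(methods::as(wIE, "CsparseMatrix"),
                          het@seed + 3L, het@jitterFraction)
  } else {
    excParams <- rsParams()
    inhParams <- fsParams()
  }
  vE <- rep(-70, n); vI <- rep(-70, n)
  new("WaveLayer", manifold = manifold, cfg = cfg,
      excParams = excParams, inhParams = inhParams,
      adj = dcl$adj, adjDist = dcl$d,
      wEE = wEE, wEI = wEI, wIE = wIE, ieSelf = ieSelf, stim = stim,
      vE = vE, uE = excParams@b * vE, vI = vI, uI = inhParams@b * vI,
      spikedE = logical(n), spikedI = logical(n), t = 0)
}

#' Synaptic input currents from the previous step's spikes
#'
#' Each neuron's current is the sum of incoming synaptic strengths from
#' neurons that spiked in the previous step, plus the DC current on
#' stimulated nodes. Spikes act as instantaneous delta currents one step
#' later (no temporal filtering, no transmission delay).
#'
#' @param layer a [WaveLayer-class]
#' @return list with numeric vectors \code{Ie} (onto excitatory neurons) and
#'   \code{Ii} (onto inhibitory neurons)
#' @export
gatherSynapticInput <- function(layer) {
  n <- length(layer@vE)
  Ie <- layer@stim
  Ii <- numeric(n)
  if (!is.null(layer@wEE)) {           # jittered explicit-weight path
    if (any(layer@spikedE)) {
      xe <- as.numeric(layer@spikedE)
      Ie <- Ie + as.numeric(Matrix::crossprod(layer@wEE, xe))
      Ii <- Ii + as.numeric(Matrix::crossprod(layer@wEI, xe))
    }
    if (any(layer@spikedI))
      Ie <- Ie + as.numeric(Matrix::crossprod(layer@wIE,
                                              as.numeric(layer@spikedI)))
    return(list(Ie = Ie, Ii = Ii))
  }
  ## homogeneous path: integer spike counts per distance class, then one
  ## weighted combination -- exactly rotation-symmetric
  cfg <- layer@cfg
  sEE <- synapticStrengthEE(layer@adjDist, cfg)
  sEI <- synapticStrengthEI(layer@adjDist, cfg)
  sIE <- synapticStrengthIE(layer@adjDist, cfg)
  if (any(layer@spikedE)) {
    xe <- as.numeric(layer@spikedE)
    for (k in seq_along(layer@adj)) {
      if (sEE[k] == 0 && sEI[k] == 0) next
      cnt <- as.numeric(Matrix::crossprod(layer@adj[[k]], xe))
      if (sEE[k] != 0) Ie <- Ie + sEE[k] * cnt
      if (sEI[k] != 0) Ii <- Ii + sEI[k] * cnt
    }
  }
  if (any(layer@spikedI)) {
    xi <- as.numeric(layer@spikedI)
    Ie <- Ie + layer@ieSelf * xi
    for (k in seq_along(layer@adj)) {
      if (sIE[k] == 0) next
      Ie <- Ie + sIE[k] * as.numeric(Matrix::crossprod(layer@adj[[k]], xi))
    }
  }
  list(Ie = Ie, Ii = Ii)
}

#' Advance the wave layer by one time step
#'
#' Gathers currents from the previous step's spikes, advances both
#' populations with one Euler step, updates the spike flags and the clock.
#'
#' @param layer a [WaveLayer-class]
#' @param dt step in ms (default 1, the reference value)
#' @return the updated [WaveLayer-class]
#' @export
stepWaveLayer <- function(layer, dt = 1) {
  inp <- gatherSynapticInput(layer)
  e <- izhikevichStep(layer@vE, layer@uE, layer@excParams, inp$Ie,
                      dt = dt, vFloor = layer@cfg@vFloor)
  i <- izhikevichStep(layer@vI, layer@uI, layer@inhParams, inp$Ii,
                      dt = dt, vFloor = layer@cfg@vFloor)
  layer@vE <- e$v; layer@uE <- e$u; layer@spikedE <- e$spiked
  layer@vI <- i$v; layer@uI <- i$u; layer@spikedI <- i$spiked
  layer@t <- layer@t + dt
  layer
}

#' Run the wave layer for a fixed duration
#'
#' Convenience driver around [stepWaveLayer()], recording the spike raster
#' and each excitatory neuron's first spike time.
#'
#' @param layer a [WaveLayer-class]
#' @param duration simulated time in ms
#' @param recordRaster logical; collect the full raster (default TRUE)
#' @return list with the final \code{layer}, \code{raster} (data.frame
#'   t_ms, population, node_x, node_y), \code{firstSpikeE} (numeric per-node
#'   vector, NA if never spiked), and \code{excPerStep} (integer vector of
#'   per-step excitatory spike counts)
#' @export
simulateWaveLayer <- function(layer, duration, recordRaster = TRUE) {
  n <- length(layer@vE)
  nx <- layer@manifold@nx
  first <- rep(NA_real_, n)
  counts <- integer(duration)
  rt <- list(); k <- 0L
  for (step in seq_len(duration)) {
    layer <- stepWaveLayer(layer)
    counts[step] <- sum(layer@spikedE)
    newly <- is.na(first) & layer@spikedE
    first[newly] <- layer@t
    if (recordRaster && (any(layer@spikedE) || any(layer@spikedI))) {
      k <- k + 1L
      rt[[k]] <- list(t = layer@t, e = which(layer@spikedE) - 1L,
                      i = which(layer@spikedI) - 1L)
    }
  }
  raster <- .rasterFrame(rt, nx)
  list(layer = layer, raster = raster, firstSpikeE = first,
       excPerStep = counts)
}

.rasterFrame <- function(rt, nx) {
  if (!length(rt))
    return(data.frame(t_ms = numeric(0), population = character(0),
                      node_x = integer(0), node_y = integer(0)))
  parts <- lapply(rt, function(z) {
    ids <- c(z$e, z$i)
    if (!length(ids)) return(NULL)
    xy <- nodeXY(ids, nx)
    data.frame(t_ms = z$t,
               population = rep(c("exc", "inh"),
                                c(length(z$e), length(z$i))),
               node_x = xy[, 1], node_y = xy[, 2])
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
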