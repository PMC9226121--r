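## Continuous attractor layer: rate-coded sheet with a shifted-Gaussian
## recurrent kernel sustaining a localized bump of activity.

#' Recurrent kernel weight between two sheet positions
#'
#' Exact evaluation of
#' \deqn{w_{ij} = J \exp(-\|((i_x-j_x)/N_x, (i_y-j_y)/N_y) + \Delta\|^2
#'   / \sigma^2) - T.}
#' Offsets are divided by the sheet dimensions before the direction vector
#' is added, so everything inside the norm lives in normalized coordinates.
#'
#' @param i,j (x, y) 0-based node coordinates
#' @param delta direction vector (normalized coordinates), length 2
#' @param cfg an [AttractorConfig-class]
#' @param nx,ny sheet dimensions
#' @return numeric weight
#' @examples
#' cfg <- new("AttractorConfig")
#' attractorWeight(c(5, 5), c(5, 5), c(0, 0), cfg, 41, 41)  # J - T = 11.95
#' @export
attractorWeight <- function(i, j, delta = c(0, 0), cfg, nx, ny) {
  off <- c((i[1] - j[1]) / nx, (i[2] - j[2]) / ny) + delta
  cfg@J * exp(-sum(off^2) / cfg@sigma^2) - cfg@T
}

## separable convolution with the shifted Gaussian part of the kernel:
## out_j = sum_o A_{j+o} exp(-((o_x/nx + dx)^2 + (o_y/ny + dy)^2)/sigma^2),
## truncated where the factor drops below ~1e-12, zero-padded at the edges
## (the sheet is planar, kernel sums simply truncate at boundaries).
.kernelConvolve <- function(A, delta, sigma) {
  nx <- nrow(A); ny <- ncol(A)
  K <- ceiling(max(nx, ny) * (sigma * sqrt(log(1e12)) + max(abs(delta)))) + 1L
  kx <- exp(-(((-K):K) / nx + delta[1])^2 / sigma^2)
  ky <- exp(-(((-K):K) / ny + delta[2])^2 / sigma^2)
  M <- matrix(0, nx, ny)
  for (o in (-K):K) {
    w <- kx[o + K + 1L]
    if (w < 1e-300) next
    src <- max(1L, 1L + o):min(nx, nx + o)
    M[src - o, ] <- M[src - o, ] + w * A[src, ]
  }
  B <- matrix(0, nx, ny)
  for (o in (-K):K) {
    w <- ky[o + K + 1L]
    if (w < 1e-300) next
    src <- max(1L, 1L + o):min(ny, ny + o)
    B[, src - o] <- B[, src - o] + w * M[, src]
  }
  B
}

#' One attractor layer update
#'
#' Computes the transfer \eqn{B_j = \sum_i A_i w_{ij}} with the current
#' direction vector, applies the stabilized rate update
#' \eqn{A' = (1-\tau) B + \tau B / \sum_i A_i}, clips negative rates to
#' zero, clamps blocked nodes to zero, and (by default) renormalizes the
#' total activation to 1. The renormalization is required for a stable
#' amplitude: the literal update is degree-1 homogeneous in A, and with the
#' reference parameters its spectral gain is about 10 per step. With total
#' activation 1 the stabilized update reduces exactly to A' = B.
#'
#' @param state an [AttractorState-class]
#' @param cfg an [AttractorConfig-class]
#' @param blocked optional logical nx by ny mask clamped to zero
#' @param dt time increment added to the state clock (default 1 ms)
#' @return the updated [AttractorState-class]
#' @export
attractorStep <- function(state, cfg, blocked = NULL, dt = 1) {
  A <- state@A
  S <- sum(A)
  if (S <= 0) stop("collapsed bump: total activation is zero")
  B <- cfg@J * .kernelConvolve(A, state@delta, cfg@sigma) - cfg@T * S
  A2 <- (1 - cfg@tau) * B + cfg@tau * B / S
  A2[A2 < 0] <- 0
  if (!is.null(blocked)) A2[blocked] <- 0
  S2 <- sum(A2)
  if (S2 <= 0) stop("collapsed bump: total activation is zero")
  if (cfg@normalize) A2 <- A2 / S2
  new("AttractorState", A = A2, delta = state@delta, t = state@t + dt)
}

#' Seed and relax a bump at a start node
#'
#' Places unit activation on the start node and iterates [attractorStep()]
#' with a zero direction vector until the maximum per-step change of A drops
#' below \code{tol}, yielding the stable radially symmetric bump centered on
#' the start node.
#'
#' @param manifold a [GridManifold-class] (its mask is clamped)
#' @param start (x, y) 0-based coordinates of a free node
#' @param cfg an [AttractorConfig-class]
#' @param tol relaxation tolerance on max |A' - A| (default 1e-8)
#' @param budget maximum number of relaxation steps (default 2000; an open
#'   sheet converges in about 860 steps, narrow corridors take up to ~1200)
#' @return a relaxed [AttractorState-class] with \code{t = 0}
#' @export
initializeBump <- function(manifold, start, cfg = new("AttractorConfig"),
                           tol = 1e-8, budget = 2000L) {
  stopifnot(is(manifold, "GridManifold"))
  start <- .checkNode(manifold, start)
  A <- matrix(0, manifold@nx, manifold@ny)
  A[start[1] + 1L, start[2] + 1L] <- 1
  st <- new("AttractorState", A = A, delta = c(0, 0), t = 0)
  blocked <- manifold@blocked
  for (i in seq_len(budget)) {
    st2 <- attractorStep(st, cfg, blocked, dt = 0)
    dmax <- max(abs(st2@A - st@A))
    st <- st2
    if (dmax < tol) return(st)
  }
  stop(sprintf("initialization error: bump did not relax within %d steps",
               budget))
}

#' @describeIn bumpCenter node of maximal activation (ties: smallest node id)
#' @export
setMethod("bumpCenter", "AttractorState", function(x) {
  if (sum(x@A) <= 0) stop("collapsed bump: total activation is zero")
  idx <- which.max(x@A) - 1L          # column-major index == node id
  as.integer(nodeXY(idx, nrow(x@A))[1, ])
})

#' @describeIn activeSet nodes with A >= frac * max(A)
#' @export
setMethod("activeSet", "AttractorState", function(x, frac = 0.1) {
  if (frac <= 0 || frac >= 1) stop("'frac' must be in (0, 1)")
  m <- max(x@A)
  if (m <= 0) stop("collapsed bump: total activation is zero")
  which(x@A >= frac * m) - 1L
})

#' @describeIn bumpDiameter extent of the active set along x through the
#'   bump center
#' @export
setMethod("bumpDiameter", "AttractorState", function(x, frac = 0.1) {
  ctr <- bumpCenter(x)
  act <- x@A[, ctr[2] + 1L] >= frac * max(x@A)
  xs <- which(act)
  as.integer(max(xs) - min(xs) + 1L)
})
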