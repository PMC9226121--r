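## Independent oracles used to cross-check the package implementations.

## Brute-force BFS over a masked grid: plain queue, neighbor offsets
## recomputed from scratch. Independent of igraph and of the package's
## connectivity construction.
bruteBFS <- function(mask, src, range) {
  nx <- nrow(mask); ny <- ncol(mask)
  K <- ceiling(range)
  offs <- expand.grid(dx = -K:K, dy = -K:K)
  offs$d <- sqrt(offs$dx^2 + offs$dy^2)
  offs <- offs[offs$d > 0 & offs$d <= range + 1e-12, ]
  dist <- matrix(NA_integer_, nx, ny)
  dist[src[1] + 1, src[2] + 1] <- 0L
  queue <- list(src)
  while (length(queue)) {
    nxt <- list()
    for (nd in queue) {
      for (r in seq_len(nrow(offs))) {
        x2 <- nd[1] + offs$dx[r]; y2 <- nd[2] + offs$dy[r]
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny) next
        if (mask[x2 + 1, y2 + 1]) next
        if (!is.na(dist[x2 + 1, y2 + 1])) next
        dist[x2 + 1, y2 + 1] <- dist[nd[1] + 1, nd[2] + 1] + 1L
        nxt[[length(nxt) + 1]] <- c(x2, y2)
      }
    }
    queue <- nxt
  }
  as.integer(dist)  # node-id order
}

## Literal dense attractor update: full weight matrix from attractorWeight(),
## explicit sums for the transfer and stabilized rate update. O(n^2); used
## on small sheets only.
denseAttractorStep <- function(A, delta, cfg, blocked = NULL,
                               normalize = TRUE) {
  nx <- nrow(A); ny <- ncol(A)
  n <- nx * ny
  ids <- 0:(n - 1)
  xs <- ids %% nx; ys <- ids %/% nx
  S <- sum(A)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    offx <- (xs[i] - xs) / nx + delta[1]
    offy <- (ys[i] - ys) / ny + delta[2]
    W[i, ] <- cfg@J * exp(-(offx^2 + offy^2) / cfg@sigma^2) - cfg@T
  }
  B <- as.numeric(as.vector(A) %*% W)
  A2 <- (1 - cfg@tau) * B + cfg@tau * B / S
  A2[A2 < 0] <- 0
  A2 <- matrix(A2, nx, ny)
  if (!is.null(blocked)) A2[blocked] <- 0
  if (normalize) A2 <- A2 / sum(A2)
  A2
}

## Direct scalar integration of the two Izhikevich ODEs (independent loop,
## no package code) returning the step of the first threshold crossing.
izhFirstSpikeOracle <- function(a, b, c, d, I, v0 = -70, u0 = b * -70,
                                steps = 200) {
  v <- v0; u <- u0
  for (k in seq_len(steps)) {
    v2 <- v + 0.04 * v^2 + 5 * v + 140 - u + I
    u2 <- u + a * (b * v - u)
    v <- v2; u <- u2
    if (v >= 30) return(k)
  }
  NA_integer_
}

## flood fill over a logical matrix (4-connectivity), for unimodality checks
connectedComponents <- function(act) {
  nx <- nrow(act); ny <- ncol(act)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    if (!act[x, y] || lab[x, y] != 0L) next
    cur <- cur + 1L
    queue <- list(c(x, y)); lab[x, y] <- cur
    while (length(queue)) {
      nd <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        p <- nd + o
        if (p[1] < 1 || p[1] > nx || p[2] < 1 || p[2] > ny) next
        if (act[p[1], p[2]] && lab[p[1], p[2]] == 0L) {
          lab[p[1], p[2]] <- cur
          queue[[length(queue) + 1]] <- p
        }
      }
    }
  }
  cur
}

refManifold <- function() buildManifold(41, 41)
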