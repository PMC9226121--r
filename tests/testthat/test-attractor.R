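cfgA <- new("AttractorConfig")

test_that("attractor kernel weight matches the closed form", {
  expect_equal(attractorWeight(c(5, 5), c(5, 5), c(0, 0), cfgA, 41, 41),
               11.95)
  expect_equal(attractorWeight(c(0, 0), c(40, 40), c(0, 0), cfgA, 41, 41),
               -0.05, tolerance = 1e-6)
  for (pair in list(list(c(3, 4), c(7, 9)), list(c(0, 0), c(1, 2)))) {
    expect_equal(
      attractorWeight(pair[[1]], pair[[2]], c(0, 0), cfgA, 41, 41),
      attractorWeight(pair[[2]], pair[[1]], c(0, 0), cfgA, 41, 41))
  }
})

test_that("attractorStep equals the literal dense update", {
  set.seed(3)
  for (rep in 1:3) {
    A <- matrix(stats::runif(15 * 15), 15, 15)
    A <- A / sum(A)
    blocked <- matrix(stats::runif(225) < 0.1, 15, 15)
    A[blocked] <- 0
    for (delta in list(c(0, 0), c(0.05, 0), c(-0.03, 0.08))) {
      st <- new("AttractorState", A = A, delta = delta, t = 0)
      got <- attractorStep(st, cfgA, blocked)
      want <- denseAttractorStep(A, delta, cfgA, blocked)
      expect_equal(got@A, want, tolerance = 1e-9)
    }
  }
})

test_that("with unit total activation the stabilized update reduces to B", {
  set.seed(4)
  A <- matrix(stats::runif(121), 11, 11); A <- A / sum(A)
  st <- new("AttractorState", A = A, delta = c(0, 0), t = 0)
  cfgRaw <- new("AttractorConfig", normalize = FALSE)
  got <- attractorStep(st, cfgRaw)
  B <- denseAttractorStep(A, c(0, 0), cfgRaw, normalize = FALSE)
  expect_equal(got@A, B, tolerance = 1e-9)  # (1-tau)B + tau B / 1 = B
})

test_that("all-zero activation signals a collapsed bump", {
  st <- new("AttractorState", A = matrix(0, 5, 5), delta = c(0, 0), t = 0)
  expect_error(attractorStep(st, cfgA), "collapsed bump")
  expect_error(bumpCenter(st), "collapsed bump")
  expect_error(activeSet(st, 0.1), "collapsed bump")
})

test_that("a seeded bump relaxes to a stable, reproducible state", {
  m <- refManifold()
  st <- initializeBump(m, c(20, 20))
  expect_equal(bumpCenter(st), c(20L, 20L))
  st2 <- initializeBump(m, c(20, 20))
  expect_identical(st@A, st2@A)      # fully deterministic

  ## center constant and totals converged over 500 further steps
  before <- st@A
  for (i in 1:500) st <- attractorStep(st, cfgA, m@blocked)
  expect_equal(bumpCenter(st), c(20L, 20L))
  expect_lt(max(abs(st@A - before)), 1e-7)
  expect_equal(sum(st@A), 1, tolerance = 1e-12)

  expect_error(initializeBump(m, c(200, 5)), "invalid node")
  mask <- matrix(FALSE, 41, 41); mask[21, 21] <- TRUE
  expect_error(initializeBump(buildManifold(41, 41, mask), c(20, 20)),
               "blocked")
})

test_that("bump center uses argmax with smallest-node-id tie break", {
  A <- matrix(0, 5, 5)
  A[2, 2] <- 1                      # node (1, 1)
  st <- new("AttractorState", A = A, delta = c(0, 0), t = 0)
  expect_equal(bumpCenter(st), c(1L, 1L))
  A[4, 4] <- 1                      # tie at node (3, 3), larger id
  st@A <- A
  expect_equal(bumpCenter(st), c(1L, 1L))
})

test_that("active set thresholds relative to the maximum", {
  A <- matrix(1, 4, 4)
  st <- new("AttractorState", A = A, delta = c(0, 0), t = 0)
  expect_length(activeSet(st, 0.5), 16L)        # uniform field: all nodes
  expect_error(activeSet(st, 0), "frac")

  m <- refManifold()
  bump <- initializeBump(m, c(20, 20))
  near1 <- activeSet(bump, 0.999999)
  expect_equal(near1, nodeId(20, 20, 41))       # limit frac -> 1: argmax

  act <- activeSet(bump, 0.1)
  actMat <- matrix(FALSE, 41, 41)
  actMat[act + 1] <- TRUE
  expect_equal(connectedComponents(actMat), 1L) # single connected disk
})

test_that("bump diameter is close to twelve nodes and translation invariant", {
  m <- refManifold()
  bump <- initializeBump(m, c(20, 20))
  d0 <- bumpDiameter(bump, 0.1)
  expect_gte(d0, 11L)
  expect_lte(d0, 13L)

  for (seedNode in list(c(12, 16), c(26, 22))) {
    b <- initializeBump(m, seedNode)
    expect_equal(bumpCenter(b), as.integer(seedNode))
    expect_equal(bumpDiameter(b, 0.1), d0)
  }

  A <- matrix(0, 9, 9); A[5, 5] <- 1
  st <- new("AttractorState", A = A, delta = c(0, 0), t = 0)
  expect_equal(bumpDiameter(st, 0.1), 1L)       # degenerate single node
})

test_that("bump profiles at interior seeds agree after shifting", {
  m <- refManifold()
  b1 <- initializeBump(m, c(18, 20))@A
  b2 <- initializeBump(m, c(22, 20))@A
  shifted <- rbind(b2[5:41, ], matrix(0, 4, 41))  # shift -4 in x
  expect_equal(b1[1:33, ], shifted[1:33, ], tolerance = 1e-6)
})

test_that("a constant direction vector steers the bump monotonically", {
  m <- refManifold()
  st <- initializeBump(m, c(10, 20))
  st@delta <- c(0.01, 0)
  xs <- integer(0)
  for (i in 1:40) {
    st <- attractorStep(st, cfgA, m@blocked)
    xs <- c(xs, bumpCenter(st)[1])
  }
  expect_true(all(diff(xs) >= 0))
  expect_gt(xs[40], 10)
  expect_true(all(abs(diff(xs)) <= 2))
})
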