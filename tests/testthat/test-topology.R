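test_that("buildManifold validates dimensions, masks and free-node counts", {
  m <- buildManifold(41, 41)
  expect_equal(freeNodes(m), 1681L)

  mask <- matrix(FALSE, 3, 3); mask[2, 2] <- TRUE
  expect_equal(freeNodes(buildManifold(3, 3, mask)), 8L)

  expect_error(buildManifold(41, 41, matrix(FALSE, 5, 5)),
               "configuration error")
  expect_error(buildManifold(2, 5), "configuration error")
  expect_error(buildManifold(3, 3, matrix(TRUE, 3, 3)), "degenerate")
})

test_that("neighborsWithin returns exact distances and respects blocks", {
  m <- buildManifold(5, 5)
  nb1 <- neighborsWithin(m, c(2, 2), 1)
  expect_equal(nrow(nb1), 4L)
  expect_true(all(nb1$d == 1))

  nb2 <- neighborsWithin(m, c(2, 2), 2)
  expect_equal(nrow(nb2), 12L)
  expect_equal(sort(table(round(nb2$d, 6))), sort(c(`1` = 4L,
    `1.414214` = 4L, `2` = 4L)), ignore_attr = TRUE)

  expect_equal(nrow(neighborsWithin(m, c(0, 0), 1)), 2L)  # corner

  mask <- matrix(FALSE, 5, 5); mask[3, 2] <- TRUE  # block (2, 1)
  mb <- buildManifold(5, 5, mask)
  nb <- neighborsWithin(mb, c(2, 2), 1)
  expect_equal(nrow(nb), 3L)
  expect_false(nodeId(2, 1, 5) %in% nb$id)
  expect_error(neighborsWithin(mb, c(2, 1), 1), "blocked")
  expect_error(neighborsWithin(m, c(7, 0), 1), "invalid node")
})

test_that("neighborsWithin is symmetric and matches brute-force distances", {
  set.seed(7)
  for (rep in 1:3) {
    mask <- matrix(stats::runif(64) < 0.2, 8, 8)
    mask[1, 1] <- FALSE; mask[8, 8] <- FALSE
    if (sum(!mask) < 2) next
    m <- buildManifold(8, 8, mask)
    free <- which(!mask) - 1L
    for (id in free) {
      xy <- nodeXY(id, 8)[1, ]
      nb <- neighborsWithin(m, xy, 2)
      ## exactness against direct all-pairs computation
      oxy <- nodeXY(free, 8)
      dd <- sqrt((oxy[, 1] - xy[1])^2 + (oxy[, 2] - xy[2])^2)
      expected <- free[dd > 0 & dd <= 2]
      expect_setequal(nb$id, expected)
      expect_equal(nb$d, sqrt((nb$x - xy[1])^2 + (nb$y - xy[2])^2))
      ## symmetry
      for (k in seq_len(nrow(nb))) {
        back <- neighborsWithin(m, c(nb$x[k], nb$y[k]), 2)
        expect_true(id %in% back$id)
      }
    }
  }
})

test_that("bfsDistances matches hand cases and the brute-force oracle", {
  g1 <- connectivityGraph(buildManifold(3, 3), range = 1)
  d <- bfsDistances(g1, c(1, 1))
  expect_equal(d[nodeId(1, 1, 3) + 1], 0L)
  axis <- c(nodeId(0, 1, 3), nodeId(2, 1, 3), nodeId(1, 0, 3), nodeId(1, 2, 3))
  corners <- c(nodeId(0, 0, 3), nodeId(2, 0, 3), nodeId(0, 2, 3),
               nodeId(2, 2, 3))
  expect_true(all(d[axis + 1] == 1L))
  expect_true(all(d[corners + 1] == 2L))

  m5 <- buildManifold(5, 5)
  d1 <- bfsDistances(connectivityGraph(m5, 1), c(0, 0))
  expect_equal(d1[nodeId(4, 4, 5) + 1], 8L)
  d2 <- bfsDistances(connectivityGraph(m5, 2), c(0, 0))
  expect_equal(d2[nodeId(4, 4, 5) + 1],
               bruteBFS(matrix(FALSE, 5, 5), c(0, 0), 2)[nodeId(4, 4, 5) + 1])

  set.seed(11)
  for (rep in 1:3) {
    mask <- matrix(stats::runif(81) < 0.25, 9, 9)
    mask[1, 1] <- FALSE
    m <- buildManifold(9, 9, mask)
    for (rg in c(1, 2)) {
      got <- bfsDistances(connectivityGraph(m, rg), c(0, 0))
      expect_identical(got, bruteBFS(mask, c(0, 0), rg))
    }
  }

  mask <- matrix(FALSE, 5, 5); mask[2, 2] <- TRUE
  expect_error(bfsDistances(connectivityGraph(buildManifold(5, 5, mask), 1),
                            c(1, 1)), "blocked")
})

test_that("BFS distances change by at most one hop across an edge", {
  mask <- makeMaze("blocks", 41, 41)
  g <- connectivityGraph(buildManifold(41, 41, mask), range = 2)
  d <- bfsDistances(g, c(5, 5))
  e <- g@edges
  ok <- !is.na(d[e$from + 1]) & !is.na(d[e$to + 1])
  expect_true(all(abs(d[e$from + 1][ok] - d[e$to + 1][ok]) <= 1L))
})

test_that("connectivity graph edges are symmetric, self-free and unblocked", {
  mask <- makeMaze("s_maze", 41, 41)
  g <- connectivityGraph(buildManifold(41, 41, mask), range = 2)
  e <- g@edges
  expect_true(all(e$from < e$to))           # undirected, stored once
  expect_true(all(e$d > 0 & e$d <= 2))
  blockedIds <- which(as.vector(mask)) - 1L
  expect_false(any(e$from %in% blockedIds | e$to %in% blockedIds))
})

test_that("maze generators produce connected, well-formed masks", {
  expect_true(all(!makeMaze("open", 41, 41)))

  for (kind in c("s_maze", "blocks", "fine_structure")) {
    mask <- makeMaze(kind, 41, 41)
    expect_false(mask[6, 6])
    expect_false(mask[36, 36])
    d <- bfsDistances(connectivityGraph(buildManifold(41, 41, mask), 2),
                      c(5, 5))
    expect_false(is.na(d[nodeId(35, 35, 41) + 1]))
  }

  dOpen <- bfsDistances(connectivityGraph(buildManifold(41, 41), 2), c(5, 5))
  dS <- bfsDistances(connectivityGraph(
    buildManifold(41, 41, makeMaze("s_maze", 41, 41)), 2), c(5, 5))
  tgt <- nodeId(35, 35, 41) + 1
  expect_gt(dS[tgt], dOpen[tgt])

  rects <- list(c(9L, 9L, 17L, 17L), c(22L, 20L, 30L, 28L))
  mask <- makeMaze("blocks", 41, 41, params = list(rects = rects))
  inRect <- function(x, y) any(vapply(rects, function(r)
    x >= r[1] && x <= r[3] && y >= r[2] && y <= r[4], TRUE))
  ids <- which(mask, arr.ind = TRUE) - 1L
  expect_true(all(apply(ids, 1, function(p) inRect(p[1], p[2]))))

  expect_error(makeMaze("s_maze", 5, 5), "configuration error")
})

test_that("mask files round-trip bit-exactly", {
  mask <- makeMaze("fine_structure", 41, 41)
  path <- tempfile(fileext = ".txt")
  writeMask(mask, path)
  lines <- readLines(path)
  expect_length(lines, 41)
  expect_true(all(nchar(lines) == 41))
  expect_identical(readMask(path), mask)
  writeLines(c("..#", "..", "..."), path)
  expect_error(readMask(path), "unequal")
  writeLines(c("..x", "...", "..."), path)
  expect_error(readMask(path), "only")
})
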