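## Grid topology, obstacle masks, maze generators and the classical BFS
## oracle that the neural traversal is validated against.

#' Convert node coordinates to node ids and back
#'
#' Node ids are 0-based, row-major over y: \code{id = y * nx + x} with
#' 0-based coordinates. The id order coincides with R's column-major order
#' of an \code{nx} by \code{ny} matrix, so \code{id + 1} is the matrix index.
#'
#' @param x,y 0-based node coordinates (vectors allowed)
#' @param id 0-based node ids (vector allowed)
#' @param nx grid width
#' @return \code{nodeId}: integer ids; \code{nodeXY}: two-column integer
#'   matrix of (x, y)
#' @examples
#' nodeId(2, 1, nx = 41)        # 43
#' nodeXY(43, nx = 41)          # (2, 1)
#' @export
nodeId <- function(x, y, nx) as.integer(y) * as.integer(nx) + as.integer(x)

#' @rdname nodeId
#' @export
nodeXY <- function(id, nx) {
  id <- as.integer(id)
  cbind(x = id %% as.integer(nx), y = id %/% as.integer(nx))
}

#' Build a validated grid manifold
#'
#' @param nx,ny grid dimensions (at least 3)
#' @param blocked optional obstacle mask: a logical matrix of dimension
#'   \code{nx} by \code{ny} (element \code{[x+1, y+1]} = node \code{(x, y)}),
#'   or a logical vector of length \code{nx * ny} in node-id order, or
#'   \code{NULL} for a fully open grid.
#' @return a [GridManifold-class]
#' @examples
#' m <- buildManifold(41, 41)
#' freeNodes(m)  # 1681
#' @export
buildManifold <- function(nx, ny, blocked = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 3L || ny < 3L)
    stop("configuration error: grid dimensions must be at least 3 x 3")
  if (is.null(blocked)) {
    blocked <- matrix(FALSE, nx, ny)
  } else if (is.matrix(blocked)) {
    if (!identical(dim(blocked), c(nx, ny)))
      stop(sprintf("configuration error: mask is %d x %d, expected %d x %d",
                   nrow(blocked), ncol(blocked), nx, ny))
  } else {
    if (length(blocked) != nx * ny)
      stop(sprintf("configuration error: mask has %d entries, expected %d",
                   length(blocked), nx * ny))
    blocked <- matrix(as.logical(blocked), nx, ny)
  }
  new("GridManifold", nx = nx, ny = ny, blocked = blocked)
}

#' @describeIn buildManifold number of free nodes
#' @param x a [GridManifold-class]
#' @export
setMethod("freeNodes", "GridManifold", function(x) sum(!x@blocked))

.checkNode <- function(manifold, node) {
  node <- as.integer(node)
  if (length(node) != 2L)
    stop("invalid node: expected (x, y) coordinates")
  if (node[1] < 0L || node[1] >= manifold@nx ||
      node[2] < 0L || node[2] >= manifold@ny)
    stop(sprintf("invalid node: (%d, %d) outside the %d x %d grid",
                 node[1], node[2], manifold@nx, manifold@ny))
  if (manifold@blocked[node[1] + 1L, node[2] + 1L])
    stop(sprintf("invalid node: (%d, %d) is blocked", node[1], node[2]))
  node
}

## lattice offsets with 0 < d <= range, exact distances
.latticeOffsets <- function(range) {
  K <- ceiling(range)
  offs <- expand.grid(dx = -K:K, dy = -K:K)
  offs$d <- sqrt(offs$dx^2 + offs$dy^2)
  offs[offs$d > 0 & offs$d <= range + 1e-12, ]
}

#' Free neighbors within a Euclidean range
#'
#' All free nodes at Euclidean distance d with 0 < d <= range from
#' \code{node}, with exact distances; excludes the node itself and blocked
#' nodes.
#'
#' @param manifold a [GridManifold-class]
#' @param node (x, y) 0-based coordinates of a free node
#' @param range positive interaction range in grid units
#' @return data.frame with columns \code{id}, \code{x}, \code{y}, \code{d}
#' @examples
#' m <- buildManifold(5, 5)
#' nrow(neighborsWithin(m, c(2, 2), 1))   # 4
#' nrow(neighborsWithin(m, c(2, 2), 2))   # 12
#' @export
neighborsWithin <- function(manifold, node, range) {
  stopifnot(is(manifold, "GridManifold"))
  if (range <= 0) stop("'range' must be positive")
  node <- .checkNode(manifold, node)
  offs <- .latticeOffsets(range)
  x2 <- node[1] + offs$dx
  y2 <- node[2] + offs$dy
  ok <- x2 >= 0L & x2 < manifold@nx & y2 >= 0L & y2 < manifold@ny
  ok[ok] <- !manifold@blocked[cbind(x2[ok] + 1L, y2[ok] + 1L)]
  out <- data.frame(id = nodeId(x2[ok], y2[ok], manifold@nx),
                    x = x2[ok], y = y2[ok], d = offs$d[ok])
  out[order(out$id), , drop = FALSE]
}

#' Build the distance-resolved connectivity graph
#'
#' Connects every pair of free nodes at Euclidean distance 0 < d <= range.
#'
#' @param manifold a [GridManifold-class]
#' @param range maximal edge length in grid units (default 2, the reference
#'   excitation range)
#' @return a [ConnectivityGraph-class]
#' @export
connectivityGraph <- function(manifold, range = 2) {
  stopifnot(is(manifold, "GridManifold"))
  if (range <= 0) stop("'range' must be positive")
  nx <- manifold@nx; ny <- manifold@ny
  offs <- .latticeOffsets(range)
  offs <- offs[offs$dy > 0 | (offs$dy == 0 & offs$dx > 0), ]  # one direction
  xs <- rep(0:(nx - 1L), ny)
  ys <- rep(0:(ny - 1L), each = nx)
  free <- !as.vector(manifold@blocked)
  from <- integer(0); to <- integer(0); dd <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    x2 <- xs + offs$dx[r]; y2 <- ys + offs$dy[r]
    ok <- x2 >= 0L & x2 < nx & y2 >= 0L & y2 < ny
    i0 <- which(ok)
    j0 <- nodeId(x2[ok], y2[ok], nx) + 1L
    keep <- free[i0] & free[j0]
    from <- c(from, i0[keep] - 1L)
    to <- c(to, j0[keep] - 1L)
    dd <- c(dd, rep(offs$d[r], sum(keep)))
  }
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  edges <- data.frame(from = from, to = to, d = dd)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::make_empty_graph(n = nx * ny, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges$from + 1L, edges$to + 1L))
  new("ConnectivityGraph", manifold = manifold, range = range,
      edges = edges, graph = g)
}

#' Unweighted BFS hop distances from a source node
#'
#' Classical breadth-first search over the connectivity graph; the neural
#' wavefront implements a parallelized variant of this traversal, which is
#' what the package's validation compares against.
#'
#' @param graph a [ConnectivityGraph-class]
#' @param source (x, y) 0-based coordinates of a free node
#' @return integer vector of length nx * ny in node-id order: hop counts,
#'   \code{NA} for unreachable (including blocked) nodes
#' @examples
#' g <- connectivityGraph(buildManifold(5, 5), range = 1)
#' d <- bfsDistances(g, c(0, 0))
#' d[nodeId(4, 4, 5) + 1]  # 8 (Manhattan)
#' @export
bfsDistances <- function(graph, source) {
  stopifnot(is(graph, "ConnectivityGraph"))
  source <- .checkNode(graph@manifold, source)
  sid <- nodeId(source[1], source[2], graph@manifold@nx)
  d <- igraph::distances(graph@graph, v = sid + 1L, weights = NA)[1, ]
  d[is.infinite(d)] <- NA
  as.integer(d)
}

## rectangles are lists c(x0, y0, x1, y1), 0-based inclusive
.fillRects <- function(mask, rects) {
  for (r in rects) {
    x0 <- max(0L, r[1]); y0 <- max(0L, r[2])
    x1 <- min(nrow(mask) - 1L, r[3]); y1 <- min(ncol(mask) - 1L, r[4])
    if (x1 >= x0 && y1 >= y0)
      mask[(x0 + 1L):(x1 + 1L), (y0 + 1L):(y1 + 1L)] <- TRUE
  }
  mask
}

#' Deterministic maze masks
#'
#' Generates the obstacle masks used by the planning experiments. The
#' geometries are parametrized reproductions of the reference topologies
#' (S-shaped corridor, field of rectangular blocks, fine multi-corridor
#' labyrinth), not pixel-exact copies. All walls are two nodes thick so that
#' the range-2 connectivity cannot jump across them, and the default start
#' and target corners remain free and mutually reachable (verified with
#' [bfsDistances()]).
#'
#' Shape parameters (all optional, with defaults scaled to the grid):
#' \describe{
#'   \item{s_maze}{\code{wallThickness} (2), \code{gapWidth} (8): two
#'     interleaved horizontal walls at 1/3 and 2/3 height forcing an
#'     S-shaped path.}
#'   \item{blocks}{\code{rects}: list of \code{c(x0, y0, x1, y1)} rectangles
#'     (0-based, inclusive). Default: four blocks, two sitting on the main
#'     diagonal.}
#'   \item{fine_structure}{\code{spacing} (8), \code{wallThickness} (2),
#'     \code{gapWidth} (6): vertical walls with alternating top/bottom gaps
#'     forming a serpentine labyrinth.}
#' }
#'
#' @param kind "open", "s_maze", "blocks" or "fine_structure"
#' @param nx,ny grid dimensions
#' @param params named list of shape parameters, see Details
#' @param start,target corners that must stay free and connected
#'   (defaults (5, 5) and (nx - 6, ny - 6))
#' @return logical \code{nx} by \code{ny} mask (TRUE = blocked)
#' @examples
#' m <- makeMaze("s_maze", 41, 41)
#' sum(m) > 0
#' @export
makeMaze <- function(kind = c("open", "s_maze", "blocks", "fine_structure"),
                     nx = 41, ny = 41, params = list(),
                     start = c(5, 5), target = c(nx - 6, ny - 6)) {
  kind <- match.arg(kind)
  nx <- as.integer(nx); ny <- as.integer(ny)
  mask <- matrix(FALSE, nx, ny)
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default
  if (kind == "s_maze") {
    th <- as.integer(p("wallThickness", 2L))
    gap <- as.integer(p("gapWidth", 8L))
    if (ny < 3L * th + 6L || nx < gap + th + 2L)
      stop("configuration error: s_maze does not fit the grid")
    y1 <- ny %/% 3L
    y2 <- (2L * ny) %/% 3L
    mask <- .fillRects(mask, list(
      c(0L, y1, nx - 1L - gap, y1 + th - 1L),       # wall open at the right
      c(gap, y2, nx - 1L, y2 + th - 1L)))           # wall open at the left
  } else if (kind == "blocks") {
    rects <- p("rects", list(
      c(9L, 9L, 17L, 17L),
      c(22L, 20L, 30L, 28L),
      c(9L, 27L, 15L, 35L),
      c(27L, 7L, 35L, 13L)))
    if (any(vapply(rects, function(r) r[1] > r[3] || r[2] > r[4] ||
                     r[3] >= nx || r[4] >= ny, TRUE)))
      stop("configuration error: block rectangle outside the grid")
    mask <- .fillRects(mask, rects)
  } else if (kind == "fine_structure") {
    spacing <- as.integer(p("spacing", 8L))
    th <- as.integer(p("wallThickness", 2L))
    gap <- as.integer(p("gapWidth", 6L))
    if (spacing <= th || nx < spacing + th)
      stop("configuration error: fine_structure does not fit the grid")
    xw <- seq(spacing - 1L, nx - 1L - th, by = spacing)
    for (i in seq_along(xw)) {
      mask <- .fillRects(mask, list(c(xw[i], 0L, xw[i] + th - 1L, ny - 1L)))
      if (i %% 2L == 1L)   # gap at the bottom
        mask[(xw[i] + 1L):(xw[i] + th), (ny - gap + 1L):ny] <- FALSE
      else                 # gap at the top
        mask[(xw[i] + 1L):(xw[i] + th), 1L:gap] <- FALSE
    }
  }
  ## connectivity guarantee between the requested endpoints
  man <- buildManifold(nx, ny, mask)
  if (mask[start[1] + 1L, start[2] + 1L] || mask[target[1] + 1L, target[2] + 1L])
    stop("degenerate maze: start or target is blocked")
  d <- bfsDistances(connectivityGraph(man, range = 2), start)
  if (is.na(d[nodeId(target[1], target[2], nx) + 1L]))
    stop("degenerate maze: start and target are disconnected")
  mask
}

#' Read and write plain-text obstacle masks
#'
#' Format: one row per line, \code{ny} lines of \code{nx} characters;
#' \code{'.'} = free, \code{'#'} = blocked. Line j (1-based) is grid row
#' y = j - 1. Round-trips bit-exactly.
#'
#' @param path file path
#' @param mask logical nx by ny matrix as in [GridManifold-class]
#' @return \code{readMask}: logical matrix; \code{writeMask}: invisible path
#' @export
readMask <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("configuration error: empty mask file")
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L)
    stop("configuration error: mask lines have unequal length")
  bad <- grepl("[^.#]", lines)
  if (any(bad))
    stop("configuration error: mask may contain only '.' and '#'")
  ny <- length(lines); nx <- widths[1]
  mask <- matrix(FALSE, nx, ny)
  for (j in seq_len(ny))
    mask[, j] <- strsplit(lines[j], "")[[1]] == "#"
  mask
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  lines <- apply(mask, 2, function(col) paste(ifelse(col, "#", "."),
                                              collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
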