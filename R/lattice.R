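## Grid geometry, neighbourhood structure and initial configurations.
##
## Nodes live on a height x width integer lattice, 1-based (row, col) in R.
## The row-major node id is (row - 1) * width + col; snapshots store the
## state as an integer matrix state[row, col] with species codes
## 0 = coral, 1 = turf, 2 = macroalgae.

#' Create a reef snapshot
#'
#' A snapshot is one time slice of the lattice reef: an integer matrix of
#' species codes (0 = coral, 1 = turf, 2 = macroalgae), one species per
#' node, together with the model time it was recorded at.
#'
#' @param state integer matrix of species codes in \{0, 1, 2\}.
#' @param time model time of the snapshot (>= 0).
#' @return An object of class `reef_snapshot`.
#' @export
snapshot <- function(state, time = 0) {
  if (!is.matrix(state)) stop("`state` must be a matrix")
  state <- matrix(as.integer(state), nrow = nrow(state), ncol = ncol(state))
  bad <- which(!(state %in% 0:2))
  if (length(bad)) {
    i <- bad[[1L]]
    stop(sprintf("invalid species code %s at row %d, col %d",
                 state[[i]], (i - 1L) %% nrow(state) + 1L,
                 (i - 1L) %/% nrow(state) + 1L))
  }
  if (!is.numeric(time) || length(time) != 1L || time < 0)
    stop("`time` must be a single non-negative number")
  structure(list(state = state, time = as.numeric(time),
                 width = ncol(state), height = nrow(state)),
            class = "reef_snapshot")
}

#' @export
print.reef_snapshot <- function(x, ...) {
  n <- x$width * x$height
  cv <- covers(x)
  cat(sprintf("reef snapshot: %d x %d nodes, t = %g\n", x$height, x$width,
              x$time))
  cat(sprintf("  covers: C = %.3f, T = %.3f, M = %.3f\n",
              cv[["C"]], cv[["T"]], cv[["M"]]))
  invisible(x)
}

#' @export
plot.reef_snapshot <- function(x, ...) {
  cols <- c("#e75480", "#9ecae1", "#2ca02c")  # coral pink, turf blue, macroalgae green
  z <- t(x$state)[, rev(seq_len(x$height)), drop = FALSE]
  image(seq_len(x$width), seq_len(x$height), z, zlim = c(0, 2),
        col = cols, xlab = "", ylab = "", axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' @export
as.matrix.reef_snapshot <- function(x, ...) x$state

## row-major state vector (id = (row-1)*width + col)
state_vec <- function(snap) as.integer(t(snap$state))

vec_snapshot <- function(v, width, height, time = 0)
  snapshot(matrix(as.integer(v), nrow = height, ncol = width, byrow = TRUE),
           time = time)

#' Fractional covers of a snapshot
#'
#' @param snap a `reef_snapshot`.
#' @return Named numeric vector `c(C = , T = , M = )`, summing to 1 exactly.
#' @export
covers <- function(snap) {
  stopifnot(inherits(snap, "reef_snapshot"))
  n <- snap$width * snap$height
  c(C = sum(snap$state == 0L) / n,
    T = sum(snap$state == 1L) / n,
    M = sum(snap$state == 2L) / n)
}

#' Build the neighbourhood index of a lattice
#'
#' Two distinct nodes are neighbours when the Euclidean norm of their integer
#' displacement is at most `radius`.  Boundaries are hard (no wrap-around):
#' internal nodes have the full offset count, edge and corner nodes fewer.
#' With `radius = 1.45` an internal node has the 8 Moore neighbours; on a
#' 25 x 25 grid `radius = 36` makes every pair of nodes neighbours.
#'
#' @param width,height grid dimensions (>= 1).
#' @param radius Euclidean distance threshold (> 0), in lattice units.
#' @return An object of class `reef_neighbourhood` with compressed
#'   sparse-row neighbour lists (`indptr`, `indices`, both 1-based in R),
#'   per-node neighbour counts `degree`, and the offset list.
#' @export
build_neighbourhood <- function(width, height, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a single positive number")
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("degenerate grid: `width` and `height` must be >= 1")

  rmax <- floor(radius)
  d <- -rmax:rmax
  off <- expand.grid(dr = d, dc = d)
  keep <- off$dr^2 + off$dc^2 <= radius^2 + 1e-9 & (off$dr != 0L | off$dc != 0L)
  off <- off[keep, , drop = FALSE]

  n <- width * height
  rows <- rep(seq_len(height), each = width)
  cols <- rep(seq_len(width), times = height)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    r2 <- rows + off$dr[k]; c2 <- cols + off$dc[k]
    ok <- r2 >= 1L & r2 <= height & c2 >= 1L & c2 <= width
    from <- c(from, which(ok))
    to <- c(to, (r2[ok] - 1L) * width + c2[ok])
  }
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  degree <- tabulate(from, nbins = n)
  structure(list(width = width, height = height, radius = radius,
                 offsets = as.matrix(off),
                 indptr = c(0L, cumsum(degree)), indices = to,
                 degree = degree),
            class = "reef_neighbourhood")
}

#' @export
print.reef_neighbourhood <- function(x, ...) {
  cat(sprintf("reef neighbourhood: %d x %d grid, radius %g\n", x$height,
              x$width, x$radius))
  cat(sprintf("  %d offsets; internal degree %d; boundary-truncated min degree %d\n",
              nrow(x$offsets), max(x$degree), min(x$degree)))
  invisible(x)
}

#' Neighbours of one node
#'
#' @param nbhd a `reef_neighbourhood`.
#' @param node row-major node id, or a `c(row, col)` pair.
#' @return Integer vector of neighbour node ids.
#' @export
neighbours <- function(nbhd, node) {
  id <- node_id(nbhd, node)
  nbhd$indices[(nbhd$indptr[id] + 1L):nbhd$indptr[id + 1L]]
}

node_id <- function(nbhd, node) {
  if (length(node) == 2L)
    node <- (node[[1L]] - 1L) * nbhd$width + node[[2L]]
  node <- as.integer(node)
  if (is.na(node) || node < 1L || node > nbhd$width * nbhd$height)
    stop("node outside grid")
  node
}

check_covers <- function(covers) {
  if (length(covers) != 3L || any(!is.finite(covers)) || any(covers < 0))
    stop("`covers` must be three non-negative numbers (C, T, M)")
  if (abs(sum(covers) - 1) > 1e-9)
    stop("`covers` must sum to 1")
  as.numeric(covers)
}

#' Random initial configuration
#'
#' Every node is drawn independently as coral, turf or macroalgae with
#' probabilities given by the target covers (a spatially mixed reef).
#'
#' @param width,height grid dimensions.
#' @param covers numeric triple `(C0, T0, M0)`, non-negative, summing to 1.
#' @param seed optional integer seed for reproducibility.
#' @return A `reef_snapshot` at time 0.
#' @export
random_config <- function(width, height, covers, seed = NULL) {
  covers <- check_covers(covers)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(width) * as.integer(height)
  draw <- sample.int(3L, n, replace = TRUE, prob = covers) - 1L
  vec_snapshot(draw, width, height, time = 0)
}

## Nodes of the centred patch, ordered by concentric Moore (Chebyshev) rings
## around the centre node, row-major within each ring.
patch_order <- function(width, height) {
  cr <- ceiling(height / 2); cc <- ceiling(width / 2)
  rows <- rep(seq_len(height), each = width)
  cols <- rep(seq_len(width), times = height)
  ring <- pmax(abs(rows - cr), abs(cols - cc))
  order(ring, rows, cols)
}

#' Coral-cluster initial configuration
#'
#' Coral is placed as a single connected patch at the centre of the domain
#' (a centred square spiral: concentric Moore rings around the centre node,
#' the last ring truncated in row-major order), with turf and macroalgae
#' i.i.d. over the remaining nodes in proportion to their covers.
#'
#' @inheritParams random_config
#' @return A `reef_snapshot` at time 0 with exactly `round(C0 * width *
#'   height)` coral nodes.
#' @export
cluster_config <- function(width, height, covers, seed = NULL) {
  covers <- check_covers(covers)
  if (!is.null(seed)) set.seed(seed)
  width <- as.integer(width); height <- as.integer(height)
  n <- width * height
  ncoral <- min(n, round(covers[[1L]] * n))
  v <- integer(n)
  ids <- patch_order(width, height)
  coral_ids <- ids[seq_len(ncoral)]
  rest <- if (ncoral) ids[-seq_len(ncoral)] else ids
  v[coral_ids] <- 0L
  tm <- covers[2:3]
  if (length(rest)) {
    if (sum(tm) <= 0) {
      v[rest] <- 0L  # rounding shortfall with C0 = 1: fill with coral
    } else {
      v[rest] <- sample(c(1L, 2L), length(rest), replace = TRUE,
                        prob = tm / sum(tm))
    }
  }
  vec_snapshot(v, width, height, time = 0)
}
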