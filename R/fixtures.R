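## Deterministic toy-data generators and golden cases that exercise every
## analysis stage without stochastic simulation.

#' Build a trajectory from scripted coral masks
#'
#' Turns a list of logical coral masks (one per time step) into a
#' trajectory whose snapshots are coral where the mask is TRUE and turf
#' elsewhere.  Useful for hand-decomposable zigzag cases (merges, splits,
#' flicker).
#'
#' @param masks list of logical matrices with identical dimensions.
#' @param times optional snapshot times (default `0, 1, ...`).
#' @return A `reef_trajectory` (no covers history beyond the recorded
#'   times; parameters are defaults).
#' @export
make_blob_movie <- function(masks, times = seq_along(masks) - 1) {
  stopifnot(length(masks) >= 1L, length(times) == length(masks))
  dims <- dim(masks[[1L]])
  snaps <- mapply(function(m, t) {
    if (!is.logical(m) || !identical(dim(m), dims))
      stop("all masks must be logical matrices of identical dimensions")
    snapshot(ifelse(m, 0L, 1L), time = t)
  }, masks, times, SIMPLIFY = FALSE)
  cov <- do.call(rbind, lapply(snaps, covers))
  structure(list(snapshots = snaps,
                 covers = data.frame(t = times, C = cov[, "C"],
                                     T = cov[, "T"], M = cov[, "M"]),
                 times = times, params = smhe_params(),
                 width = dims[[2L]], height = dims[[1L]],
                 seed = NA_integer_),
            class = "reef_trajectory")
}

#' Golden barcode cases
#'
#' Small coral patterns whose barcodes were derived by hand and
#' re-verified with [betti_oracle()]: a filled 2x2 block, a hollow 3x3
#' ring, two disjoint 2x2 blocks, and a diagonal checkerboard.  The
#' snapshots are shipped as CSV fixtures under `inst/extdata`.
#'
#' @return A named list of cases, each with the `snapshot`, the expected
#'   nonzero-length `bars` (data frame `dim`, `birth`, `death`,
#'   `essential`), and the expected Betti numbers at level 1.
#' @export
golden_barcodes <- function() {
  path <- function(f) system.file("extdata", f, package = "reeftda",
                                  mustWork = TRUE)
  list(
    block = list(
      snapshot = read_snapshot(path("golden_block2x2.csv")),
      # four vertices with f = 3; complex complete at K3; one essential
      # component, no loops
      bars = data.frame(dim = 0L, birth = 3L, death = NA_integer_,
                        essential = TRUE),
      betti_k1 = c(beta0 = 1L, beta1 = 0L)),
    ring = list(
      snapshot = read_snapshot(path("golden_ring3x3.csv")),
      # edge-centre nodes have f = 4, corners f = 2: four components at
      # K4..K3 merge into the ring at K2, which closes one loop
      bars = data.frame(dim = c(0L, 0L, 0L, 0L, 1L),
                        birth = c(4L, 4L, 4L, 4L, 2L),
                        death = c(NA, 2L, 2L, 2L, NA),
                        essential = c(TRUE, FALSE, FALSE, FALSE, TRUE)),
      betti_k1 = c(beta0 = 1L, beta1 = 1L)),
    two_blocks = list(
      snapshot = read_snapshot(path("golden_two_blocks.csv")),
      bars = data.frame(dim = c(0L, 0L), birth = c(3L, 3L),
                        death = c(NA_integer_, NA_integer_),
                        essential = c(TRUE, TRUE)),
      betti_k1 = c(beta0 = 2L, beta1 = 0L)),
    checkerboard = list(
      snapshot = read_snapshot(path("golden_checkerboard.csv")),
      # diagonal-only contacts: every coral node is its own cubical
      # component (4-adjacency), while cluster_stats at ell = 1.45 sees
      # one cluster
      bars = NULL,
      betti_k1 = NULL),
    NULL)[c("block", "ring", "two_blocks", "checkerboard")]
}

#' Standard blob-movie scripts
#'
#' Ready-made mask scripts for the zigzag tests: `merge` (two blobs, then
#' bridged), `constant` (one unchanging blob), `flicker` (blob present,
#' absent, present) and `split_asym` (one blob splitting into a
#' long-lived and a short-lived branch).
#'
#' @param name script name.
#' @return A `reef_trajectory` from [make_blob_movie()].
#' @export
blob_movie <- function(name = c("merge", "constant", "flicker",
                                "split_asym")) {
  name <- match.arg(name)
  e <- function() matrix(FALSE, 7, 9)
  blob <- function(m, rows, cols) { m[rows, cols] <- TRUE; m }
  switch(name,
    merge = {
      a <- blob(blob(e(), 2:3, 2:3), 2:3, 7:8)      # two blobs A, B
      b <- blob(a, 2:3, 2:8)                        # bridged: A u B
      make_blob_movie(list(a, b))
    },
    constant = {
      a <- blob(e(), 3:5, 4:6)
      make_blob_movie(list(a, a, a))
    },
    flicker = {
      a <- blob(e(), 3:4, 4:5)
      make_blob_movie(list(a, e(), a))
    },
    split_asym = {
      big <- blob(e(), 2:6, 4:5)                    # one tall blob
      two <- blob(blob(e(), 2:3, 4:5), 5:6, 4:5)    # split in two
      one <- blob(e(), 2:3, 4:5)                    # short branch gone
      make_blob_movie(list(big, two, one))
    })
}
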