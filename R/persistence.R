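## Persistent homology (H0, H1) of a density filtration by column
## reduction of the boundary matrix over GF(2).  Cells are processed in
## filtration order (levels 8 -> k_min, vertices before edges before
## squares, ties by anchor coordinate), which makes the pairing
## deterministic; the barcode itself is invariant to tie-breaking.

#' Barcode of a filtered cubical complex
#'
#' Bars live on the density scale: a bar `(dim, birth, death)` is alive in
#' the complex at level `k` whenever `birth >= k > death`.  Essential
#' classes (alive through the last level, `k_min`) carry `death = NA` and
#' `essential = TRUE`; they serialize as `inf`.  Zero-persistence bars
#' (`birth == death`) are kept in the multiset.
#'
#' @param fc a `reef_filtration` from [build_filtration()].
#' @return An object of class `reef_barcode`: a data frame with columns
#'   `dim` (0 or 1), `birth`, `death`, `essential`.
#' @export
barcode <- function(fc) {
  stopifnot(inherits(fc, "reef_filtration"))
  n <- nrow(fc$cells)
  empty <- data.frame(dim = integer(0), birth = integer(0),
                      death = integer(0), essential = logical(0))
  if (!n) return(structure(empty, class = c("reef_barcode", "data.frame"),
                           k_min = fc$k_min))
  cols <- fc$boundary
  pivot_of <- integer(n)            # pivot row -> column index (0 = free)
  paired <- logical(n)
  bars <- vector("list", n)
  nb <- 0L
  for (j in seq_len(n)) {
    col <- cols[[j]]
    while (length(col)) {
      low <- col[[length(col)]]
      pj <- pivot_of[[low]]
      if (pj == 0L) break
      col <- sym_diff(col, cols[[pj]])
    }
    cols[[j]] <- col
    if (length(col)) {
      low <- col[[length(col)]]
      pivot_of[[low]] <- j
      paired[[low]] <- TRUE; paired[[j]] <- TRUE
      nb <- nb + 1L
      bars[[nb]] <- c(dim = fc$cells$dim[[low]],
                      birth = fc$cells$level[[low]],
                      death = fc$cells$level[[j]])
    }
  }
  out <- if (nb) as.data.frame(do.call(rbind, bars[seq_len(nb)])) else
    data.frame(dim = integer(0), birth = integer(0), death = integer(0))
  out$essential <- logical(nrow(out))
  ess <- which(!paired & fc$cells$dim < 2L)
  if (length(ess))
    out <- rbind(out, data.frame(dim = fc$cells$dim[ess],
                                 birth = fc$cells$level[ess],
                                 death = NA_integer_, essential = TRUE))
  out <- out[order(out$dim, -out$birth, out$death, na.last = FALSE), ]
  rownames(out) <- NULL
  structure(out, class = c("reef_barcode", "data.frame"), k_min = fc$k_min)
}

## symmetric difference of two sorted integer vectors, kept sorted
sym_diff <- function(a, b) {
  u <- c(a, b)
  sort(u[!(duplicated(u) | duplicated(u, fromLast = TRUE))])
}

#' @export
print.reef_barcode <- function(x, ...) {
  cat(sprintf("barcode: %d bars (%d in H0, %d in H1), %d essential\n",
              nrow(x), sum(x$dim == 0L), sum(x$dim == 1L), sum(x$essential)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 20L))
  invisible(x)
}

#' Bars alive at a filtration level
#'
#' @param bc a `reef_barcode`.
#' @param level density level `k`.
#' @param dim homological dimension, 0 or 1.
#' @return Number of bars of that dimension alive in the complex at level
#'   `k` (birth >= k, and either essential or death < k).
#' @export
bars_alive <- function(bc, level, dim = 0) {
  sum(bc$dim == dim & bc$birth >= level & (bc$essential | bc$death < level))
}

#' Betti numbers of one filtration level (independent oracle)
#'
#' Computes `beta0` by union-find over the edges of the level-`k`
#' subcomplex and `beta1` from the Euler characteristic
#' `V - E + F = beta0 - beta1` (valid for these planar cubical
#' complexes, where every square is filled on entry).  Intended as a
#' small-scale cross-check of [barcode()]; refuses complexes beyond
#' `max_cells`.
#'
#' @param fc a `reef_filtration`.
#' @param level density level `k` (>= `k_min` of the filtration).
#' @param max_cells size guard (default 20000).
#' @return `c(beta0 = , beta1 = )`.
#' @export
betti_oracle <- function(fc, level, max_cells = 20000) {
  stopifnot(inherits(fc, "reef_filtration"))
  if (nrow(fc$cells) > max_cells) stop("complex too large for the oracle")
  keep <- fc$cells$level >= level
  V <- sum(keep & fc$cells$dim == 0L)
  Emask <- which(keep & fc$cells$dim == 1L)
  Fc <- sum(keep & fc$cells$dim == 2L)
  if (!V) return(c(beta0 = 0L, beta1 = 0L))
  vids <- which(fc$cells$dim == 0L)        # positions of vertices in cell order
  vindex <- integer(nrow(fc$cells)); vindex[vids] <- seq_along(vids)
  parent <- seq_len(length(vids))
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nx <- parent[i]; parent[i] <<- r; i <- nx }
    r
  }
  for (e in Emask) {
    vv <- vindex[fc$boundary[[e]]]
    ra <- find(vv[[1L]]); rb <- find(vv[[2L]])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  active <- vindex[which(keep & fc$cells$dim == 0L)]
  beta0 <- length(unique(vapply(active, find, integer(1))))
  beta1 <- beta0 - V + length(Emask) - Fc
  c(beta0 = beta0, beta1 = beta1)
}
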