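## Density filtration of cubical complexes built on the coral nodes of a
## snapshot.  The density f(i) of a coral node is its number of coral
## neighbours among the 8 Moore neighbours (independent of the dynamics'
## radius ell); the filtration K8 c K7 c ... c K_kmin adds coral nodes in
## decreasing density, with edges between 4-adjacent included vertices and
## filled squares on complete 2x2 blocks.  A cell enters at the minimum
## density of its vertices, so the complex at every level is determined by
## its vertex set (flag property).

#' Coral density of every coral node
#'
#' @param snap a `reef_snapshot`.
#' @return Integer matrix of the snapshot's dimensions: for coral nodes the
#'   number of coral Moore neighbours (0-8; boundary nodes count their
#'   actual coral neighbours), `NA` elsewhere.
#' @export
density_filtration <- function(snap) {
  stopifnot(inherits(snap, "reef_snapshot"))
  m <- snap$state == 0L
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  cnt <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    cnt <- cnt + pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc, drop = FALSE]
  }
  cnt[!m] <- NA_integer_
  cnt
}

#' Build the density filtration of cubical complexes
#'
#' @param snap a `reef_snapshot`.
#' @param k_min lowest filtration level kept (default 1: isolated coral
#'   nodes, f = 0, are excluded; set 0 to include them).
#' @return An object of class `reef_filtration`: a data frame of cells
#'   (`dim` 0/1/2, entry `level`, anchor `row`/`col`, edge `orient`
#'   0 = horizontal / 1 = vertical) sorted in reduction order (levels
#'   descending, vertices before edges before squares, ties by anchor),
#'   plus the boundary lists of each cell as indices into that order.
#' @export
build_filtration <- function(snap, k_min = 1) {
  stopifnot(inherits(snap, "reef_snapshot"))
  k_min <- as.integer(k_min)
  if (is.na(k_min) || k_min < 0L || k_min > 8L)
    stop("`k_min` must be in 0..8")
  f <- density_filtration(snap)
  h <- nrow(f); w <- ncol(f)
  inc <- !is.na(f) & f >= k_min

  vi <- which(inc, arr.ind = TRUE)
  cells <- data.frame(dim = integer(0), level = integer(0), row = integer(0),
                      col = integer(0), orient = integer(0))
  if (nrow(vi)) {
    cells <- data.frame(dim = 0L, level = f[inc], row = vi[, 1L],
                        col = vi[, 2L], orient = 0L)
    # horizontal edges: (r, c) -- (r, c + 1)
    eh <- which(inc[, -w, drop = FALSE] & inc[, -1L, drop = FALSE],
                arr.ind = TRUE)
    if (length(eh)) {
      lev <- pmin(f[cbind(eh[, 1L], eh[, 2L])], f[cbind(eh[, 1L], eh[, 2L] + 1L)])
      cells <- rbind(cells, data.frame(dim = 1L, level = lev, row = eh[, 1L],
                                       col = eh[, 2L], orient = 0L))
    }
    # vertical edges: (r, c) -- (r + 1, c)
    ev <- which(inc[-h, , drop = FALSE] & inc[-1L, , drop = FALSE],
                arr.ind = TRUE)
    if (length(ev)) {
      lev <- pmin(f[cbind(ev[, 1L], ev[, 2L])], f[cbind(ev[, 1L] + 1L, ev[, 2L])])
      cells <- rbind(cells, data.frame(dim = 1L, level = lev, row = ev[, 1L],
                                       col = ev[, 2L], orient = 1L))
    }
    # squares: complete 2x2 blocks, anchored at the top-left vertex
    if (h > 1L && w > 1L) {
      sq <- which(inc[-h, -w, drop = FALSE] & inc[-h, -1L, drop = FALSE] &
                    inc[-1L, -w, drop = FALSE] & inc[-1L, -1L, drop = FALSE],
                  arr.ind = TRUE)
      if (length(sq)) {
        lev <- pmin(f[cbind(sq[, 1L], sq[, 2L])],
                    f[cbind(sq[, 1L], sq[, 2L] + 1L)],
                    f[cbind(sq[, 1L] + 1L, sq[, 2L])],
                    f[cbind(sq[, 1L] + 1L, sq[, 2L] + 1L)])
        cells <- rbind(cells, data.frame(dim = 2L, level = lev, row = sq[, 1L],
                                         col = sq[, 2L], orient = 0L))
      }
    }
  }
  ord <- order(-cells$level, cells$dim, cells$row, cells$col, cells$orient)
  cells <- cells[ord, , drop = FALSE]
  rownames(cells) <- NULL

  # boundary lists via keyed lookup into the sorted order
  vkey <- function(r, c) (r - 1L) * w + c
  ekey <- function(r, c, o) o * (w * h) + vkey(r, c)
  key <- integer(nrow(cells))
  isv <- cells$dim == 0L; ise <- cells$dim == 1L
  key[isv] <- vkey(cells$row[isv], cells$col[isv])
  key[ise] <- ekey(cells$row[ise], cells$col[ise], cells$orient[ise])
  vpos <- integer(w * h); vpos[key[isv]] <- which(isv)
  epos <- integer(2L * w * h); epos[key[ise]] <- which(ise)

  boundary <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    r <- cells$row[j]; c <- cells$col[j]
    boundary[[j]] <- switch(cells$dim[j] + 1L,
      integer(0),
      if (cells$orient[j] == 0L) sort(c(vpos[vkey(r, c)], vpos[vkey(r, c + 1L)]))
      else sort(c(vpos[vkey(r, c)], vpos[vkey(r + 1L, c)])),
      sort(c(epos[ekey(r, c, 0L)], epos[ekey(r + 1L, c, 0L)],
             epos[ekey(r, c, 1L)], epos[ekey(r, c + 1L, 1L)])))
  }
  structure(list(cells = cells, boundary = boundary, width = w, height = h,
                 k_min = k_min),
            class = "reef_filtration")
}

#' @export
print.reef_filtration <- function(x, ...) {
  cat(sprintf(
    "density filtration: %d cells (%d vertices, %d edges, %d squares), levels %s..%d\n",
    nrow(x$cells), sum(x$cells$dim == 0L), sum(x$cells$dim == 1L),
    sum(x$cells$dim == 2L),
    if (nrow(x$cells)) max(x$cells$level) else x$k_min, x$k_min))
  invisible(x)
}

#' Write the cells of a filtration as TSV (debug helper)
#'
#' @param fc a `reef_filtration`.
#' @param path output file.
#' @export
write_filtration <- function(fc, path) {
  write.table(fc$cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
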