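## Zigzag persistence in dimension 0 of the alternating inclusion sequence
##
##   K1(t_0) > (K1(t_0) n K1(t_1)) < K1(t_1) > ... > K1(t_M)
##
## where K1(t) is the cubical complex on the coral nodes of the
## (pre-processed) snapshot at time t that have at least one Moore coral
## neighbour.  All complexes are determined by their vertex sets (flag
## property), so intersections of complexes are the complexes of the
## intersected vertex sets.
##
## The interval decomposition is computed by the right-filtration
## (Carlsson-de Silva) algorithm specialized to H0, with explicit GF(2)
## linear algebra on component spaces.  Interval multisets of zigzag
## modules are unique; representative choices are not, and none of the
## tie-breaking below affects the reported intervals.

#' Pre-process a snapshot for zigzag analysis
#'
#' Relabels as turf every isolated coral node (zero Moore coral
#' neighbours).  Such nodes never enter `K1`, and removing them before
#' intersecting consecutive snapshots suppresses single-node flicker
#' noise.  The operation is idempotent: an isolated coral node has no
#' coral neighbours, so removing it cannot lower any other node's coral
#' neighbour count.
#'
#' @param snap a `reef_snapshot`.
#' @return The filtered `reef_snapshot`.
#' @export
preprocess_snapshot <- function(snap) {
  stopifnot(inherits(snap, "reef_snapshot"))
  f <- density_filtration(snap)
  st <- snap$state
  st[!is.na(f) & f == 0L] <- 1L
  snapshot(st, time = snap$time)
}

## K1 vertex ids (row-major) of a snapshot
k1_vertices <- function(snap) {
  f <- density_filtration(snap)
  keep <- !is.na(f) & f >= 1L
  which(as.vector(t(keep)))
}

#' Build the alternating inclusion sequence of a trajectory
#'
#' Positions `1, 3, 5, ...` (odd) hold the `K1` complexes of the recorded
#' snapshots; even positions hold the intersections of their two
#' neighbours, included in both.  With `M + 1` snapshots the sequence has
#' `2M + 1` positions; position `p` maps to model time
#' `t_0 + ((p - 1) / 2) * stride`, so intersections sit at half-steps.
#'
#' @param traj a `reef_trajectory`, or a list of `reef_snapshot`s.
#' @param preprocess apply [preprocess_snapshot()] to each snapshot first
#'   (default TRUE); intersections are taken after pre-processing.
#' @return An object of class `reef_zigzag_seq`: vertex sets per position,
#'   position times, and grid dimensions.
#' @export
build_zigzag <- function(traj, preprocess = TRUE) {
  snaps <- if (inherits(traj, "reef_trajectory")) traj$snapshots else traj
  if (length(snaps) < 2L)
    stop("zigzag needs at least 2 recorded snapshots")
  stopifnot(all(vapply(snaps, inherits, logical(1), "reef_snapshot")))
  if (preprocess) snaps <- lapply(snaps, preprocess_snapshot)
  width <- snaps[[1L]]$width; height <- snaps[[1L]]$height
  vsets <- lapply(snaps, k1_vertices)
  times <- vapply(snaps, `[[`, numeric(1), "time")
  M <- length(snaps) - 1L
  P <- 2L * M + 1L
  sets <- vector("list", P)
  ptimes <- numeric(P)
  for (m in seq_len(M + 1L)) {
    sets[[2L * m - 1L]] <- vsets[[m]]
    ptimes[[2L * m - 1L]] <- times[[m]]
  }
  for (m in seq_len(M)) {
    sets[[2L * m]] <- intersect(vsets[[m]], vsets[[m + 1L]])
    ptimes[[2L * m]] <- (times[[m]] + times[[m + 1L]]) / 2
  }
  structure(list(vertex_sets = sets, times = ptimes, width = width,
                 height = height),
            class = "reef_zigzag_seq")
}

#' @export
print.reef_zigzag_seq <- function(x, ...) {
  cat(sprintf("zigzag sequence: %d positions (%d snapshots), t in [%g, %g]\n",
              length(x$vertex_sets), (length(x$vertex_sets) + 1L) / 2L,
              min(x$times), max(x$times)))
  invisible(x)
}

## Components of a vertex set under 4-adjacency (the cubical complex edge
## rule).  Returns list(labels = per-vertex component index, k = count);
## components are numbered by their smallest (anchor) vertex id.
h0_components <- function(ids, width) {
  if (!length(ids)) return(list(labels = integer(0), k = 0L, ids = ids))
  parent <- seq_along(ids)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nx <- parent[i]; parent[i] <<- r; i <- nx }
    r
  }
  # 4-adjacent pairs: right neighbour id + 1 unless at row end; down +width
  right <- match(ids + 1L, ids)
  at_row_end <- ids %% width == 0L
  down <- match(ids + width, ids)
  for (a in seq_along(ids)) {
    b <- right[[a]]
    if (!is.na(b) && !at_row_end[[a]]) {
      ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    b <- down[[a]]
    if (!is.na(b)) {
      ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  labels <- match(roots, sort(unique(roots)))
  list(labels = labels, k = max(labels), ids = ids)
}

## highest set coordinate of a GF(2) vector (0 when zero)
gf2_pivot <- function(x) {
  w <- which(x)
  if (length(w)) w[[length(w)]] else 0L
}

#' H0 zigzag interval decomposition
#'
#' Computes the interval decomposition of the dimension-0 zigzag
#' persistence module of an alternating inclusion sequence.  Intervals are
#' closed on integer sequence positions and are also reported on the model
#' time axis via the sequence's time map.
#'
#' @param zz a `reef_zigzag_seq` from [build_zigzag()].
#' @return An object of class `reef_zigzag`: a data frame with columns
#'   `birth_pos`, `death_pos` (1-based sequence positions), `birth_time`,
#'   `death_time`.
#' @export
zigzag_h0 <- function(zz) {
  stopifnot(inherits(zz, "reef_zigzag_seq"))
  P <- length(zz$vertex_sets)
  comps <- lapply(zz$vertex_sets, h0_components, width = zz$width)

  ## H0 matrix of the inclusion from the even-position complex `sub` into
  ## the odd-position complex `sup`: component k of sub -> containing
  ## component of sup.
  h0_map <- function(sub, sup) {
    Fm <- matrix(FALSE, nrow = sup$k, ncol = sub$k)
    if (sub$k) {
      tgt <- sup$labels[match(sub$ids, sup$ids)]
      for (k in seq_len(sub$k)) {
        v <- tgt[sub$labels == k][1L]
        Fm[v, k] <- TRUE
      }
    }
    Fm
  }

  ## Right-filtration state (Carlsson-de Silva): an ordered basis
  ## vs[[1]], ..., vs[[k]] of the current component space whose prefixes
  ## span a flag R_1 c R_2 c ... c R_k, with a birth position bs[[i]]
  ## attached to each filtration step.  Flag order is not birth order:
  ## kernel newborns of backward arrows enter at the BOTTOM of the flag,
  ## cokernel newborns of forward arrows at the top.  At every arrow the
  ## steps whose subspace fails to grow collapse, and their birth dies;
  ## this determines the canonical interval multiset without any
  ## representative tie-breaking.
  vs <- list(); bs <- integer(0)
  bars <- list()
  kill <- function(b, pos) bars[[length(bars) + 1L]] <<-
    c(birth = b, death = pos)

  ## start: one step per component of the first complex, all born at 1
  k1 <- comps[[1L]]$k
  if (k1) {
    bs <- rep(1L, k1)
    vs <- lapply(seq_len(k1), function(i) { v <- rep(FALSE, k1); v[i] <- TRUE; v })
  }

  for (p in seq_len(P - 1L)) {
    from <- comps[[p]]; to <- comps[[p + 1L]]
    if (p %% 2L == 1L) {
      ## odd -> even: backward arrow, map Fm : V_{p+1} -> V_p.
      ## New flag: ker Fm at the bottom (born p+1), then for each old
      ## step i (in flag order) the preimage grows iff
      ## v_i is in im Fm + R_{i-1}; collapsed steps die at p.
      Fm <- h0_map(to, from)
      ## echelonize Fm's columns with preimage (u) and kernel tracking
      fb <- list(); fp <- integer(0); fu <- list(); kerns <- list()
      for (cidx in seq_len(ncol(Fm))) {
        x <- Fm[, cidx]; u <- rep(FALSE, ncol(Fm)); u[cidx] <- TRUE
        for (b in seq_along(fb)) if (x[[fp[[b]]]]) { x <- xor(x, fb[[b]]); u <- xor(u, fu[[b]]) }
        if (any(x)) { fb[[length(fb) + 1L]] <- x; fu[[length(fu) + 1L]] <- u
                      fp[[length(fp) + 1L]] <- gf2_pivot(x) }
        else kerns[[length(kerns) + 1L]] <- u
      }
      new_vs <- kerns                       # kernel newborns, bottom of flag
      new_bs <- rep(p + 1L, length(kerns))
      ## processed old steps as reduction columns (remainders), with
      ## accumulated preimages so survivors get a correct representative
      vb <- list(); vp <- integer(0); vu <- list()
      for (i in seq_along(vs)) {
        x <- vs[[i]]; u <- rep(FALSE, ncol(Fm))
        for (b in seq_along(fb)) if (length(x) && x[[fp[[b]]]]) { x <- xor(x, fb[[b]]); u <- xor(u, fu[[b]]) }
        for (b in seq_along(vb)) if (length(x) && x[[vp[[b]]]]) { x <- xor(x, vb[[b]]); u <- xor(u, vu[[b]]) }
        if (!any(x)) {
          ## step survives: g(u) = v_i modulo R_{i-1}
          new_vs[[length(new_vs) + 1L]] <- u
          new_bs <- c(new_bs, bs[[i]])
        } else {
          kill(bs[[i]], p)
          vb[[length(vb) + 1L]] <- x; vp[[length(vp) + 1L]] <- gf2_pivot(x)
          vu[[length(vu) + 1L]] <- u
        }
      }
      vs <- new_vs; bs <- new_bs
    } else {
      ## even -> odd: forward arrow, map Fm : V_p -> V_{p+1}.
      ## New flag: images of the old steps in flag order (collapsed steps
      ## die at p), then cokernel newborns (born p+1) at the top.
      Fm <- h0_map(from, to)
      basis <- list(); piv <- integer(0)
      new_vs <- list(); new_bs <- integer(0)
      for (i in seq_along(vs)) {
        w <- as.vector((Fm %*% vs[[i]]) %% 2 == 1)
        for (b in seq_along(basis)) if (length(w) && w[[piv[[b]]]]) w <- xor(w, basis[[b]])
        if (any(w)) {
          basis[[length(basis) + 1L]] <- w; piv[[length(piv) + 1L]] <- gf2_pivot(w)
          new_vs[[length(new_vs) + 1L]] <- w
          new_bs <- c(new_bs, bs[[i]])
        } else {
          kill(bs[[i]], p)
        }
      }
      for (i in seq_len(to$k)) {
        e <- rep(FALSE, to$k); e[i] <- TRUE
        for (b in seq_along(basis)) if (e[[piv[[b]]]]) e <- xor(e, basis[[b]])
        if (any(e)) {
          basis[[length(basis) + 1L]] <- e; piv[[length(piv) + 1L]] <- gf2_pivot(e)
          new_vs[[length(new_vs) + 1L]] <- e
          new_bs <- c(new_bs, p + 1L)
        }
      }
      vs <- new_vs; bs <- new_bs
    }
  }
  ## steps alive at the final position close there
  for (i in seq_along(bs)) kill(bs[[i]], P)

  out <- if (length(bars)) as.data.frame(do.call(rbind, bars)) else
    data.frame(birth = integer(0), death = integer(0))
  names(out) <- c("birth_pos", "death_pos")
  out <- out[order(out$birth_pos, out$death_pos), , drop = FALSE]
  rownames(out) <- NULL
  out$birth_time <- zz$times[out$birth_pos]
  out$death_time <- zz$times[out$death_pos]
  structure(out, class = c("reef_zigzag", "data.frame"))
}

#' @export
print.reef_zigzag <- function(x, ...) {
  cat(sprintf("zigzag H0 intervals: %d\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 20L))
  invisible(x)
}

#' Consistency oracle for a zigzag interval decomposition
#'
#' Verifies, independently of the decomposition algorithm, that (a) at
#' every sequence position the number of intervals containing it equals
#' the number of connected components of the complex there (computed by
#' breadth-first flood fill), and (b) over every single inclusion arrow
#' the number of intervals containing both endpoints equals the rank of
#' the induced map on components.
#'
#' @param zz a `reef_zigzag_seq`.
#' @param intervals a `reef_zigzag` (output of [zigzag_h0()]).
#' @return A list with `pass` (logical) and a data frame `detail` of
#'   per-position and per-arrow checks.
#' @export
zigzag_consistency_check <- function(zz, intervals) {
  P <- length(zz$vertex_sets)
  b0 <- vapply(seq_len(P), function(p)
    flood_fill_count(zz$vertex_sets[[p]], zz$width), integer(1))
  covered <- vapply(seq_len(P), function(p)
    sum(intervals$birth_pos <= p & intervals$death_pos >= p), integer(1))
  pos_ok <- b0 == covered

  arrow_rank <- integer(P - 1L)
  arrow_span <- integer(P - 1L)
  comps <- lapply(zz$vertex_sets, h0_components, width = zz$width)
  for (p in seq_len(P - 1L)) {
    if (p %% 2L == 1L) { sub <- comps[[p + 1L]]; sup <- comps[[p]] }
    else { sub <- comps[[p]]; sup <- comps[[p + 1L]] }
    # rank of the component map sub -> sup: number of distinct targets
    # of independent columns == GF(2) rank of the 0/1 assignment matrix,
    # which for a map matrix is the number of distinct hit components.
    if (sub$k) {
      tgt <- sup$labels[match(sub$ids, sup$ids)]
      arrow_rank[[p]] <- length(unique(tgt[!duplicated(sub$labels)]))
    } else arrow_rank[[p]] <- 0L
    arrow_span[[p]] <- sum(intervals$birth_pos <= p &
                             intervals$death_pos >= p + 1L)
  }
  arrow_ok <- arrow_rank == arrow_span
  list(pass = all(pos_ok) && all(arrow_ok),
       detail = data.frame(position = seq_len(P), beta0 = b0,
                           intervals = covered, ok = pos_ok),
       arrows = data.frame(arrow = seq_len(P - 1L), rank = arrow_rank,
                           spanning = arrow_span, ok = arrow_ok))
}

## BFS flood-fill component count (independent of the union-find path)
flood_fill_count <- function(ids, width) {
  if (!length(ids)) return(0L)
  seen <- logical(length(ids))
  nbr <- function(a) {
    id <- ids[[a]]
    cand <- c(if (id %% width != 0L) id + 1L,
              if (id %% width != 1L && width > 1L) id - 1L,
              id + width, id - width)
    match(cand, ids)
  }
  count <- 0L
  for (s in seq_along(ids)) {
    if (seen[[s]]) next
    count <- count + 1L
    queue <- s; seen[[s]] <- TRUE
    while (length(queue)) {
      a <- queue[[1L]]; queue <- queue[-1L]
      for (b in nbr(a)) {
        if (!is.na(b) && !seen[[b]]) { seen[[b]] <- TRUE; queue <- c(queue, b) }
      }
    }
  }
  count
}

#' Write zigzag intervals as TSV
#'
#' @param intervals a `reef_zigzag`.
#' @param path output file.
#' @export
write_zigzag <- function(intervals, path) {
  write.table(as.data.frame(intervals), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
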