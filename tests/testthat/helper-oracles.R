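## Independent oracles used across the test suite.  These deliberately
## avoid the package's own code paths: brute-force enumeration, BFS
## flood fill, explicit tent evaluation, and a limit/colimit rank oracle
## for zigzag interval multiplicities.

## Brute-force neighbour count of node (r0, c0) on a w x h grid.
brute_neighbours <- function(width, height, radius, r0, c0) {
  cnt <- 0L
  for (r in seq_len(height)) for (c in seq_len(width)) {
    if (r == r0 && c == c0) next
    if ((r - r0)^2 + (c - c0)^2 <= radius^2 + 1e-9) cnt <- cnt + 1L
  }
  cnt
}

## Random snapshot with i.i.d. species draws.
rand_snapshot <- function(width, height, probs = c(0.3, 0.5, 0.2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snapshot(matrix(sample(0:2, width * height, replace = TRUE, prob = probs),
                  nrow = height, ncol = width))
}

## BFS flood-fill cluster count over an arbitrary offset neighbourhood,
## scanning the matrix directly (independent of the package union-find).
bfs_clusters <- function(snap, radius, species_code) {
  st <- as.matrix(snap)
  h <- nrow(st); w <- ncol(st)
  rmax <- floor(radius)
  offs <- list()
  for (dr in -rmax:rmax) for (dc in -rmax:rmax) {
    if ((dr != 0 || dc != 0) && dr^2 + dc^2 <= radius^2 + 1e-9)
      offs[[length(offs) + 1L]] <- c(dr, dc)
  }
  seen <- matrix(FALSE, h, w)
  sizes <- integer(0)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (seen[r, c] || st[r, c] != species_code) next
    size <- 0L
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      size <- size + 1L
      for (o in offs) {
        rr <- cur[1L] + o[1L]; cc <- cur[2L] + o[2L]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && !seen[rr, cc] &&
            st[rr, cc] == species_code) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(n = length(sizes), sizes = sizes)
}

## Explicit tent-evaluation landscape oracle: evaluate every tent at every
## grid point, sort, take the k-th largest.
brute_landscape <- function(birth, death, K, grid) {
  out <- matrix(0, K, length(grid))
  for (gi in seq_along(grid)) {
    t <- grid[[gi]]
    vals <- numeric(length(birth))
    for (i in seq_along(birth)) {
      v <- min(t - birth[[i]], death[[i]] - t)
      vals[[i]] <- max(0, v)
    }
    vals <- sort(vals, decreasing = TRUE)
    for (k in seq_len(K)) out[k, gi] <- if (k <= length(vals)) vals[[k]] else 0
  }
  out
}

## ---------------------------------------------------------------------
## Zigzag oracle: interval multiplicities of a type-A zigzag module over
## GF(2) from generalized ranks, r(a, b) = rank of the canonical map
## lim -> colim of the window [a, b], via
##   m[a, b] = r(a,b) - r(a-1,b) - r(a,b+1) + r(a-1,b+1)
## (out-of-range terms dropped).  Completely independent of the
## sequential decomposition algorithm.

## Component labelling of a vertex-id set by direct matrix scanning.
oracle_labels <- function(ids, width, height) {
  if (!length(ids)) return(list(k = 0L, lab = integer(0), ids = ids))
  m <- matrix(0L, height, width)
  for (id in ids) m[(id - 1L) %/% width + 1L, (id - 1L) %% width + 1L] <- 1L
  lab <- matrix(0L, height, width)
  k <- 0L
  for (r in seq_len(height)) for (c in seq_len(width)) {
    if (m[r, c] == 1L && lab[r, c] == 0L) {
      k <- k + 1L
      stack <- list(c(r, c)); lab[r, c] <- k
      while (length(stack)) {
        cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
          rr <- cur[1L] + d[1L]; cc <- cur[2L] + d[2L]
          if (rr >= 1 && rr <= height && cc >= 1 && cc <= width &&
              m[rr, cc] == 1L && lab[rr, cc] == 0L) {
            lab[rr, cc] <- k
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  list(k = k,
       lab = vapply(ids, function(id)
         lab[(id - 1L) %/% width + 1L, (id - 1L) %% width + 1L], integer(1)),
       ids = ids)
}

## H0 spaces and arrow matrices of a reef_zigzag_seq.  maps[[p]] is the
## matrix of the arrow between positions p and p+1; `dir[p]` is +1 for a
## forward arrow (V_p -> V_{p+1}) and -1 for backward (V_{p+1} -> V_p).
oracle_spaces <- function(zz) {
  P <- length(zz$vertex_sets)
  labs <- lapply(zz$vertex_sets, oracle_labels, width = zz$width,
                 height = zz$height)
  dims <- vapply(labs, `[[`, integer(1), "k")
  maps <- vector("list", P - 1L)
  dir <- integer(P - 1L)
  mapmat <- function(sub, sup) {
    M <- matrix(0L, nrow = sup$k, ncol = sub$k)
    if (sub$k) {
      tgt <- sup$lab[match(sub$ids, sup$ids)]
      for (j in seq_len(sub$k)) M[tgt[sub$lab == j][1L], j] <- 1L
    }
    M
  }
  for (p in seq_len(P - 1L)) {
    if (p %% 2L == 1L) { dir[p] <- -1L; maps[[p]] <- mapmat(labs[[p + 1L]], labs[[p]]) }
    else { dir[p] <- 1L; maps[[p]] <- mapmat(labs[[p]], labs[[p + 1L]]) }
  }
  list(dims = dims, maps = maps, dir = dir)
}

gf2_rank_mat <- function(M) {
  if (!length(M) || nrow(M) == 0L || ncol(M) == 0L) return(0L)
  M <- M %% 2L
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[row:nrow(M), col] == 1L)
    if (!length(piv)) next
    piv <- piv[1L] + row - 1L
    tmp <- M[row, ]; M[row, ] <- M[piv, ]; M[piv, ] <- tmp
    for (r in seq_len(nrow(M))) {
      if (r != row && M[r, col] == 1L) M[r, ] <- (M[r, ] + M[row, ]) %% 2L
    }
    rank <- rank + 1L
    row <- row + 1L
    if (row > nrow(M)) break
  }
  rank
}

## GF(2) null-space basis (columns) of M, by column reduction of M with
## an identity tail recording the column operations.
gf2_nullspace <- function(M) {
  n <- ncol(M)
  if (n == 0L) return(matrix(0L, 0L, 0L))
  if (nrow(M) == 0L) return(diag(1L, n))
  m <- nrow(M)
  A <- rbind(M %% 2L, diag(1L, n))
  col_of_low <- rep(NA_integer_, m)
  pivrow_of_col <- rep(NA_integer_, n)
  for (col in seq_len(n)) {
    x <- A[, col]
    repeat {
      piv <- which(x[seq_len(m)] == 1L)
      if (!length(piv)) break
      low <- piv[[length(piv)]]
      cc <- col_of_low[[low]]
      if (is.na(cc)) { col_of_low[[low]] <- col; pivrow_of_col[[col]] <- low; break }
      x <- (x + A[, cc]) %% 2L
    }
    A[, col] <- x
  }
  nullcols <- which(is.na(pivrow_of_col))
  A[(m + 1L):(m + n), nullcols, drop = FALSE]
}

## Generalized rank of the window [a, b] (1-based positions).
oracle_grank <- function(sp, a, b) {
  dims <- sp$dims[a:b]
  n <- sum(dims)
  if (n == 0L) return(0L)
  offs <- cumsum(c(0L, dims))  # block offsets within the window
  ## limit: kernel of the compatibility constraints
  crows <- list()
  for (p in (if (b > a) a:(b - 1L) else integer(0))) {
    i <- p - a + 1L              # window-local index of p
    M <- sp$maps[[p]]
    if (sp$dir[p] == 1L) {       # x_{p+1} = M x_p
      C <- matrix(0L, nrow(M), n)
      if (ncol(M)) C[, offs[i] + seq_len(dims[i])] <- M
      if (nrow(M)) C[, offs[i + 1L] + seq_len(dims[i + 1L])] <-
          (C[, offs[i + 1L] + seq_len(dims[i + 1L]), drop = FALSE] +
             diag(1L, nrow(M))) %% 2L
    } else {                     # x_p = M x_{p+1}
      C <- matrix(0L, nrow(M), n)
      if (ncol(M)) C[, offs[i + 1L] + seq_len(dims[i + 1L])] <- M
      if (nrow(M)) C[, offs[i] + seq_len(dims[i])] <-
          (C[, offs[i] + seq_len(dims[i]), drop = FALSE] +
             diag(1L, nrow(M))) %% 2L
    }
    crows[[length(crows) + 1L]] <- C
  }
  Cmat <- if (length(crows)) do.call(rbind, crows) else
    matrix(0L, 0L, n)
  L <- gf2_nullspace(Cmat)       # columns = limit basis, in ⊕V coords
  if (!ncol(L)) return(0L)
  ## colimit relations: for each arrow, source-vector + image-vector
  rels <- list()
  for (p in (if (b > a) a:(b - 1L) else integer(0))) {
    i <- p - a + 1L
    M <- sp$maps[[p]]
    if (sp$dir[p] == 1L) { srci <- i; tgti <- i + 1L } else { srci <- i + 1L; tgti <- i }
    if (ncol(M) == 0L) next
    R <- matrix(0L, n, ncol(M))
    R[offs[srci] + seq_len(ncol(M)), ] <- diag(1L, ncol(M))
    if (nrow(M)) R[offs[tgti] + seq_len(nrow(M)), ] <-
        (R[offs[tgti] + seq_len(nrow(M)), , drop = FALSE] + M) %% 2L
    rels[[length(rels) + 1L]] <- R
  }
  Rmat <- if (length(rels)) do.call(cbind, rels) else matrix(0L, n, 0L)
  ## canonical map: limit tuple -> class of its component at position a
  La <- matrix(0L, n, ncol(L))
  if (dims[1L]) La[seq_len(dims[1L]), ] <- L[seq_len(dims[1L]), , drop = FALSE]
  gf2_rank_mat(cbind(Rmat, La)) - gf2_rank_mat(Rmat)
}

## Interval multiset via inclusion-exclusion on generalized ranks.
oracle_intervals <- function(zz) {
  sp <- oracle_spaces(zz)
  P <- length(sp$dims)
  out <- list()
  for (a in seq_len(P)) for (b in a:P) {
    m <- oracle_grank(sp, a, b)
    if (a > 1L) m <- m - oracle_grank(sp, a - 1L, b)
    if (b < P) m <- m - oracle_grank(sp, a, b + 1L)
    if (a > 1L && b < P) m <- m + oracle_grank(sp, a - 1L, b + 1L)
    if (m > 0L) out[[length(out) + 1L]] <- cbind(birth_pos = a, death_pos = b,
                                                 mult = m)
  }
  if (!length(out)) return(data.frame(birth_pos = integer(0),
                                      death_pos = integer(0)))
  tab <- as.data.frame(do.call(rbind, out))
  tab <- tab[rep(seq_len(nrow(tab)), tab$mult), c("birth_pos", "death_pos")]
  tab <- tab[order(tab$birth_pos, tab$death_pos), ]
  rownames(tab) <- NULL
  tab
}

## Random short blob trajectory for zigzag property tests.
rand_blob_traj <- function(width, height, ntimes, p_coral = 0.35,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  masks <- lapply(seq_len(ntimes), function(i)
    matrix(runif(width * height) < p_coral, nrow = height))
  make_blob_movie(masks)
}

## Canonical form of an interval table for multiset comparison.
interval_key <- function(df)
  sort(paste(df$birth_pos, df$death_pos, sep = ":"))
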