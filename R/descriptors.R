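## Non-topological spatial summaries: the nine neighbourhood descriptors
## and cluster statistics.

#' Neighbourhood composition descriptors
#'
#' For every ordered species pair (sigma, X), the descriptor `sigma_X` is
#' the mean over all nodes `i` of type `X` of the fraction of `i`'s
#' neighbours that are of type `sigma`.  `C_C`, for instance, is the
#' average fraction of a coral node's neighbours that are coral.  A
#' descriptor whose reference species `X` is absent from the snapshot is
#' reported as `NA` (missing, never 0), so that averages over realizations
#' skip rather than bias it.
#'
#' @param snap a `reef_snapshot`.
#' @param nbhd a [build_neighbourhood()] index with matching dimensions.
#' @return A one-row data frame with the covers `C`, `T`, `M` and the nine
#'   descriptors `C_C, T_C, M_C, C_T, T_T, M_T, C_M, T_M, M_M` (in
#'   `sigma_X` order: neighbour species first, reference species second).
#' @export
neighbourhood_descriptors <- function(snap, nbhd) {
  stopifnot(inherits(snap, "reef_snapshot"),
            inherits(nbhd, "reef_neighbourhood"))
  if (snap$width != nbhd$width || snap$height != nbhd$height)
    stop("snapshot and neighbourhood have different grid dimensions")
  svec <- state_vec(snap)
  counts <- neighbour_counts_vec(svec, nbhd)
  frac <- counts / pmax(nbhd$degree, 1L)
  lab <- c("C", "T", "M")
  out <- as.list(covers(snap))
  for (X in 0:2) {
    sel <- svec == X
    for (sigma in 0:2) {
      nm <- paste0(lab[sigma + 1L], "_", lab[X + 1L])
      out[[nm]] <- if (any(sel)) mean(frac[sel, sigma + 1L]) else NA_real_
    }
  }
  as.data.frame(out[c("C", "T", "M",
                      "C_C", "T_C", "M_C", "C_T", "T_T", "M_T",
                      "C_M", "T_M", "M_M")])
}

## Connected components of the subgraph induced by `ids` (node ids) under
## the neighbourhood graph; returns component label per id (1..k).
component_labels <- function(ids, nbhd) {
  if (!length(ids)) return(integer(0))
  pos <- integer(nbhd$width * nbhd$height)
  pos[ids] <- seq_along(ids)
  parent <- seq_along(ids)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nx <- parent[i]; parent[i] <<- r; i <- nx }
    r
  }
  for (a in seq_along(ids)) {
    nb <- neighbours(nbhd, ids[a])
    for (b in pos[nb[pos[nb] > 0L]]) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' Cluster statistics of one species
#'
#' Connected components of the nodes of a species under the same
#' neighbourhood graph that drives the dynamics (so at `ell = 1.45`,
#' Moore connectivity including diagonals).
#'
#' @inheritParams neighbourhood_descriptors
#' @param species `"coral"`, `"turf"` or `"macroalgae"` (or a code 0/1/2).
#' @return A list with `n_clusters` and `mean_cluster_size` (`NA` when the
#'   species is absent).
#' @export
cluster_stats <- function(snap, nbhd, species = "coral") {
  stopifnot(inherits(snap, "reef_snapshot"))
  code <- if (is.numeric(species)) as.integer(species)
          else species_code(species)
  ids <- which(state_vec(snap) == code)
  if (!length(ids))
    return(list(n_clusters = 0L, mean_cluster_size = NA_real_))
  labels <- component_labels(ids, nbhd)
  k <- max(labels)
  list(n_clusters = k, mean_cluster_size = length(ids) / k)
}

#' Descriptor table for a trajectory
#'
#' One row per recorded snapshot: time, covers, the nine neighbourhood
#' descriptors, and coral cluster statistics.
#'
#' @param traj a `reef_trajectory`.
#' @param nbhd optional neighbourhood index (defaults to the trajectory's
#'   own `ell`).
#' @return A data frame, one row per recorded snapshot.
#' @export
describe_trajectory <- function(traj, nbhd = NULL) {
  stopifnot(inherits(traj, "reef_trajectory"))
  if (is.null(nbhd))
    nbhd <- build_neighbourhood(traj$width, traj$height, traj$params$ell)
  rows <- lapply(traj$snapshots, function(sn) {
    d <- neighbourhood_descriptors(sn, nbhd)
    cs <- cluster_stats(sn, nbhd, "coral")
    cbind(t = sn$time, d, n_clusters = cs$n_clusters,
          mean_cluster_size = cs$mean_cluster_size)
  })
  do.call(rbind, rows)
}
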