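## Persistence landscapes of (zigzag) intervals on the time axis, their
## averages over realizations, and landscape integrals.

#' Tent function of one interval
#'
#' An interval `[b, d]` contributes a triangular "tent": zero outside the
#' interval, rising linearly from `(b, 0)` to the peak at
#' `((b + d) / 2, (d - b) / 2)` and back down to `(d, 0)`.  The peak time
#' is halfway through the feature's life span; the peak height is half its
#' lifetime, so an interval `[50, 100]` peaks at `(75, 25)`.
#'
#' @param birth,death interval endpoints (`death >= birth`).
#' @return A list with `peak = c(t = , s = )` and a vectorized evaluator
#'   `value(t)`.
#' @export
tent <- function(birth, death) {
  if (death < birth) stop("`death` must be >= `birth`")
  list(peak = c(t = (birth + death) / 2, s = (death - birth) / 2),
       value = function(t) pmax(0, pmin(t - birth, death - t)))
}

interval_frame <- function(intervals) {
  if (inherits(intervals, "reef_zigzag"))
    return(data.frame(birth = intervals$birth_time,
                      death = intervals$death_time))
  intervals <- as.data.frame(intervals)
  if (all(c("birth_time", "death_time") %in% names(intervals)))
    return(data.frame(birth = intervals$birth_time,
                      death = intervals$death_time))
  if (all(c("birth", "death") %in% names(intervals)))
    return(intervals[, c("birth", "death")])
  stop("`intervals` must have birth/death (or birth_time/death_time) columns")
}

#' Persistence landscape of an interval set
#'
#' The k-th landscape \eqn{\lambda_k(t)} is the k-th largest tent value at
#' `t` (zero when fewer than `k` tents are positive).  Zero-length
#' intervals contribute zero tents and therefore vanish here.
#'
#' @param intervals a `reef_zigzag`, or a data frame with `birth`/`death`
#'   (or `birth_time`/`death_time`) columns.
#' @param K number of landscape levels (default 3).
#' @param grid time grid to sample on; defaults to a uniform grid of
#'   resolution `res` spanning the intervals.
#' @param res grid resolution in model time units (default 0.1).
#' @return An object of class `reef_landscape`: time grid `t`, a `K x
#'   length(t)` matrix `lambda`, the number of realizations `n` (1 here),
#'   and per-level integrals.
#' @export
landscape <- function(intervals, K = 3, grid = NULL, res = 0.1) {
  iv <- interval_frame(intervals)
  if (K < 1) stop("`K` must be >= 1")
  if (is.null(grid)) {
    if (!nrow(iv)) stop("empty interval set needs an explicit `grid`")
    grid <- seq(min(iv$birth), max(iv$death), by = res)
  }
  if (length(grid) < 2L) stop("`grid` must have at least 2 points")
  lam <- matrix(0, nrow = K, ncol = length(grid))
  if (nrow(iv)) {
    tents <- vapply(grid, function(t)
      pmax(0, pmin(t - iv$birth, iv$death - t)), numeric(nrow(iv)))
    tents <- matrix(tents, nrow = nrow(iv))
    for (j in seq_along(grid)) {
      v <- sort(tents[, j], decreasing = TRUE)
      kk <- min(K, length(v))
      lam[seq_len(kk), j] <- v[seq_len(kk)]
    }
  }
  new_landscape(grid, lam, n = 1L)
}

new_landscape <- function(grid, lam, n) {
  structure(list(t = grid, lambda = lam, K = nrow(lam), n = n,
                 integrals = apply(lam, 1L, trapezoid, x = grid)),
            class = "reef_landscape")
}

trapezoid <- function(y, x) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)

#' @export
print.reef_landscape <- function(x, ...) {
  cat(sprintf("persistence landscape: K = %d, grid [%g, %g] (%d points), n = %d\n",
              x$K, min(x$t), max(x$t), length(x$t), x$n))
  cat("  integrals:", paste(sprintf("int l%d = %.3g", seq_len(x$K),
                                    x$integrals), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.reef_landscape <- function(x, ...) {
  matplot(x$t, t(x$lambda), type = "l", lty = 1,
          col = hcl.colors(x$K, "Dark 3"), xlab = "time t",
          ylab = expression(lambda[k](t)), ...)
  legend("topright", sprintf("k = %d", seq_len(x$K)), lty = 1,
         col = hcl.colors(x$K, "Dark 3"), bty = "n")
  invisible(x)
}

#' Average landscapes over realizations
#'
#' Pointwise mean of per-realization landscapes on a common grid.  The
#' maximum of the k-th average landscape can be read as the average
#' half-lifetime of the k-th most time-persistent coral component.
#'
#' @param landscapes list of `reef_landscape` objects on identical grids.
#' @return A `reef_landscape` with `n` = total realizations.
#' @export
average_landscapes <- function(landscapes) {
  stopifnot(length(landscapes) >= 1L,
            all(vapply(landscapes, inherits, logical(1), "reef_landscape")))
  g <- landscapes[[1L]]$t
  for (l in landscapes)
    if (length(l$t) != length(g) || any(l$t != g))
      stop("landscapes must share an identical time grid")
  K <- max(vapply(landscapes, `[[`, integer(1), "K"))
  acc <- matrix(0, K, length(g))
  for (l in landscapes) acc[seq_len(l$K), ] <- acc[seq_len(l$K), ] + l$lambda
  new_landscape(g, acc / length(landscapes),
                n = sum(vapply(landscapes, `[[`, integer(1), "n")))
}

#' Integral of one landscape level
#'
#' Trapezoidal integral of \eqn{\lambda_k} over the landscape's grid.
#'
#' @param ls a `reef_landscape`.
#' @param k landscape level.
#' @return The integral (model time units squared).
#' @export
landscape_integral <- function(ls, k = 1) {
  stopifnot(inherits(ls, "reef_landscape"), k >= 1, k <= ls$K)
  trapezoid(ls$lambda[k, ], ls$t)
}

#' Zigzag landscapes of a set of trajectories
#'
#' End-to-end helper: pre-process, build the zigzag sequence, decompose in
#' H0, build the landscape per trajectory, and average.
#'
#' @param trajs a `reef_trajectory` or list of them.
#' @param K landscape levels (default 3).
#' @param res grid resolution (default 0.1 time units).
#' @param preprocess passed to [build_zigzag()].
#' @return A `reef_landscape` (average over the supplied trajectories).
#' @export
zigzag_landscapes <- function(trajs, K = 3, res = 0.1, preprocess = TRUE) {
  if (inherits(trajs, "reef_trajectory")) trajs <- list(trajs)
  t0 <- min(trajs[[1L]]$times); t1 <- max(trajs[[1L]]$times)
  grid <- seq(t0, t1, by = res)
  ls <- lapply(trajs, function(tr) {
    zz <- build_zigzag(tr, preprocess = preprocess)
    iv <- zigzag_h0(zz)
    landscape(iv, K = K, grid = grid)
  })
  average_landscapes(ls)
}

#' Write a landscape as CSV (with a JSON sidecar of integrals)
#'
#' @param ls a `reef_landscape`.
#' @param path output CSV path; the sidecar is `<path>.json`.
#' @export
write_landscape <- function(ls, path) {
  df <- data.frame(t = ls$t)
  for (k in seq_len(ls$K)) df[[paste0("lambda", k)]] <- ls$lambda[k, ]
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n = ls$n, integrals = ls$integrals),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
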