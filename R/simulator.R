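## Stochastic evolution of the spatial coral-turf-macroalgae lattice model,
## its deterministic mean-field ODE limit, and outcome classification.

#' Model parameters
#'
#' Rates of the stochastic lattice model.  Defaults fix the competition
#' rates to r = 1 (coral recruitment over turf), d = 0.4 (coral death),
#' a = 0.2 (macroalgae overgrowing coral), gamma = 0.75 (macroalgae
#' overgrowing turf); the grazing rate `g` and the neighbourhood radius
#' `ell` are the two parameters varied in experiments.
#'
#' The neighbourhood modulation functions default to `nu1 == 1` (coral
#' death is density-independent) and `nu2 = max(eps_div, t_i + m_i)`, the
#' local fraction of grazeable cover around a macroalgae node; these are
#' the choices under which the all-to-all neighbourhood limit reproduces
#' every term of the mean-field ODE, including the saturating grazing
#' `g M / (M + T)`.  Both can be replaced by custom functions of the
#' neighbour fractions (R engine only).
#'
#' @param r,d,a,gamma,g non-negative reaction rates.
#' @param ell neighbourhood radius (Euclidean, lattice units); 1.45 gives
#'   the 8-node Moore neighbourhood.
#' @param dt time step (model time units).
#' @param eps_div guard against division by zero in `g / nu2`.
#' @param scheme per-node event probability within `dt`: `"linear"`
#'   (default) uses `min(1, Lambda dt)`, whose expected event count per
#'   step is exact; `"exponential"` uses `1 - exp(-Lambda dt)`.
#' @param pair_scaling `"fraction"` (default): a pair reaction contributes
#'   base rate times the neighbour *fraction* of the partner species;
#'   `"count"` uses the raw neighbour count instead.
#' @param nu1,nu2 optional replacement modulation functions taking the
#'   neighbour fraction vectors `(c, t, m)` and returning a vector.
#' @return An object of class `smhe_params`.
#' @export
smhe_params <- function(r = 1, d = 0.4, a = 0.2, gamma = 0.75, g = 0.53,
                        ell = 1.45, dt = 1, eps_div = 1e-12,
                        scheme = c("linear", "exponential"),
                        pair_scaling = c("fraction", "count"),
                        nu1 = NULL, nu2 = NULL) {
  rates <- c(r = r, d = d, a = a, gamma = gamma, g = g)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive")
  if (!is.finite(ell) || ell <= 0) stop("`ell` must be positive")
  structure(list(r = r, d = d, a = a, gamma = gamma, g = g, ell = ell,
                 dt = dt, eps_div = eps_div, scheme = match.arg(scheme),
                 pair_scaling = match.arg(pair_scaling),
                 nu1 = nu1, nu2 = nu2),
            class = "smhe_params")
}

#' @export
print.smhe_params <- function(x, ...) {
  cat(sprintf(
    "sMHE parameters: r = %g, d = %g, a = %g, gamma = %g, g = %g\n",
    x$r, x$d, x$a, x$gamma, x$g))
  cat(sprintf("  ell = %g, dt = %g, scheme = %s, pair scaling = %s\n",
              x$ell, x$dt, x$scheme, x$pair_scaling))
  if (!is.null(x$nu1) || !is.null(x$nu2))
    cat("  custom nu modulation functions supplied\n")
  invisible(x)
}

#' Stochastic spatial reef model
#'
#' Bundles parameters, grid size and initial configuration into a model
#' object; realizations are drawn with [simulate()].
#'
#' @param params an [smhe_params()] object.
#' @param width,height grid dimensions (default 25 x 25).
#' @param init `"random"` or `"cluster"` initial configuration, or a
#'   `reef_snapshot` to start from.
#' @param covers initial fractional covers `(C0, T0, M0)` (ignored when
#'   `init` is a snapshot).
#' @return An object of class `smhe`.
#' @export
smhe <- function(params = smhe_params(), width = 25, height = 25,
                 init = c("random", "cluster"), covers = c(1, 1, 1) / 3) {
  stopifnot(inherits(params, "smhe_params"))
  if (!inherits(init, "reef_snapshot")) {
    init <- match.arg(init)
    covers <- check_covers(covers)
  } else {
    width <- init$width; height <- init$height
  }
  structure(list(params = params, width = as.integer(width),
                 height = as.integer(height), init = init, covers = covers,
                 nbhd = build_neighbourhood(width, height, params$ell)),
            class = "smhe")
}

#' @export
print.smhe <- function(x, ...) {
  cat(sprintf("sMHE lattice model: %d x %d nodes (%d)\n", x$height, x$width,
              x$width * x$height))
  print(x$params)
  if (inherits(x$init, "reef_snapshot")) {
    cat("  init: fixed snapshot\n")
  } else {
    cat(sprintf("  init: %s, covers (%.3g, %.3g, %.3g)\n", x$init,
                x$covers[1], x$covers[2], x$covers[3]))
  }
  invisible(x)
}

initial_snapshot <- function(model, seed = NULL) {
  if (inherits(model$init, "reef_snapshot")) {
    if (!is.null(seed)) set.seed(seed)
    return(model$init)
  }
  switch(model$init,
         random = random_config(model$width, model$height, model$covers, seed),
         cluster = cluster_config(model$width, model$height, model$covers, seed))
}

## Deterministic child seed for realization k of a base seed (31-bit LCG mix).
child_seed <- function(base, k) {
  as.integer((as.numeric(base) %% 2147483647 * 48271 +
                as.numeric(k) * 1299721) %% 2147483629 + 1)
}

## Neighbour composition of every node: counts and fractions per species.
neighbour_counts_vec <- function(svec, nbhd) {
  counts <- vapply(0:2, function(code) {
    cs <- c(0L, cumsum(svec[nbhd$indices] == code))
    cs[nbhd$indptr[-1L] + 1L] - cs[nbhd$indptr[-length(nbhd$indptr)] + 1L]
  }, integer(length(svec)))
  colnames(counts) <- c("C", "T", "M")
  counts
}

## Per-node rate table on the row-major state vector; returns the two
## possible reaction rates and their target codes for every node.
all_rates <- function(svec, params, nbhd) {
  counts <- neighbour_counts_vec(svec, nbhd)
  deg <- pmax(nbhd$degree, 1L)
  if (params$pair_scaling == "fraction") {
    fc <- counts[, 1L] / deg; ft <- counts[, 2L] / deg; fm <- counts[, 3L] / deg
  } else {
    fc <- counts[, 1L]; ft <- counts[, 2L]; fm <- counts[, 3L]
  }
  nu1 <- if (is.null(params$nu1)) rep(1, length(svec))
         else params$nu1(fc, ft, fm)
  nu2 <- if (is.null(params$nu2)) pmax(params$eps_div, ft + fm)
         else params$nu2(fc, ft, fm)

  rate1 <- rate2 <- numeric(length(svec))
  target1 <- target2 <- rep(NA_integer_, length(svec))
  turf <- svec == 1L; coral <- svec == 0L; macro <- svec == 2L
  rate1[turf] <- params$r * fc[turf];        target1[turf] <- 0L
  rate2[turf] <- params$gamma * fm[turf];    target2[turf] <- 2L
  rate1[coral] <- params$d / nu1[coral];     target1[coral] <- 1L
  rate2[coral] <- params$a * fm[coral];      target2[coral] <- 2L
  rate1[macro] <- params$g / nu2[macro];     target1[macro] <- 1L
  list(rate1 = rate1, rate2 = rate2, target1 = target1, target2 = target2)
}

#' Per-reaction rates of a single node
#'
#' The reactions available to one node given its current species and the
#' composition of its neighbourhood: a turf node can be overgrown by coral
#' (rate `r * c_i`) or macroalgae (`gamma * m_i`); a coral node dies
#' (`d / nu1`) or is overgrown by macroalgae (`a * m_i`); a macroalgae
#' node is grazed back to turf (`g / nu2`).  Here `c_i`, `t_i`, `m_i` are
#' the species fractions among the node's neighbours.
#'
#' @param snap a `reef_snapshot`.
#' @param node row-major node id or `c(row, col)`.
#' @param params an [smhe_params()] object.
#' @param nbhd a [build_neighbourhood()] index matching `params$ell`.
#' @return Named numeric vector of reaction rates, e.g. `c("T->C" = ...,
#'   "T->M" = ...)` for a turf node.
#' @export
node_rates <- function(snap, node, params, nbhd) {
  stopifnot(inherits(snap, "reef_snapshot"))
  id <- node_id(nbhd, node)
  rt <- all_rates(state_vec(snap), params, nbhd)
  lab <- c("C", "T", "M")
  own <- lab[state_vec(snap)[id] + 1L]
  out <- c(rt$rate1[id], rt$rate2[id])
  names(out) <- paste0(own, "->", lab[c(rt$target1[id], rt$target2[id]) + 1L])
  out[!is.na(names(out)) & names(out) != paste0(own, "->NA")]
}

#' One synchronous update step (reference implementation)
#'
#' All rate tables are evaluated on the state at the start of the step;
#' each node fires at most one event with probability
#' `1 - exp(-Lambda dt)`, the event chosen proportionally to the
#' individual rates, and all transitions are applied simultaneously.
#' Draws come from R's global RNG in fixed row-major order (first the
#' firing uniforms for all nodes, then the event-choice uniforms), so this
#' stepper is bit-identical to the compiled fast path under the same seed.
#'
#' @inheritParams node_rates
#' @return The updated `reef_snapshot`, with time advanced by `dt`.
#' @export
lattice_step <- function(snap, params, nbhd) {
  svec <- state_vec(snap)
  rt <- all_rates(svec, params, nbhd)
  lambda <- rt$rate1 + rt$rate2
  n <- length(svec)
  u1 <- runif(n); u2 <- runif(n)
  pfire <- if (params$scheme == "linear") pmin(1, lambda * params$dt)
           else 1 - exp(-lambda * params$dt)
  fire <- lambda > 0 & u1 < pfire
  first <- u2 < ifelse(lambda > 0, rt$rate1 / lambda, 0)
  svec[fire & first] <- rt$target1[fire & first]
  svec[fire & !first] <- rt$target2[fire & !first]
  vec_snapshot(svec, snap$width, snap$height, time = snap$time + params$dt)
}

#' Simulate the stochastic reef model
#'
#' @param object an [smhe()] model.
#' @param nsim number of realizations.  Realization `k` runs on a child
#'   seed derived deterministically from `seed` and `k`.
#' @param seed base RNG seed (integer); `NULL` continues the current RNG
#'   state (single realization only).
#' @param steps number of time steps (horizon = `steps * dt`).
#' @param record_every snapshot recording stride in steps (covers are
#'   recorded every step regardless); 0 records only the initial snapshot.
#' @param stop_on_absorption stop a realization early once coral or
#'   macroalgae has vanished (both states are absorbing for the species
#'   that vanished; used by outcome sweeps).
#' @param engine `"cpp"` (default) or `"r"` (reference stepper).  The R
#'   engine is selected automatically when custom `nu1`/`nu2` functions
#'   are supplied.
#' @param ... unused.
#' @return A `reef_trajectory` when `nsim = 1`, otherwise a list of them.
#' @export
simulate.smhe <- function(object, nsim = 1, seed = NULL, steps = 100,
                          record_every = 1, stop_on_absorption = FALSE,
                          engine = c("cpp", "r"), ...) {
  engine <- match.arg(engine)
  if (!is.null(object$params$nu1) || !is.null(object$params$nu2))
    engine <- "r"
  if (!is.numeric(steps) || steps <= 0) stop("`steps` must be positive")
  steps <- as.integer(steps)
  if (nsim == 1L) {
    sd1 <- if (is.null(seed)) NULL else as.integer(seed)
    return(one_run(object, sd1, steps, record_every, stop_on_absorption,
                   engine))
  }
  if (is.null(seed)) stop("`seed` is required for multi-realization runs")
  lapply(seq_len(nsim), function(k)
    one_run(object, child_seed(seed, k), steps, record_every,
            stop_on_absorption, engine))
}

one_run <- function(model, seed, steps, record_every, stop_on_absorption,
                    engine) {
  snap0 <- initial_snapshot(model, seed)
  p <- model$params
  if (engine == "cpp") {
    res <- sim_steps_cpp(state_vec(snap0), model$nbhd$indptr,
                         model$nbhd$indices, p$r, p$d, p$a, p$gamma, p$g,
                         p$dt, p$eps_div, p$scheme == "linear",
                         p$pair_scaling == "count", steps,
                         as.integer(record_every), stop_on_absorption,
                         snap0$time)
    times <- snap0$time + res$rec_steps * p$dt
    snaps <- lapply(seq_along(times), function(i)
      vec_snapshot(res$states[i, ], model$width, model$height, times[i]))
    cov <- as.data.frame(res$covers)
    names(cov) <- c("C", "T", "M")
    cov <- cbind(t = snap0$time + (seq_len(nrow(cov)) - 1) * p$dt, cov)
  } else {
    snaps <- list(snap0)
    cur <- snap0
    cov_list <- list(covers(cur))
    for (s in seq_len(steps)) {
      cur <- lattice_step(cur, p, model$nbhd)
      cov_list[[s + 1L]] <- covers(cur)
      if (record_every > 0 && s %% record_every == 0L)
        snaps[[length(snaps) + 1L]] <- cur
      if (stop_on_absorption &&
          (cov_list[[s + 1L]][["C"]] == 0 || cov_list[[s + 1L]][["M"]] == 0))
        break
    }
    cm <- do.call(rbind, cov_list)
    cov <- data.frame(t = snap0$time + (seq_len(nrow(cm)) - 1) * p$dt,
                      C = cm[, "C"], T = cm[, "T"], M = cm[, "M"])
  }
  structure(list(snapshots = snaps, covers = cov,
                 times = vapply(snaps, `[[`, numeric(1), "time"),
                 params = p, width = model$width, height = model$height,
                 seed = seed),
            class = "reef_trajectory")
}

#' @export
print.reef_trajectory <- function(x, ...) {
  cat(sprintf(
    "reef trajectory: %d x %d grid, t in [%g, %g], %d recorded snapshots\n",
    x$height, x$width, min(x$covers$t), max(x$covers$t), length(x$snapshots)))
  fin <- x$covers[nrow(x$covers), ]
  cat(sprintf("  final covers: C = %.3f, T = %.3f, M = %.3f\n",
              fin$C, fin$T, fin$M))
  invisible(x)
}

#' @export
plot.reef_trajectory <- function(x, ...) {
  matplot(x$covers$t, x$covers[, c("C", "T", "M")], type = "l", lty = 1,
          col = c("#e75480", "#9ecae1", "#2ca02c"), xlab = "time t",
          ylab = "fractional cover", ...)
  legend("topright", c("coral", "turf", "macroalgae"), lty = 1,
         col = c("#e75480", "#9ecae1", "#2ca02c"), bty = "n")
  invisible(x)
}

#' Mean-field ODE of the reef model
#'
#' Integrates the deterministic two-variable system
#' `dC/dt = r C T - d C - a C M`,
#' `dM/dt = a C M - g M / (M + T) + gamma M T`, with `T = 1 - C - M`,
#' which the lattice model approaches when the neighbourhood spans the
#' whole grid.
#'
#' @param covers0 initial covers `(C0, T0, M0)` on the simplex.
#' @param params an [smhe_params()] object (only the rates are used).
#' @param horizon final time.
#' @param times optional explicit output time vector.
#' @return A data frame with columns `t`, `C`, `T`, `M`.
#' @export
integrate_mhe <- function(covers0, params = smhe_params(), horizon = 100,
                          times = NULL) {
  covers0 <- check_covers(covers0)
  if (is.null(times)) times <- seq(0, horizon, by = min(0.1, horizon))
  # integration starts at t = 0: prepend it if absent and drop it on return
  had0 <- any(times == 0)
  times <- sort(unique(c(0, times)))
  eps <- params$eps_div
  rhs <- function(t, y, p) {
    C <- y[[1L]]; M <- y[[2L]]; Tt <- 1 - C - M
    dC <- p$r * C * Tt - p$d * C - p$a * C * M
    dM <- p$a * C * M - p$g * M / max(eps, M + Tt) + p$gamma * M * Tt
    list(c(dC, dM))
  }
  sol <- deSolve::ode(y = c(C = covers0[[1L]], M = covers0[[3L]]),
                      times = times, func = rhs, parms = params,
                      rtol = 1e-8, atol = 1e-8)
  out <- data.frame(t = sol[, "time"], C = sol[, "C"],
                    T = 1 - sol[, "C"] - sol[, "M"], M = sol[, "M"])
  if (!had0) out <- out[out$t != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the long-term outcome of a trajectory
#'
#' Macroalgae-dominated if coral cover hit zero (an absorbing state),
#' coral-dominated if macroalgae cover hit zero first; otherwise the final
#' covers decide: dominated if the larger of C and M exceeds `threshold`,
#' else undecided.
#'
#' @param traj a `reef_trajectory`.
#' @param threshold dominance threshold on the final cover (default 0.5).
#' @return One of `"coral-dominated"`, `"macroalgae-dominated"`,
#'   `"undecided"`.
#' @export
classify_outcome <- function(traj, threshold = 0.5) {
  stopifnot(inherits(traj, "reef_trajectory"))
  hitC <- match(TRUE, traj$covers$C == 0)
  hitM <- match(TRUE, traj$covers$M == 0)
  if (!is.na(hitC) && (is.na(hitM) || hitC <= hitM))
    return("macroalgae-dominated")
  if (!is.na(hitM)) return("coral-dominated")
  fin <- traj$covers[nrow(traj$covers), ]
  if (max(fin$C, fin$M) > threshold)
    return(if (fin$C > fin$M) "coral-dominated" else "macroalgae-dominated")
  "undecided"
}

#' Outcome fractions over a grazing-rate sweep
#'
#' Runs `nsim` realizations at each grazing rate and tabulates the
#' fraction of coral-dominated, macroalgae-dominated and undecided
#' outcomes.  Realizations stop early once either species is extinct.
#'
#' @param g_values numeric vector of grazing rates.
#' @param nsim realizations per grazing rate.
#' @param seed base seed; realization `k` at the `j`-th grazing rate uses
#'   a child seed of `(seed + j, k)`.
#' @param steps horizon in steps (default 1000).
#' @param width,height,init,covers model setup (see [smhe()]).
#' @param params baseline [smhe_params()]; its `g` is overridden.
#' @param threshold dominance threshold for [classify_outcome()].
#' @return Data frame with one row per grazing rate: `g`, `coral`,
#'   `macroalgae`, `undecided` (fractions), `n`.
#' @export
sweep_outcomes <- function(g_values, nsim = 50, seed = 1, steps = 1000,
                           width = 25, height = 25, init = "random",
                           covers = c(1, 1, 1) / 3, params = smhe_params(),
                           threshold = 0.5) {
  rows <- lapply(seq_along(g_values), function(j) {
    p <- params; p$g <- g_values[[j]]
    model <- smhe(p, width, height, init, covers)
    runs <- simulate(model, nsim = nsim, seed = seed + j, steps = steps,
                     record_every = 0, stop_on_absorption = TRUE)
    out <- vapply(runs, classify_outcome, character(1), threshold = threshold)
    data.frame(g = g_values[[j]],
               coral = mean(out == "coral-dominated"),
               macroalgae = mean(out == "macroalgae-dominated"),
               undecided = mean(out == "undecided"), n = nsim)
  })
  do.call(rbind, rows)
}
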