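## Higher-level experiment drivers: landscape ensembles and grazing-rate
## sweeps combining outcome classification with zigzag landscapes.

trim_trajectory <- function(traj, t_max) {
  keep <- traj$times <= t_max + 1e-9
  traj$snapshots <- traj$snapshots[keep]
  traj$times <- traj$times[keep]
  traj
}

#' Per-realization zigzag landscapes and outcomes
#'
#' Runs `nsim` realizations of a model, classifies each long-term outcome
#' (realizations stop stepping once a species is extinct), computes the
#' zigzag H0 landscape of the snapshots up to `t_max`, and averages the
#' landscapes overall and within each outcome class.
#'
#' @param model an [smhe()] model.
#' @param nsim number of realizations.
#' @param seed base seed (child seeds per realization).
#' @param steps classification horizon in steps (default 1000).
#' @param t_max landscapes use snapshots with `t <= t_max` (default 100).
#' @param K,res landscape levels and grid resolution.
#' @param threshold dominance threshold for [classify_outcome()].
#' @return A list: `outcomes` (character vector), `average`
#'   (`reef_landscape` over all realizations), `by_outcome` (named list
#'   of average landscapes), `integrals` (matrix `nsim x K`).
#' @export
landscape_ensemble <- function(model, nsim = 50, seed = 1, steps = 1000,
                               t_max = 100, K = 3, res = 0.1,
                               threshold = 0.5) {
  grid <- seq(min(t_max, 0), t_max, by = res)
  outcomes <- character(nsim)
  lss <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    traj <- one_run(model, child_seed(seed, k), as.integer(steps),
                    record_every = 1L, stop_on_absorption = TRUE,
                    engine = if (is.null(model$params$nu1) &&
                                   is.null(model$params$nu2)) "cpp" else "r")
    outcomes[[k]] <- classify_outcome(traj, threshold)
    traj <- trim_trajectory(traj, t_max)
    iv <- if (length(traj$snapshots) >= 2L)
      zigzag_h0(build_zigzag(traj)) else
      data.frame(birth_time = numeric(0), death_time = numeric(0))
    lss[[k]] <- landscape(iv, K = K, grid = grid)
  }
  by_outcome <- lapply(split(lss, outcomes), average_landscapes)
  list(outcomes = outcomes, average = average_landscapes(lss),
       by_outcome = by_outcome,
       integrals = do.call(rbind, lapply(lss, `[[`, "integrals")))
}

#' Grazing sweep with outcome fractions and landscape integrals
#'
#' For each grazing rate, runs a [landscape_ensemble()] and tabulates the
#' outcome fractions together with the integrals of the average
#' landscapes.
#'
#' @inheritParams sweep_outcomes
#' @param t_max,K,res landscape settings (see [landscape_ensemble()]).
#' @return A list with `table` (data frame: `g`, outcome fractions,
#'   `int_l1..int_lK`) and `ensembles` (per-g [landscape_ensemble()]
#'   results).
#' @export
sweep_grazing <- function(g_values, nsim = 50, seed = 1, steps = 1000,
                          width = 25, height = 25, init = "random",
                          covers = c(1, 1, 1) / 3, params = smhe_params(),
                          t_max = 100, K = 3, res = 0.1) {
  ens <- vector("list", length(g_values))
  rows <- vector("list", length(g_values))
  for (j in seq_along(g_values)) {
    p <- params; p$g <- g_values[[j]]
    model <- smhe(p, width, height, init, covers)
    e <- landscape_ensemble(model, nsim = nsim, seed = seed + j,
                            steps = steps, t_max = t_max, K = K, res = res)
    ens[[j]] <- e
    ints <- as.list(setNames(e$average$integrals,
                             paste0("int_l", seq_len(K))))
    rows[[j]] <- cbind(
      data.frame(g = g_values[[j]],
                 coral = mean(e$outcomes == "coral-dominated"),
                 macroalgae = mean(e$outcomes == "macroalgae-dominated"),
                 undecided = mean(e$outcomes == "undecided"), n = nsim),
      as.data.frame(ints))
  }
  list(table = do.call(rbind, rows), ensembles = ens)
}
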