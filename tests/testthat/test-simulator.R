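make_state <- function(m) snapshot(m)

test_that("node_rates implements the reaction table", {
  p <- smhe_params(g = 0.53)
  nb <- build_neighbourhood(5, 5, 1.45)

  # turf node with zero coral neighbours: no recruitment
  st <- matrix(1L, 5, 5); st[1, 1] <- 2L
  rt <- node_rates(make_state(st), c(3, 3), p, nb)
  expect_equal(unname(rt[["T->C"]]), 0)

  # coral node: death rate d regardless of neighbours (nu1 == 1)
  st <- matrix(1L, 5, 5); st[3, 3] <- 0L
  rt <- node_rates(make_state(st), c(3, 3), p, nb)
  expect_equal(unname(rt[["C->T"]]), 0.4)

  # macroalgae fully surrounded by macroalgae + turf: grazed at g
  st <- matrix(2L, 5, 5)
  rt <- node_rates(make_state(st), c(3, 3), p, nb)
  expect_equal(unname(rt[["M->T"]]), 0.53)

  # internal turf node with 2 coral Moore neighbours: rate r * 2/8
  st <- matrix(1L, 5, 5); st[2, 2] <- 0L; st[2, 3] <- 0L
  rt <- node_rates(make_state(st), c(3, 3), p, nb)
  expect_equal(unname(rt[["T->C"]]), 1 * 2 / 8)
  # and gamma * m_i for the competing reaction
  st[4, 4] <- 2L
  rt <- node_rates(make_state(st), c(3, 3), p, nb)
  expect_equal(unname(rt[["T->M"]]), 0.75 * 1 / 8)
})

test_that("all-turf grids are fixed points and extinctions are absorbing", {
  m <- smhe(smhe_params(g = 0.5), width = 10, height = 10,
            init = snapshot(matrix(1L, 10, 10)))
  tr <- simulate(m, seed = 1, steps = 20)
  expect_true(all(vapply(tr$snapshots, function(s) all(s$state == 1L),
                         logical(1))))

  # C = 0: coral never reappears
  st <- matrix(sample(1:2, 100, replace = TRUE), 10, 10)
  tr <- simulate(smhe(smhe_params(g = 0.3), init = snapshot(st)),
                 seed = 2, steps = 50)
  expect_true(all(tr$covers$C == 0))

  # M = 0: macroalgae never reappears
  st <- matrix(sample(0:1, 100, replace = TRUE), 10, 10)
  tr <- simulate(smhe(smhe_params(g = 0.3), init = snapshot(st)),
                 seed = 3, steps = 50)
  expect_true(all(tr$covers$M == 0))
})

test_that("simulation conserves covers and is deterministic per seed", {
  m <- smhe(smhe_params(g = 0.45), width = 15, height = 15)
  tr <- simulate(m, seed = 11, steps = 40)
  expect_true(all(abs(tr$covers$C + tr$covers$T + tr$covers$M - 1) < 1e-12))
  for (sn in tr$snapshots) {
    cv <- covers(sn)
    row <- tr$covers[tr$covers$t == sn$time, ]
    expect_equal(c(row$C, row$T, row$M), unname(cv))
  }
  tr2 <- simulate(m, seed = 11, steps = 40)
  expect_identical(tr$covers, tr2$covers)
  expect_identical(lapply(tr$snapshots, as.matrix),
                   lapply(tr2$snapshots, as.matrix))
})

test_that("compiled and reference steppers agree bit for bit", {
  for (scheme in c("linear", "exponential")) {
    m <- smhe(smhe_params(g = 0.53, scheme = scheme), width = 12, height = 9)
    a <- simulate(m, seed = 7, steps = 15, engine = "cpp")
    b <- simulate(m, seed = 7, steps = 15, engine = "r")
    expect_identical(lapply(a$snapshots, as.matrix),
                     lapply(b$snapshots, as.matrix))
    expect_equal(a$covers, b$covers)
  }
})

test_that("custom nu functions are injectable through the R engine", {
  # nu2 == 1 turns grazing into plain mass action g * M
  p <- smhe_params(g = 0.4, nu2 = function(cf, tf, mf) rep(1, length(cf)))
  nb <- build_neighbourhood(5, 5, 1.45)
  st <- matrix(2L, 5, 5)
  rt <- node_rates(snapshot(st), c(3, 3), p, nb)
  expect_equal(unname(rt[["M->T"]]), 0.4)
  m <- smhe(p, width = 8, height = 8)
  tr <- simulate(m, seed = 5, steps = 5)   # dispatches to the R engine
  expect_equal(nrow(tr$covers), 6L)
})

test_that("mean-field ODE integrator matches closed-form behaviour", {
  p <- smhe_params(g = 0.53)
  # all-turf is a fixed point
  sol <- integrate_mhe(c(0, 1, 0), p, horizon = 10, times = c(0, 5, 10))
  expect_true(all(abs(sol$C) < 1e-8) && all(abs(sol$M) < 1e-8))

  # with C = 0 and gamma * T < g / (M + T) everywhere (g > gamma),
  # macroalgae decays to 0
  sol <- integrate_mhe(c(0, 0.8, 0.2), smhe_params(g = 0.8), horizon = 200,
                       times = c(0, 200))
  expect_lt(tail(sol$M, 1), 1e-4)

  # pure logistic coral limit (M = 0): C* = 1 - d/r
  sol <- integrate_mhe(c(0.1, 0.9, 0), p, horizon = 300, times = c(0, 300))
  expect_equal(tail(sol$C, 1), 1 - p$d / p$r, tolerance = 1e-5)
})

test_that("halving the time step leaves ensemble means within MC error", {
  # the linear event probability makes the per-step expected transition
  # count exact, so dt = 1 vs dt = 0.5 differ only at second order
  n <- 150
  get_mean <- function(dt) {
    m <- smhe(smhe_params(g = 0.53, ell = 36, dt = dt), init = "random")
    runs <- simulate(m, nsim = n, seed = 31, steps = round(10 / dt),
                     record_every = 0)
    ce <- vapply(runs, function(r) tail(r$covers$C, 1), numeric(1))
    c(mean(ce), sd(ce) / sqrt(n))
  }
  a <- get_mean(1); b <- get_mean(0.5)
  expect_lt(abs(a[1] - b[1]), 3 * sqrt(a[2]^2 + b[2]^2))
})

test_that("classify_outcome distinguishes absorbing and threshold endings", {
  m <- smhe(smhe_params(g = 0.1), width = 12, height = 12)    # low grazing
  tr <- simulate(m, seed = 2, steps = 400, stop_on_absorption = TRUE)
  expect_equal(classify_outcome(tr), "macroalgae-dominated")

  m <- smhe(smhe_params(g = 0.8), width = 12, height = 12)    # high grazing
  tr <- simulate(m, seed = 2, steps = 400, stop_on_absorption = TRUE)
  expect_equal(classify_outcome(tr), "coral-dominated")

  # threshold logic on a hand-built trajectory
  fake <- function(C, M) structure(
    list(covers = data.frame(t = 0:1, C = c(0.3, C), T = c(0.4, 1 - C - M),
                             M = c(0.3, M))),
    class = "reef_trajectory")
  expect_equal(classify_outcome(fake(0.6, 0.2)), "coral-dominated")
  expect_equal(classify_outcome(fake(0.2, 0.6)), "macroalgae-dominated")
  expect_equal(classify_outcome(fake(0.4, 0.3)), "undecided")
})

test_that("child seeds reproduce individual realizations", {
  m <- smhe(smhe_params(g = 0.4), width = 10, height = 10)
  runs <- simulate(m, nsim = 3, seed = 17, steps = 10)
  third <- simulate(m, seed = reeftda:::child_seed(17, 3), steps = 10)
  expect_identical(lapply(runs[[3]]$snapshots, as.matrix),
                   lapply(third$snapshots, as.matrix))
})
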