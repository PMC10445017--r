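test_that("tents place their peak at mid-life and half-lifetime", {
  tt <- tent(50, 100)
  expect_equal(unname(tt$peak), c(75, 25))
  expect_equal(tt$value(75), 25)
  expect_equal(tt$value(c(50, 100, 0, 200)), c(0, 0, 0, 0))

  expect_equal(tent(3, 3)$value(3), 0)          # zero-length interval
  t02 <- tent(0, 2)
  expect_equal(t02$value(1), 1)
  expect_equal(t02$value(0.5), 0.5)
  expect_error(tent(2, 1), "birth")
})

test_that("landscape levels agree with the brute-force tent-sort oracle", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(1:12, 1)
    birth <- round(runif(n, 0, 50), 2)
    death <- birth + round(runif(n, 0, 30), 2)
    grid <- seq(-5, 90, by = 0.5)
    ls <- landscape(data.frame(birth = birth, death = death), K = 4,
                    grid = grid)
    expect_equal(ls$lambda, brute_landscape(birth, death, 4, grid))
  }
})

test_that("landscapes are ordered, non-negative and 1-Lipschitz", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:15, 1)
    birth <- runif(n, 0, 40); death <- birth + runif(n, 0, 25)
    grid <- seq(0, 70, by = 0.25)
    ls <- landscape(data.frame(birth = birth, death = death), K = 3,
                    grid = grid)
    expect_true(all(ls$lambda >= 0))
    expect_true(all(ls$lambda[1, ] >= ls$lambda[2, ]))
    expect_true(all(ls$lambda[2, ] >= ls$lambda[3, ]))
    for (k in seq_len(ls$K)) {
      slopes <- diff(ls$lambda[k, ]) / diff(grid)
      expect_true(all(abs(slopes) <= 1 + 1e-9))
    }
  }
})

test_that("simple landscape identities hold", {
  grid <- seq(0, 10, by = 0.1)
  one <- landscape(data.frame(birth = 2, death = 8), K = 2, grid = grid)
  tt <- tent(2, 8)
  expect_equal(one$lambda[1, ], tt$value(grid))
  expect_true(all(one$lambda[2, ] == 0))

  # two disjoint equal intervals: lambda1 is the max of both tents,
  # lambda2 vanishes where they do not overlap
  two <- landscape(data.frame(birth = c(0, 6), death = c(4, 10)), K = 2,
                   grid = grid)
  expect_equal(two$lambda[1, ],
               pmax(tent(0, 4)$value(grid), tent(6, 10)$value(grid)))
  expect_true(all(two$lambda[2, grid < 6 - 2] == 0))

  # derived: {[0,10], [2,6]} has lambda_2(4) = 2
  nest <- landscape(data.frame(birth = c(0, 2), death = c(10, 6)), K = 2,
                    grid = seq(0, 10, by = 0.5))
  expect_equal(nest$lambda[2, nest$t == 4], 2)
})

test_that("averaging is linear and respects the grid", {
  grid <- seq(0, 20, by = 0.2)
  a <- landscape(data.frame(birth = 0, death = 20), K = 2, grid = grid)
  b <- landscape(data.frame(birth = 5, death = 15), K = 2, grid = grid)
  avg <- average_landscapes(list(a, b))
  expect_equal(avg$lambda, (a$lambda + b$lambda) / 2)
  expect_equal(avg$n, 2L)
  # identical landscapes average to themselves
  same <- average_landscapes(list(a, a, a))
  expect_equal(same$lambda, a$lambda)
  # integral of the average equals the average of the integrals
  expect_equal(landscape_integral(avg, 1),
               (landscape_integral(a, 1) + landscape_integral(b, 1)) / 2)
  # mismatched grids refuse
  cgrid <- seq(0, 10, by = 0.2)
  cc <- landscape(data.frame(birth = 0, death = 10), K = 2, grid = cgrid)
  expect_error(average_landscapes(list(a, cc)), "grid")
})

test_that("landscape integrals are exact for triangles", {
  grid <- seq(0, 2, by = 0.01)
  ls <- landscape(data.frame(birth = 0, death = 2), K = 1, grid = grid)
  expect_equal(landscape_integral(ls, 1), 1, tolerance = 1e-10)
  zero <- landscape(data.frame(birth = numeric(0), death = numeric(0)),
                    K = 2, grid = grid)
  expect_equal(landscape_integral(zero, 1), 0)
})

test_that("zigzag landscapes run end to end on a simulation", {
  m <- smhe(smhe_params(g = 0.4), width = 10, height = 10)
  trs <- simulate(m, nsim = 3, seed = 44, steps = 10)
  avg <- zigzag_landscapes(trs, K = 3, res = 0.5)
  expect_s3_class(avg, "reef_landscape")
  expect_equal(avg$n, 3L)
  expect_true(all(avg$lambda >= 0))
  expect_true(all(avg$lambda[1, ] >= avg$lambda[2, ]))
})
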