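test_that("neighbourhood counts match brute-force enumeration", {
  nb <- build_neighbourhood(25, 25, 1.45)
  deg <- matrix(nb$degree, 25, 25, byrow = TRUE)
  expect_equal(deg[13, 13], 8L)          # internal node: Moore neighbourhood
  expect_equal(deg[1, 1], 3L)            # corner: boundary truncation
  expect_equal(deg[1, 13], 5L)           # edge midpoint

  # derived: brute force over all integer offsets for several radii
  for (radius in c(1, 1.45, 2, 2.9, 4.3)) {
    nbr <- build_neighbourhood(11, 11, radius)
    degr <- matrix(nbr$degree, 11, 11, byrow = TRUE)
    expect_equal(degr[6, 6], brute_neighbours(11, 11, radius, 6, 6),
                 info = paste("radius", radius))
    expect_equal(degr[1, 4], brute_neighbours(11, 11, radius, 1, 4),
                 info = paste("radius", radius))
  }

  # radius 36 on 25 x 25: all-to-all (max lattice distance 24 * sqrt(2))
  nb36 <- build_neighbourhood(25, 25, 36)
  expect_true(all(nb36$degree == 624L))
  expect_equal(length(nb36$degree), 625L)
})

test_that("neighbour relation is symmetric and excludes self", {
  for (radius in c(1.45, 2.9, 5)) {
    nb <- build_neighbourhood(7, 6, radius)
    for (id in seq_len(42)) {
      nbrs <- neighbours(nb, id)
      expect_false(id %in% nbrs)
      for (j in nbrs) expect_true(id %in% neighbours(nb, j))
    }
  }
})

test_that("invalid neighbourhood arguments error", {
  expect_error(build_neighbourhood(25, 25, 0), "radius")
  expect_error(build_neighbourhood(25, 25, -1), "radius")
  expect_error(build_neighbourhood(0, 25, 1.45), "degenerate")
})

test_that("random_config honours covers and conserves one species per node", {
  all_coral <- random_config(10, 10, c(1, 0, 0), seed = 1)
  expect_true(all(as.matrix(all_coral) == 0L))

  expect_error(random_config(5, 5, c(0.5, 0.4, 0.2)), "sum to 1")

  # cover expectation: coral count over seeds is Binomial(625, 0.15)
  counts <- vapply(1:200, function(s)
    sum(as.matrix(random_config(25, 25, c(0.15, 0.70, 0.15), seed = s)) == 0L),
    numeric(1))
  expect_equal(mean(counts) / 625, 0.15, tolerance = 0.02)
  # chi-square goodness of fit against the binomial on pooled bins
  brk <- qbinom(c(0, 0.2, 0.4, 0.6, 0.8, 1), 625, 0.15)
  obs <- table(cut(counts, breaks = brk, include.lowest = TRUE))
  pr <- diff(pbinom(brk, 625, 0.15))
  pr[1] <- pr[1] + dbinom(brk[1], 625, 0.15)
  chisq <- sum((obs - 200 * pr)^2 / (200 * pr))
  expect_lt(chisq, qchisq(0.999, df = length(obs) - 1))
})

test_that("cluster_config builds one connected centred coral patch", {
  snap <- cluster_config(25, 25, c(0.15, 0.70, 0.15), seed = 3)
  expect_equal(sum(as.matrix(snap) == 0L), 94L)  # round(0.15 * 625)
  nb <- build_neighbourhood(25, 25, 1.45)
  cs <- cluster_stats(snap, nb, "coral")
  expect_equal(cs$n_clusters, 1L)
  expect_equal(cs$mean_cluster_size, 94)

  # no coral requested: purely random turf/macroalgae grid
  snap0 <- cluster_config(10, 10, c(0, 0.6, 0.4), seed = 4)
  expect_equal(sum(as.matrix(snap0) == 0L), 0L)
  expect_true(all(as.matrix(snap0) %in% 1:2))

  # all-coral cover is handled
  snap1 <- cluster_config(6, 6, c(1, 0, 0), seed = 5)
  expect_true(all(as.matrix(snap1) == 0L))
})

test_that("cluster init has higher coral-coral contact than random init", {
  nb <- build_neighbourhood(25, 25, 1.45)
  cc <- function(snap) neighbourhood_descriptors(snap, nb)$C_C
  ccs <- vapply(1:30, function(s)
    cc(cluster_config(25, 25, c(0.33, 0.34, 0.33), seed = s)), numeric(1))
  ccr <- vapply(1:30, function(s)
    cc(random_config(25, 25, c(0.33, 0.34, 0.33), seed = s)), numeric(1))
  expect_gt(min(ccs), max(ccr))
  expect_gt(mean(ccs), 0.8)   # tight central patch
  expect_lt(mean(ccr), 0.4)   # well-mixed reef
})

test_that("snapshots validate their codes and conserve covers exactly", {
  expect_error(snapshot(matrix(c(0, 1, 2, 5), 2, 2)), "invalid species code")
  for (s in 1:5) {
    snap <- rand_snapshot(9, 7, seed = s)
    expect_equal(sum(covers(snap)), 1)
  }
})
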