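# Random-graph layers and coupling constructors.

test_that("er_layer respects limits and binomial edge counts", {
  expect_equal(sum(er_layer(20, 1, seed = 1)$weights) / 2, 20 * 19 / 2)
  expect_equal(sum(er_layer(20, 0, seed = 1)$weights), 0)
  # edge count within 3 binomial sd of the mean over seeds
  N <- 250
  p <- 0.25
  npairs <- N * (N - 1) / 2
  counts <- vapply(1:60, function(s)
    sum(er_layer(N, p, seed = s, ensure_connected = FALSE)$weights) / 2, 0)
  expect_lt(abs(mean(counts) - p * npairs),
            3 * sqrt(p * (1 - p) * npairs / 60))
  expect_valid_layer(er_layer(30, 0.2, seed = 7))
  # determinism
  expect_identical(er_layer(30, 0.2, seed = 7)$weights,
                   er_layer(30, 0.2, seed = 7)$weights)
})

test_that("er_layer resamples disconnected realizations with a warning", {
  # N small + sparse: disconnection is frequent, resampling must kick in
  got_warning <- FALSE
  for (s in 1:30) {
    w <- tryCatch({
      g <- withCallingHandlers(
        er_layer(20, 0.12, seed = s),
        warning = function(cond) {
          got_warning <<- TRUE
          invokeRestart("muffleWarning")
        })
      g
    })
  }
  expect_true(got_warning)
})

test_that("ba_layer follows the m(N - m) edge-count convention", {
  for (m in c(1, 3)) {
    g <- ba_layer(60, m, seed = 2)
    expect_equal(sum(g$weights) / 2, m * (60 - m))
    expect_valid_layer(g)
    # every non-seed node has degree >= m
    expect_true(all(rowSums(g$weights)[(m + 1):60] >= m))
  }
  expect_identical(ba_layer(40, 2, seed = 9)$weights,
                   ba_layer(40, 2, seed = 9)$weights)
})

test_that("diagonal_coupling builds p * diag(h)", {
  cp <- diagonal_coupling(3, 0.5)
  expect_equal(diag(cp$block), rep(0.5, 3))
  expect_identical(cp$structure, "diagonal")
  expect_true(all(cp$block[row(cp$block) != col(cp$block)] == 0))
  # h = 0 disconnects the supra-graph downstream
  net <- supra_network(list(a = path_layer(4), b = path_layer(4)),
                       list("1_2" = diagonal_coupling(4, 1, h = rep(0, 4))))
  expect_warning(l2 <- algebraic_connectivity(combinatorial_laplacian(net)),
                 "disconnected")
  expect_lt(abs(l2), 1e-12)
})

test_that("heterogeneous_weights has the stated uniform family moments", {
  expect_identical(heterogeneous_weights(5, 0), rep(1, 5))
  expect_error(heterogeneous_weights(5, 0.6), "sqrt")
  # sigma at the bound: interval [0, 2]
  h <- heterogeneous_weights(5000, 1 / sqrt(3), seed = 4)
  expect_gte(min(h), 0)
  expect_lte(max(h), 2)
  # published sigma ladder value: interval ~ [0.295, 1.705]
  a <- 0.407 * sqrt(3)
  h <- heterogeneous_weights(10000, 0.407, seed = 11)
  expect_gte(min(h), 1 - a)
  expect_lte(max(h), 1 + a)
  # mean -> 1 and sd -> sigma within 3 standard errors at N = 1e4
  se_mean <- 0.407 / sqrt(10000)
  expect_lt(abs(mean(h) - 1), 3 * se_mean)
  expect_lt(abs(sd(h) - 0.407), 3 * 0.407 / sqrt(2 * 10000))
  # CLT example: diagonal of p = 1 coupling has mean ~ 1
  hh <- heterogeneous_weights(250, 0.523, seed = 3)
  expect_lt(abs(mean(diag(diagonal_coupling(250, 1, h = hh)$block)) - 1),
            3 * 0.523 / sqrt(250))
})

test_that("full_coupling and remove_interlayer_edges do exact arithmetic", {
  cp <- full_coupling(4, 0.2)
  expect_true(all(cp$block == 0.2))
  expect_identical(cp$structure, "full")
  expect_identical(remove_interlayer_edges(cp, 0, seed = 1)$block,
                   cp$block)
  expect_equal(sum(remove_interlayer_edges(cp, 1, seed = 1)$block), 0)
  thin <- remove_interlayer_edges(diagonal_coupling(250, 1), 0.5, seed = 2)
  expect_equal(sum(thin$block > 0), 125)
  expect_identical(thin$structure, "diagonal")
})

test_that("densify_from_multiplex hits exact entry counts", {
  N <- 250
  mux <- densify_from_multiplex(N, 100 * N / N^2, 0.3, seed = 1)
  expect_equal(sum(mux$block > 0), N)
  expect_true(all(diag(mux$block) == 0.3))
  expect_identical(mux$structure, "diagonal")
  half <- densify_from_multiplex(N, 50, 0.3, seed = 1)
  expect_equal(sum(half$block > 0), 31250)
  full <- densify_from_multiplex(10, 100, 2, seed = 1)
  expect_true(all(full$block == 2))
  expect_identical(full$structure, "full")
  expect_error(densify_from_multiplex(10, 5, 1), "diagonal entries")
})

test_that("strengths matches the hand-computed K2 example", {
  net <- supra_network(list(a = complete_layer(2), b = complete_layer(2)),
                       list("1_2" = diagonal_coupling(2, 0.5)))
  s <- strengths(net)
  expect_equal(unname(s$layers), c(2, 2)) # both matrix entries per edge
  expect_equal(unname(s$couplings), 1)    # S_P = 0.5 + 0.5
  expect_equal(s$ratio, 1 / 4)
  # linearity in the coupling scale
  net2 <- supra_network(list(a = complete_layer(2), b = complete_layer(2)),
                        list("1_2" = diagonal_coupling(2, 1.5)))
  expect_equal(strengths(net2)$ratio, 3 * s$ratio)
  # empty coupling
  net0 <- supra_network(list(a = complete_layer(2), b = complete_layer(2)))
  expect_equal(strengths(net0)$ratio, 0)
})

test_that("generators satisfy type invariants across random seeds", {
  for (s in 1:10) {
    expect_valid_layer(er_layer(25, runif(1, 0.15, 0.6),
                                seed = s, ensure_connected = FALSE))
    expect_valid_layer(ba_layer(25, sample(1:4, 1), seed = s))
    cp <- densify_from_multiplex(25, runif(1, 4, 100), runif(1, 0.1, 2),
                                 seed = s)
    expect_true(all(cp$block >= 0))
  }
})
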