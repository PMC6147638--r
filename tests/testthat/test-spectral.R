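# Supra-adjacency assembly, Laplacian spectra, reference curves and
# transition-point detection.

test_that("supra_adjacency assembles the documented block structure", {
  net <- supra_network(list(a = complete_layer(2), b = complete_layer(2)),
                       list("1_2" = diagonal_coupling(2, 0.7)))
  M <- supra_adjacency(net)
  p <- 0.7
  expect_equal(M, matrix(c(0, 1, p, 0,
                           1, 0, 0, p,
                           p, 0, 0, 1,
                           0, p, 1, 0), 4, byrow = TRUE))
  expect_identical(M, t(M))
  # zero coupling -> block diagonal
  M0 <- supra_adjacency(supra_network(list(a = complete_layer(2),
                                           b = complete_layer(2))))
  expect_true(all(M0[1:2, 3:4] == 0))
})

test_that("combinatorial Laplacian has known small spectra", {
  # single weighted edge: {0, 2w}
  w <- 0.37
  L <- combinatorial_laplacian(matrix(c(0, w, w, 0), 2))
  expect_equal(smallest_eigenvalues(L, 2), c(0, 2 * w), tolerance = 1e-12)
  # unit path on 3 nodes: {0, 1, 3}
  Lp <- combinatorial_laplacian(path_layer(3))
  expect_equal(smallest_eigenvalues(Lp, 3), c(0, 1, 3), tolerance = 1e-12)
  # complete graph on N nodes: lambda2 = N
  for (N in c(5, 17)) {
    Lk <- combinatorial_laplacian(complete_layer(N))
    expect_equal(suppressWarnings(algebraic_connectivity(Lk)), N,
                 tolerance = 1e-10)
  }
})

test_that("Laplacian structural invariants hold on random supra-networks", {
  for (s in 1:8) {
    net <- toy_supra(N = 20, p_con = 0.3, p = runif(1, 0.1, 2), seed = s)
    L <- combinatorial_laplacian(net)$matrix
    expect_lt(max(abs(rowSums(L))), 1e-9)
    expect_identical(L, t(L))
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)        # positive semidefinite
    expect_lt(abs(min(ev)), 1e-9)    # smallest eigenvalue is 0
  }
})

test_that("krylov route matches the dense oracle to 1e-8 up to 1000 nodes", {
  # random supra-networks (~300 nodes) and one larger instance
  for (s in 1:5) {
    net <- toy_supra(N = 150, p_con = 0.05, p = 0.4, seed = 40 + s)
    L <- combinatorial_laplacian(net)
    expect_equal(smallest_eigenvalues(L, 5, method = "krylov"),
                 smallest_eigenvalues(L, 5, method = "dense"),
                 tolerance = 1e-8)
  }
  big <- toy_supra(N = 500, p_con = 0.02, p = 0.2, seed = 77)
  Lb <- combinatorial_laplacian(big)
  expect_equal(smallest_eigenvalues(Lb, 5, method = "krylov"),
               smallest_eigenvalues(Lb, 5, method = "dense"),
               tolerance = 1e-8)
  # disconnected instance: zero eigenvalue of multiplicity 2
  g <- path_layer(40)
  net0 <- supra_network(list(a = g, b = g),
                        list("1_2" = diagonal_coupling(40, 0)))
  L0 <- combinatorial_laplacian(net0)
  expect_equal(smallest_eigenvalues(L0, 4, method = "krylov"),
               smallest_eigenvalues(L0, 4, method = "dense"),
               tolerance = 1e-8)
  expect_error(smallest_eigenvalues(L0, 100), "exceeds")
})

test_that("algebraic connectivity detects disconnection", {
  g <- path_layer(10)
  net <- supra_network(list(a = g, b = g),
                       list("1_2" = diagonal_coupling(10, 0)))
  expect_warning(l2 <- algebraic_connectivity(combinatorial_laplacian(net)),
                 "disconnected")
  expect_lt(abs(l2), 1e-10)
})

test_that("homogeneous multiplex has 2p as an exact eigenvalue", {
  # eigenvector (1, ..., 1, -1, ..., -1) since L_layer . 1 = 0
  for (s in 1:10) {
    p <- runif(1, 0.05, 3)
    net <- toy_supra(N = 25, p_con = 0.3, p = p, seed = 100 + s)
    L <- combinatorial_laplacian(net)$matrix
    v <- c(rep(1, 25), rep(-1, 25)) / sqrt(50)
    expect_lt(max(abs(L %*% v - 2 * p * v)), 1e-9)
  }
})

test_that("identical-layer multiplex follows min(2p, lambda2(G))", {
  g <- suppressWarnings(er_layer(30, 0.3, seed = 5))
  l2g <- suppressWarnings(algebraic_connectivity(g))
  for (p in c(0.05, 0.3, 2, 10)) {
    net <- supra_network(list(a = g, b = g),
                         list("1_2" = diagonal_coupling(30, p)))
    l2 <- suppressWarnings(
      algebraic_connectivity(combinatorial_laplacian(net)))
    expect_equal(l2, min(2 * p, l2g), tolerance = 1e-9)
  }
})

test_that("lambda2 is monotone in every edge weight", {
  # L(p') - L(p) is PSD for any single-weight increase
  for (s in 1:6) {
    net <- toy_supra(N = 15, p_con = 0.35, p = 0.5, seed = 200 + s)
    M <- supra_adjacency(net)
    l2 <- smallest_eigenvalues(combinatorial_laplacian(M), 2)[2]
    nz <- which(upper.tri(M) & M > 0)
    pick <- nz[sample.int(length(nz), 1)]
    M2 <- M
    M2[pick] <- M2[pick] + runif(1, 0.1, 1)
    M2[lower.tri(M2)] <- t(M2)[lower.tri(M2)]
    l2b <- smallest_eigenvalues(combinatorial_laplacian(M2), 2)[2]
    expect_gte(l2b, l2 - 1e-10)
  }
})

test_that("multiplex lambda2 is dominated by its full-multilayer superset", {
  g1 <- suppressWarnings(er_layer(20, 0.3, seed = 31))
  g2 <- suppressWarnings(er_layer(20, 0.3, seed = 32))
  for (p in c(0.01, 0.1, 1)) {
    mux <- supra_network(list(a = g1, b = g2),
                         list("1_2" = diagonal_coupling(20, p)))
    full <- supra_network(list(a = g1, b = g2),
                          list("1_2" = full_coupling(20, p)))
    expect_lte(
      suppressWarnings(algebraic_connectivity(
        combinatorial_laplacian(mux))),
      suppressWarnings(algebraic_connectivity(
        combinatorial_laplacian(full))) + 1e-9)
  }
})

test_that("mean_weighted_degree and aggregation references are exact", {
  expect_equal(mean_weighted_degree(matrix(1, 250, 250)), 250)
  expect_equal(mean_weighted_degree(diag(7)), 1)
  C <- matrix(runif(16), 4)
  expect_equal(mean_weighted_degree(3 * C), 3 * mean_weighted_degree(C))
  # aggregate = componentwise sum; lambda2_agg halves for two layers
  net <- identical_layer_supra(N = 20, p_con = 0.4, seed = 8)
  agg <- aggregate_layers(net)
  expect_equal(agg$weights, 2 * net$layers[[1]]$weights)
  expect_equal(lambda2_agg(net),
               suppressWarnings(algebraic_connectivity(net$layers[[1]])))
})

test_that("reference curves evaluate their closed forms", {
  expect_equal(reference_lambda2("multiplex_small", 0.1), 0.2)
  C <- matrix(1, 250, 250)
  expect_equal(reference_lambda2("multilayer_small", 0.001, C = C), 0.5)
  # bipartite all-ones: lambda2(pC) = N p (dense-decomposition check)
  N <- 40
  p <- 0.3
  A <- rbind(cbind(matrix(0, N, N), p * matrix(1, N, N)),
             cbind(p * matrix(1, N, N), matrix(0, N, N)))
  l2_dense <- smallest_eigenvalues(combinatorial_laplacian(A), 2)[2]
  expect_equal(l2_dense, N * p, tolerance = 1e-9)
  g <- path_layer(N)
  expect_equal(
    reference_lambda2("multilayer_large", p, list(g, g),
                      C = matrix(1, N, N)),
    suppressWarnings(algebraic_connectivity(g)) + N * p,
    tolerance = 1e-9)
})

test_that("scan + transition recover closed-form crossing points", {
  # identical K2 layers: branches 2p and lambda2(K2) = 2 cross at p* = 1
  k2 <- complete_layer(2)
  sc <- scan_transition(list(a = k2, b = k2), diagonal_coupling(2, 1),
                        log_grid(0.2, 5, 30))
  tp <- transition_point(sc)
  expect_true(tp$crossed)
  expect_equal(tp$p_star, 1, tolerance = 1e-3)
  # identical ER layers: p* = lambda2(G) / 2
  g <- suppressWarnings(er_layer(40, 0.25, seed = 17))
  l2g <- suppressWarnings(algebraic_connectivity(g))
  sc2 <- scan_transition(list(a = g, b = g), diagonal_coupling(40, 1),
                         log_grid(l2g / 20, l2g * 5, 35))
  tp2 <- transition_point(sc2)
  expect_equal(tp2$p_star, l2g / 2, tolerance = 1e-3)
  # homogeneous full multilayer, identical layers, all-ones C:
  # crossing of 2Np with lambda2(G) + Np at p* = lambda2(G) / N
  sc3 <- scan_transition(list(a = g, b = g), full_coupling(40, 1),
                         log_grid(l2g / 40 / 20, l2g / 40 * 20, 35))
  tp3 <- transition_point(sc3)
  expect_equal(tp3$p_star, l2g / 40, tolerance = 1e-3)
})

test_that("scan limits match the analytic regimes within 1%", {
  g1 <- suppressWarnings(er_layer(40, 0.3, seed = 61))
  g2 <- suppressWarnings(er_layer(40, 0.3, seed = 62))
  layers <- list(a = g1, b = g2)
  # multiplex: small-p slope 2, large-p -> lambda2_agg
  grid <- log_grid(1e-3, 400, 30)
  sc <- scan_transition(layers, diagonal_coupling(40, 1), grid)
  expect_lt(abs(sc$table$lambda2[1] / grid[1] - 2) / 2, 0.01)
  l2agg <- lambda2_agg(supra_network(layers))
  expect_lt(abs(rev(sc$table$lambda2)[1] - l2agg) / l2agg, 0.01)
  # full multilayer: small-p slope 2 <c> = 2N
  scf <- scan_transition(layers, full_coupling(40, 1),
                         log_grid(1e-6, 1e-4, 5))
  expect_lt(abs(scf$table$lambda2[1] / 1e-6 - 80) / 80, 0.01)
  # lambda2 non-decreasing along the grid, lambda2 <= lambda3
  expect_true(all(diff(sc$table$lambda2) > -1e-9))
  expect_true(all(sc$table$lambda3 - sc$table$lambda2 > -1e-12))
})

test_that("transition_point signals an out-of-range grid", {
  k2 <- complete_layer(2)
  sc <- scan_transition(list(a = k2, b = k2), diagonal_coupling(2, 1),
                        log_grid(1e-4, 1e-2, 10)) # crossing at 1, far right
  expect_error(transition_point(sc), "widen")
})

test_that("delta and percent-deviation helpers are plain arithmetic", {
  g <- path_layer(5)
  grid <- log_grid(0.1, 2, 8)
  sc1 <- scan_transition(list(a = g, b = g), diagonal_coupling(5, 1), grid)
  sc2 <- scan_transition(list(a = g, b = g), diagonal_coupling(5, 0.5),
                         grid)
  d <- delta_lambda2(sc1, sc2)
  expect_length(d, 8)
  expect_true(all(d >= -1e-12)) # weaker coupling cannot raise lambda2
  expect_equal(percent_deviation_from_aggregate(1, 1), 0)
  expect_equal(percent_deviation_from_aggregate(0, 1), 100)
  expect_equal(percent_deviation_from_aggregate(0.75, 1), 25)
})
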