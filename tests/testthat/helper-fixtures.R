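# Fixtures built in code. Everything is deterministic given the seed
# arguments, so no data files are needed.

# Small pair of ER layers plus a diagonal coupling, for spectral tests.
toy_supra <- function(N = 40, p_con = 0.2, p = 0.5, seed = 1) {
  g1 <- suppressWarnings(er_layer(N, p_con, seed = seed))
  g2 <- suppressWarnings(er_layer(N, p_con, seed = seed + 1000))
  supra_network(list(a = g1, b = g2),
                list("1_2" = diagonal_coupling(N, p)))
}

# Identical-layer multiplex: closed forms are exact.
identical_layer_supra <- function(N = 30, p_con = 0.3, p = 0.5, seed = 3) {
  g <- suppressWarnings(er_layer(N, p_con, seed = seed))
  supra_network(list(a = g, b = g),
                list("1_2" = diagonal_coupling(N, p)))
}

# Deterministic path graph layer.
path_layer <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  layer_graph(W)
}

complete_layer <- function(n) {
  W <- matrix(1, n, n)
  diag(W) <- 0
  layer_graph(W)
}

# Two-band test signals at a modest sampling rate so filters stay short.
quick_signals <- function(n_channels = 4, n_samples = 6000, seed = 1,
                          fs = 120, cross = NULL, intra = NULL,
                          noise_sd = 0.1) {
  generate_signals(signal_config(
    n_channels, sampling_rate = fs, n_samples = n_samples,
    bands = default_bands(c("alpha", "beta")),
    cross_pairs = cross, intra_pairs = intra,
    noise_sd = noise_sd, seed = seed))
}

quick_mi_config <- function(seed = 1, n_surrogates = 1,
                            block_length = 240) {
  mi_config(n_bins = "sqrt", block_length = block_length,
            n_surrogates = n_surrogates, seed = seed)
}

expect_valid_layer <- function(g) {
  expect_s3_class(g, "layer_graph")
  expect_true(isSymmetric(g$weights))
  expect_true(all(g$weights >= 0))
  expect_true(all(diag(g$weights) == 0))
}
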