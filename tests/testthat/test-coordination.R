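# Band-pass filtering, mutual information, surrogates, thresholding and
# the network-construction orchestrator.

test_that("bandpass passes in-band tones and rejects out-of-band content", {
  fs <- 200
  n <- 8000
  tt <- (seq_len(n) - 1) / fs
  alpha <- frequency_band("alpha", 8, 12)
  amp_at <- function(x, f) {
    sp <- abs(stats::fft(x))[seq_len(n / 2)]
    freqs <- (seq_len(n / 2) - 1) * fs / n
    max(sp[abs(freqs - f) < 0.5])
  }
  x10 <- sin(2 * pi * 10 * tt)
  x50 <- sin(2 * pi * 50 * tt)
  ts <- ts_set(rbind(x10, x50, rep(1, n)), fs)
  out <- bandpass(ts, alpha)
  # 10 Hz tone: spectral amplitude preserved within 5%
  expect_lt(abs(amp_at(out$values[1, ], 10) / amp_at(x10, 10) - 1), 0.05)
  # 50 Hz tone: residual RMS below 1% of input RMS
  expect_lt(sqrt(mean(out$values[2, ]^2)) / sqrt(mean(x50^2)), 0.01)
  # constant signal: DC is outside every passband
  expect_lt(max(abs(out$values[3, ])), 1e-6)
  expect_identical(dim(out$values), dim(ts$values))
  expect_equal(out$band$name, "alpha")
})

test_that("bandpass rejects impossible requests", {
  ts <- ts_set(matrix(rnorm(2 * 3000), 2), 60)
  expect_error(bandpass(ts, frequency_band("gamma", 30, 100)), "Nyquist")
  short <- ts_set(matrix(rnorm(2 * 50), 2), 200)
  expect_error(bandpass(short, frequency_band("alpha", 8, 12)),
               "too few samples")
})

test_that("default_bin_count implements the printed rule verbatim", {
  expect_identical(default_bin_count(100), 50L)
  expect_identical(default_bin_count(149646), 74825L) # 5 * round(14964.6)
  expect_identical(default_bin_count(15), 10L)        # .5 rounds up
  expect_error(default_bin_count(9), ">= 10")
  # sqrt alternative stays modest at full scale
  expect_identical(bin_count_sqrt(20000), 5L * 45L)
})

test_that("mutual information matches hand-computed cases", {
  # joint exactly the product of marginals -> 0
  expect_equal(mutual_information(c(1, 1, 2, 2), c(1, 2, 1, 2), 2), 0,
               tolerance = 1e-12)
  # perfect dependence with two equal-mass bins -> ln 2
  expect_equal(mutual_information(1:4, 1:4, 2), log(2), tolerance = 1e-12)
  expect_error(mutual_information(1:4, 1:5, 2), "equal length")
  expect_error(mutual_information(rep(1, 10), 1:10, 4), "constant")
})

test_that("MI is exactly symmetric, non-negative, and maximal for self", {
  set.seed(42)
  for (rep in 1:10) {
    x <- rnorm(500)
    y <- 0.3 * x + rnorm(500)
    nb <- sample(2:30, 1)
    mxy <- mutual_information(x, y, nb)
    expect_identical(mxy, mutual_information(y, x, nb))
    expect_gte(mxy, -1e-12)
    expect_gte(mutual_information(x, x, nb), mxy)
  }
})

test_that("independent series stay below the reshuffled 95th percentile", {
  set.seed(7)
  n <- 5000
  x <- rnorm(n)
  y <- rnorm(n)
  mi <- mutual_information(x, y, 50)
  null_mi <- replicate(60, mutual_information(x, sample(y), 50))
  expect_lt(mi, quantile(null_mi, 0.95) * 1.5)
  # the bias itself is small positive, far below H = log(50)
  expect_lt(mi, 0.2 * log(50))
})

test_that("block surrogates permute whole blocks and keep values", {
  set.seed(1)
  ts <- ts_set(matrix(rnorm(3 * 1000), 3), 100)
  # single block: identity
  one <- block_permutation_surrogate(ts, mi_config(block_length = 1000))
  expect_identical(one$values, ts$values)
  # multiset preserved per channel
  surr <- block_permutation_surrogate(ts, mi_config(block_length = 64,
                                                    seed = 5))
  for (ch in 1:3)
    expect_identical(sort(surr$values[ch, ]), sort(ts$values[ch, ]))
  expect_false(identical(surr$values, ts$values))
  # determinism
  surr2 <- block_permutation_surrogate(ts, mi_config(block_length = 64,
                                                     seed = 5))
  expect_identical(surr$values, surr2$values)
  expect_error(
    block_permutation_surrogate(ts, mi_config(block_length = 2000)),
    "exceeds")
})

test_that("block surrogates preserve within-block autocorrelation", {
  set.seed(11)
  n <- 20000
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  ts <- ts_set(matrix(x, 1), 508.63)
  surr <- block_permutation_surrogate(ts, mi_config(block_length = 1018,
                                                    seed = 2))
  ac <- function(v) stats::acf(v, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac(surr$values[1, ]) - ac(x)), 0.05)
})

test_that("threshold_weights applies the printed rule", {
  MI <- matrix(c(0, 0.5, 0.5, 0), 2)
  MR <- matrix(c(0, 0.2, 0.2, 0), 2)
  expect_equal(threshold_weights(MI, MR)[1, 2], 0.3)
  expect_true(all(threshold_weights(MI, MI) == 0))
  W <- threshold_weights(MI, MR)
  expect_true(all(W >= 0))
  expect_identical(W, t(W))
})

test_that("normalize01 is an exact affine map onto [0, 1]", {
  W <- matrix(c(0, 0.15, 0.15, 0.3), 2)
  expect_equal(sort(unique(as.vector(normalize01(W)))), c(0, 0.5, 1))
  V <- matrix(c(0, 1, 1, 0.5), 2)
  expect_identical(normalize01(V), V)
  set.seed(3)
  R <- matrix(runif(36), 6)
  expect_identical(range(normalize01(R)), c(0, 1))
  expect_error(normalize01(matrix(2, 3, 3)), "degenerate")
})

test_that("the pipeline yields a deterministic, well-formed supra-network", {
  sim <- quick_signals(n_channels = 3, n_samples = 4000, seed = 9)
  cfg <- quick_mi_config(seed = 4)
  bands <- default_bands(c("alpha", "beta"))
  net1 <- build_frequency_network(sim$signals, bands, cfg)
  net2 <- build_frequency_network(sim$signals, bands, cfg)
  expect_identical(supra_adjacency(net1), supra_adjacency(net2))
  M <- supra_adjacency(net1)
  expect_identical(M, t(M))
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(diag(M) == 0))
  expect_equal(net1$n_layers, 2)
  expect_equal(net1$meta$bin_rule, "sqrt")
  # the unfiltered monolayer path is the same orchestrator
  mono <- build_frequency_network(sim$signals, NULL, cfg)
  expect_equal(mono$n_layers, 1)
  expect_length(mono$couplings, 0)
})

test_that("multiplex restriction zeroes off-diagonal coupling only", {
  sim <- quick_signals(n_channels = 4, n_samples = 4000, seed = 12)
  net <- build_frequency_network(sim$signals,
                                 default_bands(c("alpha", "beta")),
                                 quick_mi_config(seed = 2))
  mux <- restrict_to_multiplex(net)
  cp <- mux$couplings[["1_2"]]
  expect_identical(cp$structure, "diagonal")
  expect_lte(sum(cp$block > 0), net$n_nodes)
  # layers untouched
  expect_identical(mux$layers, net$layers)
  # idempotence and entrywise dominance
  expect_identical(supra_adjacency(restrict_to_multiplex(mux)),
                   supra_adjacency(mux))
  expect_lte(sum(cp$block), sum(net$couplings[["1_2"]]$block))
})
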