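#' Bin-count rule for the MI histograms
#'
#' The published rule sets the number of equal-width bins of the marginal
#' and joint PDFs to `5 * round(t / 10)` (nearest integer, .5 rounds up)
#' for series of `t` samples. At full recording length this yields ~75000
#' bins and an extremely sparse joint histogram; it is implemented verbatim
#' and is the `"auto"` rule, but a square-root-scaled alternative
#' (`bin_count_sqrt()`, the `"sqrt"` rule) is provided for practical use.
#' Whichever rule is used is recorded in pipeline metadata.
#'
#' @param t Number of samples (>= 10).
#' @return Integer bin count.
#' @examples
#' default_bin_count(100) # 50
#' @export
default_bin_count <- function(t) {
  t <- check_scalar(t, "t")
  if (t < 10) stopf("`t` must be >= 10 (got %g)", t)
  as.integer(5 * floor(t / 10 + 0.5))
}

#' @rdname default_bin_count
#' @export
bin_count_sqrt <- function(t) {
  t <- check_scalar(t, "t")
  if (t < 10) stopf("`t` must be >= 10 (got %g)", t)
  max(2L, as.integer(5 * floor(sqrt(t / 10) + 0.5)))
}

resolve_bins <- function(n_bins, t) {
  if (is.character(n_bins)) {
    switch(match.arg(n_bins, c("auto", "sqrt")),
           auto = default_bin_count(t),
           sqrt = bin_count_sqrt(t))
  } else {
    n_bins <- check_count(n_bins, "n_bins", min = 2L)
    n_bins
  }
}

#' MI / surrogate configuration
#'
#' @param n_bins `"auto"` (published rule, [default_bin_count()]),
#'   `"sqrt"` ([bin_count_sqrt()]) or an explicit count >= 2.
#' @param block_length Surrogate block length in samples; default 1018
#'   (about 2 s at 508.63 Hz).
#' @param n_surrogates Number of surrogate draws; with more than one, the
#'   surrogate MI threshold is their mean. Default 1.
#' @param same_permutation If `TRUE`, all channels are permuted with the
#'   same block order; by default each channel gets an independent
#'   permutation, which destroys cross-channel coupling.
#' @param seed Integer seed for the surrogate permutations.
#' @return An object of class `"mi_config"`.
#' @export
mi_config <- function(n_bins = "auto", block_length = 1018L,
                      n_surrogates = 1L, same_permutation = FALSE,
                      seed = 1L) {
  block_length <- check_count(block_length, "block_length")
  n_surrogates <- check_count(n_surrogates, "n_surrogates")
  if (!is.character(n_bins)) n_bins <- check_count(n_bins, "n_bins", 2L)
  structure(list(n_bins = n_bins, block_length = block_length,
                 n_surrogates = n_surrogates,
                 same_permutation = isTRUE(same_permutation),
                 seed = as.integer(seed)),
            class = "mi_config")
}

# Equal-width bin indices over [min(x), max(x)]; constant series error.
bin_indices <- function(x, n_bins) {
  rng <- range(x)
  if (rng[1] == rng[2])
    stopf("constant series: equal-width binning is degenerate")
  ix <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  ix[ix > n_bins] <- n_bins
  ix
}

#' Histogram mutual information (nats)
#'
#' \deqn{MI = \sum_{u,v} p_{uv} \ln\frac{p_{uv}}{p_u p_v}}
#' over an equal-width 2-D histogram with `n_bins` bins per axis spanning
#' each series' own range; empty joint cells contribute 0. The joint
#' histogram is accumulated sparsely, so large bin counts cost O(t log t)
#' rather than O(n_bins^2). Exactly symmetric in its arguments (terms are
#' summed in a canonical order).
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_bins Number of bins per axis (>= 2).
#' @return Mutual information in nats (non-negative up to float tolerance).
#' @examples
#' x <- c(1, 2, 3, 4)
#' mutual_information(x, x, 2) # ln 2
#' @export
mutual_information <- function(x, y, n_bins) {
  if (length(x) != length(y))
    stopf("`x` and `y` must have equal length")
  n_bins <- check_count(n_bins, "n_bins", 2L)
  t_len <- length(x)
  ix <- bin_indices(x, n_bins)
  iy <- bin_indices(y, n_bins)
  px <- tabulate(ix, n_bins)
  py <- tabulate(iy, n_bins)
  code <- (ix - 1) * as.numeric(n_bins) + iy # < 2^53 for any sane n_bins
  r <- rle(sort(code))
  u <- (r$values - 1) %/% n_bins + 1
  v <- (r$values - 1) %% n_bins + 1
  nuv <- r$lengths
  terms <- (nuv / t_len) * log(nuv * t_len / (px[u] * py[v]))
  sum(sort(terms)) # canonical order => exact argument symmetry
}

#' Block-permutation surrogate signals
#'
#' Cuts each channel into consecutive blocks of `block_length` samples
#' (a trailing partial block stays in place at the end) and reorders the
#' complete blocks uniformly at random — independently per channel by
#' default, which destroys genuine cross-channel coupling while preserving
#' all within-block structure (autocorrelation, nonstationarity,
#' nonlinearity below the block scale). Each output channel is an exact
#' rearrangement of its input values.
#'
#' @param ts A [ts_set()].
#' @param config An [mi_config()]; uses `block_length`,
#'   `same_permutation` and `seed`.
#' @param draw Surrogate draw index (varies the permutation for repeated
#'   draws under one seed).
#' @return A [ts_set()] of surrogate signals.
#' @export
block_permutation_surrogate <- function(ts, config = mi_config(),
                                        draw = 1L) {
  stopifnot(inherits(ts, "ts_set"), inherits(config, "mi_config"))
  B <- config$block_length
  t_len <- n_samples(ts)
  if (B > t_len)
    stopf("block_length (%d) exceeds the series length (%d)", B, t_len)
  nb <- t_len %/% B
  out <- ts$values
  if (nb >= 2L) {
    for (ch in seq_len(n_channels(ts))) {
      sd_ch <- if (config$same_permutation) 0L else ch
      perm <- with_seed(derive_seed(config$seed, "blockperm", sd_ch, draw),
                        sample.int(nb))
      idx <- as.vector(outer(seq_len(B), (perm - 1L) * B, `+`))
      out[ch, seq_len(nb * B)] <- ts$values[ch, idx]
    }
  }
  ts_set(out, ts$sampling_rate, ts$channel_ids, ts$band)
}

# Stack band-wise signal sets into the node-layer order: node n of layer l
# has global index n + (l - 1) * N.
stack_bands <- function(ts_by_band) {
  stopifnot(length(ts_by_band) >= 1L,
            all(vapply(ts_by_band, inherits, TRUE, "ts_set")))
  N <- n_channels(ts_by_band[[1L]])
  vals <- do.call(rbind, lapply(ts_by_band, function(b) b$values))
  layer_names <- names(ts_by_band)
  if (is.null(layer_names))
    layer_names <- sprintf("layer%d", seq_along(ts_by_band))
  list(values = vals, N = N, l = length(ts_by_band),
       layer_names = layer_names)
}

#' Pairwise mutual-information matrix over all node-layers
#'
#' Computes MI between every unordered pair of the `l * N` node-layer
#' series of `ts_by_band` (one filtered [ts_set()] per band, identical
#' channel sets). Entry (i, i + N) measures cross-band coordination of one
#' channel with itself; entries within a diagonal block measure
#' within-band coordination.
#'
#' @param ts_by_band Named list of [ts_set()]s, one per band/layer.
#' @param config An [mi_config()]; its bin rule is resolved against the
#'   series length.
#' @return Symmetric `lN x lN` matrix with zero diagonal; the resolved bin
#'   count is attached as attribute `"n_bins"`.
#' @export
mi_matrix <- function(ts_by_band, config = mi_config()) {
  st <- stack_bands(ts_by_band)
  t_len <- ncol(st$values)
  nb <- resolve_bins(config$n_bins, t_len)
  m <- nrow(st$values)
  idx <- lapply(seq_len(m), function(i) bin_indices(st$values[i, ], nb))
  px <- lapply(idx, tabulate, nbins = nb)
  MI <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    code <- (idx[[i]] - 1) * as.numeric(nb) + idx[[j]]
    r <- rle(sort(code))
    u <- (r$values - 1) %/% nb + 1
    v <- (r$values - 1) %% nb + 1
    terms <- (r$lengths / t_len) *
      log(r$lengths * t_len / (px[[i]][u] * px[[j]][v]))
    MI[i, j] <- MI[j, i] <- sum(sort(terms))
  }
  structure(MI, n_bins = nb)
}

#' Surrogate mutual-information matrix
#'
#' MI between block-permutation surrogates of every node-layer pair; with
#' `n_surrogates > 1` the entrywise mean over independent draws (or the
#' entrywise maximum with `aggregate = "max"`, which makes the nominal
#' per-edge false-positive rate of the threshold `1 / (n_surrogates + 1)`
#' under the null). Used as the significance threshold for
#' [threshold_weights()].
#'
#' @inheritParams mi_matrix
#' @param aggregate `"mean"` (default) or `"max"` over surrogate draws.
#' @return Symmetric `lN x lN` matrix, zero diagonal, seed-deterministic.
#' @export
surrogate_mi_matrix <- function(ts_by_band, config = mi_config(),
                                aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  acc <- NULL
  nb <- NULL
  for (d in seq_len(config$n_surrogates)) {
    surr <- lapply(seq_along(ts_by_band), function(li) {
      cfg_l <- config
      # distinct permutation streams per layer, unless one common
      # permutation was requested for every node-layer
      if (!config$same_permutation)
        cfg_l$seed <- derive_seed(config$seed, "layer", li)
      block_permutation_surrogate(ts_by_band[[li]], cfg_l, draw = d)
    })
    names(surr) <- names(ts_by_band)
    M <- mi_matrix(surr, config)
    nb <- attr(M, "n_bins")
    acc <- if (is.null(acc)) M
           else if (aggregate == "mean") acc + M
           else pmax(acc, M)
  }
  out <- if (aggregate == "mean") acc / config$n_surrogates else acc
  structure(out, n_bins = nb)
}
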