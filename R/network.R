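#' Single-layer weighted graph
#'
#' @param weights Symmetric non-negative numeric matrix with zero diagonal.
#' @param name Optional layer label.
#' @return An object of class `"layer_graph"` with fields `n_nodes`,
#'   `weights`, `name`.
#' @export
layer_graph <- function(weights, name = NULL) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stopf("`weights` must be a square matrix")
  if (!is_symmetric_matrix(weights, tol = 1e-12))
    stopf("`weights` must be symmetric")
  if (any(weights < 0)) stopf("`weights` must be non-negative")
  if (any(diag(weights) != 0)) stopf("`weights` must have a zero diagonal")
  weights <- (weights + t(weights)) / 2 # exact symmetry
  structure(list(n_nodes = nrow(weights), weights = weights, name = name),
            class = "layer_graph")
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("<layer_graph>%s %d nodes, %d edges, strength %.4g\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n_nodes, sum(x$weights > 0) / 2, sum(x$weights)))
  invisible(x)
}

#' Interlayer coupling block
#'
#' The non-negative `N_alpha x N_beta` block of interlayer edge weights
#' between an ordered pair of layers. `structure = "diagonal"` (only
#' replica-to-replica edges, the multiplex case) requires all off-diagonal
#' entries to be zero; `"full"` and `"partial"` allow arbitrary patterns.
#'
#' @param block Non-negative numeric matrix.
#' @param structure `"diagonal"`, `"full"` or `"partial"`.
#' @return An object of class `"interlayer_coupling"`.
#' @export
interlayer_coupling <- function(block,
                                structure = c("partial", "diagonal",
                                              "full")) {
  structure_tag <- match.arg(structure)
  if (!is.matrix(block) || !is.numeric(block))
    stopf("`block` must be a numeric matrix")
  if (any(block < 0)) stopf("`block` must be non-negative")
  if (structure_tag == "diagonal") {
    off <- block
    off[cbind(seq_len(min(dim(block))), seq_len(min(dim(block))))] <- 0
    if (any(off != 0))
      stopf("diagonal coupling must have zero off-diagonal entries")
  }
  base::structure(list(block = block, structure = structure_tag),
                  class = "interlayer_coupling")
}

#' @export
print.interlayer_coupling <- function(x, ...) {
  cat(sprintf("<interlayer_coupling> %dx%d [%s], %d active, strength %.4g\n",
              nrow(x$block), ncol(x$block), x$structure,
              sum(x$block > 0), sum(x$block)))
  invisible(x)
}

coupling_key <- function(i, j) paste0(i, "_", j)

#' Multilayer supra-network
#'
#' Ordered layers plus one coupling block per unordered layer pair. Node
#' `n` of layer `l` has global index `n + (l - 1) * N` in the
#' supra-adjacency matrix; coupling blocks are stored for `i < j` and the
#' `(j, i)` block is their transpose, so the supra-adjacency is symmetric
#' by construction.
#'
#' @param layers Named list of [layer_graph()]s with equal node counts.
#' @param couplings List of [interlayer_coupling()]s named `"i_j"` for
#'   layer indices `i < j` (e.g. `"1_2"`); missing pairs mean zero
#'   coupling.
#' @param meta Optional list of provenance metadata.
#' @return An object of class `"supra_network"`.
#' @export
supra_network <- function(layers, couplings = list(), meta = list()) {
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "layer_graph")))
  N <- layers[[1L]]$n_nodes
  if (!all(vapply(layers, function(l) l$n_nodes, 0L) == N))
    stopf("all layers must have the same number of nodes")
  if (is.null(names(layers)))
    names(layers) <- sprintf("layer%d", seq_along(layers))
  l <- length(layers)
  for (key in names(couplings)) {
    ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1L]])
    if (length(ij) != 2L || any(is.na(ij)) || ij[1L] >= ij[2L] ||
        ij[2L] > l)
      stopf("coupling key '%s' must be 'i_j' with layer indices i < j", key)
    cp <- couplings[[key]]
    if (!inherits(cp, "interlayer_coupling") ||
        !all(dim(cp$block) == c(N, N)))
      stopf("coupling '%s' must be an N x N interlayer_coupling", key)
  }
  structure(list(layers = layers, couplings = couplings,
                 n_nodes = N, n_layers = l, meta = meta),
            class = "supra_network")
}

#' @export
print.supra_network <- function(x, ...) {
  cat(sprintf("<supra_network> %d layers x %d nodes (%s)\n",
              x$n_layers, x$n_nodes,
              paste(names(x$layers), collapse = ", ")))
  for (key in names(x$couplings)) {
    cp <- x$couplings[[key]]
    cat(sprintf("  coupling %s: [%s] %d active, strength %.4g\n",
                key, cp$structure, sum(cp$block > 0), sum(cp$block)))
  }
  invisible(x)
}

#' Surrogate-thresholded edge weights
#'
#' Keeps an edge only where the observed MI strictly exceeds its surrogate
#' value: `W_ij = MI_ij - MI_rand_ij` if `MI_ij > MI_rand_ij`, else 0.
#' Zeros mark edges deemed not statistically significant ("missing"
#' edges).
#'
#' @param MI,MI_rand Symmetric matrices of identical dimension, as
#'   returned by [mi_matrix()] and [surrogate_mi_matrix()].
#' @return Non-negative symmetric weight matrix `W` with zero diagonal.
#' @export
threshold_weights <- function(MI, MI_rand) {
  if (!all(dim(MI) == dim(MI_rand)))
    stopf("`MI` and `MI_rand` must have identical dimensions")
  W <- ifelse(MI > MI_rand, MI - MI_rand, 0)
  diag(W) <- 0
  (W + t(W)) / 2
}

#' Linear min-max normalization to \[0, 1\]
#'
#' `M_ij = (W_ij - w_min) / (w_max - w_min)` over the whole matrix at
#' once, zeros included, so one network's weights are comparable across
#' individuals. Order-preserving; errors on a constant matrix.
#'
#' @param W Numeric matrix with `max(W) > min(W)`.
#' @return Matrix with entries in \[0, 1\], `min = 0`, `max = 1` exactly.
#' @export
normalize01 <- function(W) {
  wmin <- min(W)
  wmax <- max(W)
  if (wmax == wmin)
    stopf("degenerate input: all entries equal (w_max = w_min)")
  (W - wmin) / (wmax - wmin)
}

# Slice a normalized lN x lN supra matrix into a supra_network.
slice_supra_matrix <- function(M, N, layer_names, meta = list()) {
  l <- length(layer_names)
  blk <- function(i, j) M[(i - 1) * N + seq_len(N), (j - 1) * N + seq_len(N),
                          drop = FALSE]
  layers <- lapply(seq_len(l), function(i) {
    B <- blk(i, i)
    diag(B) <- 0
    layer_graph(B, name = layer_names[i])
  })
  names(layers) <- layer_names
  couplings <- list()
  if (l >= 2L) for (i in seq_len(l - 1L)) for (j in (i + 1L):l) {
    B <- blk(i, j)
    tag <- if (all(B[row(B) != col(B)] == 0)) "diagonal" else "partial"
    couplings[[coupling_key(i, j)]] <- interlayer_coupling(B, tag)
  }
  supra_network(layers, couplings, meta = meta)
}

#' Build a frequency-based supra-network from signals
#'
#' Full construction pipeline: band-pass filter the signals into the
#' requested bands, compute the all-pairs mutual-information matrix over
#' the `l * N` node-layers, threshold it against block-permutation
#' surrogates, normalize the surviving weights to \[0, 1\], and slice the
#' result into layer (diagonal) and coupling (off-diagonal) blocks.
#'
#' With `bands = NULL` the signals are not filtered and a monolayer
#' ("unfiltered") network is returned by the same path; the aggregated
#' monolayer network is available downstream via [aggregate_layers()].
#'
#' @param ts A raw [ts_set()].
#' @param bands Named list of [frequency_band()]s (one layer per band), or
#'   `NULL` for the unfiltered monolayer network.
#' @param config An [mi_config()].
#' @return A [supra_network()]; `$meta` records the bin rule and count,
#'   surrogate settings and seed. Deterministic given signals + config.
#' @examples
#' sim <- generate_signals(signal_config(3, n_samples = 3000, seed = 2,
#'                                       sampling_rate = 100,
#'   bands = list(alpha = frequency_band("alpha", 8, 12))))
#' net <- build_frequency_network(sim$signals,
#'   default_bands(c("alpha", "beta")),
#'   mi_config(n_bins = 16, block_length = 300))
#' @export
build_frequency_network <- function(ts, bands = default_bands(),
                                    config = mi_config()) {
  stopifnot(inherits(ts, "ts_set"), inherits(config, "mi_config"))
  if (is.null(bands)) {
    ts_by_band <- list(broadband = ts)
  } else {
    ts_by_band <- lapply(bands, function(b) bandpass(ts, b))
    names(ts_by_band) <- names(bands)
  }
  MI <- mi_matrix(ts_by_band, config)
  MI_rand <- surrogate_mi_matrix(ts_by_band, config)
  W <- threshold_weights(MI, MI_rand)
  M <- normalize01(W)
  meta <- list(
    bin_rule = if (is.character(config$n_bins)) config$n_bins else "fixed",
    n_bins = attr(MI, "n_bins"),
    block_length = config$block_length,
    n_surrogates = config$n_surrogates,
    same_permutation = config$same_permutation,
    seed = config$seed)
  slice_supra_matrix(M, n_channels(ts), names(ts_by_band), meta = meta)
}

#' Restrict a supra-network to its multiplex skeleton
#'
#' Sets every off-diagonal entry of every coupling block to zero, keeping
#' only replica-to-replica (same channel, different band) interlayer
#' edges. Layer blocks are untouched. Idempotent.
#'
#' @param net A [supra_network()].
#' @return The multiplex [supra_network()].
#' @export
restrict_to_multiplex <- function(net) {
  stopifnot(inherits(net, "supra_network"))
  net$couplings <- lapply(net$couplings, function(cp) {
    d <- diag(cp$block)
    interlayer_coupling(diag(d, nrow = length(d)), "diagonal")
  })
  net
}
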