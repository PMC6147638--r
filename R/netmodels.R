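# Random-graph layers and interlayer coupling structures for the synthetic
# ensemble experiments: ER / BA layers with unit weights, homogeneous and
# heterogeneous diagonal couplings, random edge deletion, and the
# multiplex -> full-multilayer densification path.

#' Erdős–Rényi layer
#'
#' `G(N, p_con)`: every unordered node pair is present independently with
#' probability `p_con`, with unit weight. Because the spectral scans
#' assume connected layers, a disconnected realization is resampled (up to
#' `max_tries` times, with a warning recording the count); `p_con = 0`
#' returns the empty graph unconditionally.
#'
#' @param N Number of nodes.
#' @param p_con Connection probability in \[0, 1\].
#' @param seed Integer seed; generation is seed-deterministic.
#' @param ensure_connected Resample disconnected realizations (default
#'   `TRUE`).
#' @param max_tries Resampling cap.
#' @return A [layer_graph()]; the number of resamples is attached as
#'   attribute `"resamples"`.
#' @export
er_layer <- function(N, p_con, seed = 1L, ensure_connected = TRUE,
                     max_tries = 100L) {
  N <- check_count(N, "N", 1L)
  p_con <- check_scalar(p_con, "p_con", 0, 1)
  draw <- function(try) {
    A <- matrix(0, N, N)
    up <- which(upper.tri(A))
    A[up] <- with_seed(derive_seed(seed, "er", try),
                       stats::rbinom(length(up), 1L, p_con))
    A + t(A)
  }
  A <- draw(1L)
  tries <- 1L
  if (ensure_connected && p_con > 0) {
    while (!graph_is_connected(A) && tries < max_tries) {
      tries <- tries + 1L
      A <- draw(tries)
    }
    if (!graph_is_connected(A))
      warning(sprintf("er_layer: still disconnected after %d draws", tries))
    else if (tries > 1L)
      warning(sprintf("er_layer: resampled %d time(s) for connectedness",
                      tries - 1L))
  }
  out <- layer_graph(A, name = sprintf("er(N=%d,p=%g)", N, p_con))
  attr(out, "resamples") <- tries - 1L
  out
}

#' Barabási–Albert layer
#'
#' Preferential attachment with `m` edges per new node, unit weights,
#' using the standard convention that growth starts from `m` initial
#' unconnected nodes (so the first arriving node links to all of them and
#' the final edge count is exactly `m * (N - m)`).
#'
#' @param N Number of nodes (> m).
#' @param m Edges added per new node.
#' @param seed Integer seed.
#' @return A [layer_graph()].
#' @export
ba_layer <- function(N, m, seed = 1L) {
  N <- check_count(N, "N", 2L)
  m <- check_count(m, "m", 1L)
  if (m >= N) stopf("need m < N")
  A <- matrix(0, N, N)
  with_seed(derive_seed(seed, "ba"), {
    targets <- seq_len(m)
    repeated <- integer(0) # node multiset, multiplicity = degree
    for (v in (m + 1L):N) {
      A[v, targets] <- 1
      A[targets, v] <- 1
      repeated <- c(repeated, targets, rep.int(v, m))
      # m distinct targets, probability proportional to degree
      nxt <- integer(0)
      while (length(nxt) < m) {
        cand <- repeated[sample.int(length(repeated), 1L)]
        if (!cand %in% nxt) nxt <- c(nxt, cand)
      }
      targets <- nxt
    }
  })
  layer_graph(A, name = sprintf("ba(N=%d,m=%d)", N, m))
}

#' Diagonal (multiplex) interlayer coupling
#'
#' Coupling block `P = p * diag(h)`: node `k` of one layer is linked only
#' to its replica in the other, with weight `p * h_k`. The default
#' `h = 1` is the homogeneous multiplex; a heterogeneous `h` (e.g. from
#' [heterogeneous_weights()]) perturbs the interlayer weights around `p`.
#'
#' @param N Nodes per layer.
#' @param p Overall interlayer weight scale.
#' @param h Optional length-`N` non-negative weight vector (default all
#'   ones).
#' @return An [interlayer_coupling()] with structure `"diagonal"`.
#' @export
diagonal_coupling <- function(N, p, h = NULL) {
  N <- check_count(N, "N", 1L)
  p <- check_scalar(p, "p", 0)
  if (is.null(h)) h <- rep(1, N)
  if (length(h) != N || any(h < 0))
    stopf("`h` must be a non-negative vector of length N")
  interlayer_coupling(diag(p * h, nrow = N), "diagonal")
}

#' Heterogeneous interlayer weight vector
#'
#' i.i.d. uniform weights on `[1 - a, 1 + a]` with `a = sigma * sqrt(3)`,
#' so the population mean is 1 and the population standard deviation is
#' exactly `sigma`. Non-negativity bounds `sigma` by `1 / sqrt(3)`.
#'
#' @param N Length of the vector.
#' @param sigma Target population standard deviation, in
#'   `[0, 1 / sqrt(3)]`.
#' @param seed Integer seed.
#' @return Numeric vector of length `N` with entries >= 0.
#' @export
heterogeneous_weights <- function(N, sigma, seed = 1L) {
  N <- check_count(N, "N", 1L)
  sigma <- check_scalar(sigma, "sigma", 0)
  if (sigma > 1 / sqrt(3) + 1e-12)
    stopf("sigma must be <= 1/sqrt(3) ~ 0.5774 (weights must stay >= 0)")
  if (sigma == 0) return(rep(1, N))
  a <- sigma * sqrt(3)
  with_seed(derive_seed(seed, "hweights"),
            stats::runif(N, 1 - a, 1 + a))
}

#' Full (all-to-all) interlayer coupling
#'
#' Coupling block `P = p * C`; `C` defaults to the all-ones matrix (the
#' homogeneous full multilayer, `c_ij = 1`).
#'
#' @param N Nodes per layer.
#' @param p Interlayer weight scale.
#' @param C Optional non-negative `N x N` structure matrix.
#' @return An [interlayer_coupling()] with structure `"full"`.
#' @export
full_coupling <- function(N, p, C = NULL) {
  N <- check_count(N, "N", 1L)
  p <- check_scalar(p, "p", 0)
  if (is.null(C)) C <- matrix(1, N, N)
  if (!is.matrix(C) || !all(dim(C) == N) || any(C < 0))
    stopf("`C` must be a non-negative N x N matrix")
  interlayer_coupling(p * C, "full")
}

#' Delete interlayer edges uniformly at random
#'
#' Sets `round(fraction * n_active)` currently nonzero entries of the
#' coupling block to zero, chosen uniformly at random; the transposed
#' block used in supra-adjacency assembly mirrors the deletion, so
#' symmetry is preserved.
#'
#' @param P An [interlayer_coupling()].
#' @param fraction Fraction of active entries to delete, in \[0, 1\].
#' @param seed Integer seed.
#' @return The thinned [interlayer_coupling()].
#' @export
remove_interlayer_edges <- function(P, fraction, seed = 1L) {
  stopifnot(inherits(P, "interlayer_coupling"))
  fraction <- check_scalar(fraction, "fraction", 0, 1)
  active <- which(P$block > 0)
  k <- round(fraction * length(active))
  if (k > 0) {
    kill <- with_seed(derive_seed(seed, "rmedges"),
                      sample(active, k))
    P$block[kill] <- 0
  }
  tag <- if (P$structure == "diagonal") "diagonal" else "partial"
  interlayer_coupling(P$block, tag)
}

#' Densify a multiplex coupling towards a full multilayer one
#'
#' Starts from the `N` diagonal (multiplex) entries and adds off-diagonal
#' interlayer edges uniformly at random until
#' `round(percent_active * N^2 / 100)` entries are active, all with weight
#' `p`. `percent_active = 100 * N / N^2` is the multiplex lower limit;
#' `percent_active = 100` is the full multilayer.
#'
#' @param N Nodes per layer.
#' @param percent_active Percentage of the `N^2` possible interlayer
#'   entries to activate.
#' @param p Weight of every active entry.
#' @param seed Integer seed.
#' @return An [interlayer_coupling()].
#' @export
densify_from_multiplex <- function(N, percent_active, p, seed = 1L) {
  N <- check_count(N, "N", 1L)
  p <- check_scalar(p, "p", 0)
  percent_active <- check_scalar(percent_active, "percent_active", 0, 100)
  target <- round(percent_active * N^2 / 100)
  if (target < N)
    stopf("percent_active must activate at least the N diagonal entries")
  B <- diag(p, nrow = N)
  extra <- target - N
  if (extra > 0) {
    off <- which(row(B) != col(B))
    add <- with_seed(derive_seed(seed, "densify"),
                     sample(off, extra))
    B[add] <- p
  }
  tag <- if (target == N) "diagonal"
         else if (target == N^2) "full" else "partial"
  interlayer_coupling(B, tag)
}

#' Layer and coupling strengths
#'
#' Strength of a layer is the sum of its weight-matrix entries (each edge
#' counted twice, once per matrix entry); the strength `S_P` of a coupling
#' is the sum of its block entries. The ratio `S_P / sum(S_layers)`
#' normalizes total interlayer weight by total intralayer weight.
#'
#' @param net A [supra_network()].
#' @return List with `layers` (named vector), `couplings` (named vector of
#'   `S_P`), and `ratio`.
#' @export
strengths <- function(net) {
  stopifnot(inherits(net, "supra_network"))
  S_layers <- vapply(net$layers, function(l) sum(l$weights), 0)
  S_coup <- vapply(net$couplings, function(cp) sum(cp$block), 0)
  if (!length(S_coup)) S_coup <- numeric(0)
  list(layers = S_layers, couplings = S_coup,
       ratio = if (length(S_coup)) sum(S_coup) / sum(S_layers) else 0)
}
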