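# Supra-adjacency / combinatorial supra-Laplacian assembly and spectral
# analysis: algebraic connectivity lambda2, the lambda2-lambda3 transition
# point p*, and the closed-form reference curves of the small-p and
# large-p regimes.

#' Supra-adjacency matrix
#'
#' Assembles the `lN x lN` block matrix with the layer weight matrices on
#' the diagonal and the interlayer coupling blocks off it (block `(j, i)`
#' is the transpose of block `(i, j)`). Node `n` of layer `l` maps to
#' global index `n + (l - 1) * N`.
#'
#' @param net A [supra_network()].
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
supra_adjacency <- function(net) {
  stopifnot(inherits(net, "supra_network"))
  N <- net$n_nodes
  l <- net$n_layers
  M <- matrix(0, l * N, l * N)
  for (i in seq_len(l)) {
    ix <- (i - 1L) * N + seq_len(N)
    M[ix, ix] <- net$layers[[i]]$weights
  }
  for (key in names(net$couplings)) {
    ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1L]])
    ix <- (ij[1L] - 1L) * N + seq_len(N)
    jx <- (ij[2L] - 1L) * N + seq_len(N)
    B <- net$couplings[[key]]$block
    M[ix, jx] <- B
    M[jx, ix] <- t(B)
  }
  M
}

#' Combinatorial (supra-)Laplacian
#'
#' `L = diag(s) - M`, with `s_i = sum_j M_ij` the weighted degree
#' (strength) of node-layer `i`. This weighted form reduces to the
#' unit-weight adjacency Laplacian when all weights are 0/1 and is the
#' form required for MI-weighted empirical networks. Rows sum to zero;
#' the matrix is symmetric positive semidefinite with smallest
#' eigenvalue 0.
#'
#' @param M Symmetric numeric matrix (a supra-adjacency or single-layer
#'   weight matrix), or a [supra_network()] (assembled first).
#' @return An object of class `"supra_laplacian"`: list with `matrix` and
#'   `n` fields plus any layer partition metadata.
#' @export
combinatorial_laplacian <- function(M) {
  partition <- NULL
  if (inherits(M, "supra_network")) {
    partition <- list(N = M$n_nodes, layers = names(M$layers))
    M <- supra_adjacency(M)
  } else if (inherits(M, "layer_graph")) {
    M <- M$weights
  }
  if (!is_symmetric_matrix(M, tol = 1e-9))
    stopf("`M` must be symmetric")
  L <- diag(rowSums(M)) - M
  structure(list(matrix = L, n = nrow(L), partition = partition),
            class = "supra_laplacian")
}

#' @export
print.supra_laplacian <- function(x, ...) {
  cat(sprintf("<supra_laplacian> %d x %d\n", x$n, x$n))
  invisible(x)
}

as_laplacian_matrix <- function(L) {
  if (inherits(L, "supra_laplacian")) L$matrix
  else if (inherits(L, c("supra_network", "layer_graph")))
    combinatorial_laplacian(L)$matrix
  else L
}

# Block Krylov (Rayleigh-Ritz with full reorthogonalization) for the k
# algebraically smallest eigenvalues of a symmetric PSD matrix, run on the
# spectral reflection B = cI - L so the sought eigenvalues are extremal.
# The starting block contains the constant vector (the exact kernel vector
# of a connected Laplacian) plus deterministic trigonometric vectors; the
# block width k + 2 tolerates eigenvalue multiplicities up to that width
# (e.g. multiple zero eigenvalues of disconnected supra-graphs).
smallest_eigs_krylov <- function(L, k, tol = 1e-10) {
  n <- nrow(L)
  cshift <- 2 * max(diag(L)) + 1 # Gershgorin upper bound on spec(L)
  bmv <- function(V) cshift * V - L %*% V
  b <- min(n, k + 2L)
  V <- vapply(seq_len(b), function(j) {
    if (j == 1L) rep(1, n) else sin(seq_len(n) * j + j)
  }, numeric(n))
  orth <- function(W, Q = NULL) { # two-pass Gram-Schmidt + QR
    if (!is.null(Q)) for (pass in 1:2) W <- W - Q %*% crossprod(Q, W)
    qr_w <- qr(W)
    qr.Q(qr_w)[, seq_len(qr_w$rank), drop = FALSE]
  }
  Q <- orth(V)
  repeat {
    BQ <- bmv(Q)
    T_mat <- crossprod(Q, BQ)
    T_mat <- (T_mat + t(T_mat)) / 2
    ed <- eigen(T_mat, symmetric = TRUE)
    m_take <- min(k, ncol(Q))
    theta <- ed$values[seq_len(m_take)] # largest of B
    Y <- Q %*% ed$vectors[, seq_len(m_take), drop = FALSE]
    R <- bmv(Y) - Y %*% diag(theta, m_take)
    res <- sqrt(colSums(R^2))
    if ((all(res < tol * cshift) && ncol(Q) >= k) || ncol(Q) >= n)
      return(sort(cshift - theta))
    last <- max(1L, ncol(Q) - b + 1L)
    Wnew <- orth(bmv(Q[, last:ncol(Q), drop = FALSE]), Q)
    if (!ncol(Wnew)) { # Krylov space exhausted: restart with random-ish block
      Wnew <- orth(vapply(seq_len(b), function(j)
        cos(seq_len(n) * (ncol(Q) + j) + j), numeric(n)), Q)
      if (!ncol(Wnew)) return(sort(cshift - theta))
    }
    Q <- cbind(Q, Wnew)
  }
}

#' Smallest Laplacian eigenvalues
#'
#' The `k` algebraically smallest eigenvalues in ascending order. The
#' default route is a dense LAPACK symmetric decomposition for matrices up
#' to 1500 nodes and a block Krylov solver beyond; both routes are exposed
#' so they can be cross-checked (`method = "dense"` vs
#' `method = "krylov"`). The Krylov route enlarges its subspace until the
#' Ritz residuals pass `tol` (reaching an exact decomposition in the
#' limit), so it never silently returns an unconverged approximation.
#'
#' @param L A `"supra_laplacian"`, [supra_network()], [layer_graph()] or
#'   plain symmetric matrix.
#' @param k Number of eigenvalues (1 <= k <= n).
#' @param method `"auto"`, `"dense"` or `"krylov"`.
#' @param tol Krylov residual tolerance (relative to the spectral bound).
#' @return Numeric vector of length `k`, ascending; the first entry is 0
#'   (within tolerance) for any valid Laplacian.
#' @export
smallest_eigenvalues <- function(L, k, method = c("auto", "dense", "krylov"),
                                 tol = 1e-10) {
  method <- match.arg(method)
  Lm <- as_laplacian_matrix(L)
  n <- nrow(Lm)
  k <- check_count(k, "k", 1L)
  if (k > n) stopf("k (%d) exceeds the matrix size (%d)", k, n)
  if (method == "auto") method <- if (n <= 1500) "dense" else "krylov"
  if (method == "dense") {
    vals <- eigen(Lm, symmetric = TRUE, only.values = TRUE)$values
    sort(vals)[seq_len(k)]
  } else {
    smallest_eigs_krylov(Lm, k, tol = tol)
  }
}

#' Algebraic connectivity (Fiedler value)
#'
#' Second-smallest eigenvalue of the combinatorial (supra-)Laplacian;
#' zero (within tolerance) exactly when the graph is disconnected, in
#' which case a warning is emitted rather than an error because
#' edge-deletion sweeps legitimately produce disconnected supra-graphs.
#'
#' @inheritParams smallest_eigenvalues
#' @param disc_tol Threshold below which the graph is reported
#'   disconnected.
#' @return The value of lambda2.
#' @export
algebraic_connectivity <- function(L, method = "auto", disc_tol = 1e-9) {
  v <- smallest_eigenvalues(L, 2L, method = method)
  if (v[2L] < disc_tol)
    warning("graph is disconnected (lambda2 ~ 0)")
  v[2L]
}

#' Aggregate the layers of a supra-network
#'
#' Componentwise sum of the layer weight matrices (interlayer blocks are
#' ignored), giving the uniformly aggregated monolayer network.
#'
#' @param net A [supra_network()].
#' @return A [layer_graph()].
#' @export
aggregate_layers <- function(net) {
  stopifnot(inherits(net, "supra_network"))
  W <- Reduce(`+`, lapply(net$layers, function(l) l$weights))
  layer_graph(W, name = "aggregated")
}

#' Aggregated-network reference value of lambda2
#'
#' `lambda2_agg = (1 / l) * lambda2(sum of layer Laplacians)`; for two
#' layers this is the large-p limit of the homogeneous multiplex
#' algebraic connectivity, `0.5 * lambda2(L_alpha + L_beta)`.
#'
#' @param net A [supra_network()] (or list of [layer_graph()]s).
#' @return The reference value.
#' @export
lambda2_agg <- function(net) {
  layers <- if (inherits(net, "supra_network")) net$layers else net
  Lsum <- Reduce(`+`, lapply(layers,
                             function(l) combinatorial_laplacian(l)$matrix))
  suppressWarnings(algebraic_connectivity(Lsum)) / length(layers)
}

#' Mean weighted degree of a coupling structure matrix
#'
#' Mean over rows of the row sums of `C`; for the all-ones `N x N`
#' structure this is `N`.
#'
#' @param C Numeric matrix.
#' @return Scalar mean weighted degree.
#' @export
mean_weighted_degree <- function(C) mean(rowSums(C))

# lambda2 of the 2N-node bipartite graph whose only edges are the
# interlayer ones with weights p * C. Closed form for uniform C; dense
# decomposition otherwise.
bipartite_lambda2 <- function(C, p) {
  N <- nrow(C)
  if (length(unique(as.vector(C))) == 1L) {
    # complete bipartite with uniform weight: spectrum {0, Npc (2N-2), 2Npc}
    return(N * p * C[1L, 1L])
  }
  A <- rbind(cbind(matrix(0, N, N), p * C),
             cbind(t(p * C), matrix(0, ncol(C), ncol(C))))
  suppressWarnings(algebraic_connectivity(combinatorial_laplacian(A)))
}

#' Closed-form reference curves for lambda2
#'
#' Evaluates the analytic small-p / large-p predictions for the algebraic
#' connectivity of homogeneous two-layer networks:
#' \describe{
#'   \item{`multiplex_small`}{`2p` (structurally independent layers).}
#'   \item{`multiplex_large`}{`lambda2_agg` of the layers.}
#'   \item{`multilayer_small`}{`2 p <c>`, with `<c>` the mean weighted
#'     degree of the coupling structure `C`.}
#'   \item{`multilayer_large`}{`lambda2_min(layers) + lambda2(pC)`, where
#'     `lambda2(pC)` is the algebraic connectivity of the bipartite graph
#'     holding only the interlayer edges.}
#' }
#'
#' @param regime One of the four regime labels above.
#' @param p Interlayer weight (scalar or vector).
#' @param layers List of [layer_graph()]s (two for the closed forms).
#' @param C Coupling structure matrix (full-multilayer regimes only).
#' @return Reference lambda2 value(s), same length as `p`.
#' @export
reference_lambda2 <- function(regime = c("multiplex_small",
                                         "multiplex_large",
                                         "multilayer_small",
                                         "multilayer_large"),
                              p, layers = NULL, C = NULL) {
  regime <- match.arg(regime)
  switch(regime,
    multiplex_small = 2 * p,
    multiplex_large = rep(lambda2_agg(layers), length(p)),
    multilayer_small = 2 * p * mean_weighted_degree(C),
    multilayer_large = {
      l2min <- min(vapply(layers, function(l)
        suppressWarnings(algebraic_connectivity(l)), 0))
      l2min + vapply(p, function(pp) bipartite_lambda2(C, pp), 0)
    })
}

scale_coupling <- function(cp, p) {
  interlayer_coupling(p * cp$block, cp$structure)
}

as_coupling_list <- function(coupling_template, l) {
  if (inherits(coupling_template, "interlayer_coupling")) {
    if (l != 2L)
      stopf("a single coupling template requires exactly two layers")
    list("1_2" = coupling_template)
  } else coupling_template
}

#' Log-spaced grid helper
#'
#' @param from,to Grid limits (> 0).
#' @param n Number of points.
#' @return Ascending log-spaced numeric vector.
#' @export
log_grid <- function(from, to, n = 40L) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Scan lambda2 and lambda3 over an interlayer-weight grid
#'
#' For each `p` in the grid, scales the coupling template blocks by `p`,
#' assembles the combinatorial supra-Laplacian and records its second- and
#' third-smallest eigenvalues, together with the applicable closed-form
#' reference curves (homogeneous diagonal or full templates). p-grids are
#' typically log-spaced ([log_grid()]) because the transition spans orders
#' of magnitude.
#'
#' @param layers List of [layer_graph()]s (equal node counts).
#' @param coupling_template An [interlayer_coupling()] (two-layer case) or
#'   named list keyed `"i_j"`; the blocks are the couplings at `p = 1`.
#' @param p_grid Ascending vector of positive interlayer weights.
#' @param k Number of eigenvalues tracked per grid point (>= 3).
#' @param method Eigensolver route, see [smallest_eigenvalues()].
#' @return An object of class `"spectral_scan"`: `$table` is a data frame
#'   with columns `p`, `lambda2`, `lambda3`, `ref_small_p`, `ref_large_p`;
#'   `$eval` re-evaluates `(lambda2, lambda3)` at an arbitrary `p` (used
#'   by [transition_point()]).
#' @export
scan_transition <- function(layers, coupling_template, p_grid, k = 3L,
                            method = "auto") {
  stopifnot(length(layers) >= 2L,
            all(vapply(layers, inherits, TRUE, "layer_graph")))
  if (is.unsorted(p_grid) || any(p_grid <= 0))
    stopf("`p_grid` must be ascending and positive")
  k <- max(3L, check_count(k, "k"))
  l <- length(layers)
  couplings <- as_coupling_list(coupling_template, l)
  lay_names <- names(layers)
  if (is.null(lay_names)) names(layers) <- sprintf("layer%d", seq_len(l))
  eval_p <- function(p) {
    cps <- lapply(couplings, scale_coupling, p = p)
    net <- supra_network(layers, cps)
    smallest_eigenvalues(combinatorial_laplacian(net), k, method = method)
  }
  eig <- t(vapply(p_grid, eval_p, numeric(k)))
  ref_small <- ref_large <- rep(NA_real_, length(p_grid))
  if (l == 2L && length(couplings) == 1L) {
    cp <- couplings[[1L]]
    diag_entries <- diag(cp$block)
    off <- cp$block[row(cp$block) != col(cp$block)]
    if (cp$structure == "diagonal" &&
        all(abs(diag_entries - 1) < 1e-12)) {
      ref_small <- reference_lambda2("multiplex_small", p_grid)
      ref_large <- reference_lambda2("multiplex_large", p_grid, layers)
    } else if (all(cp$block > 0)) {
      ref_small <- reference_lambda2("multilayer_small", p_grid,
                                     C = cp$block)
      ref_large <- reference_lambda2("multilayer_large", p_grid, layers,
                                     C = cp$block)
    }
  }
  structure(
    list(table = data.frame(p = p_grid,
                            lambda2 = eig[, 2L], lambda3 = eig[, 3L],
                            ref_small_p = ref_small,
                            ref_large_p = ref_large),
         eigenvalues = eig, eval = eval_p, k = k),
    class = "spectral_scan")
}

#' @export
print.spectral_scan <- function(x, ...) {
  cat(sprintf("<spectral_scan> %d grid points, p in [%g, %g]\n",
              nrow(x$table), min(x$table$p), max(x$table$p)))
  invisible(x)
}

#' Transition point p* from a spectral scan
#'
#' Locates the smallest interlayer weight at which the lambda2 and lambda3
#' branches of the supra-Laplacian intersect: finds the grid interval
#' where the gap `lambda3 - lambda2` attains its minimum, refines the
#' minimizer by golden-section search, and declares a crossing when the
#' refined gap satisfies `gap <= atol + rtol * lambda3`. Heterogeneous
#' couplings can produce avoided crossings; then the gap-minimizing `p` is
#' returned with `crossed = FALSE`.
#'
#' @param scan A `"spectral_scan"` from [scan_transition()].
#' @param atol,rtol Absolute / relative crossing tolerances (defaults
#'   1e-6 and 1e-4), echoed in the result.
#' @param refine_iter Golden-section iterations.
#' @return List of class `"transition_point"`: `p_star`, `gap`, `crossed`,
#'   `lambda2`, `lambda3`, `atol`, `rtol`.
#' @export
transition_point <- function(scan, atol = 1e-6, rtol = 1e-4,
                             refine_iter = 60L) {
  stopifnot(inherits(scan, "spectral_scan"))
  tab <- scan$table
  gap <- tab$lambda3 - tab$lambda2
  ng <- length(gap)
  eval_at <- function(p) scan$eval(p)
  gap_of <- function(v) v[3L] - v[2L]
  is_crossed <- function(v) gap_of(v) <= atol + rtol * v[3L]
  on_grid_crossed <- vapply(seq_len(ng), function(i)
    gap[i] <= atol + rtol * tab$lambda3[i], TRUE)
  finish <- function(p_star) {
    v <- eval_at(p_star)
    structure(list(p_star = p_star, gap = gap_of(v),
                   crossed = is_crossed(v),
                   lambda2 = v[2L], lambda3 = v[3L],
                   atol = atol, rtol = rtol),
              class = "transition_point")
  }
  # Bisect for the smallest p in (lo, hi] satisfying the crossing test;
  # needed because past the transition the two branches can coincide over
  # a whole interval (e.g. identical layers), where any gap minimum is far
  # to the right of the first intersection.
  bisect_left <- function(lo, hi) {
    for (it in seq_len(refine_iter)) {
      mid <- sqrt(lo * hi)
      if (is_crossed(eval_at(mid))) hi <- mid else lo <- mid
      if ((hi - lo) < 1e-12 * max(1, hi)) break
    }
    hi
  }
  # The transition is the FIRST interior local minimum of the gap: later
  # avoided crossings among higher branches can be deeper, and in the
  # large-p regime rtol * lambda3 grows until it spuriously exceeds the
  # constant branch separation, so crossings are only accepted at or
  # before that first minimum.
  interior <- which(gap[2:(ng - 1L)] <= gap[1:(ng - 2L)] &
                      gap[2:(ng - 1L)] <= gap[3:ng]) + 1L
  if (!length(interior))
    stopf(paste0("gap lambda3 - lambda2 is monotone over the grid ",
                 "(no interior minimum): widen the p grid"))
  i0 <- interior[1L]
  early_crossed <- which(on_grid_crossed[seq_len(min(i0 + 1L, ng))])
  if (length(early_crossed)) {
    j <- early_crossed[1L]
    if (j == 1L) return(finish(tab$p[1L]))
    return(finish(bisect_left(tab$p[j - 1L], tab$p[j])))
  }
  # No on-grid crossing up to the first gap minimum: golden-section refine.
  gap_at <- function(p) gap_of(eval_at(p))
  phi <- (sqrt(5) - 1) / 2
  a <- tab$p[i0 - 1L]; b <- tab$p[i0 + 1L]
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- gap_at(x1); f2 <- gap_at(x2)
  for (it in seq_len(refine_iter)) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- gap_at(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- gap_at(x2)
    }
    if ((b - a) < 1e-12 * max(1, b)) break
  }
  p_star <- (a + b) / 2
  # if the refined minimum actually crosses, report the leftmost crossing
  if (is_crossed(eval_at(p_star)) && i0 >= 2L)
    p_star <- bisect_left(tab$p[i0 - 1L], p_star)
  finish(p_star)
}

#' @export
print.transition_point <- function(x, ...) {
  cat(sprintf("<transition_point> p* = %.6g (gap %.3g%s)\n", x$p_star,
              x$gap, if (x$crossed) "" else ", no exact crossing"))
  invisible(x)
}

#' Difference of lambda2 between a reference scan and a treatment scan
#'
#' `delta_lambda2 = lambda2(reference) - lambda2(treatment)` per grid
#' point, e.g. homogeneous baseline minus heterogeneous / edge-deleted
#' variant. Both scans must share the same p grid.
#'
#' @param reference_scan,scan `"spectral_scan"` objects on one grid.
#' @return Numeric vector of per-p differences.
#' @export
delta_lambda2 <- function(reference_scan, scan) {
  if (!isTRUE(all.equal(reference_scan$table$p, scan$table$p)))
    stopf("scans must share the same p grid")
  reference_scan$table$lambda2 - scan$table$lambda2
}

#' Percent deviation of lambda2 from the aggregated-network value
#'
#' `100 * (lambda2_agg - lambda2) / lambda2_agg`.
#'
#' @param lambda2 Observed algebraic connectivity (scalar or vector).
#' @param lambda2_agg Aggregated-network reference value.
#' @return Percent deviation(s).
#' @export
percent_deviation_from_aggregate <- function(lambda2, lambda2_agg) {
  100 * (lambda2_agg - lambda2) / lambda2_agg
}
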