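#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation. Streams for different (purpose, index)
# tuples must not collide and must stay < 2^31 so they are valid R seeds.
# Multiplicative hashing over a Mersenne prime; strings are folded bytewise.
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (key in list(...)) {
    if (is.character(key)) {
      for (b in utf8ToInt(paste(key, collapse = "\r"))) {
        h <- (h * 131 + b) %% m
      }
    } else {
      for (k in as.numeric(key)) {
        h <- (h * 48271 + (k %% m) + 1) %% m
      }
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never perturbs user streams.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < lo || x > hi)
    stopf("`%s` must be a finite number in [%s, %s]", name, lo, hi)
  as.numeric(x)
}

is_symmetric_matrix <- function(M, tol = 0) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

# Breadth-first connectivity of an undirected weighted graph.
graph_is_connected <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(TRUE)
  seen <- logical(n)
  seen[1L] <- TRUE
  queue <- 1L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- which(A[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}
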