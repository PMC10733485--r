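# shared fixtures and cached heavy computations -------------------------

# small random trial container for contract tests
rand_trials <- function(n = 6, M = 4, S = 120, fs = 100, seed = 1) {
  set.seed(seed)
  epoched_trials(array(rnorm(n * M * S), c(n, M, S)),
                 rep_len(c(1L, 2L), n), fs,
                 paste0("ch", seq_len(M)))
}

# random standardized multi-view instance for solver tests
rand_views <- function(n = 40, p = 6, V = 3, seed = 7) {
  set.seed(seed)
  views <- lapply(seq_len(V), function(v)
    list(X = scale(matrix(rnorm(n * p), n, p))[, , drop = FALSE]))
  list(views = views, y = rep(c(1, -1), each = n / 2))
}

# independent oracle: plain proximal gradient at a small fixed step
prox_oracle <- function(views, y, lam, lmax, iters = 1e5) {
  p <- ncol(views[[1]]$X); V <- length(views)
  XtX <- lapply(views, function(v) crossprod(v$X))
  Xty <- vapply(views, function(v) as.numeric(crossprod(v$X, y)), numeric(p))
  L <- max(vapply(XtX, function(A) max(eigen(A, TRUE, TRUE)$values), 0))
  st <- 0.5 / L
  U <- matrix(0, p, V)
  for (k in seq_len(iters)) {
    G <- vapply(seq_len(V), function(v) as.numeric(XtX[[v]] %*% U[, v] - Xty[, v]),
                numeric(p))
    U <- l21_prox(U - st * G, st * lam * lmax)
  }
  U
}

mv_objective <- function(views, y, U, lam, lmax) {
  0.5 * sum(vapply(seq_along(views), function(v)
    sum((views[[v]]$X %*% U[, v] - y)^2), numeric(1))) +
    lam * lmax * sum(sqrt(rowSums(U^2)))
}

# cache for expensive seeded runs shared between test files (datasets are
# regenerated on demand - generation is deterministic and cheap)
.bench <- new.env(parent = emptyenv())

# one benchmark seed: MDFJO outer CV on the default synthetic dataset
bench_mdfjo <- function(seed) {
  key <- paste0("m", seed)
  if (is.null(.bench[[key]])) {
    tr <- generate_trials(synthetic_spec(seed = seed))$trials
    .bench[[key]] <- cross_validate(tr, mdfjo_config(), seed = seed)
  }
  .bench[[key]]
}
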