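make_two_class <- function(n = 20, T_ = 200, v1 = c(1, 0.1), v2 = c(0.1, 1),
                           seed = 2) {
  set.seed(seed)
  a1 <- array(0, c(n, 2, T_)); a2 <- array(0, c(n, 2, T_))
  for (i in seq_len(n)) {
    a1[i, 1, ] <- v1[1] * rnorm(T_); a1[i, 2, ] <- v1[2] * rnorm(T_)
    a2[i, 1, ] <- v2[1] * rnorm(T_); a2[i, 2, ] <- v2[2] * rnorm(T_)
  }
  list(a1 = a1, a2 = a2)
}

test_that("equal class covariances give eigenvalues 1/2", {
  d <- make_two_class()
  f <- csp_fit(d$a1, d$a1, m = 1, shrinkage = 0)
  expect_equal(f$eigenvalues, c(0.5, 0.5), tolerance = 1e-8)
})

test_that("axis-aligned two-channel toy recovers axis filters", {
  d <- make_two_class()
  f <- csp_fit(d$a1, d$a2, m = 1, shrinkage = 0.01)
  w1 <- f$W[, 1] / sqrt(sum(f$W[, 1]^2))
  w2 <- f$W[, 2] / sqrt(sum(f$W[, 2]^2))
  expect_gt(abs(w1[1]), 0.99)  # top filter ~ e1 (class-1 variance axis)
  expect_gt(abs(w2[2]), 0.99)  # bottom filter ~ e2
  expect_gt(f$eigenvalues[1], 0.5)
  expect_lt(f$eigenvalues[2], 0.5)
  # sign convention: dominant entry positive
  expect_gt(f$W[1, 1], 0)
  expect_gt(f$W[2, 2], 0)
})

test_that("swapping the class arguments maps eigenvalues to 1 - lambda", {
  d <- make_two_class(seed = 4)
  f12 <- csp_fit(d$a1, d$a2, m = 1, shrinkage = 0.05)
  f21 <- csp_fit(d$a2, d$a1, m = 1, shrinkage = 0.05)
  expect_equal(f21$eigenvalues, rev(1 - f12$eigenvalues), tolerance = 1e-8)
  expect_equal(abs(f21$W), abs(f12$W[, 2:1]), tolerance = 1e-6)
})

test_that("log-variance features follow the biased-variance formula", {
  set.seed(6)
  W <- matrix(c(1, 0.5, -0.2, 0.8), 2, 2)
  trial <- matrix(rnorm(2 * 4), 2, 4)
  f <- csp_logvar(W, trial)
  # brute-force arithmetic with the 1/T estimator
  for (p in 1:2) {
    z <- as.numeric(t(W[, p]) %*% trial)
    expect_equal(f[p], log(mean((z - mean(z))^2)), tolerance = 1e-10)
  }
  # scaling the trial by c shifts every feature by 2 log c
  expect_equal(csp_logvar(W, 3 * trial), f + 2 * log(3), tolerance = 1e-10)
  expect_error(csp_logvar(W, matrix(0, 2, 4)), "variance")
})

test_that("top CSP filter separates better than any single channel", {
  # one planted discriminative source mixed into all channels
  set.seed(11)
  n <- 30; M <- 4; T_ <- 300
  mix <- rnorm(M)
  a1 <- array(rnorm(n * M * T_, sd = 1), c(n, M, T_))
  a2 <- array(rnorm(n * M * T_, sd = 1), c(n, M, T_))
  for (i in seq_len(n)) {
    src <- rnorm(T_) * 2  # strong source in class 1 only
    a1[i, , ] <- a1[i, , ] + outer(mix, src)
  }
  f <- csp_fit(a1, a2, m = 1, shrinkage = 0.05)
  ratio <- function(w) {
    v1 <- mean(apply(a1, 1, function(X) var(as.numeric(t(w) %*% X))))
    v2 <- mean(apply(a2, 1, function(X) var(as.numeric(t(w) %*% X))))
    v1 / v2
  }
  csp_ratio <- ratio(f$W[, 1])
  chan_ratios <- vapply(seq_len(M), function(c) ratio(diag(M)[, c]), numeric(1))
  expect_gt(csp_ratio, max(chan_ratios))
})

test_that("view construction has the documented geometry", {
  cb <- checkerboard_case()
  tr <- cb$trials
  pre <- bandpass(apply_car(tr), 4, 40)
  rk <- fdc_scores(logvar_segments(pre, 50, 0.5), tr$labels, c(3L))
  bg <- make_band_grid(8, 20, 4, 2)
  tg <- make_time_grid(2, 1, 0.5)
  bv <- build_views(tr, rk, bg, tg, m = 1, shrinkage = 0.05)
  k <- nrow(bg$bands)
  expect_length(bv$views, 2 * nrow(tg$windows))   # modes (3, all=6) x windows
  expect_true(all(vapply(bv$views, function(v) ncol(v$X), 0L) == 2 * k))
  expect_equal(bv$views[[1]]$index$band, rep(seq_len(k), each = 2))
  # filters solve the generalized eigenproblem: 2m columns each
  expect_true(all(vapply(bv$bank[[1]][[1]], ncol, 0L) == 2))
  # refitting on the same trials reproduces stored features exactly
  again <- build_views(tr, rk, bg, tg, m = 1, shrinkage = 0.05)
  expect_identical(again$views[[3]]$X, bv$views[[3]]$X)
  # features are invariant to a channel permutation applied consistently
  # to the data and to the ranking
  perm <- c(4, 1, 6, 2, 5, 3)
  trp <- tr
  trp$data <- tr$data[, perm, , drop = FALSE]
  trp$channel_names <- tr$channel_names[perm]
  rkp <- rk
  rkp$scores <- rk$scores[perm]
  rkp$order <- order(-rkp$scores, seq_along(perm))
  bvp <- build_views(trp, rkp, bg, tg, m = 1, shrinkage = 0.05)
  for (v in c(1, 4))
    expect_equal(bvp$views[[v]]$X, bv$views[[v]]$X, tolerance = 1e-9)
})
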