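test_that("generation is deterministic and shaped by its specification object", {
  sp <- synthetic_spec(n_per_class = 5, n_channels = 6, duration_s = 2,
                       active_channels = 3L, erd_window = c(0.25, 1.75),
                       seed = 77)
  g1 <- generate_trials(sp)
  g2 <- generate_trials(sp)
  expect_identical(g1$trials$data, g2$trials$data)
  expect_equal(dim(g1$trials$data), c(10, 6, 200))
  expect_equal(table(g1$trials$labels), table(rep(1:2, each = 5)),
               ignore_attr = TRUE)
  expect_equal(g1$trials$channel_names[3], "F7")
  expect_error(synthetic_spec(active_channels = 25L), "montage")
  expect_error(synthetic_spec(attenuation = 0), "attenuation")
  expect_error(synthetic_spec(erd_window = c(1, 9)), "epoch")
})

test_that("manifest derived indices agree with the default grids", {
  g <- generate_trials(synthetic_spec(n_per_class = 2, seed = 1))
  expect_equal(g$manifest$bands_overlapping, c(3L, 4L, 5L))  # 8-12, 10-14, 12-16
  expect_equal(g$manifest$windows_overlapping, 1:5)
  g2 <- generate_trials(synthetic_spec(n_per_class = 2, erd_window = c(2, 3.5),
                                       seed = 1))
  expect_equal(g2$manifest$windows_overlapping, 2:5)  # all windows past 0-2 s
})

test_that("planted band-power contrast matches the attenuation", {
  # class-1 / class-2 variance of the band-filtered signal at the active
  # channels, measured on the central part of the ERD window where the
  # attenuation is fully in effect (edges are blurred by the zero-phase
  # band-pass and by the raised-cosine ramps)
  ratios <- vapply(1:20, function(s) {
    g <- generate_trials(synthetic_spec(n_per_class = 20, seed = s))
    tr <- g$trials
    bp <- slice_window(bandpass(tr, 10, 14), c(1.0, 2.0))
    v <- apply(bp$data[, g$manifest$active_channels, , drop = FALSE],
               c(1, 2), var)
    mean(v[tr$labels == 1, ]) / mean(v[tr$labels == 2, ])
  }, numeric(1))
  expect_equal(mean(ratios), 1 / 0.5^2, tolerance = 0.1)
  # inactive channels carry no class contrast
  g <- generate_trials(synthetic_spec(seed = 5))
  bp <- slice_window(bandpass(g$trials, 10, 14), c(1.0, 2.0))
  v <- apply(bp$data[, c(1, 2, 15), , drop = FALSE], c(1, 2), var)
  expect_equal(mean(v[g$trials$labels == 1, ]) / mean(v[g$trials$labels == 2, ]),
               1, tolerance = 0.05)
})

test_that("background periodogram slope matches the configured exponent", {
  slopes <- vapply(1:20, function(s) {
    sp <- synthetic_spec(n_per_class = 2, n_channels = 2, osc_amp = 1e-12,
                         active_channels = 1L, common_mode_amp = 0,
                         background_exponent = 1, seed = s)
    x <- generate_trials(sp)$trials$data[1, 1, ]
    n <- length(x)
    pw <- Mod(fft(x))[2:(n / 2)]^2
    f <- (1:(n / 2 - 1)) * 100 / n
    keep <- f >= 1 & f <= 40
    -coef(lm(log(pw[keep]) ~ log(f[keep])))[[2]]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.3)
})

test_that("CAR cancels the shared common-mode component", {
  sp <- synthetic_spec(n_per_class = 5, n_channels = 8, osc_amp = 1e-12,
                       active_channels = 1L, common_mode_amp = 5,
                       background_amp = 0.01, seed = 3)
  tr <- generate_trials(sp)$trials
  out <- apply_car(tr)
  expect_lt(sd(out$data) / sd(tr$data), 0.01)
})

test_that("the fixed fixture is reproducible with its planted structure", {
  cb1 <- checkerboard_case()
  cb2 <- checkerboard_case()
  expect_identical(cb1$trials$data, cb2$trials$data)
  tr <- cb1$trials
  pre <- bandpass(apply_car(tr), 4, 40)
  rk <- fdc_scores(logvar_segments(pre, 50, 0.5), tr$labels, integer())
  expect_equal(rk$order[1], 3L)
  # the top CSP component's spatial pattern (not the filter, whose entries
  # are rescaled by whitening) concentrates on the planted channel
  bp <- slice_window(bandpass(tr, 10, 14), c(0.25, 1.75))
  a1 <- bp$data[tr$labels == 1, , , drop = FALSE]
  a2 <- bp$data[tr$labels == 2, , , drop = FALSE]
  f <- csp_fit(a1, a2)
  cov_of <- function(a) {
    S <- matrix(0, dim(a)[2], dim(a)[2])
    for (i in seq_len(dim(a)[1])) {
      X <- a[i, , ]; X <- X - rowMeans(X)
      S <- S + tcrossprod(X) / ncol(X)
    }
    S / dim(a)[1]
  }
  pattern <- (cov_of(a1) + cov_of(a2)) %*% f$W[, 1]
  w <- abs(pattern) / sum(abs(pattern))
  expect_gt(w[3], 0.8)
})
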