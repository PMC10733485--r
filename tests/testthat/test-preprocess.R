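test_that("CAR removes common-mode signal and is idempotent", {
  set.seed(3)
  n <- 4; M <- 5; S <- 200
  uniq <- array(rnorm(n * M * S), c(n, M, S))
  cm <- array(rep(sin(2 * pi * 7 * (1:S) / 100), each = n * M), c(n, M, S))
  tr <- epoched_trials(uniq + cm, rep_len(1:2, n), 100)
  out <- apply_car(tr)
  # per-sample channel means vanish
  expect_lt(max(abs(apply(out$data, c(1, 3), mean))), 1e-10)
  # channel-unique parts survive up to their own common mode
  uniq_car <- uniq - aperm(array(apply(uniq, c(1, 3), mean), c(n, S, M)), c(1, 3, 2))
  expect_lt(max(abs(out$data - uniq_car)), 1e-8)
  # idempotence
  expect_lt(max(abs(apply_car(out)$data - out$data)), 1e-10)
  # constant common offset across channels maps to zero
  cst <- epoched_trials(array(5, c(2, 3, 10)) + 0 * array(rnorm(60), c(2, 3, 10)),
                        c(1L, 2L), 100)
  cst$data[] <- 5
  expect_lt(max(abs(apply_car(cst)$data)), 1e-12)
  expect_error(apply_car(epoched_trials(array(rnorm(20), c(2, 1, 10)),
                                        c(1L, 2L), 100)), "2 channels")
})

test_that("band-pass keeps in-band and rejects out-of-band sinusoids", {
  t <- (0:799) / 200
  mk <- function(f) epoched_trials(
    array(rep(sin(2 * pi * f * t), each = 2), c(1, 2, 800)), 1L, 200)
  keep <- bandpass(mk(20), 4, 40)
  expect_equal(sd(keep$data[1, 1, ]) / sd(mk(20)$data[1, 1, ]), 1,
               tolerance = 0.05)
  drop1 <- bandpass(mk(1), 4, 40)
  expect_lt(sd(drop1$data[1, 1, ]) / sd(mk(1)$data[1, 1, ]), 0.1)
  drop80 <- bandpass(mk(80), 4, 40)  # one octave above the passband
  expect_lt(sd(drop80$data[1, 1, ]) / sd(mk(80)$data[1, 1, ]), 0.1)
  # zero in, zero out
  z <- mk(20); z$data[] <- 0
  expect_true(all(bandpass(z, 4, 40)$data == 0))
  expect_error(bandpass(mk(20), 4, 120), "Nyquist")
})

test_that("band grid reproduces the published segmentations", {
  bg <- make_band_grid(4, 40, 4, 2)
  expect_equal(nrow(bg$bands), 17)
  expect_equal(unname(bg$bands[1, ]), c(4, 8))
  expect_equal(unname(bg$bands[17, ]), c(36, 40))
  expect_equal(nrow(make_band_grid(4, 8, 4, 2)$bands), 1)
  b2 <- make_band_grid(4, 12, 4, 4)
  expect_equal(unname(b2$bands), cbind(c(4, 8), c(8, 12)))
  expect_error(make_band_grid(8, 4, 4, 2))
  expect_error(make_band_grid(4, 40, 4, 5), "step")
})

test_that("time grid reproduces the published segmentations", {
  tg <- make_time_grid(4.0, 2.0, 0.5)
  expect_equal(nrow(tg$windows), 5)
  expect_equal(unname(tg$windows[5, ]), c(2, 4))
  expect_equal(nrow(make_time_grid(3.5, 2.0, 0.5)$windows), 4)
  tg1 <- make_time_grid(2.0, 2.0, 0.5)
  expect_equal(nrow(tg1$windows), 1)
  expect_error(make_time_grid(1.5, 2.0, 0.5), "exceeds")
})

test_that("grid counts match brute-force enumeration over random parameters", {
  set.seed(42)
  for (i in 1:50) {
    w <- runif(1, 1, 6); st <- runif(1, 0.5, w)
    span <- w + runif(1, 0, 10)
    bg <- make_band_grid(0, span, w, st)
    # brute force: count starts while start + width <= span (float-safe)
    starts <- 0; k <- 0
    while (k * st + w <= span + 1e-9) k <- k + 1
    expect_equal(nrow(bg$bands), k)
    tg <- make_time_grid(span, w, st)
    expect_equal(nrow(tg$windows), k)
  }
})

test_that("window slicing uses half-open sample intervals", {
  tr <- rand_trials(n = 2, M = 2, S = 400, fs = 100)
  w <- slice_window(tr, c(0, 2))
  expect_equal(n_samples(w), 200)
  expect_equal(w$data, tr$data[, , 1:200])
  w2 <- slice_window(tr, c(1.5, 3.5))
  expect_equal(w2$data, tr$data[, , 151:350])  # 0-based samples 150..349
  expect_equal(w2$epoch_start, 1.5)
  # idempotence: re-slicing the full extent is the identity
  expect_equal(slice_window(w, c(0, 2))$data, w$data)
  expect_error(slice_window(tr, c(3, 5)), "outside")
})
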