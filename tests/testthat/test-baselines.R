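# shared small benchmark for baseline contract tests
bl_gen <- function(seed = 41, attenuation = 0.4) {
  generate_trials(synthetic_spec(n_per_class = 25, n_channels = 8,
                                 duration_s = 3, active_channels = c(3L, 6L),
                                 attenuation = attenuation, seed = seed))
}
bl_cfg <- function(...) {
  mdfjo_config(fmin = 6, fmax = 22, band_width = 4, band_step = 4,
               mode_sizes = c(4L), seg_len = 50L, seed = 2L, ...)
}

test_that("broadband CSP decodes the separable benchmark and shares folds", {
  tr <- bl_gen()$trials
  r <- run_csp(tr, "all", bl_cfg(), seed = 6)
  expect_s3_class(r, "cv_report")
  expect_gte(r$mean, 0.9)
  # same master seed gives the same fold split as the main pipeline
  r2 <- run_csp(tr, "all", bl_cfg(), seed = 6)
  expect_identical(r$fold_accuracy, r2$fold_accuracy)
})

test_that("histogram MI ranks the planted band first and vanishes under independence", {
  g <- bl_gen(seed = 42)
  tr <- g$trials
  cfg <- bl_cfg()
  # planted band (10-14 Hz, band 2 of the 6-22/4 grid) wins the MI ranking
  wins <- vapply(1:20, function(s) {
    gs <- bl_gen(seed = 100 + s)
    trs <- gs$trials
    prep <- mdfjo:::prepare_views(
      trs, make_band_grid(6, 22, 4, 4),
      make_time_grid(3, 3, 3), broad = cfg$broad)
    fx <- mdfjo:::band_csp_features(prep, 1:8, 1:50, 1:50, cfg)
    mi <- apply(fx$train, 2, mdfjo:::mi_feature_label, y = trs$labels)
    which.max(tapply(mi, fx$band, mean)) == 2
  }, logical(1))
  expect_gte(sum(wins), 19)
  # label-independent features give MI near zero
  set.seed(3)
  mi0 <- mean(replicate(50, mdfjo:::mi_feature_label(rnorm(100),
                                                     rep(1:2, 50))))
  expect_lt(mi0, 0.1)
  # keeping every band equals no selection
  rk <- run_fbcsp_mibif(tr, "all", n_bands_keep = 99, config = cfg, seed = 6)
  expect_gte(rk$mean, 0.8)
})

test_that("lasso gamma endpoints behave as documented", {
  set.seed(4)
  X <- scale(matrix(rnorm(60 * 8), 60, 8))[, ]
  y <- rep(c(1, -1), 30)
  expect_equal(mdfjo:::lasso_select(X, y, 0), 1:8)
  expect_length(mdfjo:::lasso_select(X, y, 1), 0)
  tr <- bl_gen(seed = 43)$trials
  r <- run_sfbcsp(tr, "all", config = bl_cfg(), seed = 6)
  expect_gte(r$mean, 0.85)
})

test_that("anchor-channel band ranking finds the planted band", {
  cfg <- bl_cfg()
  hits <- vapply(1:20, function(s) {
    g <- generate_trials(synthetic_spec(
      n_per_class = 25, n_channels = 12, duration_s = 3,
      active_channels = 9L,  # "C3" in the fixed montage
      attenuation = 0.4, seed = 200 + s))
    tr <- g$trials
    prep <- mdfjo:::prepare_views(tr, make_band_grid(6, 22, 4, 4),
                                  make_time_grid(3, 3, 3), broad = cfg$broad)
    anchor <- match("C3", tr$channel_names)
    M <- prep$M
    lp <- vapply(seq_along(prep$covs), function(b)
      log(prep$covs[[b]][[1]][, (anchor - 1L) * M + anchor]),
    numeric(n_trials(tr)))
    i1 <- which(tr$labels == 1); i2 <- which(tr$labels == 2)
    fisher <- vapply(1:4, function(b)
      (mean(lp[i1, b]) - mean(lp[i2, b]))^2 /
        (var(lp[i1, b]) + var(lp[i2, b])), numeric(1))
    which.max(fisher) == 2
  }, logical(1))
  expect_gte(sum(hits), 19)
  expect_error(run_dfbcsp(bl_gen()$trials, anchor_channel = "XX"),
               "not in the montage")
})

test_that("single-window multi-view selection decodes the benchmark", {
  tr <- bl_gen(seed = 44)$trials
  r <- run_mso(tr, window = c(0.5, 2.5), config = bl_cfg(), seed = 6)
  expect_gte(r$mean, 0.9)
})
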