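# ---- comparison methods -------------------------------------------------
#
# All baselines run under the same outer cross-validation protocol as the
# joint-optimization pipeline and derive their fold assignment from the
# same master seed, so per-seed results are paired. Channel modes, band
# grids, CSP primitives and the SVM are shared with the main pipeline; only
# the feature-selection stage differs per method.

baseline_outer <- function(trials, config, seed, fold_fn, method) {
  check_two_classes(trials, config$folds)
  fold <- make_folds(trials$labels, config$folds, derive_seed(seed, 1L))
  acc <- numeric(config$folds)
  for (f in seq_len(config$folds))
    acc[f] <- fold_fn(which(fold != f), which(fold == f), f)
  cv_report(method, acc, seed = seed)
}

# FDC channel ranking computed on the (CAR + broadband) training trials
rank_on <- function(prep, fit_idx, config) {
  lp <- logvar_segments(
    epoched_trials(prep$broadband$data[fit_idx, , , drop = FALSE],
                   prep$labels[fit_idx], prep$fs, prep$channel_names),
    config$seg_len, config$seg_overlap)
  fdc_scores(lp, prep$labels[fit_idx], config$mode_sizes)
}

mode_channels <- function(ranking, mode_size) {
  M <- length(ranking$scores)
  k <- if (identical(mode_size, "all")) M else as.integer(mode_size)
  if (k > M) stop("mode size ", k, " exceeds the ", M, "-channel montage")
  ranking$order[seq_len(k)]
}

# per-band CSP features over one window for train/test index sets
band_csp_features <- function(prep, ch, fit_idx, test_idx, config) {
  nb <- length(prep$covs)
  sub <- cov_subidx(ch, prep$M)
  i1 <- fit_idx[prep$labels[fit_idx] == 1L]
  i2 <- fit_idx[prep$labels[fit_idx] == 2L]
  tr <- te <- list()
  for (b in seq_len(nb)) {
    cv <- prep$covs[[b]][[1]][, sub, drop = FALSE]
    C1 <- avg_cov(cv, i1, length(ch), config$shrinkage)
    C2 <- avg_cov(cv, i2, length(ch), config$shrinkage)
    W <- csp_fit_cov(C1, C2, config$m)$W
    WW <- apply(W, 2, function(w) as.vector(tcrossprod(w)))
    tr[[b]] <- log(cv[fit_idx, , drop = FALSE] %*% WW)
    te[[b]] <- log(cv[test_idx, , drop = FALSE] %*% WW)
  }
  list(train = do.call(cbind, tr), test = do.call(cbind, te),
       band = rep(seq_len(nb), each = 2L * config$m))
}

zscore_pair <- function(Xtr, Xte) {
  mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd); sdv[sdv < 1e-12] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

#' Broadband CSP baseline
#'
#' Classical CSP on the 4-40 Hz broadband signal over the full epoch within
#' one FDC channel mode, followed by the shared RBF-SVM.
#'
#' @param trials an [epoched_trials()] object.
#' @param mode_size channel-mode size: an integer or `"all"`.
#' @param config an [mdfjo_config()] list.
#' @param seed master seed (shared with the other methods for pairing).
#' @return A `cv_report`.
#' @export
run_csp <- function(trials, mode_size = "all", config = mdfjo_config(),
                    seed = config$seed) {
  dur <- n_samples(trials) / trials$fs
  bg <- structure(list(bands = cbind(low = config$broad[1],
                                     high = config$broad[2])),
                  class = "band_grid")
  tg <- make_time_grid(dur, dur, dur)
  prep <- prepare_views(trials, bg, tg, broad = config$broad,
                        order = config$filter_order)
  baseline_outer(trials, config, seed, function(fit_idx, test_idx, f) {
    ranking <- rank_on(prep, fit_idx, config)
    ch <- mode_channels(ranking, mode_size)
    fx <- band_csp_features(prep, ch, fit_idx, test_idx, config)
    z <- zscore_pair(fx$train, fx$test)
    svm_accuracy(z$train, prep$labels[fit_idx], z$test, prep$labels[test_idx],
                 config$svm_cost)
  }, paste0("CSP_", mode_size))
}

# equal-frequency 8-bin histogram mutual information between a continuous
# feature and the binary label (plug-in estimator, natural log)
mi_feature_label <- function(x, y, bins = 8L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2L) return(0)
  g <- cut(x, br, include.lowest = TRUE)
  tab <- table(g, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / outer(px, py)[keep]))
}

#' Filter-bank CSP with mutual-information band selection
#'
#' CSP features per sub-band over the whole epoch; each feature's mutual
#' information with the label is estimated by an equal-frequency histogram,
#' bands are ranked by the mean MI of their features, and the features of
#' the top `n_bands_keep` bands feed the SVM.
#'
#' @inheritParams run_csp
#' @param n_bands_keep sub-bands retained (default 4).
#' @return A `cv_report`.
#' @export
run_fbcsp_mibif <- function(trials, mode_size = "all", n_bands_keep = 4L,
                            config = mdfjo_config(), seed = config$seed) {
  dur <- n_samples(trials) / trials$fs
  bg <- make_band_grid(config$fmin, config$fmax, config$band_width,
                       config$band_step)
  tg <- make_time_grid(dur, dur, dur)
  prep <- prepare_views(trials, bg, tg, broad = config$broad,
                        order = config$filter_order)
  baseline_outer(trials, config, seed, function(fit_idx, test_idx, f) {
    ranking <- rank_on(prep, fit_idx, config)
    ch <- mode_channels(ranking, mode_size)
    fx <- band_csp_features(prep, ch, fit_idx, test_idx, config)
    mi <- apply(fx$train, 2, mi_feature_label, y = prep$labels[fit_idx])
    band_mi <- tapply(mi, fx$band, mean)
    keep_bands <- as.integer(names(sort(band_mi, decreasing = TRUE)))[
      seq_len(min(n_bands_keep, length(band_mi)))]
    keep <- fx$band %in% keep_bands
    z <- zscore_pair(fx$train[, keep, drop = FALSE], fx$test[, keep, drop = FALSE])
    svm_accuracy(z$train, prep$labels[fit_idx], z$test, prep$labels[test_idx],
                 config$svm_cost)
  }, paste0("FBCSP_", mode_size))
}

# lasso feature selection on z-scored band features; gamma is a fraction of
# the max-correlation bound max|x'y|/n; glmnet solves the whole path at once
# and the support for each gamma on the grid is returned as a list
lasso_supports <- function(X, y, gamma_grid) {
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, y))) / n
  pos <- sort(unique(gamma_grid[gamma_grid > 0]), decreasing = TRUE)
  supports <- vector("list", length(gamma_grid))
  if (length(pos)) {
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                          lambda = pos * lmax, standardize = FALSE,
                          intercept = TRUE)
    B <- as.matrix(fit$beta)
  }
  for (j in seq_along(gamma_grid)) {
    g <- gamma_grid[j]
    supports[[j]] <- if (g <= 0) seq_len(ncol(X))
                     else which(abs(B[, match(g, pos)]) > 0)
  }
  supports
}

lasso_select <- function(X, y, gamma) {
  lasso_supports(X, y, gamma)[[1]]
}

#' Sparse filter-band CSP baseline
#'
#' Band-wise CSP features over the whole epoch; a lasso regression of the
#' +1/-1 label on the z-scored features selects the non-zero-coefficient
#' features, with the penalty fraction `gamma` tuned by inner
#' cross-validated SVM accuracy (largest `gamma` attaining the maximum).
#'
#' @inheritParams run_csp
#' @param gamma_grid penalty fractions of the max-correlation bound
#'   (default `seq(0, 1, 0.01)`).
#' @return A `cv_report`.
#' @export
run_sfbcsp <- function(trials, mode_size = "all",
                       gamma_grid = seq(0, 1, by = 0.01),
                       config = mdfjo_config(), seed = config$seed) {
  dur <- n_samples(trials) / trials$fs
  bg <- make_band_grid(config$fmin, config$fmax, config$band_width,
                       config$band_step)
  tg <- make_time_grid(dur, dur, dur)
  prep <- prepare_views(trials, bg, tg, broad = config$broad,
                        order = config$filter_order)
  baseline_outer(trials, config, seed, function(fit_idx, test_idx, f) {
    ranking <- rank_on(prep, fit_idx, config)
    ch <- mode_channels(ranking, mode_size)
    fx <- band_csp_features(prep, ch, fit_idx, test_idx, config)
    labels <- prep$labels
    # inner CV over gamma
    ifold <- make_folds(labels[fit_idx], config$inner_folds,
                        derive_seed(seed, 200L + f))
    acc <- matrix(NA_real_, config$inner_folds, length(gamma_grid))
    for (g in seq_len(config$inner_folds)) {
      itr <- fit_idx[ifold != g]; ite <- fit_idx[ifold == g]
      fxi <- band_csp_features(prep, ch, itr, ite, config)
      zi <- zscore_pair(fxi$train, fxi$test)
      yi <- ifelse(labels[itr] == 1L, 1, -1)
      supports <- lasso_supports(zi$train, yi, gamma_grid)
      # neighbouring gammas often share a support; fit the SVM once per set
      keys <- vapply(supports, paste, "", collapse = ",")
      for (key in unique(keys)) {
        j1 <- which(keys == key)
        sel <- supports[[j1[1]]]
        if (!length(sel)) next
        acc[g, j1] <- svm_accuracy(zi$train[, sel, drop = FALSE], labels[itr],
                                   zi$test[, sel, drop = FALSE], labels[ite],
                                   config$svm_cost)
      }
    }
    mean_acc <- colMeans(acc)
    ok <- which(!is.na(mean_acc))
    if (!length(ok)) stop("every gamma produced an empty selection; decrease gamma")
    gam <- gamma_grid[max(ok[mean_acc[ok] >= max(mean_acc[ok]) - 1e-12])]
    z <- zscore_pair(fx$train, fx$test)
    # at a borderline gamma the full-training lasso can be empty even though
    # every inner fold kept features; fall back to the largest gamma (at most
    # the tuned one) whose full-training selection is non-empty
    yfit <- ifelse(labels[fit_idx] == 1L, 1, -1)
    cand <- sort(gamma_grid[gamma_grid <= gam], decreasing = TRUE)
    sel <- integer(0)
    for (gc in cand) {
      sel <- lasso_select(z$train, yfit, gc)
      if (length(sel)) break
    }
    if (!length(sel)) stop("empty selection at tuned gamma; decrease gamma")
    svm_accuracy(z$train[, sel, drop = FALSE], labels[fit_idx],
                 z$test[, sel, drop = FALSE], labels[test_idx], config$svm_cost)
  }, paste0("SFBCSP_", mode_size))
}

#' Discriminative filter-bank CSP baseline
#'
#' Ranks the sub-bands by the Fisher score of a single anchor channel's
#' whole-epoch log band-power (classically C3), keeps the top 4 bands, and
#' classifies their CSP features with the SVM.
#'
#' @inheritParams run_csp
#' @param anchor_channel channel name whose band power drives the Fisher
#'   ranking (default `"C3"`).
#' @param n_bands_keep sub-bands retained (default 4).
#' @return A `cv_report`.
#' @export
run_dfbcsp <- function(trials, anchor_channel = "C3", n_bands_keep = 4L,
                       config = mdfjo_config(), seed = config$seed) {
  anchor <- match(anchor_channel, trials$channel_names)
  if (is.na(anchor))
    stop("anchor channel `", anchor_channel, "` is not in the montage")
  dur <- n_samples(trials) / trials$fs
  bg <- make_band_grid(config$fmin, config$fmax, config$band_width,
                       config$band_step)
  tg <- make_time_grid(dur, dur, dur)
  prep <- prepare_views(trials, bg, tg, broad = config$broad,
                        order = config$filter_order)
  M <- prep$M
  # whole-epoch log band-power of the anchor channel, per trial and band
  anchor_lp <- vapply(seq_along(prep$covs), function(b)
    log(prep$covs[[b]][[1]][, (anchor - 1L) * M + anchor]),
    numeric(n_trials(trials)))
  baseline_outer(trials, config, seed, function(fit_idx, test_idx, f) {
    labels <- prep$labels
    i1 <- fit_idx[labels[fit_idx] == 1L]; i2 <- fit_idx[labels[fit_idx] == 2L]
    fisher <- vapply(seq_len(ncol(anchor_lp)), function(b) {
      (mean(anchor_lp[i1, b]) - mean(anchor_lp[i2, b]))^2 /
        (stats::var(anchor_lp[i1, b]) + stats::var(anchor_lp[i2, b]))
    }, numeric(1))
    keep_bands <- order(-fisher, seq_along(fisher))[seq_len(n_bands_keep)]
    fx <- band_csp_features(prep, seq_len(M), fit_idx, test_idx, config)
    keep <- fx$band %in% keep_bands
    z <- zscore_pair(fx$train[, keep, drop = FALSE], fx$test[, keep, drop = FALSE])
    svm_accuracy(z$train, labels[fit_idx], z$test, labels[test_idx],
                 config$svm_cost)
  }, "DFBCSP")
}

#' Multi-scale optimization baseline
#'
#' Multi-view L2,1 selection of sub-band CSP features across the channel
#' modes at a single fixed time window (default 0.5-2.5 s): the pipeline
#' without the time dimension and without the sparsification step - all
#' features of the non-zero rows at the inner-CV-selected penalty are kept.
#'
#' @inheritParams run_csp
#' @param window fixed analysis window in seconds (default `c(0.5, 2.5)`).
#' @return A `cv_report`.
#' @export
run_mso <- function(trials, window = c(0.5, 2.5), config = mdfjo_config(),
                    seed = config$seed) {
  bg <- make_band_grid(config$fmin, config$fmax, config$band_width,
                       config$band_step)
  tg <- structure(list(windows = cbind(start = window[1], end = window[2])),
                  class = "time_grid")
  prep <- prepare_views(trials, bg, tg, broad = config$broad,
                        order = config$filter_order)
  baseline_outer(trials, config, seed, function(fit_idx, test_idx, f) {
    cfg_f <- config
    cfg_f$seed <- derive_seed(seed, 100L + f)
    labels <- prep$labels
    ranking <- rank_on(prep, fit_idx, config)
    modes <- build_modes(ranking)
    ifold <- make_folds(labels[fit_idx], config$inner_folds,
                        derive_seed(cfg_f$seed, 11L))
    lam_grid <- sort(config$lam_grid)
    acc <- matrix(NA_real_, config$inner_folds, length(lam_grid))
    for (g in seq_len(config$inner_folds)) {
      ws <- inner_workspace(prep, modes, fit_idx[ifold != g],
                            fit_idx[ifold == g], config)
      yg <- ifelse(ws$ytr == 1L, 1, -1)
      U0 <- NULL
      for (j in rev(seq_along(lam_grid))) {
        sol <- l21_solve(ws$train, yg, lam_grid[j], config$max_iter,
                         config$tol, U0 = U0)
        U0 <- sol$U
        if (length(sol$row_support))
          acc[g, j] <- pairs_accuracy(ws, full_support_pairs(sol), config$svm_cost)
      }
    }
    mean_acc <- colMeans(acc)
    ok <- which(!is.na(mean_acc))
    if (!length(ok)) stop("every penalty produced an empty selection")
    lam_hat <- lam_grid[max(ok[mean_acc[ok] >= max(mean_acc[ok]) - 1e-12])]
    wfull <- inner_workspace(prep, modes, fit_idx, test_idx, config)
    sol <- l21_solve(wfull$train, ifelse(wfull$ytr == 1L, 1, -1), lam_hat,
                     config$max_iter, config$tol)
    pairs <- full_support_pairs(sol)
    if (is.null(pairs)) stop("empty selection at tuned penalty")
    svm_accuracy(assemble_features(pairs, wfull$train), labels[fit_idx],
                 assemble_features(pairs, wfull$test), labels[test_idx],
                 config$svm_cost)
  }, "MSO")
}
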