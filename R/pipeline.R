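#' Pipeline configuration
#'
#' Collects every tunable of the decoding pipeline with its default. The
#' defaults reproduce the method's standard setup: common average reference,
#' zero-phase 5th-order Butterworth 4-40 Hz broadband, 17 sub-bands of 4 Hz
#' width with 50% overlap, 2 s time windows with 0.5 s step, nested channel
#' modes of 16/32/all channels, one CSP filter pair per band, an L2,1
#' penalty grid of fractions 0..1 of the critical penalty, and an RBF-SVM.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A named list of class `mdfjo_config`.
#' @export
mdfjo_config <- function(...) {
  cfg <- list(
    broad = c(4, 40), filter_order = 5L,
    fmin = 4, fmax = 40, band_width = 4, band_step = 2,
    win_s = 2.0, win_step_s = 0.5,
    mode_sizes = c(16L, 32L),
    m = 1L, shrinkage = 0.05,
    seg_len = 100L, seg_overlap = 0.5,
    lam_grid = seq(0, 1, by = 0.1),
    ns_grid = NULL,
    tol = 1e-6, max_iter = 1000L,
    svm_cost = 1,
    folds = 5L, inner_folds = 5L,
    seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  structure(modifyList(cfg, ov), class = "mdfjo_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [mdfjo_config()] fields.
#' @return An `mdfjo_config` list.
#' @export
read_config <- function(path) {
  do.call(mdfjo_config, yaml::read_yaml(path))
}

#' Stratified fold assignment
#'
#' Deterministically assigns each trial to one of `k` folds, separately
#' shuffling within each class so every fold holds both classes.
#'
#' @param labels per-trial class codes.
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return Integer vector of fold ids in `1..k`, one per trial.
#' @export
make_folds <- function(labels, k, seed) {
  if (min(table(labels)) < k)
    stop("need at least ", k, " trials per class for ", k, "-fold CV")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# ---- internal classifier helpers ---------------------------------------

# RBF-SVM with the "scale" kernel-width heuristic: gamma = 1 / (p * var(X)).
svm_train <- function(X, y, cost = 1) {
  gam <- 1 / (ncol(X) * max(stats::var(as.numeric(X)), 1e-12))
  e1071::svm(X, factor(y, levels = c(1L, 2L)), kernel = "radial",
             cost = cost, gamma = gam, scale = FALSE)
}

svm_accuracy <- function(Xtr, ytr, Xte, yte, cost = 1) {
  fit <- svm_train(Xtr, ytr, cost)
  mean(as.integer(as.character(predict(fit, Xte))) == yte)
}

# all (row, view) pairs with non-zero weight, i.e. the selection before the
# time-level sparsification step
full_support_pairs <- function(weights) {
  idx <- which(abs(weights$U) > 0 &
                 row(weights$U) %in% weights$row_support, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  out <- data.frame(row = idx[, 1], view = idx[, 2])
  out[order(out$row, out$view), , drop = FALSE]
}

# ---- core fitting (shared by fit / tune / cross_validate) ---------------

# One inner-fold workspace: fitted bank, standardized train/test features.
inner_workspace <- function(prep, modes, fit_idx, test_idx, config) {
  bank <- fit_filter_bank(prep, modes, fit_idx, config$m, config$shrinkage)
  vtr <- bank_features(prep, bank, modes, fit_idx)
  std <- standardize_views(vtr)
  vte <- standardize_views(bank_features(prep, bank, modes, test_idx), std$stats)
  list(train = std$views, test = vte$views, stats = std$stats, bank = bank,
       ytr = prep$labels[fit_idx], yte = prep$labels[test_idx])
}

# accuracy of a candidate pair set on one inner workspace
pairs_accuracy <- function(ws, pairs, cost) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(NA_real_)
  Xtr <- assemble_features(pairs, ws$train)
  Xte <- assemble_features(pairs, ws$test)
  svm_accuracy(Xtr, ws$ytr, Xte, ws$yte, cost)
}

fit_core <- function(prep, fit_idx, config, tuning_only = FALSE,
                     tune_ns = TRUE) {
  labels <- prep$labels[fit_idx]
  if (length(unique(labels)) != 2L) stop("training folds must contain both classes")

  # channel ranking on the training trials only (no test-fold leakage)
  lp <- logvar_segments(
    epoched_trials(prep$broadband$data[fit_idx, , , drop = FALSE], labels,
                   prep$fs, prep$channel_names),
    config$seg_len, config$seg_overlap)
  ranking <- fdc_scores(lp, labels, config$mode_sizes)
  modes <- build_modes(ranking)
  n_views <- length(modes) * nrow(prep$time_grid$windows)
  ns_grid <- if (is.null(config$ns_grid)) seq_len(n_views) else config$ns_grid

  # inner cross-validation workspaces
  ifold <- make_folds(labels, config$inner_folds, derive_seed(config$seed, 11L))
  ws <- lapply(seq_len(config$inner_folds), function(f)
    inner_workspace(prep, modes, fit_idx[ifold != f], fit_idx[ifold == f], config))

  # lambda path per inner fold (warm-started), accuracy with all non-zero rows
  lam_grid <- sort(config$lam_grid)
  solves <- vector("list", length(ws))
  lam_acc <- matrix(NA_real_, length(ws), length(lam_grid))
  for (f in seq_along(ws)) {
    yf <- ifelse(ws[[f]]$ytr == 1L, 1, -1)
    U0 <- NULL
    sol <- vector("list", length(lam_grid))
    for (j in rev(seq_along(lam_grid))) {  # from lam = 1 down: sparse to dense
      sol[[j]] <- l21_solve(ws[[f]]$train, yf, lam_grid[j],
                            config$max_iter, config$tol, U0 = U0)
      U0 <- sol[[j]]$U
      if (length(sol[[j]]$row_support))
        lam_acc[f, j] <- pairs_accuracy(ws[[f]], full_support_pairs(sol[[j]]),
                                        config$svm_cost)
    }
    solves[[f]] <- sol
  }
  mean_acc <- colMeans(lam_acc)            # NA where any fold was degenerate
  ok <- which(!is.na(mean_acc))
  if (!length(ok))
    stop("every lam on the grid produced an empty selection; extend the grid")
  best <- max(mean_acc[ok])
  lam_hat <- lam_grid[max(ok[mean_acc[ok] >= best - 1e-12])]  # largest lam at max

  # full-training solve at the chosen lam, then Ns by inner-CV accuracy
  wfull <- inner_workspace(prep, modes, fit_idx, fit_idx, config)
  yfull <- ifelse(labels == 1L, 1, -1)
  weights <- l21_solve(wfull$train, yfull, lam_hat, config$max_iter, config$tol)
  if (!tune_ns && tuning_only)
    return(list(lam = lam_hat, ns = NA_integer_, lam_grid = lam_grid,
                lam_accuracy = mean_acc, ranking = ranking, weights = weights))
  sel <- sparsify(weights, function(pairs) {
    mean(vapply(ws, function(w) pairs_accuracy(w, pairs, config$svm_cost),
                numeric(1)), na.rm = TRUE)
  }, ns_grid)

  tuning <- list(lam = lam_hat, ns = sel$ns,
                 lam_grid = lam_grid, lam_accuracy = mean_acc,
                 ns_grid = sel$ns_grid, ns_accuracy = sel$accuracy_curve,
                 ranking = ranking, weights = weights)
  if (tuning_only) return(tuning)

  Xtr <- assemble_features(sel$pairs, wfull$train)
  model <- structure(list(
    config = config, channel_names = prep$channel_names, fs = prep$fs,
    band_grid = prep$band_grid, time_grid = prep$time_grid,
    ranking = ranking, modes = modes,
    bank = wfull$bank,
    feat_stats = wfull$stats, weights = weights, selection = sel,
    tuning = tuning, svm = svm_train(Xtr, labels, config$svm_cost),
    train_features = Xtr, n_train = length(fit_idx)),
    class = "mdfjo_model")
  model
}

#' Fit the multi-domain joint-optimization decoder
#'
#' End-to-end training on a set of labelled trials: FDC channel ranking and
#' nested mode construction, per-view CSP feature extraction over the
#' sub-band x time-window grids, inner cross-validated choice of the L2,1
#' penalty `lam` (largest value attaining the best inner accuracy) and of
#' the sparsification depth `Ns` (smallest value attaining the best inner
#' accuracy), a final L2,1 solve and sparsification on the full training
#' set, and an RBF-SVM on the selected features. All randomness (fold
#' assignment) derives from `config$seed`.
#'
#' @param trials an [epoched_trials()] object with both classes present.
#' @param config an [mdfjo_config()] list.
#' @return An object of class `mdfjo_model`; see [predict.mdfjo_model()].
#' @export
mdfjo_fit <- function(trials, config = mdfjo_config()) {
  check_two_classes(trials, config$inner_folds)
  band_grid <- make_band_grid(config$fmin, config$fmax, config$band_width,
                              config$band_step)
  dur <- n_samples(trials) / trials$fs
  time_grid <- make_time_grid(dur, config$win_s, config$win_step_s)
  prep <- prepare_views(trials, band_grid, time_grid, broad = config$broad,
                        order = config$filter_order)
  fit_core(prep, seq_len(n_trials(trials)), config)
}

#' Tune the pipeline hyperparameters by inner cross-validation
#'
#' Runs only the nested-CV tuning stage of [mdfjo_fit()] and returns the
#' chosen `(lam, Ns)` with the accuracy curves behind the choice.
#'
#' @inheritParams mdfjo_fit
#' @param tune_ns also run the sparsification-depth stage? Setting `FALSE`
#'   stops after the penalty choice (cheaper; `ns` is then `NA`).
#' @return A list with `lam`, `ns`, `lam_grid`, `lam_accuracy`, `ns_grid`,
#'   `ns_accuracy`, plus the training-set channel `ranking` and the
#'   full-training-set `weights` at the chosen penalty.
#' @export
tune_hyperparams <- function(trials, config = mdfjo_config(), tune_ns = TRUE) {
  check_two_classes(trials, config$inner_folds)
  band_grid <- make_band_grid(config$fmin, config$fmax, config$band_width,
                              config$band_step)
  time_grid <- make_time_grid(n_samples(trials) / trials$fs,
                              config$win_s, config$win_step_s)
  prep <- prepare_views(trials, band_grid, time_grid, broad = config$broad,
                        order = config$filter_order)
  fit_core(prep, seq_len(n_trials(trials)), config, tuning_only = TRUE,
           tune_ns = tune_ns)
}

# transform trials already reduced to a prep structure
predict_core <- function(model, prep, idx) {
  views <- bank_features(prep, model$bank, model$modes, idx)
  views <- standardize_views(views, model$feat_stats)$views
  X <- assemble_features(model$selection$pairs, views)
  as.integer(as.character(predict(model$svm, X)))
}

#' Predict class labels for unseen trials
#'
#' Applies the stored preprocessing, filter bank, standardization, feature
#' selection and classifier; nothing is refitted.
#'
#' @param object an `mdfjo_model` from [mdfjo_fit()].
#' @param trials an [epoched_trials()] object whose montage matches the
#'   model's.
#' @param ... unused.
#' @return Integer vector of predicted labels in `{1, 2}`.
#' @export
predict.mdfjo_model <- function(object, trials, ...) {
  validate_trials(trials)
  if (!identical(trials$channel_names, object$channel_names))
    stop("channel montage does not match the fitted model")
  prep <- prepare_views(trials, object$band_grid, object$time_grid,
                        broad = object$config$broad,
                        order = object$config$filter_order)
  predict_core(object, prep, seq_len(n_trials(trials)))
}

#' @export
print.mdfjo_model <- function(x, ...) {
  cat("<mdfjo_model> ", x$n_train, " training trials, ",
      length(x$modes), " modes x ", nrow(x$time_grid$windows), " windows x ",
      nrow(x$band_grid$bands), " bands; lam = ", x$tuning$lam,
      ", Ns = ", x$tuning$ns, ", ", nrow(x$selection$pairs),
      " selected features\n", sep = "")
  invisible(x)
}

#' Outer cross-validated accuracy of the decoder
#'
#' Stratified outer k-fold protocol: each fold is held out entirely while
#' channel ranking, CSP fitting, hyperparameter tuning and classifier
#' training run on the remaining folds; the held-out fold is then decoded.
#'
#' @param trials an [epoched_trials()] object.
#' @param config an [mdfjo_config()] list.
#' @param seed master seed for fold assignment and all inner randomness.
#' @return An object of class `cv_report`: list with `method`,
#'   `fold_accuracy`, `mean`, `sd`, `fold_lam`, `fold_ns`, `fold_n_pairs`,
#'   `seed`.
#' @export
cross_validate <- function(trials, config = mdfjo_config(), seed = config$seed) {
  check_two_classes(trials, config$folds)
  config$seed <- seed
  band_grid <- make_band_grid(config$fmin, config$fmax, config$band_width,
                              config$band_step)
  time_grid <- make_time_grid(n_samples(trials) / trials$fs,
                              config$win_s, config$win_step_s)
  prep <- prepare_views(trials, band_grid, time_grid, broad = config$broad,
                        order = config$filter_order)
  fold <- make_folds(trials$labels, config$folds, derive_seed(seed, 1L))
  acc <- lam <- ns <- npairs <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    cfg_f <- config
    cfg_f$seed <- derive_seed(seed, 100L + f)
    model <- fit_core(prep, which(fold != f), cfg_f)
    pred <- predict_core(model, prep, which(fold == f))
    acc[f] <- mean(pred == trials$labels[fold == f])
    lam[f] <- model$tuning$lam
    ns[f] <- model$tuning$ns
    npairs[f] <- nrow(model$selection$pairs)
  }
  cv_report("MDFJO", acc, lam, ns, npairs, seed)
}

cv_report <- function(method, acc, lam = NA, ns = NA, npairs = NA, seed = NA) {
  structure(list(method = method, fold_accuracy = acc, mean = mean(acc),
                 sd = stats::sd(acc), fold_lam = lam, fold_ns = ns,
                 fold_n_pairs = npairs, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$method, ": mean accuracy ",
      sprintf("%.3f +/- %.3f", x$mean, x$sd), " over ",
      length(x$fold_accuracy), " folds (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Squared standardized class difference (r-squared diagnostic)
#'
#' The sample-size-weighted squared standardized mean difference
#' `r^2 = (sqrt(L1 L2)/(L1 + L2) * (mean(X1) - mean(X2)) / sd(X1 u X2))^2`
#' used to visualize how strongly a spectral quantity separates the classes.
#' The pooled spread is the sample standard deviation of the concatenation.
#'
#' @param X1,X2 numeric vectors (e.g. per-frequency power of each class).
#' @return An object of class `discriminability_score`: list with `value`,
#'   `n1`, `n2`.
#' @export
r_squared <- function(X1, X2) {
  if (!length(X1) || !length(X2)) stop("both vectors must be non-empty")
  s <- stats::sd(c(X1, X2))
  if (!is.finite(s) || s == 0) stop("pooled standard deviation is zero")
  L1 <- length(X1); L2 <- length(X2)
  v <- (sqrt(L1 * L2) / (L1 + L2) * (mean(X1) - mean(X2)) / s)^2
  structure(list(value = v, n1 = L1, n2 = L2), class = "discriminability_score")
}

#' @export
print.discriminability_score <- function(x, ...) {
  cat("<discriminability_score> r^2 = ", signif(x$value, 4),
      " (n1 = ", x$n1, ", n2 = ", x$n2, ")\n", sep = "")
  invisible(x)
}

#' Per-band weight profile of a multi-view solution
#'
#' Aggregates the 2mk feature rows of a weight matrix to one L2 norm per
#' sub-band (summing its `2m` filter rows across all views), the form used
#' for reporting which bands carry the selection.
#'
#' @param weights a [l21_solve()] result.
#' @param m CSP filter pairs per band (default 1).
#' @return Numeric vector of length `k` (bands).
#' @export
band_weight_profile <- function(weights, m = 1L) {
  p <- nrow(weights$U)
  k <- p / (2L * m)
  if (k != round(k)) stop("row count is not a multiple of 2m")
  band <- rep(seq_len(k), each = 2L * m)
  vapply(seq_len(k), function(b) sqrt(sum(weights$U[band == b, ]^2)), numeric(1))
}
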