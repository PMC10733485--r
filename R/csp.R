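# ---- covariance utilities ----------------------------------------------
#
# All CSP fitting and feature extraction in this package runs on per-trial
# channel covariance matrices of the (band-filtered, windowed) signal:
#   - fitting uses trace-normalized, class-averaged, shrunk covariances;
#   - the Eq.-style log-variance feature of filter w on trial X is exactly
#     log(w' C w) with C the biased (1/T), mean-removed trial covariance.
# Covariances of the full montage are computed once per (band, window) and
# reused by every channel mode (a mode's covariance is a submatrix), which
# is what makes the nested cross-validation affordable.

# vectorized covariances (n x M^2) for an array restricted to a window
trial_covs <- function(arr, rng) {
  .window_cov_cpp(arr, as.integer(rng[1] - 1L), as.integer(rng[2]))
}

# column indices of the vectorized M x M covariance for channel subset `ch`
cov_subidx <- function(ch, M) {
  as.vector(outer(ch, (ch - 1L) * M, `+`))
}

# average trace-normalized covariances over rows `idx`, then shrink toward
# (trace/M) * I with intensity `shrinkage`
avg_cov <- function(covs, idx, M, shrinkage) {
  sub <- covs[idx, , drop = FALSE]
  tr <- rowSums(sub[, (seq_len(M) - 1L) * M + seq_len(M), drop = FALSE])
  if (any(tr <= 0)) stop("trial with non-positive covariance trace")
  Cbar <- matrix(colMeans(sub / tr), M, M)
  if (shrinkage > 0) {
    mu <- sum(diag(Cbar)) / M
    Cbar <- (1 - shrinkage) * Cbar + shrinkage * mu * diag(M)
  }
  Cbar
}

# Generalized eigenproblem of (C1, C1 + C2): whiten the composite, eigen the
# whitened C1. Eigenvalues lie in [0, 1]; the first m columns of W carry the
# largest eigenvalues (class-1-dominant variance), the last m the smallest.
csp_fit_cov <- function(C1, C2, m = 1L) {
  M <- nrow(C1)
  if (2L * m > M) stop("m too large for ", M, " channels")
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) <= max(ec$values) * 1e-10)
    stop("composite covariance is numerically singular; use shrinkage > 0")
  P <- ec$vectors %*% (t(ec$vectors) / sqrt(ec$values))
  S <- t(P) %*% C1 %*% P
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)      # eigenvalues descending
  keep <- c(seq_len(m), M - m + seq_len(m))
  W <- P %*% es$vectors[, keep, drop = FALSE]
  # sign convention: largest-magnitude entry of each column is positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  list(W = W, eigenvalues = es$values[keep])
}

#' Fit a common spatial pattern filter
#'
#' Computes the CSP projection for two classes of trials: per-trial biased
#' covariances (channel means removed) are trace-normalized, averaged per
#' class, shrunk toward `(trace/M) I`, and the generalized eigenproblem of
#' `(C1, C1 + C2)` is solved. The returned filters are the `m` eigenvectors
#' with the largest eigenvalues followed by the `m` with the smallest; each
#' column's largest-magnitude entry is made positive for reproducibility.
#'
#' @param trials_class1,trials_class2 3-d arrays (trials x channels x
#'   samples) or [epoched_trials()] objects holding the trials of each class.
#' @param m filter pairs to retain (default 1, giving `2m = 2` filters).
#' @param shrinkage shrinkage intensity in `[0, 1]` toward the scaled
#'   identity (default 0.05); guards against rank-deficient averages.
#' @return A list with `W` (channels x 2m filter matrix) and `eigenvalues`
#'   (the 2m retained generalized eigenvalues, in `[0, 1]`).
#' @export
csp_fit <- function(trials_class1, trials_class2, m = 1L, shrinkage = 0.05) {
  a1 <- if (inherits(trials_class1, "epoched_trials")) trials_class1$data else trials_class1
  a2 <- if (inherits(trials_class2, "epoched_trials")) trials_class2$data else trials_class2
  stopifnot(length(dim(a1)) == 3L, length(dim(a2)) == 3L,
            dim(a1)[2] == dim(a2)[2])
  if (dim(a1)[1] < 2L || dim(a2)[1] < 2L)
    stop("each class needs >= 2 trials")
  M <- dim(a1)[2]
  cv1 <- trial_covs(a1, c(1L, dim(a1)[3]))
  cv2 <- trial_covs(a2, c(1L, dim(a2)[3]))
  C1 <- avg_cov(cv1, seq_len(nrow(cv1)), M, shrinkage)
  C2 <- avg_cov(cv2, seq_len(nrow(cv2)), M, shrinkage)
  csp_fit_cov(C1, C2, m)
}

#' CSP log-variance features of one trial
#'
#' Projects a trial through the spatial filters and returns
#' `f_p = log(var(Z_p))`, `p = 1..2m`, with `Z = W' X` and the biased (1/T)
#' variance estimator.
#'
#' @param W channels x 2m filter matrix from [csp_fit()].
#' @param trial channels x samples matrix.
#' @return Numeric vector of length `2m`.
#' @export
csp_logvar <- function(W, trial) {
  stopifnot(is.matrix(trial), nrow(trial) == nrow(W))
  Z <- crossprod(W, trial)
  v <- rowMeans(Z^2) - rowMeans(Z)^2
  if (any(v <= 0)) stop("zero-variance projection")
  log(v)
}

# ---- view construction --------------------------------------------------

# Internal per-dataset preparation: CAR + broadband filter once, then for
# every sub-band the zero-phase filtered full epoch, and for every
# (band, window) the vectorized per-trial covariances of the full montage.
# Everything here is unsupervised and per-trial independent, so one `prep`
# on the full dataset can serve every cross-validation fold without leaking
# labels across folds.
prepare_views <- function(trials, band_grid, time_grid,
                          broad = c(4, 40), order = 5L, car = TRUE) {
  validate_trials(trials)
  tr <- if (car) apply_car(trials) else trials
  tr <- bandpass(tr, broad[1], broad[2], order)
  nb <- nrow(band_grid$bands)
  nt <- nrow(time_grid$windows)
  rngs <- lapply(seq_len(nt), function(t)
    window_samples(time_grid$windows[t, ], tr$fs, n_samples(tr)))
  d <- dim(tr$data)
  # samples-major layout (samples x trials*channels), transposed once
  xm <- matrix(aperm(tr$data, c(3, 1, 2)), nrow = d[3])
  covs <- vector("list", nb)
  for (b in seq_len(nb)) {
    co <- butter_coefs(band_grid$bands[b, 1], band_grid$bands[b, 2], tr$fs, order)
    fb <- .filtfilt_cpp(co$b, co$a, xm)
    covs[[b]] <- lapply(rngs, function(rng)
      .window_cov_sm_cpp(fb, d[1], d[2], as.integer(rng[1] - 1L),
                         as.integer(rng[2])))
  }
  list(covs = covs, broadband = tr, labels = trials$labels,
       M = n_channels(trials), fs = trials$fs,
       band_grid = band_grid, time_grid = time_grid,
       channel_names = trials$channel_names)
}

# Fit the full CSP filter bank on the trials indexed by `fit_idx`.
# bank[[s]][[t]][[b]] is the 2m-column filter for (mode s, window t, band b).
fit_filter_bank <- function(prep, modes, fit_idx, m = 1L, shrinkage = 0.05) {
  labels <- prep$labels[fit_idx]
  i1 <- fit_idx[labels == 1L]; i2 <- fit_idx[labels == 2L]
  if (length(i1) < 2L || length(i2) < 2L) stop("each class needs >= 2 trials")
  nb <- length(prep$covs); nt <- length(prep$covs[[1]])
  lapply(modes, function(ch) {
    Ms <- length(ch)
    sub <- cov_subidx(ch, prep$M)
    lapply(seq_len(nt), function(t) {
      lapply(seq_len(nb), function(b) {
        cv <- prep$covs[[b]][[t]][, sub, drop = FALSE]
        C1 <- avg_cov(cv, i1, Ms, shrinkage)
        C2 <- avg_cov(cv, i2, Ms, shrinkage)
        csp_fit_cov(C1, C2, m)$W
      })
    })
  })
}

# Features of the trials indexed by `idx` for every view: list over views
# (mode-major, window-minor) of n x 2mk matrices, columns band-major then
# filter index.
bank_features <- function(prep, bank, modes, idx) {
  nb <- length(prep$covs); nt <- length(prep$covs[[1]])
  out <- list()
  v <- 0L
  for (s in seq_along(modes)) {
    ch <- modes[[s]]
    sub <- cov_subidx(ch, prep$M)
    Ms <- length(ch)
    for (t in seq_len(nt)) {
      cols <- list()
      for (b in seq_len(nb)) {
        W <- bank[[s]][[t]][[b]]
        cv <- prep$covs[[b]][[t]][idx, sub, drop = FALSE]
        # quadratic forms w' C w for all trials at once: vec(C) . vec(w w')
        WW <- apply(W, 2, function(w) as.vector(tcrossprod(w)))
        val <- cv %*% WW
        if (any(val <= 0)) stop("zero-variance projection in view features")
        cols[[b]] <- log(val)
      }
      v <- v + 1L
      X <- do.call(cbind, cols)
      colnames(X) <- paste0("b", rep(seq_len(nb), each = ncol(bank[[s]][[t]][[1]])),
                            "f", seq_len(ncol(bank[[s]][[t]][[1]])))
      out[[v]] <- list(X = X, s = s, t = t,
                       index = data.frame(
                         band = rep(seq_len(nb), each = ncol(bank[[s]][[t]][[1]])),
                         filter = rep(seq_len(ncol(bank[[s]][[t]][[1]])), nb)))
    }
  }
  out
}

#' Build per-view CSP feature matrices
#'
#' For every (channel mode, time window) view, fits one CSP filter per
#' sub-band on the supplied trials and assembles the `N x 2mk` log-variance
#' feature matrix (columns band-major, then filter index). The trials passed
#' in are the fitting set; transforming them through the returned bank
#' reproduces the stored features exactly.
#'
#' @param trials an [epoched_trials()] object (training trials).
#' @param ranking a [fdc_scores()] channel ranking covering all channels.
#' @param band_grid a [make_band_grid()] object.
#' @param time_grid a [make_time_grid()] object.
#' @param m CSP filter pairs per band (default 1).
#' @param shrinkage covariance shrinkage intensity (default 0.05).
#' @param broad broad band-pass applied before sub-band filtering.
#' @return A list with `bank` (the fitted filter bank), `views` (list of view
#'   feature objects with fields `X`, `s`, `t`, `index`), `y` (labels coded
#'   +1 for class 1, -1 for class 2), `modes`, and the grids.
#' @export
build_views <- function(trials, ranking, band_grid, time_grid,
                        m = 1L, shrinkage = 0.05, broad = c(4, 40)) {
  check_two_classes(trials, 2L)
  prep <- prepare_views(trials, band_grid, time_grid, broad = broad)
  modes <- build_modes(ranking)
  idx <- seq_len(n_trials(trials))
  bank <- fit_filter_bank(prep, modes, idx, m, shrinkage)
  views <- bank_features(prep, bank, modes, idx)
  list(bank = bank, views = views, y = ifelse(trials$labels == 1L, 1, -1),
       modes = modes, band_grid = band_grid, time_grid = time_grid)
}
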