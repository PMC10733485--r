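# ---- L2,1-regularized multi-view least squares --------------------------
#
# The selection model is
#   min_U  1/2 sum_{views v} || X_v u_v - y ||^2  +  lambda ||U||_{2,1}
# with U = [u_1 ... u_V] (rows = feature indices shared across views,
# columns = views) and ||U||_{2,1} = sum_i ||U[i, ]||_2. The smooth term is
# block-diagonal across views, so the gradient decouples per column; the
# row-coupling enters only through the proximal step, which zeroes whole
# rows and therefore selects features jointly across all views.
#
# The regularization strength is parameterized as a FRACTION of lambda_max,
# the smallest value at which U = 0 is optimal; lam = 1 then always yields
# the empty model, independent of data scale.

# standardize view features column-wise; returns views plus the statistics
# so the identical transform can be replayed on unseen trials
standardize_views <- function(views, stats = NULL) {
  if (is.null(stats)) {
    stats <- lapply(views, function(v) {
      mu <- colMeans(v$X)
      sdv <- apply(v$X, 2, stats::sd)
      sdv[sdv < 1e-12] <- 1
      list(mean = mu, sd = sdv)
    })
  }
  out <- Map(function(v, st) {
    v$X <- sweep(sweep(v$X, 2, st$mean), 2, st$sd, "/")
    v
  }, views, stats)
  list(views = out, stats = stats)
}

#' Critical regularization strength
#'
#' Returns the smallest absolute penalty at which the all-zero weight matrix
#' is optimal: the maximum over feature rows of the L2 norm across views of
#' the gradient `X_v' y`. Fractional `lam` values in [l21_solve()] are
#' multiples of this bound, so `lam = 1` always selects nothing.
#'
#' @param views list of view feature objects (fields `X`), as produced by
#'   [build_views()] (standardized).
#' @param y common label vector coded +1 / -1.
#' @return A non-negative scalar.
#' @export
lambda_max <- function(views, y) {
  if (!length(views)) stop("empty view list")
  G <- vapply(views, function(v) as.numeric(crossprod(v$X, y)),
              numeric(ncol(views[[1]]$X)))
  if (is.null(dim(G))) G <- matrix(G, nrow = 1)
  max(sqrt(rowSums(G^2)))
}

#' Row-wise L2,1 proximal operator
#'
#' Shrinks each row of `U` toward zero: `u_i <- max(0, 1 - t/||u_i||) u_i`.
#' Rows with norm at most the threshold become exactly zero, which is the
#' mechanism by which whole feature rows are dropped across all views.
#'
#' @param U numeric matrix (rows = features, columns = views).
#' @param threshold non-negative scalar.
#' @return A matrix of the same shape.
#' @export
l21_prox <- function(U, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (threshold == 0) return(U)
  nrm <- sqrt(rowSums(U^2))
  scl <- pmax(0, 1 - threshold / pmax(nrm, 1e-300))
  U * scl
}

#' Solve the multi-view L2,1 selection problem
#'
#' Accelerated proximal gradient (FISTA) with function-value restart on the
#' row-sparse multi-view least squares objective. The step size is `1/L`
#' with `L` the largest eigenvalue of `X_v' X_v` over views; monotone
#' descent of the objective is enforced by falling back to a plain proximal
#' step whenever the accelerated iterate would increase it.
#'
#' @param views list of view feature objects (standardized columns).
#' @param y common label vector coded +1 / -1.
#' @param lam penalty as a fraction of [lambda_max()] in `[0, 1]`.
#' @param max_iter iteration cap (default 1000).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @param U0 optional warm start (features x views matrix).
#' @return An object of class `multiview_weights`: list with `U` (features x
#'   views), `lam`, `lambda_max`, `objective_trace`, `converged`, and
#'   `row_support` (indices of non-zero rows).
#' @export
l21_solve <- function(views, y, lam, max_iter = 1000L, tol = 1e-6, U0 = NULL) {
  if (!length(views)) stop("empty view list")
  if (lam < 0) stop("lam must be >= 0")
  p <- ncol(views[[1]]$X); V <- length(views); n <- length(y)
  XtX <- lapply(views, function(v) crossprod(v$X))
  Xty <- vapply(views, function(v) as.numeric(crossprod(v$X, y)), numeric(p))
  if (is.null(dim(Xty))) Xty <- matrix(Xty, nrow = p)
  yy <- sum(y^2)
  lmax <- lambda_max(views, y)
  pen <- lam * lmax
  L <- max(vapply(XtX, function(A) max(eigen(A, symmetric = TRUE,
                                             only.values = TRUE)$values), 0))
  if (L <= 0) L <- 1
  step <- 1 / L

  smooth_obj <- function(U) {
    s <- 0
    for (v in seq_len(V))
      s <- s + sum(U[, v] * (XtX[[v]] %*% U[, v])) - 2 * sum(U[, v] * Xty[, v])
    0.5 * (s + V * yy)
  }
  obj <- function(U) smooth_obj(U) + pen * sum(sqrt(rowSums(U^2)))
  grad <- function(U) {
    G <- matrix(0, p, V)
    for (v in seq_len(V)) G[, v] <- XtX[[v]] %*% U[, v] - Xty[, v]
    G
  }

  U <- if (is.null(U0)) matrix(0, p, V) else U0
  Z <- U
  tk <- 1
  f <- obj(U)
  trace <- f
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U_new <- l21_prox(Z - step * grad(Z), step * pen)
    f_new <- obj(U_new)
    if (f_new > f + 1e-15 * abs(f)) {
      # restart momentum from the last accepted iterate
      U_new <- l21_prox(U - step * grad(U), step * pen)
      f_new <- obj(U_new)
      tk <- 1
      if (f_new > f) { U_new <- U; f_new <- f }
    }
    if (!is.finite(f_new)) stop("objective became non-finite (step-size failure)")
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- U_new + ((tk - 1) / t_next) * (U_new - U)
    rel <- abs(f - f_new) / max(abs(f), 1e-12)
    U <- U_new
    tk <- t_next
    trace <- c(trace, f_new)
    done <- rel < tol && it > 1L
    f <- f_new
    if (done) { converged <- TRUE; break }
  }
  nrm <- sqrt(rowSums(U^2))
  supp <- which(nrm > 1e-8 * max(nrm, 0))
  structure(list(U = U, lam = lam, lambda_max = lmax,
                 objective_trace = trace, converged = converged,
                 row_support = supp),
            class = "multiview_weights")
}

#' @export
print.multiview_weights <- function(x, ...) {
  cat("<multiview_weights> ", nrow(x$U), " feature rows x ", ncol(x$U),
      " views; lam = ", x$lam, " (", length(x$row_support),
      " non-zero rows); ", if (x$converged) "converged" else "iteration cap",
      " after ", length(x$objective_trace) - 1L, " iterations\n", sep = "")
  invisible(x)
}
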