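# ---- time-level feature sparsification ----------------------------------
#
# After the L2,1 solve, each surviving feature row still carries one weight
# per view. The sparsification step orders, within every row, the views by
# absolute weight (matrix R over the restricted matrix Q), then grows the
# candidate set column by column: candidate set Ns keeps, for every row, its
# Ns strongest views (zero-weight entries never enter). Ns is chosen as the
# smallest value maximizing a caller-supplied accuracy (inner
# cross-validation in the pipeline), so accuracy is retained with the
# fewest features.

# candidate (row, view) pairs for a given Ns; rows/R/Q as in sparsify()
candidate_pairs <- function(rows, Q, R, ns) {
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    keep <- R[[i]][seq_len(min(ns, length(R[[i]])))]
    if (!length(keep)) return(NULL)
    data.frame(row = rows[i], view = keep)
  }))
  out <- out[order(out$row, out$view), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Feature sparsification over views
#'
#' Turns a row-sparse multi-view weight matrix into a final set of
#' (feature row, view) pairs. For each non-zero row the views are ranked by
#' absolute weight; candidate sets are nested, adding one view rank at a
#' time (`Ns = 1, 2, ...`); the returned `Ns` is the smallest value
#' attaining the maximum of `evaluate` over the grid. Zero-weight entries
#' are never selected, so rows with fewer than `Ns` non-zero weights
#' contribute only what the model actually kept.
#'
#' @param weights a [l21_solve()] result with at least one non-zero row.
#' @param evaluate function taking a data frame of candidate pairs (columns
#'   `row`, `view`) and returning a scalar accuracy.
#' @param ns_grid candidate values of `Ns` (default `1:ncol(U)`, i.e. one
#'   per view).
#' @return An object of class `sparse_selection`: list with `rows`
#'   (non-zero row indices), `Q` (their true weights, rows x views), `R`
#'   (per-row view order by descending absolute weight, zero entries
#'   excluded), `ns`, `pairs` (the selected pairs), `accuracy_curve`.
#' @export
sparsify <- function(weights, evaluate, ns_grid = NULL) {
  stopifnot(inherits(weights, "multiview_weights"))
  rows <- weights$row_support
  if (!length(rows))
    stop("all rows of U are zero; decrease lam")
  Q <- weights$U[rows, , drop = FALSE]
  nv <- ncol(Q)
  # per-row view order by |weight| descending, ties by view index,
  # zero entries excluded entirely
  R <- lapply(seq_len(nrow(Q)), function(i) {
    o <- order(-abs(Q[i, ]), seq_len(nv))
    o[abs(Q[i, o]) > 0]
  })
  if (is.null(ns_grid)) ns_grid <- seq_len(nv)
  acc <- vapply(ns_grid, function(ns)
    evaluate(candidate_pairs(rows, Q, R, ns)), numeric(1))
  ns <- ns_grid[which.max(acc)]   # smallest argmax: which.max takes first
  structure(list(rows = rows, Q = Q, R = R, ns = ns,
                 pairs = candidate_pairs(rows, Q, R, ns),
                 ns_grid = ns_grid, accuracy_curve = acc),
            class = "sparse_selection")
}

#' @export
print.sparse_selection <- function(x, ...) {
  cat("<sparse_selection> ", length(x$rows), " feature rows, Ns = ", x$ns,
      " -> ", nrow(x$pairs), " (row, view) pairs\n", sep = "")
  invisible(x)
}

#' Gather selected features into a classifier matrix
#'
#' Column `j` of the result is feature column `pairs$row[j]` of view
#' `pairs$view[j]`; columns are ordered by row then view, so the assembly is
#' deterministic.
#'
#' @param pairs data frame with columns `row` and `view`.
#' @param views list of view feature objects (field `X`).
#' @return A numeric matrix, trials x `nrow(pairs)`.
#' @export
assemble_features <- function(pairs, views) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("empty selection: no (row, view) pairs to assemble")
  if (any(pairs$view < 1L | pairs$view > length(views)))
    stop("pair references a view outside the view list")
  p <- ncol(views[[1]]$X)
  if (any(pairs$row < 1L | pairs$row > p))
    stop("pair references a feature row outside the views")
  ord <- order(pairs$row, pairs$view)
  pairs <- pairs[ord, , drop = FALSE]
  out <- vapply(seq_len(nrow(pairs)), function(j)
    views[[pairs$view[j]]]$X[, pairs$row[j]],
    numeric(nrow(views[[1]]$X)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- paste0("r", pairs$row, "v", pairs$view)
  out
}
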