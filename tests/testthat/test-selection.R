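# toy weight matrix used throughout: two surviving rows over three views
toy_weights <- function() {
  U <- rbind(c(0.9, 0.1, 0.5),
             c(0,   0.7, 0.2),
             c(0,   0,   0))
  structure(list(U = U, lam = 0.3, lambda_max = 1,
                 objective_trace = c(2, 1), converged = TRUE,
                 row_support = c(1L, 2L)),
            class = "multiview_weights")
}

test_that("candidate sets follow the column-by-column superposition", {
  w <- toy_weights()
  seen <- list()
  sel <- sparsify(w, function(pairs) {
    seen[[length(seen) + 1]] <<- pairs
    0.5
  })
  # Ns = 1: strongest view of each row
  expect_equal(seen[[1]], data.frame(row = c(1L, 2L), view = c(1L, 2L)))
  # Ns = 2 adds each row's second view (view 3 for both rows)
  expect_equal(seen[[2]], data.frame(row = c(1L, 1L, 2L, 2L),
                                     view = c(1L, 3L, 2L, 3L)))
  # Ns = 3: all non-zero entries only (row 2 has no third view)
  expect_equal(seen[[3]], data.frame(row = c(1L, 1L, 1L, 2L, 2L),
                                     view = c(1L, 2L, 3L, 2L, 3L)))
  # candidate sets are nested
  key <- function(p) paste(p$row, p$view)
  expect_true(all(key(seen[[1]]) %in% key(seen[[2]])))
  expect_true(all(key(seen[[2]]) %in% key(seen[[3]])))
})

test_that("the smallest Ns attaining the maximum accuracy is chosen", {
  w <- toy_weights()
  acc <- c(0.8, 0.9, 0.9)
  sel <- sparsify(w, local({ i <- 0; function(pairs) { i <<- i + 1; acc[i] } }))
  expect_equal(sel$ns, 2)
  expect_equal(sel$accuracy_curve, acc)
  # full superposition keeps every non-zero entry
  selF <- sparsify(w, function(p) nrow(p) / 10)  # maximal at Ns = 3
  expect_equal(nrow(selF$pairs), sum(w$U != 0))
})

test_that("accuracy depends only on the induced pair sets under row permutation", {
  w <- toy_weights()
  wp <- w
  wp$U <- w$U[c(2, 1, 3), ]
  wp$row_support <- c(1L, 2L)
  key <- function(p, map) paste(map[p$row], p$view)
  curves <- function(wts, map) {
    sets <- list()
    sparsify(wts, function(p) { sets[[length(sets) + 1]] <<- sort(key(p, map)); 0.1 })
    sets
  }
  expect_equal(curves(w, 1:3), curves(wp, c(2, 1, 3)))
})

test_that("all-zero weights are rejected with advice", {
  w <- toy_weights()
  w$U[] <- 0; w$row_support <- integer(0)
  expect_error(sparsify(w, function(p) 1), "decrease lam")
})

test_that("assemble gathers exactly the referenced columns", {
  set.seed(14)
  views <- lapply(1:3, function(v) list(X = matrix(rnorm(5 * 4), 5, 4)))
  pairs <- data.frame(row = c(2L, 2L, 4L), view = c(3L, 1L, 2L))
  X <- assemble_features(pairs, views)
  expect_equal(dim(X), c(5L, 3L))
  # deterministic order: by row then view
  expect_equal(X[, 1], views[[1]]$X[, 2])
  expect_equal(X[, 2], views[[3]]$X[, 2])
  expect_equal(X[, 3], views[[2]]$X[, 4])
  expect_error(assemble_features(pairs[0, ], views), "empty")
  expect_error(assemble_features(data.frame(row = 9L, view = 1L), views),
               "feature row")
  expect_error(assemble_features(data.frame(row = 1L, view = 7L), views),
               "view")
  one <- assemble_features(data.frame(row = 1L, view = 1L), views)
  expect_equal(one[, 1], views[[1]]$X[, 1])
})
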