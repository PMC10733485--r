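#' Segmented log-power features
#'
#' Cuts every trial and channel into overlapping segments of `seg_len`
#' samples and returns `log(var(segment))`, the scalar band-power proxy used
#' for channel scoring.
#'
#' @param trials an [epoched_trials()] object.
#' @param seg_len segment length in samples (default 100, i.e. 1 s at 100 Hz).
#' @param overlap_frac fractional overlap of neighbouring segments in
#'   `[0, 1)` (default 0.5).
#' @return A trials x channels x segments array of log-power values.
#' @export
logvar_segments <- function(trials, seg_len = 100L, overlap_frac = 0.5) {
  validate_trials(trials)
  ns <- n_samples(trials)
  if (seg_len > ns) stop("seg_len exceeds the samples per trial")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must lie in [0, 1)")
  step <- max(1L, as.integer(round(seg_len * (1 - overlap_frac))))
  starts <- seq.int(0L, ns - seg_len, by = step)
  out <- array(NA_real_, c(n_trials(trials), n_channels(trials), length(starts)))
  for (g in seq_along(starts)) {
    seg <- trials$data[, , (starts[g] + 1L):(starts[g] + seg_len), drop = FALSE]
    m <- rowMeans(seg, dims = 2)
    # sample variance from first two moments
    v <- (rowMeans(seg^2, dims = 2) - m^2) * seg_len / (seg_len - 1)
    if (any(v <= 0)) {
      bad <- which(v <= 0, arr.ind = TRUE)[1, ]
      stop("zero-variance segment: trial ", bad[1], ", channel ", bad[2],
           ", segment ", g)
    }
    out[, , g] <- log(v)
  }
  out
}

#' Fisher-discriminant channel ranking
#'
#' Scores every channel by the Fisher discriminant criterion of its segmented
#' log-power: per segment, `(m1 - m2)^2 / (var1 + var2)` across the two
#' classes, then the maximum over segments is taken as the channel score.
#' Channels are ranked by score in descending order (ties broken by ascending
#' channel index for determinism).
#'
#' @param logpower trials x channels x segments array from [logvar_segments()].
#' @param labels per-trial class codes in `{1, 2}`.
#' @param mode_sizes channel counts of the nested channel modes; sizes larger
#'   than the montage are dropped and the full montage is always included.
#' @return An object of class `channel_ranking`: list with `scores` (per
#'   channel), `order` (channel indices by descending score), `mode_sizes`.
#' @export
fdc_scores <- function(logpower, labels, mode_sizes = c(16L, 32L)) {
  stopifnot(length(dim(logpower)) == 3L, dim(logpower)[1] == length(labels))
  i1 <- which(labels == 1L); i2 <- which(labels == 2L)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each class needs >= 2 trials for within-class variances")
  M <- dim(logpower)[2]
  n1 <- length(i1); n2 <- length(i2)
  p1 <- logpower[i1, , , drop = FALSE]; p2 <- logpower[i2, , , drop = FALSE]
  m1 <- colMeans(p1); m2 <- colMeans(p2)                     # channels x segments
  v1 <- (colMeans(p1^2) - m1^2) * n1 / (n1 - 1)
  v2 <- (colMeans(p2^2) - m2^2) * n2 / (n2 - 1)
  phi <- (m1 - m2)^2 / (v1 + v2)
  scores <- apply(matrix(phi, M), 1, max)
  ord <- order(-scores, seq_len(M))  # stable: ties by ascending index
  sizes <- sort(unique(c(mode_sizes[mode_sizes < M], M)))
  structure(list(scores = scores, order = ord, mode_sizes = as.integer(sizes)),
            class = "channel_ranking")
}

#' @export
print.channel_ranking <- function(x, ...) {
  cat("<channel_ranking> ", length(x$scores), " channels; modes: ",
      paste(x$mode_sizes, collapse = "/"), "; top: ",
      paste(head(x$order, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Nested channel modes
#'
#' Mode `i` is the first `sizes[i]` channels of the ranking, so the modes are
#' nested subsets of the montage (e.g. top-16, top-32, all).
#'
#' @param ranking a [fdc_scores()] result.
#' @param sizes channel counts, strictly increasing; defaults to
#'   `ranking$mode_sizes`.
#' @return A list of integer channel-index vectors, one per mode.
#' @export
build_modes <- function(ranking, sizes = ranking$mode_sizes) {
  stopifnot(inherits(ranking, "channel_ranking"))
  M <- length(ranking$scores)
  if (any(sizes > M))
    stop("mode size ", max(sizes), " exceeds the ", M, "-channel montage")
  if (any(diff(as.numeric(sizes)) <= 0)) stop("sizes must be strictly increasing")
  lapply(as.integer(sizes), function(k) ranking$order[seq_len(k)])
}
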