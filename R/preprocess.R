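#' Common average reference
#'
#' Re-references every channel to the instantaneous mean across channels, so
#' that for each trial and sample the channel mean of the output is zero.
#' Removes common-mode (reference and far-field) activity.
#'
#' @param trials an [epoched_trials()] object with at least two channels.
#' @return An `epoched_trials` object of the same shape.
#' @export
apply_car <- function(trials) {
  validate_trials(trials)
  if (n_channels(trials) < 2L)
    stop("common average reference needs at least 2 channels")
  d <- dim(trials$data)
  # mean over the channel axis, broadcast back across channels
  m <- colMeans(aperm(trials$data, c(2, 1, 3)))       # trials x samples
  trials$data <- trials$data - aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))
  trials
}

# Zero-phase Butterworth band-pass of a trials x channels x samples array.
# The hot loop lives in compiled code; series are filtered independently, so
# results for a trial do not depend on which other trials are in the batch.
filtfilt_array <- function(arr, b, a) {
  d <- dim(arr)
  x <- matrix(aperm(arr, c(3, 1, 2)), nrow = d[3])  # samples x (trials*channels)
  y <- .filtfilt_cpp(as.numeric(b), as.numeric(a), x)
  aperm(array(y, c(d[3], d[1], d[2])), c(2, 3, 1))
}

butter_coefs <- function(low_hz, high_hz, fs, order) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < fs/2 (Nyquist = ", nyq, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  list(b = bf$b, a = bf$a)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every trial and channel with an order-`order` Butterworth band-pass
#' applied forward and backward (zero phase; the effective magnitude order is
#' doubled). Offline zero-phase filtering avoids group-delay distortion of the
#' time-window grid.
#'
#' @param trials an [epoched_trials()] object.
#' @param low_hz,high_hz band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order of each pass (default 5).
#' @return An `epoched_trials` object of the same shape.
#' @export
bandpass <- function(trials, low_hz, high_hz, order = 5L) {
  validate_trials(trials)
  co <- butter_coefs(low_hz, high_hz, trials$fs, order)
  trials$data <- filtfilt_array(trials$data, co$b, co$a)
  trials
}

#' Overlapping sub-band grid
#'
#' Bands of width `width_hz` starting at `fmin` and advancing by `step_hz`;
#' the default montage of the method is 4-40 Hz cut into 4 Hz bands with 50%
#' overlap, giving 17 sub-bands (4-8, 6-10, ..., 36-40 Hz).
#'
#' @param fmin,fmax overall frequency range in Hz.
#' @param width_hz width of each sub-band in Hz.
#' @param step_hz distance between successive band onsets in Hz.
#' @return An object of class `band_grid`: a list with a `bands` matrix
#'   (columns `low`, `high`) ordered by lower edge.
#' @examples
#' make_band_grid(4, 40, 4, 2)  # the 17-band default
#' @export
make_band_grid <- function(fmin, fmax, width_hz, step_hz) {
  if (!(fmin < fmax)) stop("need fmin < fmax")
  if (!(step_hz > 0 && step_hz <= width_hz))
    stop("need 0 < step_hz <= width_hz")
  if (width_hz > fmax - fmin)
    stop("band width exceeds the [fmin, fmax] range")
  k <- floor((fmax - width_hz - fmin) / step_hz) + 1L
  lows <- fmin + step_hz * (seq_len(k) - 1L)
  bands <- cbind(low = lows, high = lows + width_hz)
  structure(list(bands = bands), class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  cat("<band_grid> ", nrow(x$bands), " bands: ",
      paste(sprintf("%g-%g", x$bands[, 1], x$bands[, 2])[
        unique(c(1, nrow(x$bands)))], collapse = " ... "), " Hz\n", sep = "")
  invisible(x)
}

#' Overlapping time-window grid
#'
#' Windows of length `win_s` starting at 0 and advancing by `step_s`, kept
#' while they fit inside the epoch. The method's default is 2 s windows with
#' 0.5 s step: a 4 s epoch gives 5 windows, a 3.5 s epoch gives 4.
#'
#' @param duration_s epoch length in seconds.
#' @param win_s window length in seconds.
#' @param step_s distance between successive window onsets in seconds.
#' @return An object of class `time_grid`: a list with a `windows` matrix
#'   (columns `start`, `end`) in seconds relative to cue onset.
#' @examples
#' make_time_grid(4.0, 2.0, 0.5)
#' @export
make_time_grid <- function(duration_s, win_s, step_s) {
  if (win_s > duration_s) stop("window length exceeds epoch duration")
  if (!(step_s > 0)) stop("need step_s > 0")
  k <- floor((duration_s - win_s) / step_s + 1e-9) + 1L
  starts <- step_s * (seq_len(k) - 1L)
  structure(list(windows = cbind(start = starts, end = starts + win_s)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("<time_grid> ", nrow(x$windows), " windows: ",
      paste(sprintf("%g-%g", x$windows[, 1], x$windows[, 2])[
        unique(c(1, nrow(x$windows)))], collapse = " ... "), " s\n", sep = "")
  invisible(x)
}

# Half-open sample index range [first, last] (1-based, inclusive) for a
# window in seconds; [round(start*fs), round(end*fs)) in 0-based terms.
window_samples <- function(window, fs, n_samp) {
  s0 <- round(window[1] * fs)
  s1 <- round(window[2] * fs)
  if (s0 < 0 || s1 > n_samp || s1 <= s0)
    stop("window [", window[1], ", ", window[2], "] s falls outside the epoch")
  c(s0 + 1L, s1)
}

#' Extract a time window from epoched trials
#'
#' Keeps the half-open sample interval `[round(start*fs), round(end*fs))`
#' (0-based), so that windows laid `step` apart tile without duplicating
#' samples. `epoch_start` is shifted accordingly.
#'
#' @param trials an [epoched_trials()] object.
#' @param window numeric length-2 vector `(start_s, end_s)` relative to the
#'   first sample of the epoch.
#' @return An `epoched_trials` object containing only the windowed samples.
#' @export
slice_window <- function(trials, window) {
  validate_trials(trials)
  rng <- window_samples(window, trials$fs, n_samples(trials))
  trials$data <- trials$data[, , rng[1]:rng[2], drop = FALSE]
  trials$epoch_start <- trials$epoch_start + window[1]
  trials
}
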