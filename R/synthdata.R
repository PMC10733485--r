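# fixed 10-20 montage used for synthetic data, so that anchor-channel
# baselines (e.g. "C3") resolve without configuration
SYNTH_CHANNELS <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3",
                    "Cz", "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1",
                    "O2", "Oz")

#' Synthetic ERD dataset specification
#'
#' Describes a two-class motor-imagery-like dataset: every channel carries
#' independent 1/f background noise plus a shared common-mode trace; the
#' active channels additionally carry a band-limited oscillation (band-pass
#' filtered white noise in `erd_band`) whose amplitude inside `erd_window`
#' is multiplied by `attenuation` for class 2 only - an event-related
#' desynchronization of the mu rhythm. Classes are balanced.
#'
#' @param n_per_class trials per class (default 100).
#' @param n_channels montage size, at most 20 (default 20); channel names are
#'   taken from a fixed 10-20 list that includes C3/Cz/C4.
#' @param fs sampling rate in Hz (default 100).
#' @param duration_s epoch length in seconds (default 4).
#' @param active_channels indices carrying the oscillation (default C3 and
#'   C4, i.e. channels 9 and 11).
#' @param erd_band oscillation band in Hz (default 10-14, upper mu range).
#' @param erd_window attenuation window in seconds (default 0.5-2.5).
#' @param attenuation multiplicative amplitude factor applied to class-2
#'   oscillation inside the window, in (0, 1]; 1 means no class difference
#'   (default 0.5).
#' @param background_amp standard deviation of the per-channel 1/f
#'   background (default 1).
#' @param background_exponent spectral exponent of the background power
#'   spectrum `1/f^a` (default 1).
#' @param common_mode_amp standard deviation of the shared common-mode trace
#'   (default 0.5).
#' @param osc_amp standard deviation of the unattenuated oscillation at the
#'   active channels (default 3, a prominent mu rhythm dominating the
#'   in-band background so planted power ratios are directly measurable).
#' @param seed integer seed making the dataset fully deterministic.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 100L, n_channels = 20L, fs = 100,
                           duration_s = 4.0, active_channels = c(9L, 11L),
                           erd_band = c(10, 14), erd_window = c(0.5, 2.5),
                           attenuation = 0.5, background_amp = 1,
                           background_exponent = 1, common_mode_amp = 0.5,
                           osc_amp = 3, seed = 1L) {
  if (n_channels > length(SYNTH_CHANNELS))
    stop("at most ", length(SYNTH_CHANNELS), " synthetic channels are supported")
  if (any(active_channels < 1L | active_channels > n_channels))
    stop("active_channels outside the montage")
  if (!(attenuation > 0 && attenuation <= 1))
    stop("attenuation must lie in (0, 1]")
  if (erd_window[1] < 0 || erd_window[2] > duration_s || diff(erd_window) <= 0)
    stop("erd_window must lie inside the epoch")
  structure(as.list(environment()), class = "synthetic_spec")
}

# one 1/f-shaped noise trace of length n (std 1) via spectral shaping
pink_trace <- function(n, fs, exponent) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- f^(-exponent / 2)
  re <- rnorm(nf); im <- rnorm(nf)
  spec <- complex(real = amp * re, imaginary = amp * im)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * re[nf], imaginary = 0)
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# raised-cosine ERD envelope: 1 outside the window, `att` inside, with
# ramps of `ramp_s` seconds just inside the window edges
erd_envelope <- function(n, fs, window, att, ramp_s = 0.1) {
  t <- (seq_len(n) - 1) / fs
  env <- rep(1, n)
  lo <- window[1]; hi <- window[2]
  inside <- t >= lo & t < hi
  env[inside] <- att
  rise <- t >= lo & t < lo + ramp_s
  env[rise] <- 1 + (att - 1) * (1 - cos(pi * (t[rise] - lo) / ramp_s)) / 2
  fall <- t >= hi - ramp_s & t < hi
  env[fall] <- att + (1 - att) * (1 - cos(pi * (t[fall] - (hi - ramp_s)) / ramp_s)) / 2
  env
}

#' Generate a synthetic two-class ERD dataset
#'
#' Draws trials according to a [synthetic_spec()] and returns both the data
#' and a ground-truth manifest recording what was planted where, including
#' which default-grid sub-bands and time windows overlap the planted effect.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `trials` (an [epoched_trials()]) and `manifest` (list
#'   of class `truth_manifest`).
#' @export
generate_trials <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- 2L * spec$n_per_class
  ns <- as.integer(round(spec$duration_s * spec$fs))
  M <- spec$n_channels
  labels <- rep(c(1L, 2L), each = spec$n_per_class)
  co <- butter_coefs(spec$erd_band[1], spec$erd_band[2], spec$fs, 4L)
  data <- array(0, c(n, M, ns))
  with_seed(spec$seed, {
    for (i in seq_len(n)) {
      bg <- vapply(seq_len(M), function(ch)
        pink_trace(ns, spec$fs, spec$background_exponent), numeric(ns))
      cm <- pink_trace(ns, spec$fs, spec$background_exponent)
      X <- t(bg) * spec$background_amp +
        matrix(cm * spec$common_mode_amp, M, ns, byrow = TRUE)
      env <- erd_envelope(ns, spec$fs,
                          spec$erd_window,
                          if (labels[i] == 2L) spec$attenuation else 1)
      for (ch in spec$active_channels) {
        osc <- .filtfilt_cpp(co$b, co$a, matrix(rnorm(ns), ns, 1))[, 1]
        osc <- osc / stats::sd(osc) * spec$osc_amp
        X[ch, ] <- X[ch, ] + osc * env
      }
      data[i, , ] <- X
    }
  })
  trials <- epoched_trials(data, labels, spec$fs,
                           SYNTH_CHANNELS[seq_len(M)], epoch_start = 0)
  bg_grid <- make_band_grid(4, 40, 4, 2)
  tg <- make_time_grid(spec$duration_s, 2, 0.5)
  manifest <- structure(list(
    spec = spec,
    active_channels = spec$active_channels,
    erd_band = spec$erd_band, erd_window = spec$erd_window,
    bands_overlapping = which(bg_grid$bands[, "high"] > spec$erd_band[1] &
                                bg_grid$bands[, "low"] < spec$erd_band[2]),
    windows_overlapping = which(tg$windows[, "end"] > spec$erd_window[1] &
                                  tg$windows[, "start"] < spec$erd_window[2])),
    class = "truth_manifest")
  list(trials = trials, manifest = manifest)
}

#' Tiny fixed verification fixture
#'
#' A deterministic 20-trial, 6-channel, 2 s dataset with a strong planted
#' oscillation (10-14 Hz, channel 3, attenuated for class 2 over 0.25-1.75 s),
#' small enough for unit tests where the best channel/band/window is known by
#' construction.
#'
#' @return As [generate_trials()]: list with `trials` and `manifest`.
#' @export
checkerboard_case <- function() {
  generate_trials(synthetic_spec(
    n_per_class = 10L, n_channels = 6L, duration_s = 2.0,
    active_channels = 3L, erd_band = c(10, 14), erd_window = c(0.25, 1.75),
    attenuation = 0.3, osc_amp = 3, common_mode_amp = 0.3, seed = 42L))
}
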