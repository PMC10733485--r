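#' Epoched EEG trial container
#'
#' Bundles cue-aligned single-trial EEG with its metadata. The data axis order
#' is fixed throughout the package as trials x channels x samples; every entry
#' point asserts it, so a container built here can be passed anywhere without
#' silent transposition.
#'
#' @param data numeric 3-d array, trials x channels x samples (microvolts).
#' @param labels per-trial class codes; a dataset used for fitting must
#'   contain exactly the two codes 1 and 2.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of channel labels (10-20 system),
#'   one per channel.
#' @param epoch_start epoch onset in seconds relative to the cue (0 means the
#'   first sample coincides with the cue).
#' @return An object of class `epoched_trials`: a list with the fields above.
#' @examples
#' x <- array(rnorm(4 * 3 * 50), c(4, 3, 50))
#' tr <- epoched_trials(x, c(1, 1, 2, 2), fs = 100, channel_names = c("C3", "Cz", "C4"))
#' n_trials(tr)
#' @export
epoched_trials <- function(data, labels, fs, channel_names = NULL,
                           epoch_start = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2]))
  labels <- as.integer(labels)
  x <- structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         epoch_start = as.numeric(epoch_start)),
    class = "epoched_trials")
  validate_trials(x)
  x
}

#' @rdname epoched_trials
#' @param x an `epoched_trials` object.
#' @export
validate_trials <- function(x) {
  stopifnot(inherits(x, "epoched_trials"))
  d <- dim(x$data)
  if (d[1] != length(x$labels))
    stop("label length (", length(x$labels), ") does not match trial count (", d[1], ")")
  if (d[2] != length(x$channel_names))
    stop("channel_names length (", length(x$channel_names),
         ") does not match channel count (", d[2], ")")
  if (!all(is.finite(x$data)))
    stop("`data` contains NaN or Inf")
  if (!is.finite(x$fs) || x$fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz")
  bad <- setdiff(unique(x$labels), c(1L, 2L))
  if (length(bad))
    stop("labels must be coded 1/2; found: ", paste(bad, collapse = ", "))
  invisible(x)
}

# Assert the two-class condition needed before any fitting runs.
check_two_classes <- function(x, min_per_class = 1L) {
  tab <- table(factor(x$labels, levels = c(1L, 2L)))
  if (any(tab == 0))
    stop("fitting requires both classes; class ", names(tab)[tab == 0][1], " is absent")
  if (any(tab < min_per_class))
    stop("each class needs at least ", min_per_class, " trials")
  invisible(x)
}

#' @rdname epoched_trials
#' @export
n_trials <- function(x) dim(x$data)[1]

#' @rdname epoched_trials
#' @export
n_channels <- function(x) dim(x$data)[2]

#' @rdname epoched_trials
#' @export
n_samples <- function(x) dim(x$data)[3]

#' Subset trials by index
#'
#' @param x an `epoched_trials` object.
#' @param idx trial indices to keep (in the given order).
#' @return An `epoched_trials` object with the selected trials.
#' @export
subset_trials <- function(x, idx) {
  validate_trials(x)
  epoched_trials(x$data[idx, , , drop = FALSE], x$labels[idx], x$fs,
                 x$channel_names, x$epoch_start)
}

#' @export
print.epoched_trials <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoched_trials> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  epoch start: ", x$epoch_start, " s; labels: ",
      paste(sprintf("%d (n=%d)", as.integer(names(table(x$labels))),
                    as.integer(table(x$labels))), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write epoched trials as HDF5
#'
#' The container layout is one HDF5 file with datasets `/data` (trials x
#' channels x samples), `/labels`, and root attributes `fs`, `channel_names`,
#' `epoch_start`. Validation runs on read before anything numeric happens.
#'
#' @param path file path of the HDF5 container.
#' @return `read_trials` returns a validated [epoched_trials()] object;
#'   `write_trials` invisibly returns `path`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)
  for (ds in c("data", "labels")) {
    if (!ds %in% contents$name)
      stop("container is missing required dataset `", ds, "`: ", path)
  }
  at <- rhdf5::h5readAttributes(path, "/")
  for (a in c("fs", "channel_names", "epoch_start")) {
    if (is.null(at[[a]]))
      stop("container is missing required attribute `", a, "`: ", path)
  }
  data <- rhdf5::h5read(path, "data")
  labels <- as.integer(rhdf5::h5read(path, "labels"))
  epoched_trials(data, labels, fs = as.numeric(at$fs),
                 channel_names = as.character(at$channel_names),
                 epoch_start = as.numeric(at$epoch_start))
}

#' @rdname read_trials
#' @param trials an `epoched_trials` object.
#' @param overwrite replace an existing file? Defaults to `FALSE`.
#' @export
write_trials <- function(trials, path, overwrite = FALSE) {
  validate_trials(trials)
  if (file.exists(path)) {
    if (!overwrite) stop("file exists (set overwrite = TRUE): ", path)
    unlink(path)
  }
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("could not create HDF5 file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  suppressMessages({
    rhdf5::h5write(trials$data, path, "data")
    rhdf5::h5write(as.integer(trials$labels), path, "labels")
  })
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(trials$fs, fid, "fs")
  rhdf5::h5writeAttribute(trials$channel_names, fid, "channel_names")
  rhdf5::h5writeAttribute(trials$epoch_start, fid, "epoch_start")
  rhdf5::H5Fclose(fid)
  invisible(path)
}
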