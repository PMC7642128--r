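#' Labelled collection of fixed-length EEG trials
#'
#' An `epoch_set` holds a 3-d numeric array of trials in microvolts, the class
#' label of every trial, and the timing metadata needed to interpret samples
#' relative to the imagery cue. All sample indices in the package are 0-based
#' and all time windows half-open, `[a, b)`.
#'
#' @param data numeric array `[trial, channel, sample]`, in uV.
#' @param labels factor or character vector, one of `"left"`/`"right"` per
#'   trial.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of 10-20-style channel labels, length
#'   equal to `dim(data)[2]`.
#' @param cue_index 0-based sample index of the cue (t = 0) within each trial.
#' @param provenance optional list describing how the data were produced
#'   (e.g. generator config hash and seed).
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, channel_names, cue_index,
                      provenance = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trial, channel, sample]", call. = FALSE)
  labels <- as_mi_labels(labels)
  if (length(labels) != dim(data)[1L])
    stop("length(labels) must equal the number of trials", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  if (length(channel_names) != dim(data)[2L])
    stop("`channel_names` must match the number of channels", call. = FALSE)
  if (anyDuplicated(channel_names))
    stop("`channel_names` must be unique", call. = FALSE)
  cue_index <- as.integer(cue_index)
  if (cue_index < 0L || cue_index >= dim(data)[3L])
    stop("`cue_index` must satisfy 0 <= cue_index < n_samples", call. = FALSE)
  structure(
    list(data = data, labels = labels, fs = fs,
         channel_names = as.character(channel_names),
         cue_index = cue_index, provenance = provenance),
    class = "epoch_set")
}

as_mi_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("left", "right"))
  if (length(bad))
    stop("labels must be 'left' or 'right'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  factor(labels, levels = c("left", "right"))
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  cat(sprintf("  cue at sample %d (t = 0 s); trial spans [%.3f, %.3f) s\n",
              x$cue_index, -x$cue_index / x$fs,
              (d[3L] - x$cue_index) / x$fs))
  invisible(x)
}

#' @rdname epoch_set
#' @param es an `epoch_set`.
#' @export
n_trials <- function(es) dim(es$data)[1L]

#' @rdname epoch_set
#' @export
n_channels <- function(es) dim(es$data)[2L]

#' @rdname epoch_set
#' @export
n_samples <- function(es) dim(es$data)[3L]

#' Subset an epoch_set by trial
#'
#' @param es an `epoch_set`.
#' @param trials integer vector of 1-based trial indices.
#' @return An `epoch_set` with the selected trials.
#' @export
subset_epochs <- function(es, trials) {
  stopifnot(inherits(es, "epoch_set"))
  trials <- as.integer(trials)
  if (any(trials < 1L | trials > n_trials(es)))
    stop("trial indices out of range", call. = FALSE)
  epoch_set(es$data[trials, , , drop = FALSE], es$labels[trials], es$fs,
            es$channel_names, es$cue_index, es$provenance)
}

#' Sample indices for a time window relative to the cue
#'
#' Converts a half-open window `[a, b)` in seconds (t = 0 at the cue) to
#' 1-based sample indices into a trial. Second-to-sample conversion uses
#' round-half-even, applied once per endpoint.
#'
#' @param es an `epoch_set`.
#' @param window numeric length-2, `c(a, b)` with `a < b`, seconds.
#' @return Integer vector of 1-based sample indices.
#' @keywords internal
window_indices <- function(es, window) {
  stopifnot(length(window) == 2L, window[1L] < window[2L])
  i0 <- es$cue_index + round(window[1L] * es$fs)  # 0-based, inclusive
  i1 <- es$cue_index + round(window[2L] * es$fs)  # 0-based, exclusive
  if (i0 < 0L || i1 > n_samples(es))
    stop(sprintf("window [%g, %g) s falls outside the trial", window[1L],
                 window[2L]), call. = FALSE)
  if (i1 <= i0) stop("window contains no samples", call. = FALSE)
  seq.int(i0 + 1L, i1)
}

# Polynomial rolling hash (mod 2^31 - 1) of a serialized R object; a stable
# configuration fingerprint, not a cryptographic digest.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

# Quantize doubles to the nearest float32-representable value. The epochs
# container stores 32-bit floats; applying this once makes write/read
# round-trips bit-identical.
quantize_float32 <- function(x) {
  dm <- dim(x)
  y <- readBin(writeBin(as.vector(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  dim(y) <- dm
  y
}
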