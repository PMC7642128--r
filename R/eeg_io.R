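#' Continuous multichannel recording
#'
#' @param data numeric matrix `[channel, sample]` in uV.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param start_time recording start in seconds (default 0).
#' @return A `continuous_recording` object.
#' @export
continuous_recording <- function(data, fs, channel_names, start_time = 0) {
  if (!is.matrix(data)) stop("`data` must be a [channel, sample] matrix",
                             call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (nrow(data) != length(channel_names))
    stop("channel count does not match channel_names", call. = FALSE)
  structure(list(data = data, fs = fs,
                 channel_names = as.character(channel_names),
                 start_time = start_time),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: ", x, call. = FALSE)
  formatC(x, width = -width)
}

#' Write a continuous recording
#'
#' `format = "edf"` writes a minimal EDF file (16-bit samples, per-channel
#' physical scaling, 1-second data records when the length allows, otherwise
#' a single record). `format = "csv"` writes one column per channel plus a
#' JSON sidecar `<path>.json` holding `fs` and the channel names.
#'
#' @param rec a [continuous_recording()].
#' @param path output file path.
#' @param format `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_continuous <- function(rec, path, format = c("edf", "csv")) {
  stopifnot(inherits(rec, "continuous_recording"))
  format <- match.arg(format)
  if (format == "csv") {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channel_names
    utils::write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(list(fs = rec$fs,
                              channel_names = rec$channel_names,
                              start_time = rec$start_time),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(path))
  }
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  if (rec$fs == round(rec$fs) && n %% rec$fs == 0L) {
    spr <- as.integer(rec$fs)
    n_rec <- n %/% spr
    dur <- 1
  } else {
    spr <- n
    n_rec <- 1L
    dur <- n / rec$fs
  }
  pmaxs <- pmax(apply(abs(rec$data), 1L, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8L), pad_field("X", 80L), pad_field("X", 80L),
    pad_field("01.01.00", 8L), pad_field("00.00.00", 8L),
    pad_field(256L * (1L + ns), 8L), pad_field("", 44L),
    pad_field(n_rec, 8L), pad_field(format(dur, digits = 7), 8L),
    pad_field(ns, 4L),
    paste(vapply(rec$channel_names, pad_field, "", width = 16L),
          collapse = ""),
    paste(rep(pad_field("", 80L), ns), collapse = ""),
    paste(rep(pad_field("uV", 8L), ns), collapse = ""),
    paste(vapply(-pmaxs, function(p) pad_field(format(p, digits = 6), 8L), ""),
          collapse = ""),
    paste(vapply(pmaxs, function(p) pad_field(format(p, digits = 6), 8L), ""),
          collapse = ""),
    paste(rep(pad_field(-32767L, 8L), ns), collapse = ""),
    paste(rep(pad_field(32767L, 8L), ns), collapse = ""),
    paste(rep(pad_field("", 80L), ns), collapse = ""),
    paste(rep(pad_field(spr, 8L), ns), collapse = ""),
    paste(rep(pad_field("", 32L), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  dig <- round(sweep(rec$data, 1L, pmaxs, "/") * 32767)
  dig[dig > 32767] <- 32767; dig[dig < -32767] <- -32767
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns))
      writeBin(as.integer(dig[s, cols]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(con, width) trimws(readChar(con, width))

#' Read a continuous recording
#'
#' @param path file path.
#' @param format `"edf"` or `"csv"` (CSV expects the `<path>.json` sidecar
#'   written by [write_continuous()]; values are assumed to be in uV).
#' @return A [continuous_recording()].
#' @export
read_continuous <- function(path, format = c("edf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("missing sidecar metadata: ", side, call. = FALSE)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    return(continuous_recording(t(as.matrix(df)), meta$fs,
                                names(df),
                                if (is.null(meta$start_time)) 0 else
                                  meta$start_time))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8L)                                  # version
  readChar(con, 160L)                                # patient + recording id
  readChar(con, 16L)                                 # date + time
  hdr_bytes <- suppressWarnings(as.integer(read_edf_field(con, 8L)))
  readChar(con, 44L)
  n_rec <- suppressWarnings(as.integer(read_edf_field(con, 8L)))
  dur <- suppressWarnings(as.numeric(read_edf_field(con, 8L)))
  ns <- suppressWarnings(as.integer(read_edf_field(con, 4L)))
  if (anyNA(c(hdr_bytes, n_rec, dur, ns)) || ns < 1L)
    stop("malformed EDF header in ", path, call. = FALSE)
  if (hdr_bytes != 256L * (1L + ns))
    stop(sprintf(
      "malformed EDF header in %s: header size %d inconsistent with %d signals",
      path, hdr_bytes, ns), call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) read_edf_field(con, 16L), "")
  readChar(con, 80L * ns)                            # transducer
  readChar(con, 8L * ns)                             # physical dimension
  pmin <- vapply(seq_len(ns), function(i)
    as.numeric(read_edf_field(con, 8L)), 0)
  pmax <- vapply(seq_len(ns), function(i)
    as.numeric(read_edf_field(con, 8L)), 0)
  dmin <- vapply(seq_len(ns), function(i)
    as.numeric(read_edf_field(con, 8L)), 0)
  dmax <- vapply(seq_len(ns), function(i)
    as.numeric(read_edf_field(con, 8L)), 0)
  readChar(con, 80L * ns)                            # prefiltering
  spr <- vapply(seq_len(ns), function(i)
    as.integer(read_edf_field(con, 8L)), 0L)
  readChar(con, 32L * ns)
  expected <- hdr_bytes + 2 * n_rec * sum(spr)
  if (file.size(path) != expected)
    stop(sprintf(
      "malformed EDF in %s: %d records x %d signals imply %d bytes, file has %d",
      path, n_rec, ns, expected, file.size(path)), call. = FALSE)
  if (length(unique(spr)) != 1L)
    stop("EDF with per-signal sampling rates is not supported", call. = FALSE)
  data <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1L], size = 2L,
                     endian = "little", signed = TRUE)
      data[s, cols] <- (dig - dmin[s]) * (pmax[s] - pmin[s]) /
        (dmax[s] - dmin[s]) + pmin[s]
    }
  }
  continuous_recording(data, spr[1L] / dur, labels)
}

#' Event table for epoch extraction
#'
#' @param onset_sample integer vector of 0-based cue onset samples, strictly
#'   increasing.
#' @param label character vector, `"left"`/`"right"`, same length.
#' @return An `event_table` data.frame.
#' @export
event_table <- function(onset_sample, label) {
  onset_sample <- as.integer(onset_sample)
  if (length(onset_sample) != length(label))
    stop("onset_sample and label lengths differ", call. = FALSE)
  if (any(onset_sample < 0L)) stop("onsets must be >= 0", call. = FALSE)
  if (is.unsorted(onset_sample, strictly = TRUE))
    stop("onsets must be strictly increasing", call. = FALSE)
  label <- as_mi_labels(label)
  structure(data.frame(onset_sample = onset_sample, label = label),
            class = c("event_table", "data.frame"))
}

#' @rdname event_table
#' @param path CSV path with columns `onset_sample,label`.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("onset_sample", "label") %in% names(df)))
    stop("events CSV must have columns onset_sample,label", call. = FALSE)
  event_table(df$onset_sample, df$label)
}

#' @rdname event_table
#' @param events an `event_table`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Extract fixed-length epochs around events
#'
#' Cuts the half-open sample window
#' `[onset + round(a * fs), onset + round(b * fs))` around every event
#' (round-half-even, applied once per endpoint). Events whose window falls
#' outside the recording are dropped with a message; extraction fails if no
#' valid epochs remain.
#'
#' @param rec a [continuous_recording()].
#' @param events an [event_table()] with onsets inside the recording.
#' @param window `c(a, b)` seconds relative to each event, `a < 0 <= b`.
#' @return An [epoch_set()].
#' @export
epoch_extract <- function(rec, events, window) {
  stopifnot(inherits(rec, "continuous_recording"),
            inherits(events, "event_table"))
  if (!(window[1L] < window[2L]))
    stop("window must satisfy a < b", call. = FALSE)
  if (!(window[1L] < 0 && window[2L] >= 0))
    stop("window must satisfy a < 0 <= b (it must contain the cue)",
         call. = FALSE)
  fs <- rec$fs
  off0 <- round(window[1L] * fs)
  off1 <- round(window[2L] * fs)
  n_samp <- off1 - off0
  if (n_samp < 1L) stop("window contains no samples", call. = FALSE)
  n_total <- ncol(rec$data)
  i0 <- events$onset_sample + off0          # 0-based inclusive
  i1 <- events$onset_sample + off1          # 0-based exclusive
  ok <- i0 >= 0L & i1 <= n_total
  if (!any(ok)) stop("no valid epochs: all event windows fall outside the recording",
                     call. = FALSE)
  if (any(!ok))
    message(sum(!ok), " event(s) dropped: window outside the recording")
  keep <- which(ok)
  data <- array(0, dim = c(length(keep), nrow(rec$data), n_samp))
  for (k in seq_along(keep))
    data[k, , ] <- rec$data[, (i0[keep[k]] + 1L):i1[keep[k]]]
  epoch_set(data, events$label[keep], fs, rec$channel_names,
            cue_index = as.integer(-off0),
            provenance = list(source = "epoch_extract",
                              n_dropped = sum(!ok)))
}

#' Epochs container on disk
#'
#' `write_epochs()` stores an [epoch_set()] as `data.bin` — one little-endian
#' 32-bit float blob in trial-major order (trial slowest, channel, then
#' sample fastest) — plus a JSON sidecar `epochs.json` with dimensions,
#' labels, sampling rate, channel names, cue index, provenance and a content
#' checksum. `read_epochs()` verifies the checksum and sidecar consistency.
#' Data already at float32 resolution (everything produced by
#' [generate_session()] or [preprocess_epochs()]) round-trips bit-identically;
#' other data is quantized to float32 once, on first write.
#'
#' @param es an [epoch_set()].
#' @param dir container directory (created if needed).
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()` returns
#'   the stored [epoch_set()].
#' @export
write_epochs <- function(es, dir) {
  stopifnot(inherits(es, "epoch_set"))
  if (n_trials(es) == 0L) stop("refusing to write an empty epoch_set",
                               call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(es$data)
  # trial-major: reverse of R's column-major array order
  v <- as.vector(aperm(es$data, c(3L, 2L, 1L)))
  con <- file(file.path(dir, "data.bin"), "wb")
  writeBin(v, con, size = 4L, endian = "little")
  close(con)
  v32 <- quantize_float32(v)
  meta <- list(n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
               fs = es$fs, labels = as.character(es$labels),
               channel_names = es$channel_names, cue_index = es$cue_index,
               provenance = es$provenance,
               checksum = list(sum = sum(v32), sumsq = sum(v32^2)))
  jsonlite::write_json(meta, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta_path <- file.path(dir, "epochs.json")
  bin_path <- file.path(dir, "data.bin")
  if (!file.exists(meta_path) || !file.exists(bin_path))
    stop("not an epochs container: ", dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n_val <- meta$n_trials * meta$n_channels * meta$n_samples
  if (length(meta$labels) != meta$n_trials)
    stop("corrupt container: sidecar has ", length(meta$labels),
         " labels for ", meta$n_trials, " trials", call. = FALSE)
  con <- file(bin_path, "rb")
  v <- readBin(con, "double", n = n_val + 1L, size = 4L, endian = "little")
  close(con)
  if (length(v) != n_val)
    stop("corrupt container: expected ", n_val, " float32 values, found ",
         length(v), call. = FALSE)
  ok <- is.finite(sum(v)) &&
    abs(sum(v) - meta$checksum$sum) <= 1e-6 * max(1, abs(meta$checksum$sum)) &&
    abs(sum(v^2) - meta$checksum$sumsq) <= 1e-6 * max(1, meta$checksum$sumsq)
  if (!isTRUE(ok))
    stop("corrupt container: checksum mismatch in ", bin_path, call. = FALSE)
  data <- aperm(array(v, dim = c(meta$n_samples, meta$n_channels,
                                 meta$n_trials)), c(3L, 2L, 1L))
  prov <- meta$provenance
  epoch_set(data, meta$labels, meta$fs, meta$channel_names, meta$cue_index,
            provenance = if (length(prov)) prov else NULL)
}
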