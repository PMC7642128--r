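#' Band energy of a windowed segment
#'
#' Energy of one channel of one trial within a frequency band and a time
#' window relative to the cue: the periodogram band power of the windowed
#' segment multiplied by the window duration (so units are uV^2 * s). The
#' window must span at least four cycles of the band's lower edge for the
#' periodogram estimate to resolve the band.
#'
#' @param es an [epoch_set()].
#' @param trial 1-based trial index.
#' @param channel channel name (e.g. `"C4"`).
#' @param band numeric `c(f_lo, f_hi)` in Hz.
#' @param window numeric `c(a, b)` in seconds relative to the cue, half-open.
#' @return Band energy in uV^2 * s.
#' @export
band_energy <- function(es, trial, channel, band, window) {
  stopifnot(inherits(es, "epoch_set"), length(band) == 2L)
  ch <- match(channel, es$channel_names)
  if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
  if (band[1L] < 0 || band[2L] > es$fs / 2 || band[1L] >= band[2L])
    stop("band must satisfy 0 <= f_lo < f_hi <= fs/2", call. = FALSE)
  dur <- window[2L] - window[1L]
  if (band[1L] > 0 && dur < 4 / band[1L])
    stop(sprintf(
      "window of %.3g s is shorter than 4 cycles of f_lo = %g Hz (%.3g s)",
      dur, band[1L], 4 / band[1L]), call. = FALSE)
  idx <- window_indices(es, window)
  seg <- es$data[trial, ch, idx]
  band_power(periodogram(seg, es$fs), band[1L], band[2L]) * dur
}

#' ERD/ERS percentage from event and reference band energies
#'
#' `100 * (E - R) / R`, where `E` is the band energy in the event (post-cue)
#' window and `R` the band energy in the reference (pre-cue) window. Negative
#' values indicate event-related desynchronization (ERD, power drop during
#' imagery), positive values event-related synchronization (ERS).
#'
#' @param E event-window band energy (>= 0).
#' @param R reference-window band energy (> 0).
#' @return ERD/ERS in percent.
#' @examples
#' erd_ers_percent(50, 100)  # -50: the band lost half its power
#' @export
erd_ers_percent <- function(E, R) {
  if (any(R <= 0)) stop("reference energy R must be positive", call. = FALSE)
  if (any(E < 0)) stop("event energy E must be non-negative", call. = FALSE)
  100 * (E - R) / R
}

#' Trial-averaged ERD/ERS map over channels and bands
#'
#' For every requested channel and band, averages the event-window band
#' energy `E` and the reference-window band energy `R` across all trials of
#' one class, then reports `100 * (E_bar - R_bar) / R_bar`. Averaging
#' energies before the ratio is the standard ERD estimator (lower variance
#' than averaging per-trial ratios). Because the reference and event windows
#' may have different durations, `E` and `R` are normalized per second of
#' window (band power, uV^2), which leaves the ratio invariant to the window
#' lengths.
#'
#' @param es an [epoch_set()].
#' @param label class to analyse, `"left"` or `"right"`.
#' @param channels channel names (default `c("C3", "C4")`).
#' @param windows list with `ref` and `event`, each `c(a, b)` seconds
#'   relative to the cue. Defaults: reference `[-1.5, -0.5)`, event
#'   `[0.5, 2.5)` — both clear of the 250 ms modulation ramp at the cue.
#' @param bands named list of `c(f_lo, f_hi)` in Hz; defaults to the dyadic
#'   mu `[6.25, 12.5)` and beta `[12.5, 25)` bands.
#' @param min_trials minimum trials of `label` required (default 10).
#' @return An `erd_ers_result`: data.frame with columns `channel`, `band`,
#'   `E`, `R`, `erd_ers_percent`, plus the windows used as attributes.
#' @export
erd_ers_map <- function(es, label, channels = c("C3", "C4"),
                        windows = list(ref = c(-1.5, -0.5),
                                       event = c(0.5, 2.5)),
                        bands = list(mu = c(6.25, 12.5),
                                     beta = c(12.5, 25)),
                        min_trials = 10L) {
  stopifnot(inherits(es, "epoch_set"))
  label <- match.arg(label, c("left", "right"))
  trials <- which(es$labels == label)
  if (length(trials) == 0L) stop("no trials with label ", label,
                                 call. = FALSE)
  if (length(trials) < min_trials)
    stop(sprintf("need at least %d '%s' trials, have %d", min_trials, label,
                 length(trials)), call. = FALSE)
  dur_event <- diff(windows$event)
  dur_ref <- diff(windows$ref)
  rows <- list()
  for (ch in channels) {
    for (b in names(bands)) {
      E <- mean(vapply(trials, band_energy, numeric(1), es = es,
                       channel = ch, band = bands[[b]],
                       window = windows$event)) / dur_event
      R <- mean(vapply(trials, band_energy, numeric(1), es = es,
                       channel = ch, band = bands[[b]],
                       window = windows$ref)) / dur_ref
      rows[[length(rows) + 1L]] <-
        data.frame(channel = ch, band = b, E = E, R = R,
                   erd_ers_percent = erd_ers_percent(E, R))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "windows") <- windows
  attr(out, "label") <- label
  class(out) <- c("erd_ers_result", "data.frame")
  out
}
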