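#' Periodogram power spectral density
#'
#' One-sided periodogram estimate `P[k] = |DFT(x)[k]|^2 / (N * fs)`, with
#' interior bins doubled so that the rectangle-rule integral over `[0, fs/2]`
#' equals the mean square of the signal (Parseval). The frequency grid is
#' `k * fs / N` for `k = 0..floor(N/2)`; at 100 Hz the grid tops out at the
#' 50 Hz Nyquist bin.
#'
#' @param signal finite numeric vector, length >= 2, in uV.
#' @param fs sampling rate in Hz.
#' @return A `psd_result`: `freqs` (Hz), `psd` (uV^2/Hz), `n_samples`, `fs`.
#' @examples
#' p <- periodogram(sin(2 * pi * 10 * (0:999) / 100), fs = 100)
#' band_power(p, 9, 11)  # ~0.5, the mean square of a unit sine
#' @export
periodogram <- function(signal, fs) {
  if (!is.numeric(signal) || length(signal) < 2L)
    stop("`signal` must be numeric with at least 2 samples", call. = FALSE)
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("`signal` must be finite", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  N <- length(signal)
  X <- stats::fft(signal)
  n_keep <- N %/% 2L + 1L
  p <- Mod(X[seq_len(n_keep)])^2 / (N * fs)
  # double interior bins (not DC; not Nyquist when N is even)
  interior <- seq_len(n_keep)[-1L]
  if (N %% 2L == 0L) interior <- interior[-length(interior)]
  p[interior] <- 2 * p[interior]
  structure(list(freqs = (seq_len(n_keep) - 1L) * fs / N, psd = p,
                 n_samples = N, fs = fs),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> N = %d @ %g Hz, %d bins, df = %g Hz\n",
              x$n_samples, x$fs, length(x$freqs), x$fs / x$n_samples))
  invisible(x)
}

#' Band power from a periodogram
#'
#' Rectangle-rule integral of the PSD over the half-open band
#' `[f_lo, f_hi)`. As a convenience for totals, when `f_hi` reaches the
#' Nyquist frequency the Nyquist bin is included, so
#' `band_power(p, 0, fs/2)` recovers the signal's mean square exactly.
#'
#' @param psd a `psd_result` from [periodogram()].
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @return Band power in uV^2.
#' @export
band_power <- function(psd, f_lo, f_hi) {
  stopifnot(inherits(psd, "psd_result"))
  if (f_lo < 0 || f_hi > psd$fs / 2)
    stop("band must lie within [0, fs/2]", call. = FALSE)
  if (f_lo >= f_hi)
    stop("`f_lo` must be strictly less than `f_hi`", call. = FALSE)
  df <- psd$fs / psd$n_samples
  sel <- psd$freqs >= f_lo & psd$freqs < f_hi
  if (f_hi >= psd$fs / 2) sel <- sel | psd$freqs == psd$fs / 2
  sum(psd$psd[sel]) * df
}
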