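#' @useDynLib mierd, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Daubechies-6 (12-tap) orthonormal filter pair, standard table values.
# Analysis low-pass; the other three follow by quadrature-mirror relations.
.db6_dec_lo <- c(
  -1.0773010853084796e-03,  4.7772575109455108e-03,  5.5384220116149613e-04,
  -3.1582039317486030e-02,  2.7522865530305727e-02,  9.7501605587323043e-02,
  -1.2976686756726194e-01, -2.2626469396543983e-01,  3.1525035170919763e-01,
   7.5113390802109536e-01,  4.9462389039845306e-01,  1.1154074335010947e-01)
.db6_dec_hi <- rev(.db6_dec_lo) * c(1, -1)  # g[j] = (-1)^j h[F-1-j], 0-based
.db6_rec_lo <- rev(.db6_dec_lo)
.db6_rec_hi <- rev(.db6_dec_hi)
.db6_len <- 12L

# Orthonormality self-test, run when the package is loaded: unit norm,
# sqrt(2) DC gain, vanishing even-shift autocorrelation, low/high
# orthogonality. Guards against transcription errors in the hardcoded taps.
db6_self_test <- function(tol = 1e-12) {
  h <- .db6_dec_lo
  g <- .db6_dec_hi
  stopifnot(abs(sum(h^2) - 1) < tol, abs(sum(h) - sqrt(2)) < tol)
  for (s in seq(2L, 10L, by = 2L)) {
    stopifnot(abs(sum(h[seq_len(12L - s)] * h[(s + 1L):12L])) < tol)
    stopifnot(abs(sum(h[seq_len(12L - s)] * g[(s + 1L):12L])) < tol)
  }
  stopifnot(abs(sum(h * g)) < tol)
  invisible(TRUE)
}

.onLoad <- function(libname, pkgname) {
  db6_self_test()
}

#' Wavelet decomposition settings
#'
#' The package implements a single family, the 12-tap orthonormal Daubechies-6
#' wavelet, applied as a Mallat pyramid: each level splits the current
#' approximation into a half-band detail and approximation by
#' convolve-and-downsample.
#'
#' @param n_levels number of decomposition levels (default 3).
#' @param boundary `"symmetric"` (half-point signal extension; default) or
#'   `"periodic"` (circular convolution; requires even length at every level,
#'   conserves coefficient energy exactly).
#' @return A `wavelet_spec` object.
#' @export
wavelet_spec <- function(n_levels = 3L, boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("n_levels must be >= 1", call. = FALSE)
  structure(list(family = "db6", n_levels = n_levels, boundary = boundary),
            class = "wavelet_spec")
}

# Full linear convolution of each column of X (n x m) with filter f,
# implemented as shift-and-add so it vectorizes across columns.
conv_cols <- function(X, f) {
  n <- nrow(X)
  F <- length(f)
  out <- matrix(0, n + F - 1L, ncol(X))
  for (j in seq_len(F))
    out[j:(j + n - 1L), ] <- out[j:(j + n - 1L), ] + f[j] * X
  out
}

# One analysis step on columns. Returns list(a, d) coefficient matrices.
dwt_step <- function(X, boundary) {
  L <- nrow(X)
  F <- .db6_len
  if (L < F)
    stop(sprintf(
      "signal too short for db6 analysis: length %d < filter length %d", L, F),
      call. = FALSE)
  if (boundary == "symmetric") {
    ext <- c(seq(F - 1L, 1L), seq_len(L), seq(L, L - F + 2L))
    n_out <- (L + F - 1L) %/% 2L
  } else {
    if (L %% 2L)
      stop("periodic boundary requires an even signal length at every level",
           call. = FALSE)
    ext <- c((L - F + 2L):L, seq_len(L))  # prepend the last F-1 samples
    n_out <- L %/% 2L
  }
  Xe <- X[ext, , drop = FALSE]
  rows <- seq(F + 1L, by = 2L, length.out = n_out)
  list(a = conv_cols(Xe, .db6_dec_lo)[rows, , drop = FALSE],
       d = conv_cols(Xe, .db6_dec_hi)[rows, , drop = FALSE])
}

# One synthesis step: invert dwt_step, cropping to the child length.
idwt_step <- function(A, D, child_len, boundary) {
  n <- nrow(A)
  F <- .db6_len
  stopifnot(nrow(D) == n)
  up <- function(C) {
    U <- matrix(0, 2L * n, ncol(C))
    U[seq(1L, 2L * n, by = 2L), ] <- C
    U
  }
  S <- conv_cols(up(A), .db6_rec_lo) + conv_cols(up(D), .db6_rec_hi)
  if (boundary == "symmetric") {
    # valid segment starts at offset F-2 (0-based); crop to child length
    S[(F - 1L):(F - 2L + child_len), , drop = FALSE]
  } else {
    L <- 2L * n
    out <- S[(F - 1L):(F - 2L + L), , drop = FALSE]
    out[(L - F + 3L):L, ] <- out[(L - F + 3L):L, ] +
      S[seq_len(F - 2L), , drop = FALSE]
    out[1L, ] <- out[1L, ] + S[L + F - 1L, ]
    out[seq_len(child_len), , drop = FALSE]
  }
}

# Matrix-core multilevel analysis: columns of X are independent signals.
dwt_mat <- function(X, n_levels, boundary) {
  details <- vector("list", n_levels)
  lengths <- integer(n_levels)
  A <- X
  for (l in seq_len(n_levels)) {
    lengths[l] <- nrow(A)
    st <- dwt_step(A, boundary)
    details[[l]] <- st$d
    A <- st$a
  }
  list(details = details, approx = A, lengths = lengths)
}

reconstruct_mat <- function(dec, keep, boundary) {
  n <- length(dec$details)
  an_name <- paste0("A", n)
  A <- if (an_name %in% keep) dec$approx else
    matrix(0, nrow(dec$approx), ncol(dec$approx))
  for (l in seq(n, 1L)) {
    D <- if (paste0("D", l) %in% keep) dec$details[[l]] else
      matrix(0, nrow(dec$details[[l]]), ncol(dec$details[[l]]))
    A <- idwt_step(A, D, dec$lengths[l], boundary)
  }
  A
}

#' Multilevel db6 discrete wavelet transform
#'
#' Decomposes a signal with the Mallat pyramid: at every level the current
#' approximation is split into a detail (high-pass) and approximation
#' (low-pass) half, each obtained by filtering and downsampling by two. At
#' sampling rate `fs` the bands tile `[0, fs/2)` dyadically: detail `Dl`
#' covers `[fs/2^(l+1), fs/2^l)` and the final approximation `An` covers
#' `[0, fs/2^(n+1))`.
#'
#' @param signal numeric vector (one channel, uV).
#' @param spec a [wavelet_spec()].
#' @param fs sampling rate in Hz (used only for the band map).
#' @return A `band_decomposition`: `details` (list `D1..Dn`), `approx`,
#'   `band_map` (named list of `c(f_lo, f_hi)`), `fs`, `original_length`,
#'   `boundary`.
#' @examples
#' d <- dwt(sin(2 * pi * 20 * (0:511) / 100), wavelet_spec(), fs = 100)
#' d$band_map$D2  # c(12.5, 25)
#' @export
dwt <- function(signal, spec = wavelet_spec(), fs) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (!is.numeric(signal) || anyNA(signal) || any(!is.finite(signal)))
    stop("`signal` must be a finite numeric vector", call. = FALSE)
  if (missing(fs) || fs <= 0) stop("`fs` must be a positive Hz value",
                                   call. = FALSE)
  dec <- dwt_mat(matrix(signal, ncol = 1L), spec$n_levels, spec$boundary)
  n <- spec$n_levels
  structure(
    list(details = lapply(dec$details, drop),
         approx = drop(dec$approx),
         band_map = band_map(fs, n),
         fs = fs, original_length = length(signal),
         lengths = dec$lengths, boundary = spec$boundary),
    class = "band_decomposition")
}

#' Dyadic frequency band map for an n-level decomposition
#'
#' @param fs sampling rate in Hz.
#' @param n_levels number of levels.
#' @return Named list: for each `Dl` and `An`, `c(f_lo, f_hi)` in Hz.
#' @export
band_map <- function(fs, n_levels = 3L) {
  bm <- lapply(seq_len(n_levels), function(l) c(fs / 2^(l + 1L), fs / 2^l))
  names(bm) <- paste0("D", seq_len(n_levels))
  bm[[paste0("A", n_levels)]] <- c(0, fs / 2^(n_levels + 1L))
  bm
}

#' Inverse transform keeping selected bands
#'
#' Zeroes every band not named in `keep` and runs the inverse Mallat pyramid.
#' With `keep` equal to all bands this is a perfect reconstruction of the
#' input. The denoising scheme used throughout the package keeps `D2` and
#' `D3` (6.25-25 Hz at 100 Hz sampling), discarding the `D1` high-frequency
#' band and the `A3` low-frequency drift/artifact band.
#'
#' @param decomp a `band_decomposition` from [dwt()].
#' @param keep character vector of band names, subset of
#'   `c("D1", ..., "Dn", "An")`.
#' @return Numeric vector of length `decomp$original_length`.
#' @export
reconstruct <- function(decomp, keep) {
  stopifnot(inherits(decomp, "band_decomposition"))
  valid <- names(decomp$band_map)
  if (length(keep) == 0L)
    stop("`keep` must name at least one band", call. = FALSE)
  bad <- setdiff(keep, valid)
  if (length(bad))
    stop("unknown band(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "), call. = FALSE)
  dec <- list(details = lapply(decomp$details, matrix, ncol = 1L),
              approx = matrix(decomp$approx, ncol = 1L),
              lengths = decomp$lengths)
  drop(reconstruct_mat(dec, keep, decomp$boundary))
}

#' Wavelet band-pass preprocessing of an epoch_set
#'
#' Applies the db6 three-level decomposition and reconstructs only the kept
#' bands (default `D2` + `D3`, i.e. 6.25-25 Hz) for every trial and channel.
#' The dyadic band semantics assume 100 Hz sampling; recordings at other
#' rates must be resampled first (see [resample_epochs()]).
#'
#' @param es an [epoch_set()] sampled at 100 Hz.
#' @param spec a [wavelet_spec()].
#' @param keep band names to retain (default `c("D2", "D3")`).
#' @return An `epoch_set` of identical shape with band-limited data.
#' @export
preprocess_epochs <- function(es, spec = wavelet_spec(),
                              keep = c("D2", "D3")) {
  stopifnot(inherits(es, "epoch_set"))
  if (es$fs != 100)
    stop("preprocess_epochs expects fs = 100 Hz (dyadic bands 6.25-25 Hz); ",
         "resample first with resample_epochs(es, 100)", call. = FALSE)
  d <- dim(es$data)
  # columns = trial within channel; samples along rows
  X <- matrix(aperm(es$data, c(3L, 1L, 2L)), nrow = d[3L])
  dec <- dwt_mat(X, spec$n_levels, spec$boundary)
  Y <- reconstruct_mat(dec, keep, spec$boundary)
  out <- aperm(array(Y, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
  epoch_set(quantize_float32(out), es$labels, es$fs, es$channel_names,
            es$cue_index,
            c(es$provenance,
              list(preprocess = list(family = spec$family,
                                     n_levels = spec$n_levels,
                                     boundary = spec$boundary, keep = keep))))
}

#' Polyphase resampling of an epoch_set
#'
#' Anti-aliased rational-rate resampling (via `signal::resample`) of every
#' trial and channel, used to bring 250 Hz recordings to the 100 Hz rate the
#' dyadic band map assumes.
#'
#' @param es an [epoch_set()].
#' @param fs_new target sampling rate in Hz.
#' @return A resampled `epoch_set`.
#' @export
resample_epochs <- function(es, fs_new) {
  stopifnot(inherits(es, "epoch_set"))
  if (fs_new == es$fs) return(es)
  g <- gcd_int(round(fs_new), round(es$fs))
  p <- round(fs_new) / g
  q <- round(es$fs) / g
  d <- dim(es$data)
  n_new <- ceiling(d[3L] * p / q)
  out <- array(0, dim = c(d[1L], d[2L], n_new))
  for (i in seq_len(d[1L]))
    for (j in seq_len(d[2L]))
      out[i, j, ] <- signal::resample(es$data[i, j, ], p, q)[seq_len(n_new)]
  epoch_set(quantize_float32(out), es$labels, fs_new, es$channel_names,
            as.integer(round(es$cue_index * p / q)), es$provenance)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
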