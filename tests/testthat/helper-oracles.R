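# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain double loops and textbook definitions only.

# db6 analysis filters, written out again here so the oracle does not share
# the package's constants object.
oracle_db6_lo <- c(
  -1.0773010853084796e-03,  4.7772575109455108e-03,  5.5384220116149613e-04,
  -3.1582039317486030e-02,  2.7522865530305727e-02,  9.7501605587323043e-02,
  -1.2976686756726194e-01, -2.2626469396543983e-01,  3.1525035170919763e-01,
   7.5113390802109536e-01,  4.9462389039845306e-01,  1.1154074335010947e-01)
# high-pass by the quadrature-mirror rule g[j] = (-1)^j h[F-1-j] (0-based)
oracle_db6_hi <- rev(oracle_db6_lo) * (-1)^(seq_len(12) - 1)

# One analysis level by direct convolution + decimation (half-point symmetric
# extension), O(L * F) loops.
oracle_dwt_level <- function(x, boundary = "symmetric") {
  Fl <- 12L
  L <- length(x)
  if (boundary == "symmetric") {
    xe <- c(rev(x[seq_len(Fl - 1L)]), x, rev(x[(L - Fl + 2L):L]))
    n_out <- (L + Fl - 1L) %/% 2L
  } else {
    xe <- c(x[(L - Fl + 2L):L], x)
    n_out <- L %/% 2L
  }
  a <- numeric(n_out)
  d <- numeric(n_out)
  for (k in seq_len(n_out)) {
    # 1-based full-convolution index Fl + 2(k-1) + 1
    t <- Fl + 2L * (k - 1L) + 1L
    sa <- 0
    sd <- 0
    for (j in seq_len(Fl)) {
      idx <- t - j + 1L
      if (idx >= 1L && idx <= length(xe)) {
        sa <- sa + oracle_db6_lo[j] * xe[idx]
        sd <- sd + oracle_db6_hi[j] * xe[idx]
      }
    }
    a[k] <- sa
    d[k] <- sd
  }
  list(a = a, d = d)
}

# Textbook O(N^2) one-sided periodogram.
oracle_periodogram <- function(x, fs) {
  N <- length(x)
  ks <- 0:(N %/% 2)
  p <- vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(N - 1)) / N))
    im <- sum(x * sin(-2 * pi * k * (0:(N - 1)) / N))
    (re^2 + im^2) / (N * fs)
  }, 0)
  scale <- rep(2, length(ks))
  scale[1L] <- 1
  if (N %% 2L == 0L) scale[length(scale)] <- 1
  p * scale
}

# Squared magnitude response of the db6 low-pass at angular frequency w,
# normalized so a sine at w keeps this fraction of its energy through the
# level-1 approximation branch.
oracle_lowpass_gain <- function(w) {
  j <- 0:11
  Mod(sum(oracle_db6_lo * exp(-1i * w * j)))^2 / 2
}

# Shared fixtures, built once per test run.
.fx <- new.env()

fixture_session <- function(key, ...) {
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_session(generator_config(...))
  .fx[[key]]
}

# Separable session used by the classifier tests: strong effect, compact
# montage, short epochs to keep training quick.
fixture_separable <- function() {
  fixture_session("sep",
                  n_trials_per_class = 70L,
                  channel_names = c("FC3", "FC4", "C3", "C4", "Cz", "CP3",
                                    "CP4", "Pz"),
                  epoch_window = c(-1, 2.5),
                  erd_depth = 0.6, snr_db = 5, seed = 401L)
}

# band-limited version, computed once
fixture_separable_prep <- function() {
  if (is.null(.fx$sep_prep))
    .fx$sep_prep <- preprocess_epochs(fixture_separable())
  .fx$sep_prep
}

# balanced holdout: the first n trials of each class
holdout_idx <- function(es, n = 15L) {
  c(which(es$labels == "left")[seq_len(n)],
    which(es$labels == "right")[seq_len(n)])
}

fast_cnn <- function(...) {
  args <- utils::modifyList(list(arch = "cnn", max_epochs = 25L,
                                 early_stop_patience = 5L,
                                 batch_size = 16L),
                            list(...))
  do.call(classifier_config, args)
}
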