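#' Configuration for the synthetic motor-imagery session generator
#'
#' Parameterizes a labelled left/right motor-imagery EEG session with the
#' statistical structure the downstream analysis assumes: mu (~10 Hz) and
#' beta (~20 Hz) rhythms sourced at C3 and C4, contralateral event-related
#' desynchronization and ipsilateral synchronization after the cue, 1/f
#' background noise, and optional blink and mains-line artifacts.
#'
#' `erd_depth` is defined directly on band POWER: during imagery the
#' contralateral mu+beta rhythm power is multiplied by `(1 - erd_depth)`
#' (amplitude by its square root), so the expected ERD/ERS percentage of the
#' noiseless rhythm component is exactly `-100 * erd_depth`. Likewise the
#' ipsilateral power is multiplied by `(1 + ers_gain)`. The modulation
#' switches on with a 250 ms raised-cosine ramp at the cue.
#'
#' Presets mirror two acquisition protocols: `comp118` (118-channel cap,
#' 100 Hz, 140 trials per class) and `lab32` (32 leads, 250 Hz).
#'
#' @param preset `"custom"` (default), `"comp118"`, or `"lab32"`.
#' @param n_trials_per_class trials per class (comp118 fixes 140).
#' @param fs sampling rate, Hz (comp118 fixes 100, lab32 fixes 250).
#' @param channel_names 10-20-style labels; must include `"C3"` and `"C4"`.
#'   Presets supply their own montages; the custom default is a 16-channel
#'   sensorimotor montage.
#' @param epoch_window `c(t_start, t_end)` seconds relative to the cue at
#'   t = 0; must span the cue (`t_start < 0 < t_end`).
#' @param mu_freq,beta_freq rhythm frequencies in Hz (defaults 10 and 20).
#' @param mu_amp,beta_amp rhythm peak amplitudes at C3/C4 in uV (defaults
#'   10 and 5).
#' @param erd_depth contralateral band-power reduction fraction in `[0, 1]`.
#' @param ers_gain ipsilateral band-power increase fraction, `>= 0`.
#' @param noise_exponent spectral slope of the 1/f^a background (default 1).
#' @param snr_db ratio (dB) of pre-cue rhythm power to background power at
#'   C3/C4; `Inf` disables noise.
#' @param blink_rate blink events per minute on frontal channels (default 0).
#' @param line_freq mains frequency in Hz, or `NULL` for none; must be below
#'   fs/2.
#' @param seed integer RNG seed used by [generate_session()].
#' @return A `generator_config` object.
#' @export
generator_config <- function(preset = c("custom", "comp118", "lab32"),
                             n_trials_per_class = 140L,
                             fs = 100,
                             channel_names = NULL,
                             epoch_window = c(-2, 3.5),
                             mu_freq = 10, beta_freq = 20,
                             mu_amp = 10, beta_amp = 5,
                             erd_depth = 0.4, ers_gain = 0.15,
                             noise_exponent = 1, snr_db = 6,
                             blink_rate = 0, line_freq = NULL,
                             seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "comp118") {
    fs <- 100
    n_trials_per_class <- 140L
    channel_names <- montage_names("comp118")
  } else if (preset == "lab32") {
    fs <- 250
    channel_names <- montage_names("lab32")
  } else if (is.null(channel_names)) {
    channel_names <- montage_names("motor16")
  }
  if (!all(c("C3", "C4") %in% channel_names))
    stop("channel_names must include C3 and C4", call. = FALSE)
  if (erd_depth < 0 || erd_depth > 1)
    stop("erd_depth must lie in [0, 1]", call. = FALSE)
  if (ers_gain < 0) stop("ers_gain must be >= 0", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (!(epoch_window[1L] < 0 && 0 < epoch_window[2L]))
    stop("epoch_window must span the cue: t_start < 0 < t_end",
         call. = FALSE)
  if (blink_rate < 0) stop("blink_rate must be >= 0", call. = FALSE)
  if (!is.null(line_freq) && line_freq >= fs / 2)
    stop(sprintf("line_freq = %g Hz is at or above Nyquist (%g Hz): it would alias",
                 line_freq, fs / 2), call. = FALSE)
  structure(list(
    preset = preset, n_trials_per_class = as.integer(n_trials_per_class),
    fs = fs, n_channels = length(channel_names),
    channel_names = as.character(channel_names),
    epoch_window = epoch_window,
    mu_freq = mu_freq, beta_freq = beta_freq,
    mu_amp = mu_amp, beta_amp = beta_amp,
    erd_depth = erd_depth, ers_gain = ers_gain,
    noise_exponent = noise_exponent, snr_db = snr_db,
    blink_rate = blink_rate, line_freq = line_freq,
    seed = as.integer(seed)), class = "generator_config")
}

#' Built-in montages
#'
#' @param which `"motor16"`, `"lab32"`, or `"comp118"`.
#' @return Character vector of channel names.
#' @keywords internal
montage_names <- function(which) {
  motor16 <- c("F3", "Fz", "F4", "FC3", "FCz", "FC4", "C5", "C3", "C1",
               "Cz", "C2", "C4", "C6", "CP3", "CPz", "CP4")
  lab32 <- c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3", "CP1",
             "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz", "O2", "PO4", "P4",
             "P8", "CP6", "CP2", "C4", "T8", "FC6", "FC2", "F4", "F8",
             "AF4", "Fp2", "Fz", "Cz")
  if (which == "motor16") return(motor16)
  if (which == "lab32") return(lab32)
  # dense 10-10 set (61) plus interleaved filler electrodes to 118
  rows <- list(Fp = c("1", "z", "2"),
               AF = c("7", "3", "z", "4", "8"),
               F  = c("7", "5", "3", "1", "z", "2", "4", "6", "8"),
               FC = c("7", "5", "3", "1", "z", "2", "4", "6", "8"),
               C  = c("7", "5", "3", "1", "z", "2", "4", "6", "8"),
               CP = c("7", "5", "3", "1", "z", "2", "4", "6", "8"),
               P  = c("7", "5", "3", "1", "z", "2", "4", "6", "8"),
               PO = c("7", "3", "z", "4", "8"),
               O  = c("1", "z", "2"))
  std <- unlist(lapply(names(rows), function(r) paste0(r, rows[[r]])),
                use.names = FALSE)
  std[std == "C7"] <- "T7"; std[std == "C8"] <- "T8"
  std[std == "CP7"] <- "TP7"; std[std == "CP8"] <- "TP8"
  std[std == "FC7"] <- "FT7"; std[std == "FC8"] <- "FT8"
  c(std, sprintf("X%02d", seq_len(118L - length(std))))
}

# Approximate 2-d scalp positions (head radius 1, x = right, y = front) for
# 10-20-style labels; filler X## electrodes sit on an interleaved spiral.
montage_positions <- function(channel_names) {
  row_y <- c(Fp = 0.8, AF = 0.6, F = 0.4, FT = 0.2, FC = 0.2, T = 0,
             C = 0, TP = -0.2, CP = -0.2, P = -0.4, PO = -0.6, O = -0.8,
             I = -1.0)
  pos <- matrix(NA_real_, length(channel_names), 2L,
                dimnames = list(channel_names, c("x", "y")))
  fillers <- grep("^X[0-9]+$", channel_names)
  m <- regmatches(channel_names,
                  regexec("^([A-Za-z]+)(z|[0-9]+)$", channel_names))
  for (i in seq_along(channel_names)) {
    if (i %in% fillers) next
    parts <- m[[i]]
    if (length(parts) != 3L || !(parts[2L] %in% names(row_y))) next
    y <- row_y[[parts[2L]]]
    if (parts[3L] == "z") {
      x <- 0
    } else {
      num <- as.integer(parts[3L])
      mag <- 0.2 * ceiling(num / 2)
      if (parts[2L] %in% c("T", "FT", "TP")) mag <- max(mag, 0.8)
      x <- if (num %% 2L == 1L) -mag else mag
    }
    pos[i, ] <- c(x, y)
  }
  # unresolved or filler channels: deterministic spiral placement
  todo <- which(is.na(pos[, 1L]))
  if (length(todo)) {
    k <- seq_along(todo)
    r <- 0.15 + 0.75 * (k - 0.5) / length(todo)
    th <- 2.39996 * k  # golden angle
    pos[todo, ] <- cbind(r * cos(th), r * sin(th))
  }
  pos
}

# Raised-cosine step from 0 to 1 over ramp_s seconds starting at t = 0.
ramp_profile <- function(t, ramp_s = 0.25) {
  p <- numeric(length(t))
  p[t >= ramp_s] <- 1
  on <- t >= 0 & t < ramp_s
  p[on] <- (1 - cos(pi * t[on] / ramp_s)) / 2
  p
}

# 1/f^a noise, one column per channel, unit variance per column.
pink_noise <- function(n, n_ch, exponent, fs, f_floor = 0.5) {
  W <- stats::mvfft(matrix(stats::rnorm(n * n_ch), n, n_ch))
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)            # two-sided frequency magnitude
  w <- pmax(f, f_floor)^(-exponent / 2)
  w[1L] <- 0                      # remove DC
  X <- Re(stats::mvfft(W * w, inverse = TRUE)) / n
  X <- sweep(X, 2L, apply(X, 2L, stats::sd), "/")
  X
}

#' Generate one synthetic motor-imagery trial
#'
#' Single-trial kernel of [generate_session()]: rhythm components
#' (amplitude-modulated sinusoids with random phase) at C3 and C4, spatially
#' spread unmodulated copies on the remaining channels, 1/f background noise
#' mixed by inter-electrode distance and scaled to `snr_db`, plus optional
#' artifacts. Draws from R's global RNG; seed it (`set.seed`) for
#' reproducibility.
#'
#' @param label `"left"` or `"right"`.
#' @param config a [generator_config()].
#' @return Numeric matrix `[channel, sample]` in uV.
#' @export
make_trial <- function(label, config) {
  label <- match.arg(label, c("left", "right"))
  fs <- config$fs
  tt <- seq(config$epoch_window[1L], config$epoch_window[2L] - 1 / fs,
            by = 1 / fs)
  n <- length(tt)
  chn <- config$channel_names
  n_ch <- length(chn)
  pos <- montage_positions(chn)
  i_c3 <- match("C3", chn)
  i_c4 <- match("C4", chn)

  # contralateral control: left-hand imagery modulates C4, right-hand C3
  contra <- if (label == "left") i_c4 else i_c3
  ipsi <- if (label == "left") i_c3 else i_c4
  rmp <- ramp_profile(tt)
  m_contra <- 1 + (sqrt(1 - config$erd_depth) - 1) * rmp
  m_ipsi <- 1 + (sqrt(1 + config$ers_gain) - 1) * rmp

  rhythm <- function(mod) {
    ph <- stats::runif(2L, 0, 2 * pi)
    mod * (config$mu_amp * sin(2 * pi * config$mu_freq * tt + ph[1L]) +
           config$beta_amp * sin(2 * pi * config$beta_freq * tt + ph[2L]))
  }
  # order of RNG draws is fixed: C3 source first, then C4, then noise
  r3 <- rhythm(if (contra == i_c3) m_contra else m_ipsi)
  r4 <- rhythm(if (contra == i_c4) m_contra else m_ipsi)
  ph_u <- stats::runif(2L, 0, 2 * pi)
  r_u <- config$mu_amp * sin(2 * pi * config$mu_freq * tt + ph_u[1L]) +
    config$beta_amp * sin(2 * pi * config$beta_freq * tt + ph_u[2L])

  d3 <- sqrt(rowSums(sweep(pos, 2L, pos[i_c3, ], "-")^2))
  d4 <- sqrt(rowSums(sweep(pos, 2L, pos[i_c4, ], "-")^2))
  w3 <- exp(-d3^2 / (2 * 0.25^2))
  w4 <- exp(-d4^2 / (2 * 0.25^2))
  trial <- outer(w3 + w4, r_u)      # unmodulated rhythm field
  trial[i_c3, ] <- r3
  trial[i_c4, ] <- r4

  if (is.finite(config$snr_db)) {
    p_rhythm <- (config$mu_amp^2 + config$beta_amp^2) / 2
    sigma <- sqrt(p_rhythm / 10^(config$snr_db / 10))
    noise <- t(pink_noise(n, n_ch, config$noise_exponent, fs))
    dmat <- as.matrix(stats::dist(pos))
    M <- exp(-dmat^2 / (2 * 0.35^2))
    M <- M / sqrt(rowSums(M^2))     # unit-variance mixed noise
    trial <- trial + sigma * (M %*% noise)
  }
  trial <- inject_artifacts(trial, config)
  dimnames(trial) <- list(chn, NULL)
  trial
}

#' Add blink and mains-line artifacts to a trial
#'
#' Blinks are ~300 ms, ~100 uV raised-cosine transients (spectral content
#' below 4 Hz) applied to frontal channels with amplitude falling off toward
#' central sites; mains interference is a fixed-amplitude sinusoid at
#' `line_freq` on all channels. Returns a modified copy; with `blink_rate = 0`
#' and no `line_freq` the input is returned unchanged.
#'
#' @param trial numeric matrix `[channel, sample]`.
#' @param config a [generator_config()].
#' @return Modified `[channel, sample]` matrix.
#' @export
inject_artifacts <- function(trial, config) {
  if (config$blink_rate < 0) stop("blink_rate must be >= 0", call. = FALSE)
  if (!is.null(config$line_freq) && config$line_freq >= config$fs / 2)
    stop(sprintf("line_freq = %g Hz is at or above Nyquist (%g Hz): it would alias",
                 config$line_freq, config$fs / 2), call. = FALSE)
  fs <- config$fs
  n <- ncol(trial)
  dur <- n / fs
  if (config$blink_rate > 0) {
    pos <- montage_positions(config$channel_names)
    w <- pmax(0, (pos[, "y"] - 0.4) / 0.4)  # Fp ~ 1, AF ~ 0.5, F = 0
    n_blinks <- stats::rpois(1L, config$blink_rate * dur / 60)
    if (n_blinks > 0 && any(w > 0)) {
      width <- round(0.3 * fs)
      shape <- 100 * (1 - cos(2 * pi * seq_len(width) / (width + 1L))) / 2
      starts <- sample.int(max(1L, n - width), n_blinks, replace = TRUE)
      for (s in starts) {
        idx <- s:(s + width - 1L)
        trial[, idx] <- trial[, idx] + outer(w, shape)
      }
    }
  }
  if (!is.null(config$line_freq)) {
    ph <- stats::runif(1L, 0, 2 * pi)
    line <- 5 * sin(2 * pi * config$line_freq * seq_len(n) / fs + ph)
    trial <- trial + matrix(line, nrow(trial), n, byrow = TRUE)
  }
  trial
}

#' Generate a labelled synthetic motor-imagery session
#'
#' Produces a balanced [epoch_set()] (`n_trials_per_class` trials of each
#' class, order shuffled) by repeated calls to [make_trial()], seeded from
#' `config$seed` so that identical configurations yield bit-identical
#' sessions. Values are quantized to 32-bit float resolution, matching the
#' epochs container.
#'
#' @param config a [generator_config()].
#' @return An [epoch_set()] with provenance recording the config hash and
#'   seed.
#' @examples
#' es <- generate_session(generator_config(n_trials_per_class = 5, seed = 42))
#' es
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  fs <- config$fs
  n_per <- config$n_trials_per_class
  labels <- sample(rep(c("left", "right"), each = n_per))
  n_samples <- length(seq(config$epoch_window[1L],
                          config$epoch_window[2L] - 1 / fs, by = 1 / fs))
  data <- array(0, dim = c(2L * n_per, config$n_channels, n_samples))
  for (i in seq_along(labels))
    data[i, , ] <- make_trial(labels[i], config)
  cue_index <- as.integer(-round(config$epoch_window[1L] * fs))
  epoch_set(quantize_float32(data), labels, fs, config$channel_names,
            cue_index,
            provenance = list(config_hash = config_hash(unclass(config)),
                              seed = config$seed))
}
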