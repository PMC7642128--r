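test_that("3-level band map at 100 Hz tiles [0, 50) dyadically", {
  bm <- band_map(100, 3)
  expect_equal(bm$D1, c(25, 50))
  expect_equal(bm$D2, c(12.5, 25))
  expect_equal(bm$D3, c(6.25, 12.5))
  expect_equal(bm$A3, c(0, 6.25))
  lo <- unname(sort(vapply(bm, `[`, 0, 1L)))
  hi <- unname(sort(vapply(bm, `[`, 0, 2L)))
  expect_equal(hi[-length(hi)], lo[-1L])  # bands tile without gaps
})

test_that("analysis coefficients match the brute-force filter-bank oracle", {
  set.seed(10)
  for (boundary in c("symmetric", "periodic")) {
    x <- rnorm(128)
    d <- dwt(x, wavelet_spec(3, boundary), fs = 100)
    ref <- x
    for (l in 1:3) {
      o <- oracle_dwt_level(ref, boundary)
      expect_lt(max(abs(d$details[[l]] - o$d)), 1e-10)
      ref <- o$a
    }
    expect_lt(max(abs(d$approx - ref)), 1e-10)
  }
})

test_that("keeping all bands reconstructs the input", {
  set.seed(11)
  for (boundary in c("symmetric", "periodic")) {
    for (L in c(64, 256, 550, 1024)) {
      if (boundary == "periodic" && L %% 8 != 0) next
      x <- rnorm(L)
      d <- dwt(x, wavelet_spec(3, boundary), fs = 100)
      r <- reconstruct(d, names(d$band_map))
      expect_equal(length(r), L)
      expect_lt(max(abs(r - x)) / max(abs(x)), 1e-10)
    }
  }
})

test_that("periodic-boundary transform conserves coefficient energy", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(512)
    d <- dwt(x, wavelet_spec(3, "periodic"), fs = 100)
    e <- sum(unlist(d$details)^2) + sum(d$approx^2)
    expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-10)
  }
})

test_that("band reconstructions are linear: single bands sum to the signal", {
  set.seed(13)
  x <- rnorm(512)
  d <- dwt(x, wavelet_spec(), fs = 100)
  parts <- lapply(names(d$band_map), function(b) reconstruct(d, b))
  expect_lt(max(abs(Reduce(`+`, parts) - x)), 1e-8)
})

test_that("band selectivity of keep = {D2, D3} follows the db6 response", {
  t <- (0:999) / 100
  ret <- function(f) {
    x <- sin(2 * pi * f * t)
    r <- reconstruct(dwt(x, wavelet_spec(), 100), c("D2", "D3"))
    sum(r^2) / sum(x^2)
  }
  # 20 Hz sits in the level-1 transition band: retention is bounded by the
  # closed-form low-pass gain |H(2*pi*20/100)|^2 / 2 = 0.8588
  expect_equal(ret(20), oracle_lowpass_gain(2 * pi * 20 / 100),
               tolerance = 0.01)
  # mid-band mu rhythm passes nearly intact; 2 Hz is rejected
  expect_gt(ret(10), 0.95)
  expect_lt(ret(2), 0.10)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(dwt(rnorm(8), wavelet_spec(1), 100), "too short")
  expect_error(dwt(c(1, NA, 3, rep(0, 20)), wavelet_spec(1), 100), "finite")
  d <- dwt(rnorm(64), wavelet_spec(), 100)
  expect_error(reconstruct(d, character(0)), "at least one band")
  expect_error(reconstruct(d, "D9"), "unknown band")
  expect_error(wavelet_spec(0), "n_levels")
  z <- dwt(numeric(64), wavelet_spec(), 100)
  expect_true(all(unlist(z$details) == 0) && all(z$approx == 0))
})

test_that("epoch preprocessing keeps shape and strips low frequencies", {
  es <- fixture_session("prep_demo", n_trials_per_class = 10L,
                        snr_db = 3, seed = 301L)
  prep <- preprocess_epochs(es)
  expect_identical(dim(prep$data), dim(es$data))
  expect_identical(prep$channel_names, es$channel_names)
  # low-frequency mass (< 6.25 Hz) drops to <= 10% of its pre-filter value
  lows <- vapply(seq_len(n_trials(es)), function(i) {
    pre <- band_power(periodogram(es$data[i, 1, ], 100), 0.5, 6.25)
    post <- band_power(periodogram(prep$data[i, 1, ], 100), 0.5, 6.25)
    post / pre
  }, 0)
  expect_lt(mean(lows), 0.10)
  # filtering is nearly idempotent: a second pass removes only edge leakage
  prep2 <- preprocess_epochs(prep)
  e1 <- sum(prep$data^2)
  expect_lt(abs(sum(prep2$data^2) - e1) / e1, 0.01)
  # zero epochs stay zero
  zs <- epoch_set(array(0, c(2, 2, 64)), c("left", "right"), 100,
                  c("C3", "C4"), 32L)
  expect_true(all(preprocess_epochs(zs)$data == 0))
  # wrong sampling rate is refused with a pointer to the resampler
  es250 <- epoch_set(array(rnorm(2 * 2 * 128), c(2, 2, 128)),
                     c("left", "right"), 250, c("C3", "C4"), 64L)
  expect_error(preprocess_epochs(es250), "resample")
})

test_that("250 Hz epochs resample to 100 Hz with rhythms preserved", {
  t250 <- (0:1374) / 250
  x <- sin(2 * pi * 10 * t250)
  es <- epoch_set(array(rep(x, each = 2), c(1, 2, length(t250))),
                  "left", 250, c("C3", "C4"), 500L)
  r <- resample_epochs(es, 100)
  expect_equal(r$fs, 100)
  expect_equal(n_samples(r), 550)
  expect_equal(r$cue_index, 200L)
  p <- periodogram(r$data[1, 1, 100:500], 100)
  expect_gt(band_power(p, 9, 11) / band_power(p, 0, 50), 0.95)
})
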