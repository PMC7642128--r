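# Post/pre band-power ratio at one channel, averaged over trials of a label;
# the direct oracle for the generator's power modulation contract.
post_pre_ratio <- function(es, label, channel, band = c(6.25, 12.5),
                           pre = c(-1.5, -0.5), post = c(0.5, 2.5)) {
  trials <- which(es$labels == label)
  ch <- match(channel, es$channel_names)
  r <- vapply(trials, function(i) {
    pw <- function(win) {
      idx <- mierd:::window_indices(es, win)
      band_power(periodogram(es$data[i, ch, idx], es$fs), band[1], band[2])
    }
    c(pw(post), pw(pre))
  }, numeric(2))
  mean(r[1, ]) / mean(r[2, ])
}

test_that("preset protocols fix the acquisition parameters", {
  cfg <- generator_config("comp118")
  expect_equal(cfg$fs, 100)
  expect_equal(cfg$n_channels, 118L)
  expect_equal(cfg$n_trials_per_class, 140L)
  expect_true(all(c("C3", "C4") %in% cfg$channel_names))
  lab <- generator_config("lab32")
  expect_equal(lab$fs, 250)
  expect_equal(lab$n_channels, 32L)
})

test_that("generated sessions are balanced, shaped, and seed-deterministic", {
  cfg <- generator_config(n_trials_per_class = 6L, seed = 7L)
  es1 <- generate_session(cfg)
  expect_identical(dim(es1$data), c(12L, 16L, 550L))
  expect_equal(as.vector(table(es1$labels)), c(6L, 6L))
  expect_equal(es1$cue_index, 200L)
  es2 <- generate_session(cfg)
  expect_identical(es1$data, es2$data)
  expect_identical(es1$labels, es2$labels)
  es3 <- generate_session(generator_config(n_trials_per_class = 6L,
                                           seed = 8L))
  expect_false(identical(es1$data, es3$data))
})

test_that("make_trial is a pure function of the RNG state", {
  cfg <- generator_config()
  set.seed(99)
  t1 <- make_trial("left", cfg)
  set.seed(99)
  t2 <- make_trial("left", cfg)
  expect_identical(t1, t2)
  expect_identical(dim(t1), c(16L, 550L))
})

test_that("noiseless modulation obeys the closed form (1 - erd_depth)", {
  cfg <- generator_config(erd_depth = 0.19, ers_gain = 0, snr_db = Inf,
                          seed = 5L, n_trials_per_class = 3L)
  es <- generate_session(cfg)
  # mu + beta power ratio post/pre at the contralateral electrode
  r_mu <- post_pre_ratio(es, "left", "C4")
  r_beta <- post_pre_ratio(es, "left", "C4", band = c(12.5, 25))
  expect_equal(r_mu, 0.81, tolerance = 0.01)
  expect_equal(r_beta, 0.81, tolerance = 0.01)
  # full suppression: zero contralateral rhythm after the 250 ms ramp
  cfg1 <- generator_config(erd_depth = 1, ers_gain = 0, snr_db = Inf,
                           seed = 5L, n_trials_per_class = 2L)
  es1 <- generate_session(cfg1)
  i_c4 <- match("C4", es1$channel_names)
  left <- which(es1$labels == "left")[1]
  post <- mierd:::window_indices(es1, c(0.3, 3.4))
  expect_lt(max(abs(es1$data[left, i_c4, post])), 1e-6)
})

test_that("with noise, erd_depth = 0.4 gives a post/pre mu ratio near 0.60", {
  es <- fixture_session("erd04", n_trials_per_class = 140L, erd_depth = 0.4,
                        seed = 201L)
  expect_equal(post_pre_ratio(es, "left", "C4"), 0.60, tolerance = 0.05)
})

test_that("zero effect leaves C3/C4 band power class-independent", {
  es <- fixture_session("null", n_trials_per_class = 100L, erd_depth = 0,
                        ers_gain = 0, seed = 202L)
  for (ch in c("C3", "C4")) {
    ci <- match(ch, es$channel_names)
    post <- mierd:::window_indices(es, c(0.5, 2.5))
    bp <- vapply(seq_len(n_trials(es)), function(i)
      band_power(periodogram(es$data[i, ci, post], 100), 6.25, 25), 0)
    p <- t.test(bp[es$labels == "left"], bp[es$labels == "right"])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("measured ERD magnitude grows with erd_depth", {
  erds <- vapply(c(0, 0.2, 0.4, 0.6), function(d) {
    es <- generate_session(generator_config(n_trials_per_class = 40L,
                                            erd_depth = d, seed = 203L))
    m <- erd_ers_map(es, "left")
    m$erd_ers_percent[m$channel == "C4" & m$band == "mu"]
  }, 0)
  expect_true(all(diff(erds) < 0))  # more depth, more negative ERD
})

test_that("non-motor channels carry no class information", {
  es <- fixture_session("erd04", n_trials_per_class = 140L, erd_depth = 0.4,
                        seed = 201L)
  r_fz <- post_pre_ratio(es, "left", "Fz")
  expect_equal(r_fz, 1, tolerance = 0.1)
})

test_that("artifact injection adds line peaks and respects Nyquist", {
  cfg <- generator_config(preset = "lab32", n_trials_per_class = 2L,
                          line_freq = 50, seed = 20L)
  set.seed(1)
  tr <- make_trial("left", cfg)
  cfg_clean <- generator_config(preset = "lab32", n_trials_per_class = 2L,
                                seed = 20L)
  set.seed(1)
  tr0 <- make_trial("left", cfg_clean)
  p1 <- periodogram(tr[1, ], 250)
  p0 <- periodogram(tr0[1, ], 250)
  expect_gt(band_power(p1, 49, 51), 10 * band_power(p0, 49, 51))
  # no-op when no artifacts are configured
  expect_identical(inject_artifacts(tr0, cfg_clean), tr0)
  # line at or above Nyquist is rejected
  expect_error(generator_config(line_freq = 50, fs = 100), "alias")
  cfg_bad <- cfg_clean
  cfg_bad$line_freq <- 125
  expect_error(inject_artifacts(tr0, cfg_bad), "alias")
})

test_that("blinks land on frontal channels only", {
  cfg <- generator_config(preset = "lab32", n_trials_per_class = 2L,
                          blink_rate = 60, snr_db = Inf, erd_depth = 0,
                          ers_gain = 0, seed = 21L)
  set.seed(2)
  tr <- make_trial("left", cfg)
  fp <- match("Fp1", cfg$channel_names)
  cz <- match("Cz", cfg$channel_names)
  expect_gt(max(abs(tr[fp, ])), 50)      # blink transient dominates
  expect_lt(max(abs(tr[cz, ])), 30)      # central channels untouched
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(channel_names = c("Fz", "Cz")), "C3")
  expect_error(generator_config(erd_depth = 1.2), "erd_depth")
  expect_error(generator_config(ers_gain = -0.1), "ers_gain")
  expect_error(generator_config(epoch_window = c(1, 2)), "span the cue")
})
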