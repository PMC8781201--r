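sine_recording <- function(freq, fs = 500, dur = 10, amp = 1, nch = 1) {
  tt <- seq_len(dur * fs) / fs
  eeg_recording(matrix(rep(amp * sin(2 * pi * freq * tt), nch), nch,
                       byrow = TRUE), fs, paste0("ch", seq_len(nch)))
}

# interior amplitude: skip start-up transients and trailing edge effects
steady_amp <- function(x, fs, discard_s = 2) {
  max(abs(x[(discard_s * fs):(length(x) - fs)]))
}

# direct evaluation of a digital filter's response at frequency f
freq_response <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(b) - 1))
  za <- exp(-1i * 2 * pi * f / fs * (seq_along(a) - 1))
  Mod(sum(b * z) / sum(a * za))
}

test_that("band-pass removes DC and matches its designed frequency response", {
  fs <- 500
  rec <- eeg_recording(matrix(5, 1, fs * 10), fs, "ch1")
  out <- bandpass_filter(rec)
  expect_lt(mean(abs(out$data[1, (5 * fs):(10 * fs)])), 0.05)

  bf <- signal::butter(2, c(1, 50) / (fs / 2), type = "pass")
  s10 <- bandpass_filter(sine_recording(10))
  expect_equal(steady_amp(s10$data[1, ], fs),
               freq_response(bf$b, bf$a, 10, fs), tolerance = 0.01)
  expect_lt(abs(steady_amp(s10$data[1, ], fs) - 1), 0.05)

  # 60 Hz sits on the roll-off: attenuated exactly as the design predicts,
  # and well below the passband gain
  s60 <- bandpass_filter(sine_recording(60))
  H60 <- freq_response(bf$b, bf$a, 60, fs)
  expect_equal(steady_amp(s60$data[1, ], fs), H60, tolerance = 0.02)
  expect_lt(steady_amp(s60$data[1, ], fs), 0.65)
  # far stop band reaches 20 dB
  s150 <- bandpass_filter(sine_recording(150))
  expect_lt(steady_amp(s150$data[1, ], fs), 10^(-20 / 20))
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- sine_recording(10)
  expect_error(bandpass_filter(rec, 1, 250),
               class = "passivebci_parameter_error")
  expect_error(bandpass_filter(rec, 0, 50),
               class = "passivebci_parameter_error")
})

test_that("resampling gives the exact length and preserves tones", {
  rec <- eeg_recording(matrix(stats::rnorm(500), 1), 500, "ch1")
  out <- resample_recording(rec, 256)
  expect_equal(ncol(out$data), 256)
  expect_equal(out$fs_hz, 256)

  s10 <- resample_recording(sine_recording(10, dur = 10), 256)
  expect_lt(abs(steady_amp(s10$data[1, ], 256) - 1), 0.01)

  # content above the new Nyquist rate is gone
  s150 <- resample_recording(sine_recording(150, dur = 10), 256)
  expect_lt(steady_amp(s150$data[1, ], 256), 0.05)

  expect_error(resample_recording(sine_recording(10), 500),
               class = "passivebci_parameter_error")
})

test_that("filtering and resampling commute with channel reordering", {
  set.seed(8)
  rec <- eeg_recording(matrix(stats::rnorm(4 * 5000), 4), 500, paste0("ch", 1:4))
  perm <- c(3, 1, 4, 2)
  rec_p <- eeg_recording(rec$data[perm, ], 500, rec$channel_labels[perm])
  a <- resample_recording(bandpass_filter(rec), 256)
  b <- resample_recording(bandpass_filter(rec_p), 256)
  expect_equal(b$data, a$data[perm, ], tolerance = 1e-10)
})

test_that("ASR calibration yields an orthonormal basis and k-linear thresholds", {
  set.seed(5)
  clean <- eeg_recording(matrix(stats::rnorm(8 * 256 * 40), 8), 256, paste0("ch", 1:8))
  m <- asr_calibrate(clean, cutoff_k = 4)
  V <- m$component_basis
  expect_lt(max(abs(crossprod(V) - diag(8))), 1e-8)
  expect_true(all(m$component_thresholds > 0))
  m2 <- asr_calibrate(clean, cutoff_k = 8)
  expect_equal(m2$component_thresholds, 2 * m$component_thresholds,
               tolerance = 1e-12)
})

test_that("ASR calibration preconditions are enforced", {
  set.seed(5)
  short <- eeg_recording(matrix(stats::rnorm(4 * 256 * 10), 4), 256, paste0("ch", 1:4))
  expect_error(asr_calibrate(short), class = "passivebci_calibration_error")
  flat <- matrix(stats::rnorm(256 * 40), 1)
  rank_def <- eeg_recording(rbind(flat, flat, flat[1, ] * 2), 256, paste0("ch", 1:3))
  expect_error(asr_calibrate(rank_def), class = "passivebci_calibration_error")
})

test_that("ASR passes clean windows, removes bursts, and is linear at zero", {
  set.seed(6)
  ch_sd <- 1:8    # distinct channel variances give a stable component basis
  clean <- matrix(stats::rnorm(8 * 256 * 40), 8) * ch_sd
  m <- asr_calibrate(eeg_recording(clean, 256, paste0("ch", 1:8)), cutoff_k = 4)

  w_clean <- matrix(stats::rnorm(8 * 1024), 8) * ch_sd
  out <- asr_apply(w_clean, m)
  expect_lt(abs(sqrt(mean(out^2)) / sqrt(mean(w_clean^2)) - 1), 0.05)

  w_art <- w_clean
  burst_idx <- 300:500
  w_art[3, burst_idx] <- w_art[3, burst_idx] + 10 * ch_sd[3] *
    stats::rnorm(length(burst_idx))
  cleaned <- asr_apply(w_art, m)
  expect_lt(sqrt(mean(cleaned[, burst_idx]^2)), sqrt(mean(w_art[, burst_idx]^2)))

  expect_equal(asr_apply(matrix(0, 8, 100), m), matrix(0, 8, 100))
  expect_error(asr_apply(matrix(0, 5, 100), m), class = "passivebci_shape_error")
})

test_that("stream windows follow the per-step emission convention", {
  rec <- eeg_recording(matrix(stats::rnorm(804 * 256), 1), 256, "ch1")
  sw <- stream_windows(rec, win_s = 4, step_s = 2)
  expect_equal(sw$n_steps, 402)
  expect_equal(sw$step_times_s, seq(2, 804, by = 2))

  rec4 <- eeg_recording(matrix(stats::rnorm(4 * 256), 1), 256, "ch1")
  expect_equal(stream_windows(rec4, 4, 2)$n_steps, 2)

  # first window is left-padded with the first sample
  w1 <- sw$get_window(1)
  expect_equal(ncol(w1), 4 * 256)
  expect_true(all(w1[1, 1:(2 * 256 - 1)] == rec$data[1, 1]))
  # step t only sees samples up to t * step_s
  w3 <- sw$get_window(3)
  expect_equal(w3[1, ncol(w3)], rec$data[1, 6 * 256])
})

test_that("windows are causal: truncating the future changes nothing", {
  set.seed(9)
  rec <- eeg_recording(matrix(stats::rnorm(20 * 256), 1), 256, "ch1")
  rec_short <- crop_recording(rec, 0, 10)
  sw_full <- stream_windows(rec)
  sw_short <- stream_windows(rec_short)
  for (i in seq_len(sw_short$n_steps)) {
    expect_identical(sw_full$get_window(i), sw_short$get_window(i))
  }
})
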