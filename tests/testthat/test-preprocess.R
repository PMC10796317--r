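test_that("band-pass rejects DC and passes the band per its own response", {
  fs <- 250
  t <- seq(0, 10, by = 1 / fs)
  # DC lies outside the 0.5-3 Hz passband
  y_dc <- bandpass(rep(1, length(t)), fs, 0.5, 3)
  core <- seq(round(3 * fs), length(t) - round(3 * fs))
  expect_lt(max(abs(y_dc[core])), 1e-3)

  # oracle: the designed filter's squared magnitude response (applied
  # forward-backward), evaluated independently of the filtering path
  gain_oracle <- function(f_hz, lo, hi) {
    filt <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
    w <- 2 * pi * f_hz / fs
    H <- sum(filt$b * exp(-1i * w * (seq_along(filt$b) - 1))) /
      sum(filt$a * exp(-1i * w * (seq_along(filt$a) - 1)))
    Mod(H)^2  # forward-backward application squares the magnitude
  }
  t20 <- seq(0, 20, by = 1 / fs)
  for (f in c(1.5, 10)) {
    y <- bandpass(sin(2 * pi * f * t20), fs, 0.5, 3)
    steady <- max(abs(y[seq(round(6 * fs), length(t20) - round(6 * fs))]))
    expect_equal(steady, gain_oracle(f, 0.5, 3), tolerance = 0.02)
  }
  expect_gt(max(abs(bandpass(sin(2 * pi * 1.5 * t20), fs, 0.5, 3))), 0.95)
  y10 <- bandpass(sin(2 * pi * 10 * t20), fs, 0.5, 3)
  expect_lt(max(abs(y10[seq(round(6 * fs), length(t20) - round(6 * fs))])), 0.1)

  expect_error(bandpass(rnorm(1000), fs, 3, 0.5), class = "bcgco_parameter_error")
  expect_error(bandpass(rnorm(1000), fs, 0.5, 200), class = "bcgco_parameter_error")
})

test_that("band-pass filtering is linear", {
  set.seed(3)
  fs <- 250
  x <- rnorm(2000); y <- rnorm(2000)
  lhs <- bandpass(2 * x - 3 * y, fs, 0.5, 30)
  rhs <- 2 * bandpass(x, fs, 0.5, 30) - 3 * bandpass(y, fs, 0.5, 30)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("QRS detection finds every clean beat within 40 ms", {
  sim <- simulate_subject(fixed_hr_config(hr_bpm = 60, duration_s = 20),
                          subject_seed = 21L)
  fs <- sim$record$fs_signal
  qrs <- detect_qrs(bandpass(sim$record$ecg, fs, 0.5, 30), fs)
  truth <- sim$truth$qrs_indices
  expect_length(qrs$indices, length(truth))
  expect_length(truth, 20)  # 20 s at 60 bpm
  expect_true(all(abs(qrs$indices - truth) <= 0.04 * fs))
})

test_that("QRS detection stays sensitive and precise in noise", {
  sim <- simulate_subject(fixed_hr_config(hr_bpm = 72, duration_s = 30,
                                          snr_db = 10),
                          subject_seed = 22L)
  fs <- sim$record$fs_signal
  qrs <- detect_qrs(bandpass(sim$record$ecg, fs, 0.5, 30), fs)
  m <- match_events(qrs$indices, sim$truth$qrs_indices, 0.04 * fs)
  sens <- m$tp / (m$tp + m$fn)
  ppv <- m$tp / (m$tp + m$fp)
  expect_gte(sens, 0.95)
  expect_gte(ppv, 0.95)
})

test_that("degenerate inputs are handled", {
  expect_error(detect_qrs(rnorm(100), 250),
               class = "bcgco_insufficient_data_error")
  empty <- detect_qrs(numeric(1000), 250)
  expect_s3_class(empty, "qrs_train")
  expect_length(empty$indices, 0)
})

test_that("detected trains always respect the refractory period", {
  set.seed(9)
  fs <- 250
  for (i in 1:5) {
    x <- bandpass(rnorm(5 * fs, sd = c(1, 3)[1 + (i %% 2)]), fs, 0.5, 30)
    q <- detect_qrs(x, fs)
    if (length(q$indices) > 1) expect_true(all(diff(q$indices) >= 0.2 * fs))
  }
  expect_error(qrs_train(c(100, 120), 250),
               class = "bcgco_consistency_error")
  expect_error(qrs_train(c(100, 90), 250),
               class = "bcgco_consistency_error")
})
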