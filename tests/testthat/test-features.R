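test_that("window grid: 10-s windows with 80% overlap", {
  expect_equal(make_windows(30), seq(0, 20, by = 2))   # 11 windows
  expect_length(make_windows(30), 11)
  expect_equal(make_windows(10), 0)                     # exact fit
  expect_length(make_windows(9), 0)                     # too short
  expect_equal(make_windows(20, win_s = 5, overlap = 0), c(0, 5, 10, 15))
  expect_error(make_windows(30, overlap = 1), class = "bcgco_parameter_error")
})

test_that("triangular-pulse delineation hits the construction landmarks", {
  fs <- 250
  cc <- triangle_cc(2000, start = 551, base_s = 0.4, h = 2, fs = fs)
  qrs <- qrs_train(c(250, 551, 1500), fs)  # pulse apex at qrs2 + 0.2 s
  d <- delineate_beats(cc, qrs, fs, skip_beats = 0)
  expect_equal(nrow(d), 3)
  b <- d[2, ]
  expect_true(b$valid)
  expect_equal(b$onset_index, 551)
  expect_equal(b$peak_index, 601)
  expect_equal(b$offset_index, 651)
  # beats on an identically-zero component are invalid
  d0 <- delineate_beats(numeric(2000), qrs, fs, skip_beats = 0)
  expect_false(any(d0$valid))
})

test_that("delineation recovers simulator landmarks in noise", {
  sim <- simulate_subject(quick_sim_config(duration_s = 40, snr_db = 10),
                          subject_seed = 31L)
  rec <- sim$record; fs <- rec$fs_signal
  qrs <- qrs_train(sim$truth$qrs_indices, fs)
  cc <- rls_extract(bandpass(rec$bcg_c, fs, 0.5, 3), qrs, fs)
  d <- delineate_beats(cc, qrs, fs)
  ok <- d$valid
  err_ms <- abs(d$peak_index[ok] - sim$truth$beats_c$peak_index[ok]) / fs * 1000
  expect_gte(mean(err_ms <= 20), 0.95)
})

test_that("triangle morphology matches closed-form geometry", {
  fs <- 250
  cc <- triangle_cc(500, start = 101, base_s = 0.4, h = 2, fs = fs)
  m <- beat_morphology(cc, 101, 151, 201, fs, interpolate = FALSE)
  expect_equal(m[["d_total"]], 0.4, tolerance = 1e-9)
  expect_equal(m[["d_onset_peak"]], 0.2, tolerance = 1e-9)
  expect_equal(m[["a_peak"]], 2, tolerance = 1e-9)
  expect_equal(m[["a_max"]], 2, tolerance = 1e-9)
  expect_equal(m[["a_mean"]], 2, tolerance = 1e-9)
  expect_equal(m[["d_pulse_width"]], 0.2, tolerance = 1e-9)
  expect_equal(m[["ar_total"]], 0.4, tolerance = 1e-9)        # h * base / 2
  expect_equal(m[["l_onset_peak"]], sqrt(0.2^2 + 2^2), tolerance = 1e-9)
  expect_equal(m[["l_total"]], 2 * sqrt(0.2^2 + 2^2), tolerance = 1e-9)
  # interpolation does not change sample-aligned crossings
  m2 <- beat_morphology(cc, 101, 151, 201, fs, interpolate = TRUE)
  expect_equal(m2[["d_pulse_width"]], 0.2, tolerance = 1e-9)
})

test_that("morphology additivity and scaling covariance hold for random beats", {
  set.seed(17)
  fs <- 250
  for (i in 1:10) {
    n <- 400
    cc <- as.numeric(stats::filter(rnorm(n), rep(1 / 20, 20), sides = 2))
    cc[is.na(cc)] <- 0
    on <- 50L; pk <- on + sample(20:80, 1); off <- pk + sample(20:80, 1)
    cc[pk] <- max(cc) + 1  # make the peak a genuine maximum
    m <- beat_morphology(cc, on, pk, off, fs)
    expect_equal(m[["d_total"]], m[["d_onset_peak"]] + m[["d_peak_offset"]],
                 tolerance = 1e-9)
    expect_equal(m[["ar_total"]], m[["ar_onset_peak"]] + m[["ar_peak_offset"]],
                 tolerance = 1e-9)
    expect_equal(m[["l_total"]], m[["l_onset_peak"]] + m[["l_peak_offset"]],
                 tolerance = 1e-9)
    expect_equal(m[["a_max"]], max(m[["a_onset_peak"]], m[["a_offset_peak"]]))
    expect_equal(m[["a_mean"]],
                 (m[["a_onset_peak"]] + m[["a_offset_peak"]]) / 2)
    expect_lte(m[["d_pulse_width"]], m[["d_total"]] + 1e-9)
    # amplitude/area features scale with k; durations do not
    k <- 3.7
    mk <- beat_morphology(k * cc, on, pk, off, fs)
    for (f in c("a_peak", "a_onset_peak", "a_offset_peak", "a_max", "a_mean",
                "ar_onset_peak", "ar_peak_offset", "ar_total"))
      expect_equal(mk[[f]], k * m[[f]], tolerance = 1e-9)
    for (f in c("d_onset_peak", "d_peak_offset", "d_total"))
      expect_equal(mk[[f]], m[[f]], tolerance = 1e-9)
  }
})

test_that("every usable window yields exactly 66 ordered features", {
  nm <- feature_names()
  expect_length(nm, 66)
  expect_length(grep("^ccc_", nm), 33)
  expect_length(grep("^cca_", nm), 33)
  # 30 of the 33 per channel are beat-morphology medians/SDs
  expect_length(grep("^ccc_(med|sd)_", nm), 30)
  expect_identical(nm[1:3], c("ccc_sd", "ccc_skew", "ccc_kurt"))

  fs <- 250
  cc <- numeric(3000)
  peaks <- integer()
  for (s in seq(101, 2601, by = 250)) {  # identical triangles, 1-s spacing
    cc <- cc + triangle_cc(3000, s, 0.4, 2, fs)
    peaks <- c(peaks, s + 50L)
  }
  qrs <- qrs_train(peaks - 50L, fs)
  d <- delineate_beats(cc, qrs, fs, skip_beats = 0)
  mt <- morphology_table(cc, d, fs)
  fv <- window_features(cc, cc, mt, mt, 0, fs, win_s = 10)
  expect_length(fv, 66)
  expect_identical(names(fv), nm)
  expect_true(attr(fv, "usable"))
  # identical beats: all morphology SDs zero, medians equal the single beat
  expect_equal(unname(fv["ccc_sd_d_total"]), 0)
  expect_equal(unname(fv["ccc_med_d_total"]), 0.4, tolerance = 1e-9)
  expect_equal(unname(fv["cca_med_a_peak"]), 2, tolerance = 1e-9)
  sd_cols <- grep("_sd_", nm, value = TRUE)
  expect_true(all(fv[sd_cols] == 0))
})

test_that("windows with fewer than 2 valid beats are unusable", {
  fs <- 250
  cc <- triangle_cc(3000, 101, 0.4, 2, fs)
  qrs <- qrs_train(c(101, 1500, 2600), fs)
  d <- delineate_beats(cc, qrs, fs, skip_beats = 0)
  mt <- morphology_table(cc, d, fs)
  fv <- window_features(cc, cc, mt, mt, 0, fs, win_s = 10)
  expect_false(attr(fv, "usable"))
  expect_true(is.na(fv[["ccc_med_d_total"]]))
  # distribution features are still defined
  expect_false(is.na(fv[["ccc_sd"]]))
})

test_that("distribution features: symmetry gives zero skewness", {
  fs <- 250
  tt <- (0:2499) / fs
  cc <- sin(2 * pi * 2 * tt)  # symmetric around 0 over full cycles
  qrs <- qrs_train(seq(1, 2401, by = 125), fs)
  d <- delineate_beats(cc, qrs, fs, skip_beats = 0)
  mt <- morphology_table(cc, d, fs)
  fv <- window_features(cc, cc, mt, mt, 0, fs, win_s = 10)
  expect_equal(unname(fv["ccc_skew"]), 0, tolerance = 1e-6)
  expect_equal(unname(fv["ccc_sd"]), sd(cc[1:2500]), tolerance = 1e-12)
})
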