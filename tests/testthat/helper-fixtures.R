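# Fixtures built in code, shared across test files.

# Minimal deterministic record: 60 s at 250 Hz, CO at 0.5 Hz.
make_test_record <- function(duration_s = 60, fs = 250, fs_co = 0.5,
                             subject_id = "T01", seed = 11L) {
  set.seed(seed)
  n <- duration_s * fs
  co <- 6 + 0.5 * sin(seq(0, 2 * pi, length.out = duration_s * fs_co))
  bcg_record(
    subject_id = subject_id,
    ecg = rnorm(n), bcg_c = rnorm(n), bcg_a = rnorm(n),
    co = co, fs_signal = fs, fs_co = fs_co, co_t0_offset = 0,
    phases = data.frame(label = c("Normoventilation", "Trendelenburg"),
                        start_s = c(0, 30), end_s = c(30, 60))
  )
}

# One-phase simulator configuration for fast subject-level tests.
quick_sim_config <- function(duration_s = 40, snr_db = 10, seed = 1L, ...) {
  sim_config(n_subjects = 2L,
             phases = data.frame(label = "Normoventilation",
                                 duration_s = duration_s),
             noise_snr_db = snr_db, seed = seed, ...)
}

# ECG at a fixed heart rate: collapse the CO influence on HR.
fixed_hr_config <- function(hr_bpm = 60, duration_s = 20, snr_db = Inf, ...) {
  quick_sim_config(duration_s = duration_s, snr_db = snr_db,
                   hr_co_slope = 0, hr_intercept = hr_bpm, rr_jitter = 0, ...)
}

# A single triangular pulse on a zero baseline: base `base_s` seconds,
# height h, apex centered, starting at sample `start`.
triangle_cc <- function(n, start, base_s, h, fs) {
  cc <- numeric(n)
  len <- round(base_s * fs)  # samples start..start+len span the base
  half <- len / 2
  idx <- 0:len
  cc[start + idx] <- h * (1 - abs(idx - half) / half)
  cc
}

# Match detected events to true events within a tolerance; returns counts
# for sensitivity / positive predictivity.
match_events <- function(detected, truth, tol_samples) {
  tp <- 0L
  used <- logical(length(truth))
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol_samples)
    if (length(j)) { tp <- tp + 1L; used[j[1L]] <- TRUE }
  }
  list(tp = tp, fn = sum(!used), fp = length(detected) - tp)
}

# Synthetic feature table with grouped subjects for selection tests.
make_feature_sim <- function(n = 300, p = 10, n_subjects = 10, seed = 5L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  subjects <- sprintf("P%02d", rep_len(seq_len(n_subjects), n))
  list(X = as.data.frame(X), subjects = subjects)
}

# CO sample timestamps of a record (seconds from signal start).
co_timestamps_test <- function(record)
  record$co_t0_offset + (seq_along(record$co) - 1) / record$fs_co
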