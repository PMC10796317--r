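# Seeded synthetic cardio-mechanical signal generator. Emulates the
# statistical structure the estimation pipeline assumes: a slow latent CO
# trajectory per subject, a CO-linked heart rate, QRS-template ECG,
# beat-locked circulatory fluctuations in two BCG channels whose duration
# and amplitude depend on CO, a respiratory baseline, broadband noise, and
# a 0.5 Hz CO reference channel. Every additive component and every beat
# landmark is stored as ground truth.

#' Simulator configuration
#'
#' Defaults describe a cohort of 20 healthy adults at rest undergoing the
#' four analyzable protocol phases (Normoventilation, Hypoventilation,
#' Trendelenburg, Infusion) with per-phase durations of 40/30/45/60 s,
#' matching typical artifact-free segment lengths. CO stays in
#' `co_range = [3, 9]` L/min; heart rate is linear in CO
#' (`hr = hr_intercept + hr_co_slope * CO`); fluctuation duration decreases
#' with CO (`duration_co_slope < 0`: longer fluctuations at lower heart
#' rate hence lower CO) and amplitude increases with CO.
#'
#' @param n_subjects Cohort size.
#' @param phases `data.frame` with `label` and `duration_s` per phase.
#' @param fs_signal,fs_co Sampling rates (Hz) of the signal channels and
#'   the CO reference (250 and 0.5 by default).
#' @param co_range Bounds of the latent CO walk, L/min, within (0, 15).
#' @param co_baseline_mean,co_baseline_sd Distribution of per-subject
#'   resting CO (L/min).
#' @param phase_co_shift Named numeric: additive shift of the latent CO
#'   attractor per phase (L/min).
#' @param hr_co_slope,hr_intercept Heart-rate coupling, bpm per L/min and
#'   bpm.
#' @param rr_jitter Fractional beat-to-beat RR jitter (SD).
#' @param template Beat-fluctuation template family.
#' @param duration_base_s Fluctuation duration at the reference CO of
#'   6.5 L/min, seconds.
#' @param duration_co_slope Seconds per L/min (negative).
#' @param amplitude_base,amplitude_co_slope Fluctuation amplitude at the
#'   reference CO (arbitrary units) and its CO slope.
#' @param cc_delay_s Named numeric: mechanical delay from the QRS instant
#'   to fluctuation onset per channel, seconds.
#' @param respiration_freq_hz,respiration_amp Respiratory baseline
#'   frequency (Hz) and amplitude relative to `amplitude_base`.
#' @param noise_snr_db Broadband-noise SNR relative to each channel's
#'   circulatory component, dB (`Inf` disables noise).
#' @param co_noise_sd Measurement noise SD of the CO reference channel,
#'   L/min.
#' @param motion_artifact_rate Low-frequency artifact bumps per minute
#'   (default 0 = off).
#' @param seed Master seed; fixed seed implies bit-reproducible output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20L,
                       phases = data.frame(
                         label = c("Normoventilation", "Hypoventilation",
                                   "Trendelenburg", "Infusion"),
                         duration_s = c(40, 30, 45, 60)),
                       fs_signal = 250, fs_co = 0.5,
                       co_range = c(3, 9),
                       co_baseline_mean = 6.5, co_baseline_sd = 0.8,
                       phase_co_shift = c(Normoventilation = 0,
                                          Hypoventilation = -0.5,
                                          Trendelenburg = 0.7,
                                          Infusion = 0.5),
                       hr_co_slope = 6, hr_intercept = 32,
                       rr_jitter = 0.02,
                       template = c("raised-cosine", "gaussian", "triangle"),
                       duration_base_s = 0.45, duration_co_slope = -0.03,
                       amplitude_base = 1, amplitude_co_slope = 0.08,
                       cc_delay_s = c(carotid = 0.12, abdominal = 0.22),
                       respiration_freq_hz = 0.27, respiration_amp = 0.5,
                       noise_snr_db = 10,
                       co_noise_sd = 0.15,
                       motion_artifact_rate = 0,
                       seed = 1L) {
  template <- match.arg(template)
  stopifnot(n_subjects >= 1L, fs_signal > 0, fs_co > 0,
            co_range[1] > 0, co_range[2] < 15, co_range[1] < co_range[2])
  cfg <- list(n_subjects = as.integer(n_subjects), phases = phases,
              fs_signal = fs_signal, fs_co = fs_co, co_range = co_range,
              co_baseline_mean = co_baseline_mean,
              co_baseline_sd = co_baseline_sd,
              phase_co_shift = phase_co_shift,
              hr_co_slope = hr_co_slope, hr_intercept = hr_intercept,
              rr_jitter = rr_jitter, template = template,
              duration_base_s = duration_base_s,
              duration_co_slope = duration_co_slope,
              amplitude_base = amplitude_base,
              amplitude_co_slope = amplitude_co_slope,
              cc_delay_s = cc_delay_s,
              respiration_freq_hz = respiration_freq_hz,
              respiration_amp = respiration_amp,
              noise_snr_db = noise_snr_db, co_noise_sd = co_noise_sd,
              motion_artifact_rate = motion_artifact_rate,
              seed = as.integer(seed))
  # infeasibility check at the extremes of the CO range
  hr_max <- hr_intercept + hr_co_slope * co_range[2]
  if (60 / hr_max < 0.3)
    stop_bcg("configuration implies RR < 0.3 s at the top of the CO range",
             class = "bcgco_configuration_error")
  structure(cfg, class = "sim_config")
}

# Beat-fluctuation template sampled at `fs`: amplitude a, duration d (s).
# Peak at d/2 for every family; onset/offset at 0/d.
beat_template <- function(kind, a, d, fs) {
  n <- max(3L, round(d * fs))
  x <- (seq_len(n) - 1) / (n - 1)  # 0..1
  y <- switch(kind,
    "raised-cosine" = a * 0.5 * (1 - cos(2 * pi * x)),
    "gaussian" = {
      g <- exp(-(x - 0.5)^2 / (2 * (1 / 6)^2))
      a * (g - g[1L]) / (1 - g[1L])  # pinned to zero at the edges
    },
    "triangle" = a * (1 - abs(2 * x - 1))
  )
  y
}

#' Simulate one subject's recording
#'
#' Generates the latent CO trajectory (a bounded, phase-shifted
#' mean-reverting walk), the beat train at a CO-linked heart rate, the ECG
#' (QRS + T-wave templates plus baseline and noise), both BCG channels
#' (beat-locked fluctuation train + respiratory sinusoid + white noise at
#' the configured SNR, plus optional motion bumps), and the 0.5 Hz CO
#' reference with measurement noise.
#'
#' @param cfg A [sim_config()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Subject identifier.
#' @return List with `record` (a [bcg_record()]) and `truth`: QRS instants
#'   (samples), per-channel beat landmark tables (onset/peak/offset
#'   samples, duration, amplitude), the latent CO at signal resolution,
#'   and the stored additive components (`circulatory`, `respiratory`,
#'   `noise` per channel; their sum reconstructs the channel exactly).
#' @export
simulate_subject <- function(cfg, subject_seed = cfg$seed,
                             subject_id = "S01") {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(subject_seed, {
    fs <- cfg$fs_signal
    total_s <- sum(cfg$phases$duration_s)
    n <- round(total_s * fs)
    tt <- (seq_len(n) - 1) / fs

    # per-subject heterogeneity
    baseline_co <- clamp(stats::rnorm(1, cfg$co_baseline_mean, cfg$co_baseline_sd),
                         cfg$co_range[1] + 0.5, cfg$co_range[2] - 0.5)
    gain <- c(carotid = exp(stats::rnorm(1, 0, 0.15)),
              abdominal = exp(stats::rnorm(1, 0, 0.15)))
    delay <- pmax(0.05, cfg$cc_delay_s + stats::rnorm(2, 0, 0.015))
    names(delay) <- names(cfg$cc_delay_s)
    resp_phase <- stats::runif(1, 0, 2 * pi)

    # latent CO: mean-reverting walk on a 1 Hz grid toward the phase target
    phase_end <- cumsum(cfg$phases$duration_s)
    phase_at <- function(t) cfg$phases$label[which(t < phase_end + 1e-9)[1L]]
    grid_t <- seq(0, total_s, by = 1)
    co_grid <- numeric(length(grid_t))
    co_grid[1L] <- baseline_co
    for (i in seq_along(grid_t)[-1L]) {
      target <- baseline_co +
        cfg$phase_co_shift[[phase_at(min(grid_t[i], total_s - 1e-6))]]
      step <- 0.08 * (target - co_grid[i - 1L]) + stats::rnorm(1, 0, 0.06)
      co_grid[i] <- clamp(co_grid[i - 1L] + step,
                          cfg$co_range[1], cfg$co_range[2])
    }
    co_latent <- stats::approx(grid_t, co_grid, xout = tt, rule = 2)$y

    # beat train: RR from the CO-linked heart rate plus jitter
    beat_t <- numeric()
    t_cur <- 0.3
    while (t_cur < total_s - 0.05) {
      beat_t <- c(beat_t, t_cur)
      co_here <- co_grid[min(length(co_grid), floor(t_cur) + 1L)]
      hr <- cfg$hr_intercept + cfg$hr_co_slope * co_here
      rr <- (60 / hr) * (1 + cfg$rr_jitter * stats::rnorm(1))
      if (rr < 0.3)
        stop_bcg("infeasible RR interval < 0.3 s", class = "bcgco_configuration_error")
      t_cur <- t_cur + rr
    }
    qrs_idx <- pmin(n, round(beat_t * fs) + 1L)

    # ECG: R spike + S dip + T wave per beat
    ecg_clean <- numeric(n)
    add_gauss <- function(sig, center_s, sd_s, amp) {
      i0 <- max(1L, round((center_s - 4 * sd_s) * fs))
      i1 <- min(n, round((center_s + 4 * sd_s) * fs))
      if (i0 > i1) return(sig)
      idx <- i0:i1
      sig[idx] <- sig[idx] + amp * exp(-((idx - 1) / fs - center_s)^2 / (2 * sd_s^2))
      sig
    }
    for (bt in beat_t) {
      ecg_clean <- add_gauss(ecg_clean, bt, 0.012, 1.0)
      ecg_clean <- add_gauss(ecg_clean, bt + 0.035, 0.014, -0.22)
      ecg_clean <- add_gauss(ecg_clean, bt + 0.28, 0.05, 0.22)
    }

    # per-beat fluctuation parameters (shared by both BCG channels up to
    # channel gain and delay)
    co_at_beat <- co_latent[qrs_idx]
    dur_b <- pmax(0.15, cfg$duration_base_s +
                    cfg$duration_co_slope * (co_at_beat - 6.5) +
                    stats::rnorm(length(beat_t), 0, 0.008))
    amp_b <- pmax(0.1, cfg$amplitude_base +
                    cfg$amplitude_co_slope * (co_at_beat - 6.5) +
                    stats::rnorm(length(beat_t), 0, 0.03))

    make_channel <- function(ch) {
      circ <- numeric(n)
      onset <- integer(length(beat_t)); peak <- integer(length(beat_t))
      offset <- integer(length(beat_t))
      for (i in seq_along(beat_t)) {
        tpl <- beat_template(cfg$template, amp_b[i] * gain[[ch]], dur_b[i], fs)
        i0 <- qrs_idx[i] + round(delay[[ch]] * fs)
        i1 <- min(n, i0 + length(tpl) - 1L)
        if (i0 <= n) circ[i0:i1] <- circ[i0:i1] + tpl[seq_len(i1 - i0 + 1L)]
        onset[i] <- i0
        peak[i] <- i0 + round((length(tpl) - 1L) / 2)
        offset[i] <- i0 + length(tpl) - 1L
      }
      resp <- cfg$respiration_amp * cfg$amplitude_base * gain[[ch]] *
        sin(2 * pi * cfg$respiration_freq_hz * tt + resp_phase)
      p_circ <- mean(circ^2)
      noise <- if (is.finite(cfg$noise_snr_db)) {
        stats::rnorm(n, 0, sqrt(p_circ / 10^(cfg$noise_snr_db / 10)))
      } else numeric(n)
      if (cfg$motion_artifact_rate > 0) {
        n_art <- stats::rpois(1, cfg$motion_artifact_rate * total_s / 60)
        for (k in seq_len(n_art)) {
          ctr <- stats::runif(1, 1, total_s - 1)
          amp <- stats::rnorm(1, 0, 3 * cfg$amplitude_base)
          noise <- noise + amp * exp(-(tt - ctr)^2 / (2 * 0.4^2))
        }
      }
      list(signal = circ + resp + noise, circulatory = circ,
           respiratory = resp, noise = noise,
           beats = data.frame(onset_index = onset, peak_index = peak,
                              offset_index = offset, duration_s = dur_b,
                              amplitude = amp_b * gain[[ch]]))
    }
    ch_c <- make_channel("carotid")
    ch_a <- make_channel("abdominal")

    ecg_noise <- if (is.finite(cfg$noise_snr_db))
      stats::rnorm(n, 0, sqrt(mean(ecg_clean^2) / 10^(cfg$noise_snr_db / 10)))
    else numeric(n)
    ecg <- ecg_clean + ecg_noise

    # 0.5 Hz CO reference with measurement noise
    t_co <- seq(0, total_s - 1 / cfg$fs_co + 1e-9, by = 1 / cfg$fs_co)
    co_ref <- stats::approx(grid_t, co_grid, xout = t_co, rule = 2)$y +
      stats::rnorm(length(t_co), 0, cfg$co_noise_sd)
    co_ref <- pmax(0.5, co_ref)

    phases_df <- data.frame(label = cfg$phases$label,
                            start_s = c(0, utils::head(phase_end, -1L)),
                            end_s = phase_end, stringsAsFactors = FALSE)
    record <- bcg_record(subject_id = subject_id,
                         ecg = ecg, bcg_c = ch_c$signal, bcg_a = ch_a$signal,
                         co = co_ref, fs_signal = fs, fs_co = cfg$fs_co,
                         co_t0_offset = 0, phases = phases_df)
    truth <- list(
      subject_id = subject_id, subject_seed = subject_seed,
      qrs_indices = qrs_idx, qrs_times_s = beat_t,
      co_latent = co_latent, baseline_co = baseline_co,
      beats_c = ch_c$beats, beats_a = ch_a$beats,
      components = list(
        ecg = list(clean = ecg_clean, noise = ecg_noise),
        bcg_c = ch_c[c("circulatory", "respiratory", "noise")],
        bcg_a = ch_a[c("circulatory", "respiratory", "noise")]
      )
    )
    list(record = record, truth = truth)
  })
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Simulate a cohort
#'
#' Per-subject seeds are derived deterministically from the master seed,
#' so regenerating with the same configuration reproduces the cohort
#' bit-identically.
#'
#' @param cfg A [sim_config()].
#' @param n Number of subjects (defaults to `cfg$n_subjects`, >= 2).
#' @return List with `records` (list of [bcg_record()]) and `truths`.
#' @export
simulate_cohort <- function(cfg, n = cfg$n_subjects) {
  stopifnot(inherits(cfg, "sim_config"), n >= 2L)
  sims <- lapply(seq_len(n), function(i) {
    sseed <- (cfg$seed %% 100000L) * 10000L + i * 131L
    simulate_subject(cfg, subject_seed = sseed,
                     subject_id = sprintf("S%02d", i))
  })
  list(records = lapply(sims, `[[`, "record"),
       truths = lapply(sims, `[[`, "truth"))
}
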