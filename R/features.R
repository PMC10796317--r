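# Per-beat morphology and the 66 window features.

# The 15 per-beat morphology scalars, in canonical order:
# 5 amplitudes, 4 durations, 3 areas, 3 curve lengths.
MORPH_NAMES <- c(
  "a_peak", "a_onset_peak", "a_offset_peak", "a_max", "a_mean",
  "d_onset_peak", "d_peak_offset", "d_total", "d_pulse_width",
  "ar_onset_peak", "ar_peak_offset", "ar_total",
  "l_onset_peak", "l_peak_offset", "l_total"
)

#' Names of the 66 window features
#'
#' Stable, ordered feature naming: the carotid block (`ccc_*`, 33 features)
#' followed by the abdominal block (`cca_*`, 33 features). Within a block:
#' the standard deviation, skewness and kurtosis of the circulatory
#' component's samples, then the median (`*_med_*`) and the standard
#' deviation (`*_sd_*`) over the window's beats of each of the 15 per-beat
#' morphology scalars.
#'
#' @return Character vector of length 66.
#' @export
feature_names <- function() {
  per_channel <- function(ch) c(
    paste0(ch, "_", c("sd", "skew", "kurt")),
    paste0(ch, "_med_", MORPH_NAMES),
    paste0(ch, "_sd_", MORPH_NAMES)
  )
  c(per_channel("ccc"), per_channel("cca"))
}

#' Analysis-window start times
#'
#' Windows of `win_s` seconds starting at 0 with `overlap` fractional
#' overlap between consecutive windows; only fully contained windows are
#' returned.
#'
#' @param duration_s Segment duration in seconds.
#' @param win_s Window length in seconds (default 10).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.8, i.e. 2-s
#'   steps for 10-s windows).
#' @return Numeric vector of window start times (possibly empty).
#' @export
make_windows <- function(duration_s, win_s = 10, overlap = 0.8) {
  stopifnot(is_scalar_number(duration_s), duration_s > 0)
  if (!is_scalar_number(overlap) || overlap < 0 || overlap >= 1)
    stop_bcg("overlap must be in [0, 1)", class = "bcgco_parameter_error")
  if (duration_s < win_s - 1e-9) return(numeric())
  step <- win_s * (1 - overlap)
  n <- floor((duration_s - win_s) / step + 1e-9) + 1
  (seq_len(n) - 1) * step
}

#' Delineate per-beat fluctuations in a circulatory component
#'
#' For beat `i` the peak is the maximum of the component in
#' `(qrs_i, qrs_i + min(RR_i, max_lag_s)]`; the onset is the nearest local
#' minimum at or before the peak within the search window (falling back to
#' the window start) and the offset the nearest local minimum after the
#' peak (falling back to the window end). Beats with non-positive
#' onset-to-peak amplitude are marked invalid, as are the first
#' `skip_beats` beats (RLS warm-up).
#'
#' @param cc A [rls_extract()] result or a plain numeric circulatory
#'   component.
#' @param qrs A [qrs_train()] aligned with `cc`.
#' @param fs Sampling rate in Hz.
#' @param max_lag_s Longest post-QRS lag searched for the fluctuation
#'   (default 1 s).
#' @param skip_beats Initial beats to mark invalid; defaults to the
#'   component's `warmup_beats` (or 0 for plain numeric input).
#' @return `data.frame` with one row per beat: `qrs_index`, `onset_index`,
#'   `peak_index`, `offset_index`, `valid`.
#' @export
delineate_beats <- function(cc, qrs, fs, max_lag_s = 1.0, skip_beats = NULL) {
  if (inherits(cc, "circulatory_component")) {
    if (is.null(skip_beats)) skip_beats <- cc$warmup_beats
    cc <- cc$cc
  }
  if (is.null(skip_beats)) skip_beats <- 0L
  stopifnot(inherits(qrs, "qrs_train"))
  q <- qrs$indices
  n <- length(cc)
  empty <- data.frame(qrs_index = integer(), onset_index = integer(),
                      peak_index = integer(), offset_index = integer(),
                      valid = logical())
  if (!length(q)) return(empty)
  max_lag <- round(max_lag_s * fs)
  rr <- c(diff(q), if (length(q) > 1L) diff(q)[length(q) - 1L] else max_lag)
  out <- empty[rep(1L, 0L), ]
  rows <- vector("list", length(q))
  for (i in seq_along(q)) {
    lo <- q[i] + 1L
    hi <- min(n, q[i] + min(rr[i], max_lag))
    if (lo > hi) {
      rows[[i]] <- data.frame(qrs_index = q[i], onset_index = NA_integer_,
                              peak_index = NA_integer_,
                              offset_index = NA_integer_, valid = FALSE)
      next
    }
    win <- cc[lo:hi]
    peak <- lo + which.max(win) - 1L
    # local minima within [q_i, hi] (onset may sit on the QRS instant itself)
    on_lo <- max(1L, q[i])
    onset <- local_min_before(cc, peak, on_lo)
    offset <- local_min_after(cc, peak, hi)
    valid <- i > skip_beats &&
      onset < peak && peak < offset &&
      (cc[peak] - cc[onset]) > 0
    rows[[i]] <- data.frame(qrs_index = q[i], onset_index = onset,
                            peak_index = peak, offset_index = offset,
                            valid = valid)
  }
  do.call(rbind, rows)
}

# Nearest local minimum of x at or before index i (search floor lo);
# falls back to lo.
local_min_before <- function(x, i, lo) {
  j <- i
  while (j > lo) {
    left <- if (j - 1L >= lo) x[j - 1L] else Inf
    right <- if (j + 1L <= length(x)) x[j + 1L] else Inf
    if (x[j] <= left && x[j] <= right && j < i) return(j)
    j <- j - 1L
  }
  lo
}

# Nearest local minimum of x after index i (search ceiling hi);
# falls back to hi.
local_min_after <- function(x, i, hi) {
  j <- i + 1L
  while (j <= hi) {
    left <- x[j - 1L]
    right <- if (j + 1L <= length(x)) x[j + 1L] else Inf
    if (x[j] <= left && x[j] <= right) return(j)
    j <- j + 1L
  }
  hi
}

#' Morphology scalars of one delineated beat
#'
#' Computes the 15 per-beat scalars from a circulatory component and one
#' beat's landmarks: 5 amplitudes (peak, onset-to-peak, offset-to-peak,
#' and the max and mean of the two limb amplitudes), 4 durations
#' (onset-to-peak, peak-to-offset, total, and the pulse width, i.e. the
#' time the component stays above the half-amplitude level
#' `cc[peak] - a_mean/2`), 3 areas (trapezoidal integral of the component
#' above the onset-offset chord, split at the peak), and 3 curve lengths
#' (sum of `sqrt(dt^2 + dcc^2)` along each limb; seconds and signal units
#' mixed in one plane).
#'
#' @param cc Numeric circulatory component (or [rls_extract()] result).
#' @param onset_index,peak_index,offset_index Landmark sample indices
#'   (`onset < peak < offset`).
#' @param fs Sampling rate in Hz.
#' @param interpolate Linearly interpolate the pulse-width crossings
#'   between samples (default TRUE); with `FALSE` the width is the span of
#'   samples at or above the half level.
#' @return Named numeric vector with the 15 scalars (see `MORPH_NAMES`
#'   ordering in [feature_names()]).
#' @export
beat_morphology <- function(cc, onset_index, peak_index, offset_index, fs,
                            interpolate = TRUE) {
  if (inherits(cc, "circulatory_component")) cc <- cc$cc
  if (any(is.na(c(onset_index, peak_index, offset_index))) ||
      !(onset_index < peak_index && peak_index < offset_index))
    return(stats::setNames(rep(NA_real_, 15L), MORPH_NAMES))
  on <- onset_index; pk <- peak_index; off <- offset_index
  a_peak <- cc[pk]
  a_op <- cc[pk] - cc[on]
  a_fp <- cc[pk] - cc[off]
  a_max <- max(a_op, a_fp)
  a_mean <- (a_op + a_fp) / 2
  d_op <- (pk - on) / fs
  d_po <- (off - pk) / fs
  d_total <- d_op + d_po

  # pulse width at the half level referenced to the mean limb amplitude
  level <- cc[pk] - a_mean / 2
  t_left <- cross_left(cc, on, pk, level, interpolate)
  t_right <- cross_right(cc, pk, off, level, interpolate)
  d_pw <- (t_right - t_left) / fs

  # areas above the onset-offset chord (robust to residual drift)
  idx <- on:off
  chord <- cc[on] + (cc[off] - cc[on]) * (idx - on) / (off - on)
  dev <- cc[idx] - chord
  ar_op <- trapz_sum(dev[1:(pk - on + 1L)]) / fs
  ar_po <- trapz_sum(dev[(pk - on + 1L):length(dev)]) / fs

  dt <- 1 / fs
  seg_len <- function(a, b) {
    dy <- diff(cc[a:b])
    sum(sqrt(dt^2 + dy^2))
  }
  l_op <- seg_len(on, pk)
  l_po <- seg_len(pk, off)

  stats::setNames(
    c(a_peak, a_op, a_fp, a_max, a_mean,
      d_op, d_po, d_total, d_pw,
      ar_op, ar_po, ar_op + ar_po,
      l_op, l_po, l_op + l_po),
    MORPH_NAMES
  )
}

trapz_sum <- function(y) {
  if (length(y) < 2L) return(0)
  sum((y[-1L] + y[-length(y)]) / 2)
}

# Leftmost crossing (in samples, fractional when interpolating) of `level`
# on the rising limb [on, pk]; falls back to `on` when the limb never dips
# below the level.
cross_left <- function(cc, on, pk, level, interpolate) {
  j <- pk
  while (j > on && cc[j - 1L] >= level) j <- j - 1L
  if (j == on) return(as.numeric(on))
  below <- cc[j - 1L]; above <- cc[j]
  if (interpolate && above > below)
    (j - 1L) + (level - below) / (above - below)
  else as.numeric(j)
}

cross_right <- function(cc, pk, off, level, interpolate) {
  j <- pk
  while (j < off && cc[j + 1L] >= level) j <- j + 1L
  if (j == off) return(as.numeric(off))
  below <- cc[j + 1L]; above <- cc[j]
  if (interpolate && above > below)
    j + (above - level) / (above - below)
  else as.numeric(j)
}

#' Morphology table for all delineated beats
#'
#' @param cc Circulatory component ([rls_extract()] result or numeric).
#' @param delineation Output of [delineate_beats()].
#' @param fs Sampling rate in Hz.
#' @param interpolate Passed to [beat_morphology()].
#' @return `data.frame`: one row per beat with `peak_index`, `valid` and
#'   the 15 morphology scalars (NA for invalid beats).
#' @export
morphology_table <- function(cc, delineation, fs, interpolate = TRUE) {
  if (inherits(cc, "circulatory_component")) cc <- cc$cc
  vals <- lapply(seq_len(nrow(delineation)), function(i) {
    b <- delineation[i, ]
    if (!isTRUE(b$valid))
      return(stats::setNames(rep(NA_real_, 15L), MORPH_NAMES))
    beat_morphology(cc, b$onset_index, b$peak_index, b$offset_index, fs,
                    interpolate = interpolate)
  })
  cbind(delineation[, c("peak_index", "valid"), drop = FALSE],
        as.data.frame(do.call(rbind, vals)))
}

#' Compute the 66 features of one analysis window
#'
#' Per channel (carotid then abdominal): the standard deviation, skewness
#' and kurtosis of the window's circulatory-component samples (SD with the
#' n-1 denominator; skewness/kurtosis as uncorrected standardized moments,
#' normal kurtosis = 3), then the median and SD over the window's valid
#' beats of each of the 15 morphology scalars. Beats belong to the window
#' whose half-open interval contains their peak; windows with fewer than 2
#' valid beats in either channel are marked unusable (`usable`
#' attribute FALSE, morphology statistics NA).
#'
#' @param cc_c,cc_a Circulatory components (numeric or [rls_extract()]
#'   results) of the carotid and abdominal channel.
#' @param morph_c,morph_a [morphology_table()] outputs for each channel.
#' @param window_start_s Window start in seconds.
#' @param fs Sampling rate in Hz.
#' @param win_s Window length in seconds (default 10).
#' @return Named numeric vector of length 66 (names from
#'   [feature_names()]), with attribute `usable`.
#' @export
window_features <- function(cc_c, cc_a, morph_c, morph_a, window_start_s,
                            fs, win_s = 10) {
  if (inherits(cc_c, "circulatory_component")) cc_c <- cc_c$cc
  if (inherits(cc_a, "circulatory_component")) cc_a <- cc_a$cc
  k0 <- floor(window_start_s * fs + 1e-9) + 1L
  k1 <- floor((window_start_s + win_s) * fs + 1e-9)
  if (k0 < 1L || k1 > length(cc_c) || k1 > length(cc_a))
    stop_bcg("analysis window outside the signal", class = "bcgco_range_error")
  usable <- TRUE
  block <- function(cc, morph) {
    seg <- cc[k0:k1]
    stats3 <- c(stats::sd(seg), moment_skewness(seg), moment_kurtosis(seg))
    inb <- morph$valid & morph$peak_index >= k0 & morph$peak_index <= k1
    m <- morph[inb, MORPH_NAMES, drop = FALSE]
    if (nrow(m) < 2L) {
      usable <<- FALSE
      med <- rep(NA_real_, 15L); sdv <- rep(NA_real_, 15L)
    } else {
      med <- vapply(m, stats::median, numeric(1))
      sdv <- vapply(m, stats::sd, numeric(1))
    }
    c(stats3, med, sdv)
  }
  vals <- c(block(cc_c, morph_c), block(cc_a, morph_a))
  names(vals) <- feature_names()
  attr(vals, "usable") <- usable
  vals
}

#' Feature table of a record
#'
#' Full feature-extraction path for one (segment) record: band-pass the
#' ECG (0.5-30 Hz) and the two BCG channels (0.5-3 Hz), detect QRS
#' complexes, extract both circulatory components by QRS-referenced RLS,
#' delineate beats, and compute the 66 features plus the median reference
#' CO on 10-s windows with 80% overlap.
#'
#' @param record A [bcg_record()] (typically a segment from
#'   [extract_segments()]).
#' @param config A [pipeline_config()]; defaults control filter bands, RLS
#'   parameters and windowing.
#' @return `data.frame` with one row per window: `subject_id`, `phase`,
#'   `window_start_s`, the 66 feature columns, `target_co` and `usable`.
#'   Returns zero rows when the segment is too short or QRS detection finds
#'   fewer than 3 beats.
#' @export
compute_feature_table <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "bcg_record"))
  fs <- record$fs_signal
  dur <- record_duration(record)
  starts <- make_windows(dur, config$win_s, config$overlap)
  if (!length(starts)) return(empty_feature_table())

  ecg_f <- bandpass(record$ecg, fs, config$ecg_band[1], config$ecg_band[2],
                    config$filter_order)
  qrs <- detect_qrs(ecg_f, fs)
  if (length(qrs$indices) < 3L) return(empty_feature_table())

  params <- rls_params(n_taps = round(config$rls_taps_s * fs),
                       lam = config$rls_lambda)
  proc <- lapply(stats::setNames(nm = c("carotid", "abdominal")), function(ch) {
    x <- if (ch == "carotid") record$bcg_c else record$bcg_a
    xf <- bandpass(x, fs, config$bcg_band[1], config$bcg_band[2],
                   config$filter_order)
    comp <- rls_extract(xf, qrs, fs, params, source_channel = ch,
                        warmup_beats = config$warmup_beats)
    delin <- delineate_beats(comp, qrs, fs)
    list(cc = comp$cc, morph = morphology_table(comp, delin, fs))
  })

  phase_of <- function(t) {
    ph <- record$phases
    if (!nrow(ph)) return(NA_character_)
    hit <- which(ph$start_s <= t + 1e-9 & t < ph$end_s - 1e-9)
    if (length(hit)) ph$label[hit[1L]] else NA_character_
  }

  rows <- lapply(starts, function(s0) {
    fv <- window_features(proc$carotid$cc, proc$abdominal$cc,
                          proc$carotid$morph, proc$abdominal$morph,
                          s0, fs, config$win_s)
    df <- as.data.frame(as.list(fv))
    df$subject_id <- record$subject_id
    df$phase <- phase_of(s0 + config$win_s / 2)
    df$window_start_s <- s0
    df$target_co <- window_target_co(record, s0, config$win_s)
    df$usable <- attr(fv, "usable")
    df
  })
  out <- do.call(rbind, rows)
  out[, c("subject_id", "phase", "window_start_s", feature_names(),
          "target_co", "usable")]
}

empty_feature_table <- function() {
  cols <- c("subject_id", "phase", "window_start_s", feature_names(),
            "target_co", "usable")
  df <- as.data.frame(stats::setNames(rep(list(numeric()), length(cols)), cols))
  df$subject_id <- character(); df$phase <- character(); df$usable <- logical()
  df
}
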