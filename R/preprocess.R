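#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filters a signal with a 4th-order Butterworth design applied
#' forward-backward (`signal::filtfilt`), so the output has no group delay
#' and beat landmarks stay aligned across channels. The input is
#' reflect-padded by one filter-transient length (`3 / lo` seconds, capped
#' at the signal length) before filtering to suppress edge transients on
#' short segments. ECG uses 0.5-30 Hz, BCG 0.5-3 Hz.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz; must satisfy `0 < lo < hi < fs/2`.
#' @param order Butterworth order of the band-pass prototype (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, lo, hi, order = 4) {
  if (!is_scalar_number(lo) || !is_scalar_number(hi) ||
      lo <= 0 || hi <= lo || hi >= fs / 2)
    stop_bcg("band edges must satisfy 0 < lo < hi < fs/2",
             class = "bcgco_parameter_error")
  n <- length(x)
  if (n < 3L * (2L * order + 1L))
    stop_bcg("signal too short for the filter transient",
             class = "bcgco_insufficient_data_error")
  filt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  pad <- min(n - 1L, round(3 * fs / lo))
  xp <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  yp <- signal::filtfilt(filt, xp)
  yp[(pad + 1L):(pad + n)]
}

#' QRS train
#'
#' Strictly increasing sample indices of detected QRS complexes.
#'
#' @param indices Integer sample positions (1-based), strictly increasing.
#' @param fs Sampling rate in Hz.
#' @param n_samples Optional signal length for bounds checking.
#' @return An object of class `qrs_train` with elements `indices` and `fs`.
#' @export
qrs_train <- function(indices, fs, n_samples = NULL) {
  indices <- as.integer(indices)
  stopifnot(is_scalar_number(fs), fs > 0)
  if (length(indices)) {
    if (any(diff(indices) <= 0))
      stop_bcg("QRS indices must be strictly increasing",
               class = "bcgco_consistency_error")
    if (any(diff(indices) < 0.2 * fs))
      stop_bcg("QRS train violates the 0.2 s refractory period",
               class = "bcgco_consistency_error")
    if (indices[1L] < 1L ||
        (!is.null(n_samples) && indices[length(indices)] > n_samples))
      stop_bcg("QRS indices outside the signal", class = "bcgco_consistency_error")
  }
  structure(list(indices = indices, fs = fs), class = "qrs_train")
}

#' @export
print.qrs_train <- function(x, ...) {
  cat(sprintf("<qrs_train> %d beats @ %g Hz", length(x$indices), x$fs))
  if (length(x$indices) > 1L)
    cat(sprintf(", mean HR %.1f bpm",
                60 / mean(diff(x$indices) / x$fs)))
  cat("\n")
  invisible(x)
}

#' Detect QRS complexes (Hamilton-Tompkins)
#'
#' Runs the Hamilton-Tompkins detector on a band-passed (0.5-30 Hz) ECG:
#' differentiation, rectification, 80-ms moving-window integration, peak
#' picking, adaptive dual signal/noise thresholds with search-back for
#' missed beats, and a 0.2 s refractory period. Each detection is refined to
#' the largest absolute ECG deflection near the integrated-signal peak.
#'
#' @param ecg Preprocessed ECG (numeric).
#' @param fs Sampling rate in Hz.
#' @param threshold_coef Fraction of the signal/noise estimate gap placed
#'   above the noise estimate for the detection threshold (default 0.3125).
#' @return A [qrs_train()] (possibly empty for peak-free input).
#' @export
detect_qrs <- function(ecg, fs, threshold_coef = 0.3125) {
  n <- length(ecg)
  if (n < 2 * fs)
    stop_bcg("ECG shorter than 2 s: not enough data for QRS detection",
             class = "bcgco_insufficient_data_error")
  refractory <- round(0.2 * fs)

  # feature signal: derivative -> rectify -> moving-window integration (80 ms)
  d <- c(diff(ecg), 0)
  r <- abs(d)
  w <- max(1L, round(0.08 * fs))
  cs <- cumsum(c(0, r))
  mwi <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
  mwi <- c(rep(mwi[1L], w - 1L), mwi)  # align so mwi[i] ends at sample i

  if (max(mwi) <= 0) return(qrs_train(integer(), fs, n))

  # candidate peaks: local maxima of the integrated signal
  is_pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(is_pk)) return(qrs_train(integer(), fs, n))
  # thin candidates: keep the largest within each refractory-length run
  keep <- logical(length(is_pk))
  i <- 1L
  while (i <= length(is_pk)) {
    j <- i
    while (j < length(is_pk) && is_pk[j + 1L] - is_pk[i] < refractory) j <- j + 1L
    grp <- i:j
    keep[grp[which.max(mwi[is_pk[grp]])]] <- TRUE
    i <- j + 1L
  }
  pk_idx <- is_pk[keep]
  pk_amp <- mwi[pk_idx]

  # adaptive thresholds, initialized from the first 2 s
  init <- mwi[1:round(2 * fs)]
  spk <- 0.7 * max(init)
  npk <- 0.1 * max(init)
  beats <- integer()
  rr_hist <- numeric()
  last_amp <- -Inf
  rejected_idx <- integer(); rejected_amp <- numeric()

  for (p in seq_along(pk_idx)) {
    idx <- pk_idx[p]; amp <- pk_amp[p]
    th <- npk + threshold_coef * (spk - npk)
    accepted <- FALSE
    if (amp > th && (!length(beats) || idx - beats[length(beats)] >= refractory)) {
      beats <- c(beats, idx)
      spk <- 0.125 * amp + 0.875 * spk
      last_amp <- amp
      if (length(beats) > 1L) {
        rr_hist <- c(rr_hist, diff(utils::tail(beats, 2L)))
        if (length(rr_hist) > 8L) rr_hist <- utils::tail(rr_hist, 8L)
      }
      accepted <- TRUE
    } else if (amp > th && length(beats) &&
               idx - beats[length(beats)] < refractory && amp > last_amp) {
      # larger deflection inside the refractory window supersedes the last
      beats[length(beats)] <- idx
      spk <- 0.125 * amp + 0.875 * spk
      last_amp <- amp
      accepted <- TRUE
    }
    if (!accepted) {
      npk <- 0.125 * amp + 0.875 * npk
      rejected_idx <- c(rejected_idx, idx); rejected_amp <- c(rejected_amp, amp)
    }
    # search-back: if the expected beat did not arrive, re-examine rejected
    # peaks in the gap against half the threshold
    if (length(beats) && length(rr_hist) >= 2L) {
      mean_rr <- mean(rr_hist)
      if (idx - beats[length(beats)] > 1.5 * mean_rr) {
        gap <- rejected_idx > beats[length(beats)] + refractory &
          rejected_idx < idx - refractory
        if (any(gap)) {
          cand <- which(gap)
          best <- cand[which.max(rejected_amp[cand])]
          if (rejected_amp[best] > 0.5 * (npk + threshold_coef * (spk - npk))) {
            beats <- sort(c(beats, rejected_idx[best]))
            spk <- 0.125 * rejected_amp[best] + 0.875 * spk
            rejected_idx <- rejected_idx[-best]; rejected_amp <- rejected_amp[-best]
          }
        }
      }
    }
  }

  if (!length(beats)) return(qrs_train(integer(), fs, n))

  # refine each detection to the strongest ECG deflection near the MWI peak
  # (the MWI peak lags the R wave by about half the integration window)
  half_w <- round(w / 2)
  search <- round(0.1 * fs)
  refined <- vapply(beats, function(b) {
    c0 <- max(1L, b - half_w - search)
    c1 <- min(n, b - half_w + search)
    as.integer(c0 + which.max(abs(ecg[c0:c1])) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce refractory after refinement (keep the larger deflection)
  if (length(refined) > 1L) {
    out <- refined[1L]
    for (b in refined[-1L]) {
      if (b - out[length(out)] >= refractory) out <- c(out, b)
      else if (abs(ecg[b]) > abs(ecg[out[length(out)]])) out[length(out)] <- b
    }
    refined <- out
  }
  qrs_train(refined, fs, n)
}
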