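#' RLS parameters
#'
#' Tuning parameters of the QRS-referenced recursive least-squares filter.
#' `n_taps` spans the modeled beat response (default one second of samples,
#' covering a full beat at 60 bpm and above); `lam` is the forgetting
#' factor controlling how fast the template adapts beat-to-beat; `delta`
#' scales the initial inverse-correlation matrix `P(0) = delta * I`
#' (default `100 * var(input)`, resolved when the filter runs).
#'
#' @param n_taps Filter length in samples (`1 <= n_taps <= 2 * fs` at use).
#' @param lam Forgetting factor in `[0.9, 1]`.
#' @param delta Initial inverse-correlation scaling (> 0), or `NULL` to use
#'   `100 * var(input)`.
#' @return An object of class `rls_params`.
#' @export
rls_params <- function(n_taps = 250, lam = 0.999, delta = NULL) {
  stopifnot(is_scalar_number(n_taps), n_taps >= 1)
  if (!is_scalar_number(lam) || lam < 0.9 || lam > 1)
    stop_bcg("forgetting factor must be in [0.9, 1]",
             class = "bcgco_parameter_error")
  if (!is.null(delta) && (!is_scalar_number(delta) || delta <= 0))
    stop_bcg("delta must be > 0", class = "bcgco_parameter_error")
  structure(list(n_taps = as.integer(n_taps), lam = lam, delta = delta),
            class = "rls_params")
}

#' Build the QRS-referenced impulse-train reference
#'
#' @param qrs A [qrs_train()] with at least one beat.
#' @param n_samples Length of the reference to build.
#' @return Numeric vector of length `n_samples`: 1 at each QRS index, 0
#'   elsewhere.
#' @export
build_reference <- function(qrs, n_samples) {
  stopifnot(inherits(qrs, "qrs_train"))
  if (!length(qrs$indices))
    stop_bcg("cannot build a reference from an empty QRS train",
             class = "bcgco_empty_reference_error")
  if (any(qrs$indices > n_samples))
    stop_bcg("QRS indices exceed the requested reference length",
             class = "bcgco_consistency_error")
  ref <- numeric(n_samples)
  ref[qrs$indices] <- 1
  ref
}

#' Extract the beat-locked circulatory component of a BCG channel
#'
#' Runs a sample-wise RLS adaptive filter whose input is the unit-impulse
#' train at the QRS instants and whose desired signal is the preprocessed
#' BCG. The filter taps form the current estimate of the per-beat
#' circulatory response (allowed to evolve via the forgetting factor); the
#' filter output is the circulatory component `cc` and the error signal the
#' residual, so `cc + residual` reconstructs the input exactly. Overlapping
#' beat responses (RR shorter than the tap span) superpose linearly. The
#' component is zero before the first QRS-referenced response can exist,
#' and the first `warmup_beats` beats should be excluded from downstream
#' feature computation while the template converges.
#'
#' @param bcg Preprocessed (band-passed 0.5-3 Hz) BCG channel.
#' @param qrs A [qrs_train()] with at least 3 beats, sharing `fs` with `bcg`.
#' @param fs Sampling rate in Hz.
#' @param params An [rls_params()].
#' @param source_channel `"carotid"` or `"abdominal"` (metadata only).
#' @param warmup_beats Number of initial beats flagged unreliable
#'   (default 3).
#' @return An object of class `circulatory_component`: list with `cc`,
#'   `residual`, `taps` (final beat template), `source_channel`, `fs`,
#'   `warmup_beats` and `params`.
#' @export
rls_extract <- function(bcg, qrs, fs, params = rls_params(n_taps = round(fs)),
                        source_channel = c("carotid", "abdominal"),
                        warmup_beats = 3L) {
  source_channel <- match.arg(source_channel)
  stopifnot(inherits(qrs, "qrs_train"), inherits(params, "rls_params"))
  if (!isTRUE(all.equal(qrs$fs, fs)))
    stop_bcg("bcg and qrs sampling rates differ", class = "bcgco_consistency_error")
  if (length(qrs$indices) < 3L)
    stop_bcg("at least 3 beats are required for RLS extraction",
             class = "bcgco_insufficient_beats_error")
  if (any(!is.finite(bcg)))
    stop_bcg("non-finite values in the BCG input", class = "bcgco_data_error")
  if (params$n_taps > 2 * fs)
    stop_bcg("n_taps must not exceed 2 s of samples", class = "bcgco_parameter_error")
  delta <- params$delta
  if (is.null(delta)) {
    v <- stats::var(bcg)
    delta <- if (is.finite(v) && v > 0) 100 * v else 1
  }
  ref <- build_reference(qrs, length(bcg))
  fit <- rls_filter_cpp(ref, as.numeric(bcg), params$n_taps, params$lam, delta)
  structure(
    list(cc = fit$cc, residual = fit$residual, taps = fit$taps,
         source_channel = source_channel, fs = fs,
         warmup_beats = as.integer(warmup_beats),
         params = rls_params(params$n_taps, params$lam, delta)),
    class = "circulatory_component"
  )
}

#' @export
print.circulatory_component <- function(x, ...) {
  cat(sprintf("<circulatory_component> %s: %d samples @ %g Hz, %d taps, lambda %g\n",
              x$source_channel, length(x$cc), x$fs, x$params$n_taps,
              x$params$lam))
  invisible(x)
}
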