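#' Multichannel BCG/ECG record
#'
#' Container for one subject's time-aligned recording: ECG, carotid BCG
#' (`bcg_c`) and abdominal BCG (`bcg_a`) sampled at `fs_signal` (Hz), plus a
#' cardiac-output reference channel `co` (L/min) sampled at `fs_co` (Hz,
#' typically 0.5, i.e. one sample every 2 s). The CO sample `k` (0-based) is
#' located at `co_t0_offset + k / fs_co` seconds from signal start.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param ecg,bcg_c,bcg_a Numeric vectors of identical length: the ECG and
#'   the carotid/abdominal ballistocardiogram in sensor units.
#' @param co Numeric vector of cardiac-output reference samples in L/min.
#'   `NA` marks invalid samples; valid samples must be finite and positive.
#' @param fs_signal Sampling rate of `ecg`/`bcg_c`/`bcg_a` in Hz.
#' @param fs_co Sampling rate of `co` in Hz.
#' @param co_t0_offset Seconds from signal start to the first CO sample.
#' @param phases Optional `data.frame` with columns `label`, `start_s`,
#'   `end_s`: non-overlapping protocol-phase annotations within the record.
#'
#' @return An object of class `bcg_record`.
#' @export
bcg_record <- function(subject_id, ecg, bcg_c, bcg_a, co,
                       fs_signal = 250, fs_co = 0.5,
                       co_t0_offset = 0, phases = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  ecg <- as.numeric(ecg); bcg_c <- as.numeric(bcg_c); bcg_a <- as.numeric(bcg_a)
  co <- as.numeric(co)
  if (!(length(ecg) == length(bcg_c) && length(ecg) == length(bcg_a)))
    stop_bcg("ecg, bcg_c and bcg_a must have identical length",
             class = "bcgco_consistency_error")
  if (!is_scalar_number(fs_signal) || fs_signal <= 0)
    stop_bcg("fs_signal must be a positive number", class = "bcgco_parameter_error")
  if (!is_scalar_number(fs_co) || fs_co <= 0)
    stop_bcg("fs_co must be a positive number", class = "bcgco_parameter_error")
  if (!is_scalar_number(co_t0_offset))
    stop_bcg("co_t0_offset must be a finite number", class = "bcgco_parameter_error")
  ok <- !is.na(co)
  if (any(!is.finite(co[ok]) | co[ok] <= 0))
    stop_bcg("valid CO samples must be finite and > 0",
             class = "bcgco_consistency_error")
  dur <- length(ecg) / fs_signal
  phases <- validate_phases(phases, dur)
  structure(
    list(subject_id = subject_id, fs_signal = fs_signal, fs_co = fs_co,
         ecg = ecg, bcg_c = bcg_c, bcg_a = bcg_a, co = co,
         co_t0_offset = co_t0_offset, phases = phases),
    class = "bcg_record"
  )
}

validate_phases <- function(phases, duration_s) {
  if (is.null(phases) || nrow(as.data.frame(phases)) == 0L) {
    return(data.frame(label = character(), start_s = numeric(),
                      end_s = numeric(), stringsAsFactors = FALSE))
  }
  phases <- as.data.frame(phases, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "start_s", "end_s") %in% names(phases)))
  phases <- phases[order(phases$start_s), , drop = FALSE]
  rownames(phases) <- NULL
  eps <- 1e-9
  if (any(phases$end_s - phases$start_s <= 0))
    stop_bcg("phase intervals must have positive duration",
             class = "bcgco_consistency_error")
  if (any(phases$start_s < -eps) || any(phases$end_s > duration_s + eps))
    stop_bcg("phase intervals must lie within the record",
             class = "bcgco_consistency_error")
  if (nrow(phases) > 1L &&
      any(phases$start_s[-1L] < phases$end_s[-nrow(phases)] - eps))
    stop_bcg("phase intervals must not overlap",
             class = "bcgco_consistency_error")
  phases
}

#' @export
print.bcg_record <- function(x, ...) {
  n <- length(x$ecg)
  cat(sprintf("<bcg_record> subject %s: %.1f s @ %g Hz (%d samples), %d CO samples @ %g Hz\n",
              x$subject_id, n / x$fs_signal, x$fs_signal, n,
              length(x$co), x$fs_co))
  if (nrow(x$phases))
    cat("  phases:", paste(sprintf("%s [%g, %g)", x$phases$label,
                                   x$phases$start_s, x$phases$end_s),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Record duration in seconds
#' @param record A [bcg_record()].
#' @return Duration of the signal channels in seconds.
#' @export
record_duration <- function(record) length(record$ecg) / record$fs_signal

# Timestamps (s from signal start) of the CO samples of a record.
co_timestamps <- function(record) {
  record$co_t0_offset + (seq_along(record$co) - 1L) / record$fs_co
}

#' Write a record to disk
#'
#' On-disk layout: `<path>.yaml` holds the metadata (subject id, rates, CO
#' offset, phases); `<path>_signals.csv` the three signal channels;
#' `<path>_co.csv` the CO channel. Numbers are written with 17 significant
#' digits so a write/read cycle is bit-exact.
#'
#' @param record A [bcg_record()].
#' @param path Base path (no extension); directories must exist.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "bcg_record"))
  meta <- list(
    format = "bcgco-record-v1",
    subject_id = record$subject_id,
    fs_signal = num_to_chr(record$fs_signal),
    fs_co = num_to_chr(record$fs_co),
    co_t0_offset = num_to_chr(record$co_t0_offset),
    n_signal = length(record$ecg),
    n_co = length(record$co),
    channels = c("ecg", "bcg_c", "bcg_a"),
    phases = if (nrow(record$phases)) lapply(seq_len(nrow(record$phases)), function(i)
      list(label = record$phases$label[i],
           start_s = num_to_chr(record$phases$start_s[i]),
           end_s = num_to_chr(record$phases$end_s[i]))) else list()
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  sig <- data.frame(ecg = num_to_chr(record$ecg),
                    bcg_c = num_to_chr(record$bcg_c),
                    bcg_a = num_to_chr(record$bcg_a))
  utils::write.csv(sig, paste0(path, "_signals.csv"), row.names = FALSE,
                   quote = FALSE)
  co_chr <- ifelse(is.na(record$co), "NA", num_to_chr(record$co))
  utils::write.csv(data.frame(co = co_chr), paste0(path, "_co.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a record from disk
#'
#' @param path Base path as used by [write_record()].
#' @param dialect On-disk dialect; only `"csv"` (the native CSV + YAML
#'   sidecar layout) is supported.
#' @return A validated [bcg_record()].
#' @export
read_record <- function(path, dialect = "csv") {
  dialect <- match.arg(dialect, c("csv", "wfdb"))
  if (dialect == "wfdb")
    stop_bcg("the WFDB dialect is not supported by this reader",
             class = "bcgco_format_error")
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path))
    stop_bcg("metadata file not found: ", meta_path, class = "bcgco_format_error")
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$format) || !identical(meta$format, "bcgco-record-v1"))
    stop_bcg("unrecognized record format in ", meta_path,
             class = "bcgco_format_error")
  need <- c("subject_id", "fs_signal", "fs_co", "co_t0_offset", "channels")
  if (!all(need %in% names(meta)))
    stop_bcg("malformed record header: missing ",
             paste(setdiff(need, names(meta)), collapse = ", "),
             class = "bcgco_format_error")
  sig <- utils::read.csv(paste0(path, "_signals.csv"),
                         colClasses = "character")
  for (ch in c("ecg", "bcg_c", "bcg_a"))
    if (!ch %in% names(sig))
      stop_bcg("signal file is missing channel '", ch, "'",
               class = "bcgco_consistency_error")
  co <- utils::read.csv(paste0(path, "_co.csv"), colClasses = "character")$co
  bcg_record(
    subject_id = meta$subject_id,
    ecg = as.numeric(sig$ecg), bcg_c = as.numeric(sig$bcg_c),
    bcg_a = as.numeric(sig$bcg_a),
    co = suppressWarnings(as.numeric(co)),
    fs_signal = as.numeric(meta$fs_signal), fs_co = as.numeric(meta$fs_co),
    co_t0_offset = as.numeric(meta$co_t0_offset),
    phases = if (length(meta$phases)) do.call(rbind, lapply(meta$phases, function(p)
      data.frame(label = p$label, start_s = as.numeric(p$start_s),
                 end_s = as.numeric(p$end_s), stringsAsFactors = FALSE)))
    else NULL
  )
}

# Phase labels excluded from analysis unless explicitly overridden: both were
# too artifact-ridden for morphological analysis.
EXCLUDED_PHASES <- c("Hyperventilation", "AmbulanceTour", "Ambulance Tour")

#' Extract annotated segments from a record
#'
#' Cuts artifact-free segments out of a record. Sample values are carried
#' over unchanged (no resampling); CO samples whose timestamps fall inside
#' `[start_s, end_s)` are kept with the offset adjusted to the new time
#' origin. Segments labelled Hyperventilation or AmbulanceTour are dropped
#' with a warning unless `keep_excluded = TRUE`.
#'
#' @param record A [bcg_record()].
#' @param specs `data.frame` with columns `label`, `start_s`, `end_s`
#'   (seconds from record start).
#' @param keep_excluded Keep segments from the excluded-by-default phases.
#' @return A list of `bcg_record` segments (possibly shorter than
#'   `nrow(specs)` when excluded labels are dropped).
#' @export
extract_segments <- function(record, specs, keep_excluded = FALSE) {
  stopifnot(inherits(record, "bcg_record"))
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "start_s", "end_s") %in% names(specs)))
  dur <- record_duration(record)
  out <- list()
  for (i in seq_len(nrow(specs))) {
    lab <- specs$label[i]; s0 <- specs$start_s[i]; s1 <- specs$end_s[i]
    if (s1 <= s0)
      stop_bcg("segment spec has non-positive duration", class = "bcgco_range_error")
    if (s0 < 0 || s1 > dur + 1e-9)
      stop_bcg(sprintf("segment [%g, %g) outside record bounds [0, %g)", s0, s1, dur),
               class = "bcgco_range_error")
    if (lab %in% EXCLUDED_PHASES && !keep_excluded) {
      warning(sprintf("dropping excluded-by-default segment '%s' [%g, %g)",
                      lab, s0, s1), call. = FALSE)
      next
    }
    fs <- record$fs_signal
    # sample k (1-based) sits at (k-1)/fs; keep t in [s0, s1)
    k0 <- floor(s0 * fs + 1e-9) + 1L
    k1 <- ceiling(s1 * fs - 1e-9)
    tco <- co_timestamps(record)
    keep_co <- which(tco >= s0 - 1e-9 & tco < s1 - 1e-9)
    out[[length(out) + 1L]] <- bcg_record(
      subject_id = record$subject_id,
      ecg = record$ecg[k0:k1], bcg_c = record$bcg_c[k0:k1],
      bcg_a = record$bcg_a[k0:k1],
      co = record$co[keep_co],
      fs_signal = fs, fs_co = record$fs_co,
      co_t0_offset = if (length(keep_co)) tco[keep_co[1L]] - s0 else 0,
      phases = data.frame(label = lab, start_s = 0,
                          end_s = (k1 - k0 + 1L) / fs,
                          stringsAsFactors = FALSE)
    )
  }
  out
}

#' Median reference CO inside an analysis window
#'
#' @param record A [bcg_record()].
#' @param window_start_s Window start in seconds from record start.
#' @param window_len_s Window length in seconds.
#' @return Median of the CO samples whose timestamps fall in
#'   `[window_start_s, window_start_s + window_len_s)`; `NA_real_` when no
#'   valid CO sample falls in the window.
#' @export
window_target_co <- function(record, window_start_s, window_len_s) {
  stopifnot(inherits(record, "bcg_record"))
  if (window_start_s < -1e-9 ||
      window_start_s + window_len_s > record_duration(record) + 1e-9)
    stop_bcg("window outside record bounds", class = "bcgco_range_error")
  tco <- co_timestamps(record)
  inside <- tco >= window_start_s - 1e-9 &
    tco < window_start_s + window_len_s - 1e-9
  vals <- record$co[inside]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  stats::median(vals)
}
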