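#' Pipeline configuration
#'
#' Collects every stage's tunable parameters with validated defaults: the
#' ECG and BCG band-pass edges (0.5-30 and 0.5-3 Hz), the filter order,
#' the RLS tap span (0.7 s: long enough for the mechanical response and
#' its filter undershoot, short enough to stay below the shortest resting
#' RR interval so every tap lag is re-excited each beat and the template
#' stays identifiable under forgetting), forgetting factor (0.999) and
#' warm-up beats (3), the analysis-window length (10 s) and overlap (0.8), the
#' patient-wise split fraction (0.75) and seed, the CV fold count (5), the
#' PTA add/remove counts (3/2), the selection tolerance (1e-4) and the
#' baseline feature of the wrapper (median total fluctuation duration of
#' the carotid component).
#'
#' @param ecg_band,bcg_band Band edges in Hz, length-2.
#' @param filter_order Butterworth order.
#' @param rls_taps_s RLS tap span in seconds.
#' @param rls_lambda RLS forgetting factor.
#' @param warmup_beats Initial beats excluded from features.
#' @param win_s,overlap Analysis-window length (s) and fractional overlap.
#' @param dev_fraction,split_seed Patient-wise split parameters.
#' @param cv_folds Cross-validation folds.
#' @param pta_l,pta_r Features added/removed per PTA iteration.
#' @param tol Relative CV-MSE decrease required to accept a change.
#' @param baseline_feature Baseline feature of the wrapper.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(ecg_band = c(0.5, 30), bcg_band = c(0.5, 3),
                            filter_order = 4,
                            rls_taps_s = 0.7, rls_lambda = 0.999,
                            warmup_beats = 3L,
                            win_s = 10, overlap = 0.8,
                            dev_fraction = 0.75, split_seed = 1L,
                            cv_folds = 5L, pta_l = 3L, pta_r = 2L,
                            tol = 1e-4,
                            baseline_feature = "ccc_med_d_total") {
  check <- function(ok, msg) if (!ok)
    stop_bcg(msg, class = "bcgco_configuration_error")
  check(length(ecg_band) == 2 && ecg_band[1] > 0 && ecg_band[1] < ecg_band[2],
        "invalid ECG band")
  check(length(bcg_band) == 2 && bcg_band[1] > 0 && bcg_band[1] < bcg_band[2],
        "invalid BCG band")
  check(is_scalar_number(rls_taps_s) && rls_taps_s > 0 && rls_taps_s <= 2,
        "rls_taps_s must be in (0, 2]")
  check(is_scalar_number(rls_lambda) && rls_lambda >= 0.9 && rls_lambda <= 1,
        "rls_lambda must be in [0.9, 1]")
  check(is_scalar_number(overlap) && overlap >= 0 && overlap < 1,
        "overlap must be in [0, 1)")
  check(is_scalar_number(win_s) && win_s > 0, "win_s must be positive")
  check(is_scalar_number(dev_fraction) && dev_fraction > 0 && dev_fraction < 1,
        "dev_fraction must be in (0, 1)")
  check(cv_folds >= 2L, "cv_folds must be >= 2")
  check(pta_l >= 1L && pta_r >= 0L && pta_l > pta_r,
        "PTA requires l >= 1 and l > r")
  check(is_scalar_number(tol) && tol >= 0, "tol must be >= 0")
  structure(list(ecg_band = ecg_band, bcg_band = bcg_band,
                 filter_order = filter_order, rls_taps_s = rls_taps_s,
                 rls_lambda = rls_lambda, warmup_beats = as.integer(warmup_beats),
                 win_s = win_s, overlap = overlap,
                 dev_fraction = dev_fraction, split_seed = as.integer(split_seed),
                 cv_folds = as.integer(cv_folds), pta_l = as.integer(pta_l),
                 pta_r = as.integer(pta_r), tol = tol,
                 baseline_feature = baseline_feature),
            class = "pipeline_config")
}

#' Run the full CO-estimation pipeline
#'
#' Executes, for a set of records, the complete chain: preprocessing, QRS
#' detection, RLS circulatory-component extraction, window feature
#' computation, patient-wise 75/25 split, mRMR-seeded PTA(3,2) wrapper
#' selection with subject-wise fivefold CV on the development set, final
#' refit, and agreement evaluation on both sets. Only usable windows with
#' a CO target enter the model.
#'
#' @param records List of [bcg_record()] (e.g. from [simulate_cohort()] or
#'   [extract_segments()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: writes `features.csv`, `model.yaml`,
#'   `report.json` and `manifest.json`.
#' @return List with `features` (full window table), `split`, `selection`
#'   (the [pta_select()] result), `model`, `report_dev`, `report_val`.
#' @export
run_pipeline <- function(records, config = pipeline_config(), out_dir = NULL) {
  stopifnot(is.list(records), length(records) >= 2L,
            inherits(config, "pipeline_config"))
  features <- do.call(rbind, lapply(records, compute_feature_table,
                                    config = config))
  usable <- features$usable & !is.na(features$target_co) &
    stats::complete.cases(features[, feature_names()])
  dat <- features[usable, , drop = FALSE]
  if (nrow(dat) < 20L)
    stop_bcg("too few usable windows to fit a model", class = "bcgco_fitting_error")

  split <- split_by_subject(dat, config$dev_fraction, config$split_seed)
  X_dev <- split$dev[, feature_names()]
  y_dev <- split$dev$target_co
  selection <- pta_select(X_dev, y_dev, split$dev$subject_id,
                          l = config$pta_l, r = config$pta_r,
                          k = config$cv_folds,
                          baseline_feature = config$baseline_feature,
                          tol = config$tol)
  model <- selection$model
  pred_dev <- predict(model, split$dev)
  report_dev <- agreement(y_dev, pred_dev, split$dev$phase)
  report_val <- NULL
  if (nrow(split$val) >= 2L) {
    pred_val <- predict(model, split$val)
    report_val <- agreement(split$val$target_co, pred_val, split$val$phase)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    write_model(model, file.path(out_dir, "model.yaml"))
    report <- list(dev = unclass_report(report_dev),
                   val = if (!is.null(report_val)) unclass_report(report_val))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest <- list(package = "bcgco",
                     version = as.character(utils::packageVersion("bcgco")),
                     config = unclass(config),
                     n_records = length(records),
                     n_windows = nrow(features),
                     n_usable = nrow(dat),
                     dev_subjects = split$dev_subjects,
                     val_subjects = split$val_subjects)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(features = features, split = split, selection = selection,
       model = model, report_dev = report_dev, report_val = report_val)
}

unclass_report <- function(rep) {
  out <- unclass(rep)
  if (!is.null(out$per_phase)) out$per_phase <- as.data.frame(out$per_phase)
  out
}
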