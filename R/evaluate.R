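#' Agreement between estimated and reference cardiac output
#'
#' Computes the full agreement suite on per-window CO pairs with the error
#' defined as reference minus estimate: mean absolute error
#' `MAE = mean(|y - yhat|)`, mean squared error `MSE = mean((y - yhat)^2)`,
#' percentage error `PE = 100 * 1.96 * sigma / mean(y)` (Critchley;
#' `sigma` = SD of the error, n-1 denominator), Bland-Altman bias and 95%
#' limits of agreement `bias +/- 1.96 sigma`, and R-squared as the squared
#' Pearson correlation of estimate and reference. Estimates are considered
#' interchangeable with the reference when PE <= 30%. With phase labels,
#' per-phase quartile summaries of the absolute error are added.
#'
#' @param y Reference CO per window (L/min).
#' @param yhat Estimated CO per window (L/min).
#' @param phases Optional phase label per window.
#' @return An object of class `co_agreement`: `n`, `mae`, `mse`, `pe`,
#'   `bias`, `sigma`, `loa_low`, `loa_high`, `r2`, `interchangeable`,
#'   and (when phases are given) `per_phase`.
#' @export
agreement <- function(y, yhat, phases = NULL) {
  if (length(y) != length(yhat))
    stop_bcg("y and yhat must have equal length", class = "bcgco_consistency_error")
  if (length(y) < 2L)
    stop_bcg("at least 2 windows are required", class = "bcgco_insufficient_data_error")
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stop_bcg("non-finite CO values", class = "bcgco_data_error")
  e <- y - yhat
  ybar <- mean(y)
  if (ybar == 0)
    stop_bcg("mean reference CO is zero: PE undefined", class = "bcgco_data_error")
  sigma <- stats::sd(e)
  bias <- mean(e)
  r2 <- if (stats::sd(y) > 0 && stats::sd(yhat) > 0)
    stats::cor(y, yhat)^2 else NA_real_
  pe <- 100 * 1.96 * sigma / ybar
  out <- list(
    n = length(y),
    mae = mean(abs(e)),
    mse = mean(e^2),
    pe = pe,
    bias = bias,
    sigma = sigma,
    loa_low = bias - 1.96 * sigma,
    loa_high = bias + 1.96 * sigma,
    r2 = r2,
    interchangeable = pe <= 30
  )
  if (!is.null(phases)) {
    stopifnot(length(phases) == length(y))
    ph <- split(abs(e), phases)
    out$per_phase <- do.call(rbind, lapply(names(ph), function(p) {
      q <- stats::quantile(ph[[p]], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      data.frame(phase = p, n = length(ph[[p]]), min = q[1], q1 = q[2],
                 median = q[3], q3 = q[4], max = q[5],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(out, class = "co_agreement")
}

#' @export
print.co_agreement <- function(x, ...) {
  cat(sprintf("<co_agreement> n = %d windows\n", x$n))
  cat(sprintf("  MAE  %.3f L/min   MSE  %.3f L^2/min^2\n", x$mae, x$mse))
  cat(sprintf("  bias %.3f L/min   sigma %.3f L/min\n", x$bias, x$sigma))
  cat(sprintf("  LOA95 [%.3f, %.3f] L/min\n", x$loa_low, x$loa_high))
  cat(sprintf("  PE   %.1f %%  (interchangeable: %s)   R2 %.3f\n",
              x$pe, if (isTRUE(x$interchangeable)) "yes" else "no", x$r2))
  if (!is.null(x$per_phase)) {
    cat("  |error| by phase (median [q1, q3]):\n")
    for (i in seq_len(nrow(x$per_phase)))
      cat(sprintf("    %-16s n=%-4d %.3f [%.3f, %.3f]\n",
                  x$per_phase$phase[i], x$per_phase$n[i],
                  x$per_phase$median[i], x$per_phase$q1[i],
                  x$per_phase$q3[i]))
  }
  invisible(x)
}

#' Bland-Altman plot of CO agreement
#'
#' Error (reference minus estimate) against the reference CO, with the
#' bias and the 95% limits of agreement.
#'
#' @param y,yhat Reference and estimated CO (L/min).
#' @return A `ggplot` object.
#' @export
plot_bland_altman <- function(y, yhat) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_bcg("ggplot2 is required for plotting", class = "bcgco_configuration_error")
  rep <- agreement(y, yhat)
  df <- data.frame(reference = y, error = y - yhat)
  ggplot2::ggplot(df, ggplot2::aes(x = reference, y = error)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = rep$bias, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(rep$loa_low, rep$loa_high),
                        linetype = "dotdash") +
    ggplot2::labs(x = "Reference CO (L/min)",
                  y = "Error, reference - estimate (L/min)")
}

#' Per-phase absolute-error boxplot
#'
#' @param y,yhat Reference and estimated CO (L/min).
#' @param phases Phase label per window.
#' @return A `ggplot` object.
#' @export
plot_phase_error <- function(y, yhat, phases) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_bcg("ggplot2 is required for plotting", class = "bcgco_configuration_error")
  df <- data.frame(phase = phases, abs_error = abs(y - yhat))
  ggplot2::ggplot(df, ggplot2::aes(x = phase, y = abs_error)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "|error| (L/min)")
}
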