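# Feature standardization, mRMR ranking, subject-wise cross-validated
# wrapper selection (Plus-l Take-Away-r), multiple linear regression, and
# the frozen published model.

#' Patient-wise development/validation split
#'
#' Randomly allocates whole subjects (never individual windows) to a
#' development and a validation set, 75/25 by default.
#'
#' @param features Feature table with a `subject_id` column.
#' @param dev_fraction Fraction of subjects in the development set.
#' @param seed Integer seed making the split reproducible.
#' @return List with `dev`, `val` (row subsets of `features`),
#'   `dev_subjects`, `val_subjects`.
#' @export
split_by_subject <- function(features, dev_fraction = 0.75, seed = 1L) {
  stopifnot("subject_id" %in% names(features))
  subjects <- sort(unique(features$subject_id))
  if (length(subjects) < 2L)
    stop_bcg("at least 2 subjects are required for a patient-wise split",
             class = "bcgco_split_error")
  n_dev <- round(dev_fraction * length(subjects))
  n_dev <- max(1L, min(length(subjects) - 1L, n_dev))
  perm <- with_local_seed(seed, sample(subjects))
  dev_subjects <- sort(perm[seq_len(n_dev)])
  val_subjects <- sort(setdiff(subjects, dev_subjects))
  list(dev = features[features$subject_id %in% dev_subjects, , drop = FALSE],
       val = features[features$subject_id %in% val_subjects, , drop = FALSE],
       dev_subjects = dev_subjects, val_subjects = val_subjects)
}

# Run expr under a temporary RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' mRMR feature ranking for a continuous target
#'
#' Greedy minimum-redundancy maximum-relevance ordering. Relevance of a
#' feature is its absolute Pearson correlation with the target; redundancy
#' is the mean absolute correlation with the already-ranked features. The
#' default scores candidates by relevance minus mean redundancy (the MID
#' difference form); `variant = "quotient"` divides instead. Constant
#' features get zero relevance and are ranked last with a warning.
#'
#' @param X Numeric matrix or data.frame of features (>= 2 columns).
#' @param y Numeric target (CO in L/min).
#' @param variant `"difference"` (default) or `"quotient"`.
#' @return Character vector: all feature names in rank order.
#' @export
mrmr_rank <- function(X, y, variant = c("difference", "quotient")) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2L, nrow(X) == length(y), nrow(X) >= 10L)
  nm <- colnames(X)
  sds <- apply(X, 2L, stats::sd)
  constant <- !is.finite(sds) | sds == 0
  if (any(constant))
    warning("constant feature(s) ranked last: ",
            paste(nm[constant], collapse = ", "), call. = FALSE)
  rel <- rep(0, ncol(X))
  rel[!constant] <- abs(stats::cor(X[, !constant, drop = FALSE], y))
  ranked <- integer()
  candidates <- which(!constant)
  if (length(candidates)) {
    first <- candidates[which.max(rel[candidates])]
    ranked <- first
    candidates <- setdiff(candidates, first)
    while (length(candidates)) {
      red <- vapply(candidates, function(j)
        mean(abs(stats::cor(X[, j], X[, ranked, drop = FALSE]))), numeric(1))
      score <- if (variant == "difference") rel[candidates] - red
      else rel[candidates] / pmax(red, .Machine$double.eps)
      pick <- candidates[which.max(score)]
      ranked <- c(ranked, pick)
      candidates <- setdiff(candidates, pick)
    }
  }
  nm[c(ranked, which(constant))]
}

# Standardized design matrix with squared terms for flagged features.
# means/sds come from the fitting data; squared terms are squares of the
# standardized values.
build_design <- function(X, features, squared, means, sds) {
  Z <- sweep(sweep(as.matrix(X[, features, drop = FALSE]), 2L, means, "-"),
             2L, sds, "/")
  colnames(Z) <- features
  if (any(squared)) {
    Z2 <- Z[, squared, drop = FALSE]^2
    colnames(Z2) <- paste0(features[squared], "__sq")
    Z <- cbind(Z, Z2)
  }
  Z
}

#' Subject-wise k-fold cross-validated MSE of a linear model
#'
#' Subjects are partitioned into `k` folds (deterministically, round-robin
#' over the sorted subject ids, so overlapping windows of one subject never
#' straddle folds). Per fold an ordinary least-squares model with the
#' declared squared terms is fitted on the training folds (standardization
#' constants from the training folds only) and scored by the mean squared
#' error on the held-out fold; the mean across folds is returned.
#'
#' @param X Feature matrix/data.frame.
#' @param y CO targets (L/min).
#' @param subjects Subject id per row.
#' @param features Character: columns of `X` entering the model.
#' @param squared Logical of the same length: include that feature's
#'   squared (standardized) term.
#' @param k Number of folds (default 5); requires >= k subjects.
#' @return Mean CV MSE in L^2/min^2.
#' @export
cv_mse <- function(X, y, subjects, features, squared = rep(FALSE, length(features)),
                   k = 5L) {
  stopifnot(length(features) >= 1L, length(squared) == length(features))
  us <- sort(unique(subjects))
  if (length(us) < k)
    stop_bcg("need at least k subjects for k subject-wise folds",
             class = "bcgco_fold_error")
  fold_of <- stats::setNames(((seq_along(us) - 1L) %% k) + 1L, us)
  fold <- fold_of[as.character(subjects)]
  mses <- vapply(seq_len(k), function(f) {
    tr <- fold != f; te <- !tr
    if (sum(te) < 2L || sum(tr) < 2L)
      stop_bcg("fold with fewer than 2 windows", class = "bcgco_fold_error")
    mu <- colMeans(as.matrix(X[tr, features, drop = FALSE]))
    sg <- apply(as.matrix(X[tr, features, drop = FALSE]), 2L, stats::sd)
    sg[!is.finite(sg) | sg == 0] <- 1
    Dtr <- build_design(X[tr, , drop = FALSE], features, squared, mu, sg)
    Dte <- build_design(X[te, , drop = FALSE], features, squared, mu, sg)
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Dtr), y[tr])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0  # drop aliased columns
    pred <- cbind(1, Dte) %*% beta
    mean((y[te] - pred)^2)
  }, numeric(1))
  mean(mses)
}

#' Plus-l Take-Away-r wrapper feature selection
#'
#' mRMR-seeded PTA(l, r) selection under subject-wise fivefold
#' cross-validation. The baseline is a single-feature linear regressor on
#' `baseline_feature` (by default the top mRMR feature; in the BCG pipeline
#' this is the median total fluctuation duration of the carotid circulatory
#' component). Each iteration stepwise-adds the `l` candidates with the
#' lowest CV-MSE and then stepwise-removes the `r` features whose removal
#' lowers it most, yielding the accepted (K+1)-feature model. Whenever a
#' feature is evaluated/selected its squared (standardized) term is also
#' tried and kept iff it decreases the CV-MSE. Iterations stop when the
#' accepted model no longer decreases the CV-MSE by more than a relative
#' `tol`; the final model is refitted on the whole development set.
#'
#' @param X Development feature matrix/data.frame (all 66 features in the
#'   BCG pipeline).
#' @param y Development CO targets (L/min).
#' @param subjects Subject id per row (grouped CV folds).
#' @param l,r Features added/removed per iteration (default 3/2).
#' @param k CV folds (default 5).
#' @param baseline_feature Name of the baseline feature; `NULL` picks the
#'   top-ranked mRMR feature.
#' @param tol Relative CV-MSE decrease required to accept a change
#'   (default 1e-4).
#' @param max_iter Safety cap on PTA iterations.
#' @return List with `model` (a [fit_linear()] model on the full set),
#'   `features`, `squared`, `cv_mse`, and `trace` (`data.frame` of
#'   add/remove/accept actions with CV-MSE).
#' @export
pta_select <- function(X, y, subjects, l = 3L, r = 2L, k = 5L,
                       baseline_feature = NULL, tol = 1e-4,
                       max_iter = 50L) {
  Xm <- as.data.frame(X)
  all_feats <- names(Xm)
  if (is.null(baseline_feature))
    baseline_feature <- mrmr_rank(Xm, y)[1L]
  if (!baseline_feature %in% all_feats)
    stop_bcg("baseline feature '", baseline_feature, "' not found",
             class = "bcgco_configuration_error")

  # a CV-MSE decrease only counts when it exceeds tol relative to the
  # current error, with an absolute floor so that numerically-zero errors
  # (perfect fits) cannot keep "improving" within floating-point noise
  mse_floor <- 1e-8 * stats::var(y)
  improved <- function(old, new) (old - new) > tol * max(old, mse_floor)

  trace <- list()
  log_row <- function(iter, action, feature, squared, mse) {
    trace[[length(trace) + 1L]] <<- data.frame(
      iteration = iter, action = action, feature = feature,
      squared = squared, cv_mse = mse, stringsAsFactors = FALSE)
  }
  eval_set <- function(feats, sq) cv_mse(Xm, y, subjects, feats, sq, k)

  # candidate evaluation: try the linear term and, per the squared-term
  # rule, its squared augmentation; keep the square iff it lowers CV-MSE
  eval_candidate <- function(feats, sq, f) {
    m_lin <- eval_set(c(feats, f), c(sq, FALSE))
    m_sq <- eval_set(c(feats, f), c(sq, TRUE))
    if (improved(m_lin, m_sq)) list(mse = m_sq, squared = TRUE)
    else list(mse = m_lin, squared = FALSE)
  }

  # baseline model (squared term tested as for any selected feature)
  base <- eval_candidate(character(), logical(), baseline_feature)
  S <- baseline_feature; SQ <- base$squared
  best_mse <- base$mse
  log_row(0L, "baseline", baseline_feature, base$squared, best_mse)

  for (iter in seq_len(max_iter)) {
    S_w <- S; SQ_w <- SQ
    # plus-l: stepwise-add the best candidate l times
    for (a in seq_len(l)) {
      cand <- setdiff(all_feats, S_w)
      if (!length(cand)) break
      evals <- lapply(cand, function(f) eval_candidate(S_w, SQ_w, f))
      mses <- vapply(evals, `[[`, numeric(1), "mse")
      pick <- which.min(mses)  # ties: lowest feature index
      S_w <- c(S_w, cand[pick]); SQ_w <- c(SQ_w, evals[[pick]]$squared)
      log_row(iter, "add", cand[pick], evals[[pick]]$squared, mses[pick])
    }
    # take-away-r: stepwise-remove the least useful feature r times
    for (b in seq_len(r)) {
      if (length(S_w) <= 1L) break
      mses <- vapply(seq_along(S_w), function(j)
        eval_set(S_w[-j], SQ_w[-j]), numeric(1))
      drop <- which.min(mses)
      log_row(iter, "remove", S_w[drop], SQ_w[drop], mses[drop])
      S_w <- S_w[-drop]; SQ_w <- SQ_w[-drop]
    }
    m_new <- eval_set(S_w, SQ_w)
    if (improved(best_mse, m_new)) {
      S <- S_w; SQ <- SQ_w; best_mse <- m_new
      log_row(iter, "accept", paste(S, collapse = "+"), any(SQ), best_mse)
    } else break
  }

  model <- fit_linear(Xm[, S, drop = FALSE], y, squared = SQ)
  list(model = model, features = S, squared = stats::setNames(SQ, S),
       cv_mse = best_mse, trace = do.call(rbind, trace))
}

#' Fit a multiple linear regression of CO on standardized features
#'
#' Ordinary least squares of the target on the standardized features (mean
#' 0, SD 1, constants estimated from the fitting set) plus the squared
#' standardized terms of flagged features.
#'
#' @param X Feature matrix/data.frame (columns = model features).
#' @param y CO targets in L/min.
#' @param squared Logical per feature: add its squared term.
#' @return An object of class `co_model`: selected feature names, squared
#'   flags, standardization means/SDs, intercept and coefficients.
#' @export
fit_linear <- function(X, y, squared = rep(FALSE, ncol(as.data.frame(X)))) {
  X <- as.data.frame(X)
  features <- names(X)
  p <- length(features) + sum(squared)
  if (nrow(X) < p + 1L)
    stop_bcg("need more rows than model terms", class = "bcgco_fitting_error")
  means <- vapply(X, mean, numeric(1))
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(!is.finite(sds) | sds <= 0))
    stop_bcg("constant feature(s) cannot be standardized: ",
             paste(features[!is.finite(sds) | sds <= 0], collapse = ", "),
             class = "bcgco_fitting_error")
  D <- build_design(X, features, squared, means, sds)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, D), y)
  if (fit$rank < ncol(D) + 1L) {
    aliased <- names(fit$coefficients)[is.na(fit$coefficients)]
    stop_bcg("rank-deficient design; aliased terms: ",
             paste(aliased, collapse = ", "), class = "bcgco_fitting_error")
  }
  beta <- fit$coefficients
  co_model(features = features,
           squared = stats::setNames(squared, features),
           means = means, sds = sds,
           intercept = unname(beta["(Intercept)"]),
           beta = beta[features],
           beta_sq = if (any(squared))
             stats::setNames(beta[paste0(features[squared], "__sq")],
                             features[squared]) else stats::setNames(numeric(), character()))
}

# Internal constructor for the regression-model class.
co_model <- function(features, squared, means, sds, intercept, beta, beta_sq) {
  structure(list(features = features, squared = squared, means = means,
                 sds = sds, intercept = intercept, beta = beta,
                 beta_sq = beta_sq),
            class = "co_model")
}

#' @export
print.co_model <- function(x, digits = 3, ...) {
  cat("<co_model> CO regression on", length(x$features), "features (",
      length(x$features) + sum(x$squared), "terms + intercept )\n")
  cat(sprintf("  intercept: %.*f L/min\n", digits, x$intercept))
  for (f in x$features) {
    line <- sprintf("  %+.3f * %s", x$beta[[f]], f)
    if (isTRUE(x$squared[[f]]))
      line <- paste0(line, sprintf("  %+.3f * %s^2", x$beta_sq[[f]], f))
    cat(line, "\n")
  }
  if (is.null(x$means)) cat("  standardization constants: not set\n")
  invisible(x)
}

#' Predict CO from a fitted model
#'
#' `yhat = b0 + sum_j beta_j v_j + sum_j beta'_j v_j^2` with
#' `v_j = (x_j - mean_j) / sd_j`.
#'
#' @param object A `co_model`.
#' @param newdata `data.frame`/matrix (or named vector) containing the
#'   model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of CO estimates in L/min.
#' @export
predict.co_model <- function(object, newdata, ...) {
  if (is.null(object$means) || is.null(object$sds))
    stop_bcg("standardization constants not set; supply means/SDs",
             class = "bcgco_configuration_error")
  if (is.vector(newdata) && !is.list(newdata))
    newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stop_bcg("missing feature(s): ", paste(missing, collapse = ", "),
             class = "bcgco_prediction_error")
  V <- sweep(sweep(as.matrix(newdata[, object$features, drop = FALSE]),
                   2L, object$means, "-"), 2L, object$sds, "/")
  yhat <- object$intercept + drop(V %*% object$beta)
  if (length(object$beta_sq)) {
    sq_feats <- names(object$beta_sq)
    yhat <- yhat + drop(V[, sq_feats, drop = FALSE]^2 %*% object$beta_sq)
  }
  unname(yhat)
}

#' The published fixed-coefficient CO model
#'
#' The frozen 9-term multiple linear regression of CO on five standardized
#' window features:
#' `yhat = 6.70 - 3.42 v1 + 2.47 v1^2 - 0.31 v2 + 0.19 v3 + 0.05 v3^2
#'  - 1.11 v4 + 1.00 v4^2 - 0.01 v5 + 0.24 v5^2`, where
#' v1 = median total fluctuation duration in the carotid component
#' (`ccc_med_d_total`), v2 = median peak-to-offset curve length in the
#' carotid component (`ccc_med_l_peak_offset`), v3 = skewness of the
#' abdominal component (`cca_skew`), v4 = median onset-to-peak duration in
#' the abdominal component (`cca_med_d_onset_peak`), and v5 = median
#' peak-to-offset curve length in the abdominal component
#' (`cca_med_l_peak_offset`). The standardization constants of the source
#' cohort are not public, so they must be supplied explicitly (or
#' `standardization = "identity"` for already-standardized inputs);
#' prediction without constants raises a configuration error.
#'
#' @param means,sds Named numeric vectors (names = the five feature names)
#'   with the standardization constants to apply.
#' @param standardization `"supplied"` (use `means`/`sds`) or `"identity"`
#'   (means 0, SDs 1).
#' @return A `co_model` with 5 base features and 4 squared terms.
#' @export
published_model <- function(means = NULL, sds = NULL,
                            standardization = c("supplied", "identity")) {
  standardization <- match.arg(standardization)
  features <- c("ccc_med_d_total", "ccc_med_l_peak_offset", "cca_skew",
                "cca_med_d_onset_peak", "cca_med_l_peak_offset")
  squared <- stats::setNames(c(TRUE, FALSE, TRUE, TRUE, TRUE), features)
  beta <- stats::setNames(c(-3.42, -0.31, 0.19, -1.11, -0.01), features)
  beta_sq <- stats::setNames(c(2.47, 0.05, 1.00, 0.24), features[squared])
  if (standardization == "identity") {
    means <- stats::setNames(rep(0, 5L), features)
    sds <- stats::setNames(rep(1, 5L), features)
  } else if (!is.null(means) || !is.null(sds)) {
    if (is.null(means) || is.null(sds) ||
        !all(features %in% names(means)) || !all(features %in% names(sds)))
      stop_bcg("means and sds must both be supplied and named for all five features",
               class = "bcgco_configuration_error")
    if (any(sds[features] <= 0))
      stop_bcg("standardization SDs must be positive",
               class = "bcgco_configuration_error")
    means <- means[features]; sds <- sds[features]
  }
  co_model(features = features, squared = squared, means = means, sds = sds,
           intercept = 6.70, beta = beta, beta_sq = beta_sq)
}

#' Serialize / read a CO regression model
#'
#' Versioned plain-text (YAML) representation; numbers are written with 17
#' significant digits so coefficients round-trip bit-exactly.
#'
#' @param model A `co_model`.
#' @param path File path.
#' @return `write_model`: `path` invisibly. `read_model`: the `co_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "co_model"))
  num_list <- function(x) if (is.null(x)) NULL else
    as.list(stats::setNames(num_to_chr(x), names(x)))
  obj <- list(
    format = "bcgco-model-v1",
    features = model$features,
    squared = as.list(model$squared),
    means = num_list(model$means),
    sds = num_list(model$sds),
    intercept = num_to_chr(model$intercept),
    beta = num_list(model$beta),
    beta_sq = num_list(model$beta_sq)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "bcgco-model-v1"))
    stop_bcg("unrecognized model format", class = "bcgco_format_error")
  num_vec <- function(x) if (is.null(x)) NULL else
    stats::setNames(as.numeric(unlist(x)), names(x))
  co_model(features = obj$features,
           squared = stats::setNames(as.logical(unlist(obj$squared)),
                                     names(obj$squared)),
           means = num_vec(obj$means), sds = num_vec(obj$sds),
           intercept = as.numeric(obj$intercept),
           beta = num_vec(obj$beta),
           beta_sq = if (length(obj$beta_sq)) num_vec(obj$beta_sq)
           else stats::setNames(numeric(), character()))
}
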