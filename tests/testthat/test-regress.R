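test_that("patient-wise split: subjects never straddle the two sets", {
  sim <- make_feature_sim(n = 400, n_subjects = 20)
  df <- data.frame(subject_id = sim$subjects, sim$X)
  sp <- split_by_subject(df, 0.75, seed = 4L)
  expect_length(sp$dev_subjects, 15)
  expect_length(sp$val_subjects, 5)
  expect_length(intersect(sp$dev_subjects, sp$val_subjects), 0)
  expect_equal(nrow(sp$dev) + nrow(sp$val), nrow(df))
  # determinism and seed sensitivity
  sp2 <- split_by_subject(df, 0.75, seed = 4L)
  expect_identical(sp$dev_subjects, sp2$dev_subjects)
  for (s in c(1L, 2L, 3L)) {
    spi <- split_by_subject(df, 0.75, seed = s)
    expect_length(intersect(spi$dev_subjects, spi$val_subjects), 0)
    expect_setequal(c(spi$dev_subjects, spi$val_subjects), unique(sim$subjects))
  }
  expect_error(split_by_subject(df[df$subject_id == "P01", ]),
               class = "bcgco_split_error")
})

test_that("mRMR ranks the informative feature first and penalizes redundancy", {
  sim <- make_feature_sim(n = 400, p = 6, seed = 8L)
  X <- sim$X
  y <- X$x3  # exact dependence
  expect_identical(mrmr_rank(X, y)[1], "x3")
  # a duplicate of the top feature is pushed below a mildly informative one
  X2 <- X
  X2$x4 <- X$x3                                     # duplicate of x3
  y2 <- X$x3 + 0.35 * X$x1 + rnorm(400, sd = 0.2)   # x1 mildly informative
  rk <- mrmr_rank(X2, y2)
  expect_identical(rk[1], "x3")
  expect_lt(which(rk == "x1"), which(rk == "x4"))
  # constant features go last, with a warning
  X3 <- X; X3$x6 <- 1
  expect_warning(rk3 <- mrmr_rank(X3, y), "constant")
  expect_identical(rk3[length(rk3)], "x6")
})

test_that("subject-wise CV-MSE behaves like an out-of-sample error", {
  sim <- make_feature_sim(n = 500, p = 5, n_subjects = 10, seed = 12L)
  X <- sim$X
  # noiseless linear truth is interpolated exactly
  y_lin <- 2 + 3 * X$x1 - 1.5 * X$x2
  expect_lt(cv_mse(X, y_lin, sim$subjects, c("x1", "x2")), 1e-10)
  # pure noise: CV-MSE approximates Var(y)
  set.seed(13)
  y_noise <- rnorm(500)
  m <- cv_mse(X, y_noise, sim$subjects, c("x1", "x2"))
  expect_lt(abs(m - var(y_noise)) / var(y_noise), 0.25)
  # an irrelevant extra feature cannot produce a large apparent gain
  y_mix <- X$x1 + rnorm(500, sd = 0.5)
  m_base <- cv_mse(X, y_mix, sim$subjects, "x1")
  m_plus <- cv_mse(X, y_mix, sim$subjects, c("x1", "x5"))
  expect_gt(m_plus, m_base * 0.95)
  expect_error(cv_mse(X, y_mix, rep("P1", 500), "x1"),
               class = "bcgco_fold_error")
})

test_that("PTA(3,2) recovers a sparse linear + quadratic generative law", {
  sim <- make_feature_sim(n = 400, p = 10, n_subjects = 10, seed = 21L)
  X <- sim$X
  set.seed(22)
  y <- 3 - 2 * X$x1 + X$x2^2 + rnorm(400, sd = 0.1)
  sel <- pta_select(X, y, sim$subjects)
  expect_true(all(c("x1", "x2") %in% sel$features))
  expect_true(sel$squared[["x2"]])
  expect_false(sel$squared[["x1"]])
  # accepted CV-MSE trace is non-increasing
  acc <- sel$trace[sel$trace$action %in% c("baseline", "accept"), "cv_mse"]
  expect_true(all(diff(acc) <= 0))
})

test_that("selection stops immediately when one feature is perfect", {
  sim <- make_feature_sim(n = 200, p = 5, n_subjects = 10, seed = 23L)
  y <- 1 + 4 * sim$X$x1
  sel <- pta_select(sim$X, y, sim$subjects, baseline_feature = "x1")
  expect_identical(sel$features, "x1")
  expect_lt(sel$cv_mse, 1e-10)
  expect_error(pta_select(sim$X, y, sim$subjects, baseline_feature = "nope"),
               class = "bcgco_configuration_error")
})

test_that("OLS on standardized features recovers exact and noisy truths", {
  set.seed(31)
  z <- rnorm(200)
  X <- data.frame(f = 5 + 2 * z)  # mean 5, sd 2 -> standardizes back to z
  y <- 1 + 2 * (X$f - mean(X$f)) / sd(X$f)
  m <- fit_linear(X, y)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(m$beta["f"]), 2, tolerance = 1e-10)
  expect_equal(predict(m, X), y, tolerance = 1e-10)
  # residuals have zero mean on the fitting set
  X2 <- data.frame(a = rnorm(200), b = rnorm(200))
  y2 <- 2 + X2$a - 0.5 * X2$b + rnorm(200, sd = 0.3)
  m2 <- fit_linear(X2, y2, squared = c(FALSE, TRUE))
  expect_equal(mean(y2 - predict(m2, X2)), 0, tolerance = 1e-10)
  # coefficient recovery within 2 SEs on simulated data (n = 500)
  set.seed(32)
  X3 <- data.frame(u = rnorm(500, sd = 2))
  y3 <- 6 - 1.2 * (X3$u - mean(X3$u)) / sd(X3$u) + rnorm(500, sd = 0.4)
  m3 <- fit_linear(X3, y3)
  se <- 0.4 / sqrt(500)
  expect_lt(abs(unname(m3$beta["u"]) - (-1.2)), 2 * se * 1.5)
  # rank deficiency is reported with the offending columns
  X4 <- data.frame(p = rnorm(50))
  X4$q <- 2 * X4$p
  expect_error(fit_linear(X4, rnorm(50)), class = "bcgco_fitting_error")
})

test_that("the published model reproduces its printed arithmetic", {
  m <- published_model(standardization = "identity")
  expect_length(m$features, 5)
  expect_length(m$beta_sq, 4)  # 9 terms + intercept
  at <- function(...) {
    v <- stats::setNames(rep(0, 5), m$features)
    args <- list(...)
    v[names(args)] <- unlist(args)
    predict(m, as.data.frame(as.list(v)))
  }
  expect_identical(at(), 6.70)
  expect_equal(at(ccc_med_d_total = 1), 6.70 - 3.42 + 2.47, tolerance = 1e-12)
  all1 <- stats::setNames(rep(1, 5), m$features)
  expect_equal(predict(m, as.data.frame(as.list(all1))),
               6.70 - 3.42 + 2.47 - 0.31 + 0.19 + 0.05 - 1.11 + 1.00 - 0.01 + 0.24,
               tolerance = 1e-12)
  # without standardization constants prediction is a configuration error
  m0 <- published_model()
  expect_error(predict(m0, as.data.frame(as.list(all1))),
               class = "bcgco_configuration_error")
  expect_error(published_model(means = c(a = 1), sds = c(a = 1)),
               class = "bcgco_configuration_error")
})

test_that("models serialize to text and round-trip bit-exactly", {
  m <- published_model(standardization = "identity")
  path <- file.path(withr::local_tempdir(), "model.yaml")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$beta, m$beta)
  expect_identical(m2$beta_sq, m$beta_sq)
  expect_identical(m2$intercept, m$intercept)
  expect_identical(m2$squared, m$squared)
  x <- stats::setNames(as.list(rnorm(5)), m$features)
  expect_identical(predict(m2, as.data.frame(x)), predict(m, as.data.frame(x)))
  # a fitted model with irrational coefficients round-trips too
  set.seed(41)
  Xf <- data.frame(a = rnorm(60), b = rnorm(60))
  mf <- fit_linear(Xf, rnorm(60), squared = c(TRUE, FALSE))
  pf <- file.path(withr::local_tempdir(), "fit.yaml")
  write_model(mf, pf)
  mf2 <- read_model(pf)
  expect_identical(mf2$beta, mf$beta)
  expect_identical(mf2$means, mf$means)
  expect_identical(mf2$sds, mf$sds)
})

test_that("standardized prediction is invariant to affine feature rescaling", {
  set.seed(51)
  X <- data.frame(a = rnorm(120), b = rnorm(120))
  y <- 5 + X$a - 2 * X$b + rnorm(120, sd = 0.2)
  m1 <- fit_linear(X, y, squared = c(TRUE, FALSE))
  Xr <- data.frame(a = 10 * X$a - 3, b = 0.5 * X$b + 7)
  m2 <- fit_linear(Xr, y, squared = c(TRUE, FALSE))
  expect_equal(predict(m1, X), predict(m2, Xr), tolerance = 1e-9)
})
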