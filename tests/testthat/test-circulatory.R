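test_that("impulse-train reference construction", {
  q <- qrs_train(c(100, 350), 250)
  ref <- build_reference(q, 500)
  expect_equal(sum(ref), 2)
  expect_equal(which(ref == 1), c(100, 350))
  expect_equal(which(build_reference(qrs_train(1, 250), 10) == 1), 1)
  expect_error(build_reference(qrs_train(integer(), 250), 100),
               class = "bcgco_empty_reference_error")
  # conservation for arbitrary trains
  q2 <- qrs_train(c(5, 300, 720, 999), 250)
  expect_equal(sum(build_reference(q2, 1000)), 4)
})

# Noiseless train of identical pulses locked to the QRS instants.
locked_pulse_signal <- function(n_beats = 20, rr_s = 1.0, fs = 250,
                                pulse_s = 0.6, delay_s = 0.1, amp = 1) {
  q <- round(seq(0.2, by = rr_s, length.out = n_beats) * fs) + 1L
  n <- q[n_beats] + fs
  x <- numeric(n)
  tpl_n <- round(pulse_s * fs)
  tpl <- amp * 0.5 * (1 - cos(2 * pi * (0:(tpl_n - 1)) / (tpl_n - 1)))
  for (b in q) {
    i0 <- b + round(delay_s * fs)
    x[i0:(i0 + tpl_n - 1)] <- x[i0:(i0 + tpl_n - 1)] + tpl
  }
  list(x = x, qrs = qrs_train(q, fs), n = n, fs = fs)
}

test_that("RLS decomposition is exact and locks onto beat-synchronous pulses", {
  sig <- locked_pulse_signal()
  cc <- rls_extract(sig$x, sig$qrs, sig$fs)
  expect_equal(cc$cc + cc$residual, sig$x, tolerance = 1e-12)
  # after the first 5 beats the output tracks the pulse train
  from <- sig$qrs$indices[6]
  expect_gte(cor(cc$cc[from:sig$n], sig$x[from:sig$n]), 0.95)
})

test_that("an unsynchronized respiration sinusoid is rejected", {
  sig <- locked_pulse_signal(n_beats = 40)
  tt <- (seq_len(sig$n) - 1) / sig$fs
  resp <- sin(2 * pi * 0.27 * tt)
  cc <- rls_extract(resp, sig$qrs, sig$fs)
  from <- sig$qrs$indices[11]
  ratio <- mean(cc$cc[from:sig$n]^2) / mean(resp[from:sig$n]^2)
  expect_lte(ratio, 0.15)
})

test_that("locked pulses are recovered from under a respiration baseline", {
  sig <- locked_pulse_signal(n_beats = 40)
  tt <- (seq_len(sig$n) - 1) / sig$fs
  mix <- sig$x + sin(2 * pi * 0.27 * tt)
  cc <- rls_extract(mix, sig$qrs, sig$fs)
  from <- sig$qrs$indices[11]
  expect_gte(cor(cc$cc[from:sig$n], sig$x[from:sig$n]), 0.9)
})

test_that("with lambda = 1 the taps converge to the ensemble-average template", {
  sig <- locked_pulse_signal(n_beats = 25, rr_s = 1.0)
  cc <- rls_extract(sig$x, sig$qrs, sig$fs,
                    rls_params(n_taps = 250, lam = 1))
  # direct oracle: average the signal over beat-aligned windows
  q <- sig$qrs$indices
  ens <- rowMeans(vapply(q[1:24], function(b) sig$x[b:(b + 249)],
                         numeric(250)))
  expect_lt(max(abs(cc$taps - ens)) / max(ens), 0.05)
})

test_that("the forgetting factor tracks a step change in beat amplitude", {
  fs <- 250
  q <- round(seq(0.2, by = 1.0, length.out = 40) * fs) + 1L
  n <- q[40] + fs
  x <- numeric(n)
  tpl_n <- 150
  tpl <- 0.5 * (1 - cos(2 * pi * (0:(tpl_n - 1)) / (tpl_n - 1)))
  for (i in seq_along(q)) {
    amp <- if (i <= 20) 1 else 2  # amplitude doubles at beat 21
    i0 <- q[i] + 25
    x[i0:(i0 + tpl_n - 1)] <- x[i0:(i0 + tpl_n - 1)] + amp * tpl
  }
  cc <- rls_extract(x, qrs_train(q, fs), fs, rls_params(250, lam = 0.995))
  # well after the step the output matches the doubled pulses
  late <- q[32]:n
  expect_lt(mean((cc$cc[late] - x[late])^2) / mean(x[late]^2), 0.05)
})

test_that("RLS input validation", {
  sig <- locked_pulse_signal(n_beats = 2)
  expect_error(rls_extract(sig$x, sig$qrs, sig$fs),
               class = "bcgco_insufficient_beats_error")
  sig3 <- locked_pulse_signal(n_beats = 5)
  bad <- sig3$x; bad[10] <- NaN
  expect_error(rls_extract(bad, sig3$qrs, sig3$fs), class = "bcgco_data_error")
  expect_error(rls_params(lam = 0.5), class = "bcgco_parameter_error")
  expect_error(rls_params(delta = -1), class = "bcgco_parameter_error")
})
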