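test_that("double reference subtraction removes shared structure", {
  s <- simulate_sensorgram(63, 0.12, amplitude = 0.4, drift = 5e-4,
                           noise_sd = 0, seed = 1)
  # experimental identical to the control: output identically zero
  z <- double_reference_subtract(s$experimental, s$drift_control,
                                 s$experimental, s$drift_control)
  expect_lt(max(abs(z$signal)), 1e-12)
  # shared linear drift is removed: the corrected trace is the pure binding
  # signal (up to smoothing of the phase-boundary kinks)
  corr <- double_reference_subtract(s$experimental, s$drift_control,
                                    s$binding_control)
  s0 <- simulate_sensorgram(63, 0.12, amplitude = 0.4, drift = 0,
                            noise_sd = 0, seed = 1)
  expect_lt(median(abs(corr$signal - s0$experimental$signal)), 1e-3)
  expect_lt(max(abs(corr$signal - s0$experimental$signal)), 0.05)
  bad <- s$binding_control[s$binding_control$phase != "dissociation", ]
  expect_error(double_reference_subtract(s$experimental, s$drift_control, bad),
               "mismatch")
})

test_that("dissociation fits recover the lifetime exactly when noiseless", {
  s <- simulate_sensorgram(63, 0.12, amplitude = 0.4, drift = 0,
                           noise_sd = 0, seed = 1)
  fit <- fit_dissociation(s$experimental)
  expect_equal(fit$tau, 63, tolerance = 1e-6)
  # invariance to amplitude scaling and phase time-offset
  s2 <- s$experimental
  s2$signal <- 5 * s2$signal
  expect_equal(fit_dissociation(s2)$tau, 63, tolerance = 1e-6)
  s3 <- s$experimental
  s3$time <- s3$time + 1000
  expect_equal(fit_dissociation(s3)$tau, 63, tolerance = 1e-6)
  flat <- s$experimental
  flat$signal <- seq(0, 1, length.out = nrow(flat))
  expect_error(fit_dissociation(flat), "non-decaying")
})

test_that("Savitzky-Golay smoothing does not bias the fitted lifetime", {
  s <- simulate_sensorgram(63, 0.12, amplitude = 0.4, drift = 2e-4,
                           noise_sd = 0.005, seed = 5)
  raw <- s$experimental
  raw$signal <- raw$signal -
    approx(s$drift_control$time, s$drift_control$signal, raw$time)$y
  tau_raw <- fit_dissociation(raw)$tau
  corr <- double_reference_subtract(s$experimental, s$drift_control,
                                    s$binding_control)
  expect_equal(fit_dissociation(corr)$tau, tau_raw, tolerance = 0.01)
})

test_that("reference subtraction removes drift-induced lifetime bias", {
  biases <- purrr::map_dfr(1:10, function(s) {
    tri <- simulate_sensorgram(63, 0.12, amplitude = 0.4, drift = 4e-4,
                               noise_sd = 0.003, seed = 50 + s)
    raw <- fit_dissociation(tri$experimental)$tau
    corr <- fit_dissociation(
      double_reference_subtract(tri$experimental, tri$drift_control,
                                tri$binding_control))$tau
    tibble::tibble(raw = raw, corr = corr)
  })
  expect_gt(abs(mean(biases$raw) - 63) / 63, 0.02)
  expect_lt(abs(mean(biases$corr) - 63) / 63, 0.02)
})

test_that("the replicate suite reproduces the published lifetime spread", {
  taus <- vapply(1:18, function(s) {
    tri <- simulate_sensorgram(tau = 63, k_obs = 0.12, amplitude = 0.4,
                               noise_sd = 0.005, seed = 200 + s)
    corr <- double_reference_subtract(tri$experimental, tri$drift_control,
                                      tri$binding_control)
    fit_dissociation(corr)$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 63) / 63, 0.05)
})

test_that("association fits return the effective on-rate", {
  # ground truth mirroring the published kinetics: on-rate 3.5e5 at 300 nM
  conc <- 300e-9
  k_obs <- 3.5e5 * conc + 1 / 63
  s <- simulate_sensorgram(63, k_obs, amplitude = 0.4, drift = 0,
                           noise_sd = 0, seed = 1)
  fit <- fit_association(s$experimental, conc = conc, tau = 63)
  expect_equal(fit$k_obs, k_obs, tolerance = 1e-4)
  expect_equal(fit$on_rate, 3.5e5, tolerance = 0.01)
  expect_true(fit$dissociation_corrected)
  expect_false(fit$non_saturating)
  # without a known lifetime the uncorrected rate is flagged
  fit2 <- fit_association(s$experimental, conc = conc)
  expect_false(fit2$dissociation_corrected)
  expect_error(fit_association(s$experimental, conc = 0), "positive")
})

test_that("association recovery is unbiased under noise", {
  conc <- 300e-9
  k_obs <- 3.5e5 * conc + 1 / 63
  on <- vapply(1:20, function(s) {
    tri <- simulate_sensorgram(63, k_obs, amplitude = 0.4, noise_sd = 0.005,
                               seed = 300 + s)
    corr <- double_reference_subtract(tri$experimental, tri$drift_control,
                                      tri$binding_control)
    fit_association(corr, conc = conc, tau = 63)$on_rate
  }, numeric(1))
  expect_lt(abs(mean(on) - 3.5e5) / 3.5e5, 0.03)
})

test_that("the full chain recovers the effective concentration", {
  # tau generated from the zero-force lifetime formula, then recovered by
  # subtract -> smooth -> fit -> invert
  k_on <- 6.2e4
  ceffs <- vapply(1:10, function(s) {
    C_true <- 465e-6
    tau <- (C_true * k_on + 3 * 0.5) / (2 * 0.5^2)
    tri <- simulate_sensorgram(tau, 0.12, amplitude = 0.4, noise_sd = 0.005,
                               seed = 400 + s)
    corr <- double_reference_subtract(tri$experimental, tri$drift_control,
                                      tri$binding_control)
    invert_lifetime_to_ceff(fit_dissociation(corr)$tau, 0.5, k_on)
  }, numeric(1))
  expect_lt(max(abs(ceffs - 465e-6) / 465e-6), 0.1)
})
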