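be_points <- function(p = wt_bond(), lr = c(22.7, 45, 95.6, 190, 377.8),
                      error = 1.3) {
  tibble::tibble(condition = p$label, loading_rate = lr,
                 mean_loading_rate = lr,
                 mode_force = bell_evans_mode_force(lr, p),
                 error = error, n_events = 70L)
}

test_that("the Bell-Evans fit inverts exactly on noiseless mode points", {
  fit <- fit_bell_evans(be_points())
  expect_equal(fit$f_beta, 13.5, tolerance = 1e-6)
  expect_equal(fit$k_off0, 0.5, tolerance = 1e-6)
  expect_equal(fit$chi2, 0, tolerance = 1e-12)
  expect_error(fit_bell_evans(be_points(lr = c(10, 20))), "fewer than 3")
  expect_warning(fit_bell_evans(be_points(lr = c(30, 40, 50))), "decade")
})

test_that("fit results are invariant to ordering and weight rescaling", {
  pts <- be_points()
  pts$mode_force <- pts$mode_force + c(0.5, -0.3, 0.2, -0.4, 0.1)
  f1 <- fit_bell_evans(pts)
  f2 <- fit_bell_evans(pts[sample.int(5), ])
  expect_equal(f2$f_beta, f1$f_beta)
  f3 <- fit_bell_evans(dplyr::mutate(pts, error = error * 7))
  expect_equal(f3$f_beta, f1$f_beta)
  expect_equal(f3$k_off0, f1$k_off0)
})

test_that("chi-square matches direct summation", {
  pts <- be_points()
  pts$mode_force <- pts$mode_force + c(1.3, 0, -1.3, 2.6, 0)
  model <- function(l_r, params)
    params[["f_beta"]] * log(l_r / (params[["f_beta"]] * params[["k_off0"]]))
  pars <- c(f_beta = 13.5, k_off0 = 0.5)
  direct <- sum((pts$mode_force - model(pts$mean_loading_rate, pars))^2 /
                pts$error^2)
  expect_equal(chi_squared(pts, model, pars), direct)
  expect_equal(direct, (1 + 0 + 1 + 4 + 0))
  # perfect model gives zero
  expect_equal(chi_squared(be_points(), model, pars), 0, tolerance = 1e-20)
  # random parameter sets agree with independent recomputation
  withr::with_seed(1, for (i in 1:5) {
    pr <- c(f_beta = runif(1, 5, 20), k_off0 = runif(1, 0.1, 2))
    expect_equal(chi_squared(pts, model, pr),
                 sum((pts$mode_force - model(pts$mean_loading_rate, pr))^2 /
                     pts$error^2))
  })
  expect_error(chi_squared(dplyr::mutate(pts, error = 0), model, pars),
               "zero or negative")
})

test_that("simplex minimization finds the analytic minimum", {
  pts <- tibble::tibble(mean_loading_rate = c(10, 100, 1000),
                        mode_force = c(12, 17, 22), error = 1)
  model <- function(l_r, params) params[["a"]] + params[["b"]] * log10(l_r)
  # weighted least squares has a closed-form solution; here the design is
  # balanced so it is the plain regression line
  fit <- withr::with_seed(1, minimize_chi2(pts, model, start = c(a = 3, b = 1)))
  expect_equal(unname(fit$estimate["a"]), 7, tolerance = 1e-3)
  expect_equal(unname(fit$estimate["b"]), 5, tolerance = 1e-3)
  expect_lt(fit$chi2, 1e-5)
  expect_true(fit$restarts_agree)
})

test_that("curvature errors match the weighted-least-squares closed form", {
  withr::with_seed(3, {
    pts <- tibble::tibble(
      mean_loading_rate = c(5, 20, 80, 320),
      error = c(1, 2, 1.5, 1),
      mode_force = 4 + 3 * log(c(5, 20, 80, 320)) + rnorm(4, 0, 0.5))
  })
  model <- function(l_r, params) params[["a"]] + params[["b"]] * log(l_r)
  fit <- minimize_chi2(pts, model, start = c(a = 2, b = 2))
  fit <- param_errors(fit)
  se <- attr(fit, "std.error")
  # the curvature convention gives per-parameter (conditional) errors:
  # sigma_i^2 = 2 / (d^2 chi2 / d x_i^2) = 1 / [X' W X]_ii for a linear model
  X <- cbind(1, log(pts$mean_loading_rate))
  W <- diag(1 / pts$error^2)
  info <- t(X) %*% W %*% X
  expect_equal(unname(se["a"]), 1 / sqrt(info[1, 1]), tolerance = 0.01)
  expect_equal(unname(se["b"]), 1 / sqrt(info[2, 2]), tolerance = 0.01)
  # doubling every error bar doubles each parameter sigma
  fit2 <- param_errors(minimize_chi2(dplyr::mutate(pts, error = 2 * error),
                                     model, start = c(a = 2, b = 2)))
  expect_equal(unname(attr(fit2, "std.error")), unname(2 * se),
               tolerance = 0.02)
})

test_that("parameters that do not enter the model are flagged unconstrained", {
  pts <- tibble::tibble(mean_loading_rate = c(10, 100, 1000),
                        mode_force = c(12, 17, 22), error = 1)
  model <- function(l_r, params) params[["a"]] + params[["b"]] * log10(l_r)
  fit <- minimize_chi2(pts, model, start = c(a = 3, b = 1, ghost = 1))
  fit <- param_errors(fit)
  expect_true(attr(fit, "unconstrained")[["ghost"]])
  expect_true(is.na(attr(fit, "std.error")[["ghost"]]))
  expect_false(attr(fit, "unconstrained")[["a"]])
})

test_that("the avidity fit recovers rebinding parameters from its own model", {
  a <- wt_dimer()
  lr <- c(0.39, 2.45, 15.3, 95.6)
  pts <- tibble::tibble(condition = "dimer", loading_rate = lr,
                        mean_loading_rate = lr,
                        mode_force = predict_mode_force(lr, a, eps = 0.005),
                        error = 1.5, n_events = 35L)
  withr::with_seed(7, {
    fit <- fit_avidity(pts, avidity_params(wt_bond(), 6.2e4, 300e-6, 7),
                       free = c("C_eff0", "f_c"), restarts = 2)
  })
  expect_equal(unname(fit$estimate["C_eff0"]), 465e-6, tolerance = 0.01)
  expect_equal(unname(fit$estimate["f_c"]), 10, tolerance = 0.01)
  expect_s3_class(fit$params, "avidity_params")
  # rebinding clearly beats the no-rebinding variant on dimer data
  expect_gt(fit$delta_chi2_no_rebinding, 10)
  td <- tidy(fit)
  expect_setequal(td$term, c("C_eff0", "f_c"))
  expect_true(all(is.finite(td$std.error)))
})

test_that("the simultaneous het/hom fit recovers the mutant bond", {
  h <- het_params()
  lr <- exp(seq(log(0.39), log(95.6), length.out = 4))
  pts_het <- tibble::tibble(condition = "het", loading_rate = lr,
                            mean_loading_rate = lr,
                            mode_force = predict_mode_force(lr, h, eps = 0.005),
                            error = 1.2, n_events = 35L)
  pts_hom <- tibble::tibble(condition = "hom", loading_rate = lr,
                            mean_loading_rate = lr,
                            mode_force = predict_mode_force(lr, mut_dimer(),
                                                            eps = 0.005),
                            error = 1.2, n_events = 35L)
  template <- hetero_avidity_params(wt_bond(), single_bond_params(1, 3, "R113G"),
                                    6.2e4, 6.2e4, 465e-6, 10, 10)
  withr::with_seed(8, {
    fit <- fit_hetero_simultaneous(pts_het, pts_hom, template, restarts = 2)
  })
  expect_equal(unname(fit$estimate["k_off0_mut"]), 1.4, tolerance = 0.02)
  expect_equal(unname(fit$estimate["f_beta_mut"]), 1.8, tolerance = 0.02)
  expect_s3_class(fit$params, "hetero_avidity_params")
})
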