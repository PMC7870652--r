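test_that("slip-bond off-rates follow the Bell relation", {
  wt <- wt_bond()
  expect_equal(bond_off_rate(0, wt), 0.5)
  expect_equal(bond_off_rate(10, wt), 0.5 * exp(10 / 13.5), tolerance = 1e-12)
  expect_equal(bond_off_rate(10, wt), 1.049, tolerance = 1e-3)
  expect_equal(bond_off_rate(10, mut_bond()), 362.1, tolerance = 1e-3)
  expect_equal(shared_load_off_rate(0, wt), bond_off_rate(0, wt))
  expect_equal(shared_load_off_rate(10, wt), 0.5 * exp(10 / 27), tolerance = 1e-12)
  expect_equal(shared_load_off_rate(10, wt), 0.724, tolerance = 1e-3)
  # algebraic identity: sharing halves the effective force
  F <- seq(0, 60, by = 7.5)
  expect_equal(shared_load_off_rate(2 * F, wt), bond_off_rate(F, wt))
  expect_true(all(diff(bond_off_rate(F, wt)) > 0))
  expect_error(bond_off_rate(-1, wt), "non-negative")
  expect_error(shared_load_off_rate(c(3, -2), wt), "non-negative")
})

test_that("single-bond mean lifetime reproduces the published forces", {
  p <- single_bond_params(k_off0 = 1 / 1.9, f_beta = 13.5)
  expect_equal(bond_mean_lifetime(0, p), 1.9)
  expect_equal(bond_mean_lifetime(10, p), 0.9, tolerance = 0.01)
  # the deafness-mutant bond at resting tension lasts under 10 ms
  expect_lt(bond_mean_lifetime(10, mut_bond()), 10e-3)
  expect_equal(bond_mean_lifetime(10, mut_bond()), 2.76e-3, tolerance = 1e-3)
  expect_true(all(diff(bond_mean_lifetime(seq(0, 40, 5), wt_bond())) < 0))
})

test_that("Bell-Evans mode force is log-linear in loading rate", {
  wt <- wt_bond()
  expect_equal(bell_evans_mode_force(13.5 * 0.5, wt), 0)
  expect_equal(bell_evans_mode_force(22.5, wt), 13.5 * log(22.5 / 6.75))
  expect_equal(bell_evans_mode_force(22.5, wt), 16.25, tolerance = 1e-3)
  # one decade of loading rate adds f_beta * ln(10)
  lr <- c(1, 5, 40)
  expect_equal(bell_evans_mode_force(10 * lr, wt) - bell_evans_mode_force(lr, wt),
               rep(13.5 * log(10), 3))
  # negative values at slow loading are returned unclamped
  expect_lt(bell_evans_mode_force(1, wt), 0)
  expect_error(bell_evans_mode_force(0, wt), "positive")
})

test_that("effective concentration decays as a Gaussian in force", {
  a <- wt_dimer()
  expect_equal(ceff_at_force(0, a), 465e-6)
  expect_equal(ceff_at_force(10, a), 465e-6 / exp(1))
  expect_equal(ceff_at_force(10, a) * 1e6, 171, tolerance = 1e-3)
  expect_true(all(diff(ceff_at_force(seq(0, 30, 2), a)) < 0))
})

test_that("one molecule in a binding-domain-sized sphere is ~400 uM", {
  expect_equal(sphere_ceff(10) * 1e6, 396, tolerance = 2e-3)
  # volume scaling: doubling the radius divides the concentration by 8
  expect_equal(sphere_ceff(20), sphere_ceff(10) / 8)
  # a ~220-nm-diameter confinement corresponds to ~0.3 uM
  expect_equal(sphere_ceff(110) * 1e6, 0.298, tolerance = 1e-2)
  expect_error(sphere_ceff(0), "positive")
})

test_that("rebinding rate is the concentration-on-rate product", {
  expect_equal(rebinding_rate(400e-6, 6.2e4), 24.8)
  expect_equal(rebinding_rate(0, 6.2e4), 0)
  expect_equal(rebinding_rate(171e-6, 6.2e4), 10.6, tolerance = 1e-2)
})

test_that("dimer mean lifetime has the correct closed form", {
  a <- wt_dimer()
  # no rebinding: two-step cascade at equal rates gives 3/(2 k_off0)
  a0 <- avidity_params(wt_bond(), 6.2e4, 0, 10)
  expect_equal(zero_force_dimer_lifetime(a0), 3.0)
  expect_equal(zero_force_dimer_lifetime(a), 60.66, tolerance = 1e-4)
  expect_equal(zero_force_dimer_lifetime(a), 62, tolerance = 0.05)
  expect_equal(dimer_mean_lifetime(0, a), zero_force_dimer_lifetime(a))
  expect_equal(dimer_mean_lifetime(10, a), 8.63, tolerance = 1e-3)
  # mutant/WT lifetime ratio at resting tension is ~0.3%
  ratio <- dimer_mean_lifetime(10, mut_dimer()) / dimer_mean_lifetime(10, a)
  expect_equal(100 * ratio, 0.3, tolerance = 0.05)
  expect_true(all(diff(dimer_mean_lifetime(seq(0, 50, 5), a)) < 0))
})

test_that("lifetime inversion recovers the effective concentration", {
  expect_equal(invert_lifetime_to_ceff(3 / (2 * 0.5), 0.5, 6.2e4), 0)
  expect_equal(invert_lifetime_to_ceff(63.3, 0.5, 6.2e4) * 1e6, 486,
               tolerance = 1e-3)
  expect_equal(invert_lifetime_to_ceff(27.1, 0.5, 6.2e4) * 1e6, 194,
               tolerance = 2e-3)
  # round trip through the zero-force lifetime formula
  a <- wt_dimer()
  expect_equal(invert_lifetime_to_ceff(zero_force_dimer_lifetime(a), 0.5, 6.2e4),
               465e-6)
  expect_error(invert_lifetime_to_ceff(1, 0.5, 6.2e4), "inconsistent")
})

test_that("parameter containers validate and derive correctly", {
  wt <- wt_bond()
  expect_equal(wt$tau0, 2)
  expect_equal(wt$x_ts, kT / 13.5)
  expect_error(single_bond_params(-1, 13.5), "k_off0")
  expect_error(single_bond_params(0.5, 0), "f_beta")
  a <- wt_dimer()
  expect_equal(a$kappa, 100 / (2 * kT))
  expect_error(avidity_params(wt, -1, 465e-6, 10), "k_on")
  expect_error(avidity_params(wt, 6.2e4, -1e-6, 10), "C_eff0")
  expect_error(hetero_avidity_params(wt, wt, 6.2e4, 6.2e4, 465e-6, -1),
               "positive")
})

test_that("parameters survive a JSON round trip with units in key names", {
  tmp <- withr::local_tempfile(fileext = ".json")
  for (p in list(wt_bond(), wt_dimer(), het_params())) {
    write_params(p, tmp)
    expect_equal(read_params(tmp), p)
  }
  txt <- jsonlite::read_json(tmp)
  expect_true(any(grepl("_pN$|_per_s$|_uM$", names(txt))))
  # unknown keys are rejected by name
  bad <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  bad$bogus_key <- 1
  jsonlite::write_json(bad, tmp, auto_unbox = TRUE)
  expect_error(read_params(tmp), "bogus_key")
})
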