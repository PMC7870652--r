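test_that("rupture detection finds abrupt drops and rejects flat traces", {
  tr <- simulate_fx_trace(22.5, 25, noise_sd = 0.3, seed = 1)
  det <- detect_rupture(tr)
  expect_equal(det$rupture_force, 25, tolerance = 0.1)
  expect_equal(det$noise_sd, 0.3, tolerance = 0.25)
  # a 5-sigma threshold on ~1000 samples has a small but real false-alarm
  # rate, so the flat-trace check uses a fixed representative draw
  flat <- withr::with_seed(8, tibble::tibble(
    time = seq(0, 1, 1e-3), extension = 0,
    force = 5 + rnorm(1001, 0, 0.2)))
  expect_error(detect_rupture(flat), "no rupture detected")
  flat0 <- tibble::tibble(time = seq(0, 1, 1e-3), extension = 0, force = 5)
  expect_error(detect_rupture(flat0), "no rupture detected")
})

test_that("WLC fits recover generator parameters under noise", {
  errs <- vapply(1:30, function(s) {
    tr <- simulate_fx_trace(60, 30, noise_sd = 0.5, seed = s)
    fit <- fit_wlc(tr)
    abs(fit$contour_length - 850) / 850
  }, numeric(1))
  expect_lt(mean(errs), 0.03)
})

test_that("wlc_fit supports tidy and glance", {
  fit <- fit_wlc(simulate_fx_trace(22.5, 25, noise_sd = 0, seed = 1))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("contour_length", "persistence_length",
                             "stretch_modulus"))
  expect_true(glance(fit)$converged)
  expect_gt(fit$contour_length, fit$persistence_length)
})

test_that("single-tether filtering counts rejections and is idempotent", {
  fits <- tibble::tibble(
    contour_length = c(rep(850, 7), 400, 420, 2000),
    persistence_length = c(rep(45, 9), 45))
  res <- filter_single_tethers(fits, contour_range = c(700, 1000),
                               persistence_range = c(20, 80))
  expect_equal(nrow(res$accepted), 7)
  expect_equal(res$report$rejected_contour, 3)
  expect_equal(res$report$n_rejected, 3)
  # identity bounds
  all_in <- filter_single_tethers(fits, c(0, 1e4), c(0, 1e3))
  expect_equal(nrow(all_in$accepted), nrow(fits))
  # idempotence
  again <- filter_single_tethers(res$accepted, c(700, 1000), c(20, 80))
  expect_identical(again$accepted, res$accepted)
  expect_error(filter_single_tethers(fits[0, ], c(0, 1), c(0, 1)),
               "non-empty")
})

test_that("double-tether events are rejected by contour-length bounds", {
  # a double tether shares the load between two tethers, halving the
  # apparent contour length of the force-extension curve
  singles <- purrr::map_dfr(1:6, function(s)
    tidy(fit_wlc(simulate_fx_trace(22.5, 20, Lc = 850, noise_sd = 0.3,
                                   seed = s))) |>
      tidyr::pivot_wider(names_from = "term", values_from = "estimate",
                         id_cols = c()))
  doubles <- purrr::map_dfr(7:9, function(s)
    tidy(fit_wlc(simulate_fx_trace(22.5, 20, Lc = 425, noise_sd = 0.3,
                                   seed = s))) |>
      tidyr::pivot_wider(names_from = "term", values_from = "estimate",
                         id_cols = c()))
  med <- stats::median(singles$contour_length)
  res <- filter_single_tethers(dplyr::bind_rows(singles, doubles),
                               contour_range = med * c(0.75, 1.25),
                               persistence_range = c(5, 200))
  expect_equal(nrow(res$accepted), 6)
  expect_equal(res$report$rejected_contour, 3)
})

test_that("loading-rate extraction is exact on linear ramps", {
  tm <- seq(0, 1, by = 1 / 1400)
  tr <- tibble::tibble(time = tm, extension = tm * 500,
                       force = c(22.5 * head(tm, -20), rep(0, 20)))
  expect_equal(extract_loading_rate(tr), 22.5, tolerance = 1e-6)
})

test_that("loading-rate extraction is unbiased under noise", {
  slopes <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      tm <- seq(0, 1, by = 1 / 1400)
      n <- length(tm)
      force <- c(22.5 * head(tm, -20), rep(0, 20)) + rnorm(n, 0, 0.5)
      tr <- tibble::tibble(time = tm, extension = tm * 500, force = force)
      extract_loading_rate(tr)
    })
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 22.5) / 22.5, 0.02)
})

test_that("loading-rate extraction tracks the terminal WLC slope", {
  tr <- simulate_fx_trace(22.5, 25, noise_sd = 0, seed = 3)
  expect_equal(extract_loading_rate(tr), 22.5, tolerance = 0.1)
  short <- tibble::tibble(time = (0:6) / 1400, extension = 1:7,
                          force = c(1, 2, 3, 4, 5, 0, 0))
  expect_error(extract_loading_rate(short), "linear regime|no rupture")
})

test_that("the KDE mode is symmetric, equivariant and order-invariant", {
  mp <- estimate_mode_kde(c(10, 12, 14, 16, 18))
  expect_equal(mp$mode_force, 14, tolerance = 1e-6)
  expect_equal(mp$error, bw.nrd0(c(10, 12, 14, 16, 18)))
  x <- withr::with_seed(1, rnorm(200, 20, 4))
  m0 <- estimate_mode_kde(x)
  # affine equivariance
  m1 <- estimate_mode_kde(3 + 2 * x)
  expect_equal(m1$mode_force, 3 + 2 * m0$mode_force, tolerance = 1e-6)
  expect_equal(m1$error, 2 * m0$error)
  # order invariance
  m2 <- estimate_mode_kde(rev(sort(x)))
  expect_equal(m2$mode_force, m0$mode_force)
  # duplicating every event (equal weights) with the bandwidth held fixed
  m3 <- estimate_mode_kde(rep(x, 2), bw = m0$error)
  expect_equal(m3$mode_force, estimate_mode_kde(x, bw = m0$error)$mode_force,
               tolerance = 1e-9)
  expect_error(estimate_mode_kde(1:4), "at least 5")
})

test_that("mode points group events by condition and loading rate", {
  spec <- condition_spec("WT_single_2mM", seed = 21)
  dat <- simulate_rupture_forces(spec)
  pts <- rupture_modes(dat)
  expect_equal(nrow(pts), 6)
  expect_true(all(pts$error > 0))
  expect_true(all(pts$n_events >= 2))
  expect_equal(pts$mean_loading_rate, pts$loading_rate)
  # modes rise with loading rate
  expect_gt(stats::cor(log(pts$mean_loading_rate), pts$mode_force), 0.9)
})

test_that("Freedman-Diaconis binning uses 2 IQR n^(-1/3) and scans offsets", {
  x <- c(0, 2, 2, 4, 4, 6, 6, 8)   # IQR exactly 4, n = 8
  fd <- fd_histogram(x)
  expect_equal(fd$bin_width, 4.0)
  expect_equal(sum(fd$bins$count), 8)
  expect_error(fd_histogram(rep(3, 10)), "zero IQR")
  # the offset scan cannot lose events and maximizes the modal bin
  y <- withr::with_seed(2, runif(1000))
  fdy <- fd_histogram(y)
  expect_equal(sum(fdy$bins$count), 1000)
  expected <- 1000 * fdy$bin_width  # uniform density 1 on [0, 1]
  expect_lt(abs(max(fdy$bins$count) - expected), 3 * sqrt(expected) + 1)
})

test_that("synthetic single-bond spectra regress back to their generator", {
  # end-to-end: sample at the six instrument loading rates, estimate modes,
  # and recover the generating Bell parameters from the weighted fit; the
  # per-seed scatter of f_beta is ~15% (it equals the fit-propagated error),
  # so the centre of a small seed ensemble is the stable quantity
  fits <- purrr::map(1:5, function(s) {
    spec <- condition_spec("WT_single_2mM", seed = 100 + s)
    fit_bell_evans(rupture_modes(simulate_rupture_forces(spec)))
  })
  fb <- vapply(fits, `[[`, numeric(1), "f_beta")
  k0 <- vapply(fits, `[[`, numeric(1), "k_off0")
  expect_lt(abs(stats::median(fb) - 13.5) / 13.5, 0.15)
  expect_lt(abs(stats::median(k0) - 0.5) / 0.5, 0.2)
  expect_true(all(abs(fb - 13.5) / 13.5 < 0.45))
})
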