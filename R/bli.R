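check_sensorgram <- function(s) {
  if (!is.data.frame(s) || !all(c("time", "signal", "phase") %in% names(s)))
    abort("A sensorgram must have columns `time`, `signal`, `phase`.")
  ph <- rle(as.character(s$phase))$values
  valid <- c("baseline", "association", "dissociation")
  if (!all(ph %in% valid) || any(duplicated(ph)) ||
      !identical(ph, valid[valid %in% ph]))
    abort("Sensorgram phases must be contiguous and ordered baseline, association, dissociation.")
  invisible(s)
}

#' Double reference subtraction of a BLI sensorgram
#'
#' Standard biolayer-interferometry referencing: the drift sensor is
#' subtracted from the experimental sensor, the binding-control sensor
#' (analyte lacking the binding domain) is drift-corrected the same way,
#' and the corrected control is subtracted from the corrected experimental
#' trace.  The result is then smoothed with a Savitzky-Golay filter.
#' Sensors on different time grids are resampled onto the experimental grid
#' by linear interpolation.
#'
#' @param exp Experimental sensorgram (tibble `time`, `signal`, `phase`).
#' @param drift Drift-control sensorgram for the experimental sensor.
#' @param ctrl Binding-control sensorgram.
#' @param ctrl_drift Drift control for the binding-control sensor (defaults
#'   to `drift`).
#' @param sg_window,sg_order Savitzky-Golay window length (samples, odd) and
#'   polynomial order.
#' @return The corrected, smoothed sensorgram tibble (same grid and phases
#'   as `exp`).
#' @export
double_reference_subtract <- function(exp, drift, ctrl, ctrl_drift = drift,
                                      sg_window = 25, sg_order = 3) {
  check_sensorgram(exp)
  for (s in list(drift, ctrl, ctrl_drift)) check_sensorgram(s)
  if (!setequal(unique(exp$phase), unique(ctrl$phase)))
    abort("Phase-label mismatch between experimental and control sensorgrams.")
  resamp <- function(s) approx(s$time, s$signal, xout = exp$time, rule = 2)$y
  corrected <- (exp$signal - resamp(drift)) - (resamp(ctrl) - resamp(ctrl_drift))
  if (sg_window %% 2 == 0) sg_window <- sg_window + 1
  smoothed <- as.numeric(signal::sgolayfilt(corrected, p = sg_order,
                                            n = sg_window))
  tibble::tibble(time = exp$time, signal = smoothed, phase = exp$phase)
}

#' Dissociation lifetime from a sensorgram
#'
#' Least-squares fit of `A * exp(-t/tau) + offset` over the dissociation
#' phase.  The offset absorbs residual baseline left after referencing.
#'
#' @param s A (corrected) sensorgram tibble.
#' @param min_samples Minimum dissociation-phase length.
#' @return An object of class `bli_dissociation_fit`: `tau` (s), `tau_se`,
#'   `amplitude`, `offset`, `n`.  Supports [tidy()].
#' @export
fit_dissociation <- function(s, min_samples = 30) {
  check_sensorgram(s)
  d <- s[s$phase == "dissociation", ]
  if (nrow(d) < min_samples) abort("dissociation phase has fewer than 30 samples.")
  t <- d$time - min(d$time)
  y <- d$signal
  drop_total <- y[1] - utils::tail(y, 1)
  if (!(drop_total > 0) || stats::cor(t, y) > 0)
    abort("non-decaying signal: dissociation phase does not decay.")
  tau0 <- max(t) / max(log(max(y[1] - min(y), 1e-9) /
                           max(utils::tail(y, 1) - min(y) + 1e-9, 1e-9)), 1)
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-t / tau) + c0,
    data = data.frame(t = t, y = y),
    start = list(A = drop_total, tau = tau0, c0 = min(y)),
    lower = c(A = 1e-9, tau = 1e-6, c0 = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- summary(fit)$coefficients
  structure(
    list(tau = est["tau", "Estimate"], tau_se = est["tau", "Std. Error"],
         amplitude = est["A", "Estimate"], offset = est["c0", "Estimate"],
         n = nrow(d)),
    class = "bli_dissociation_fit")
}

#' @export
print.bli_dissociation_fit <- function(x, ...) {
  cat(sprintf("<bli_dissociation_fit>  tau = %.2f +/- %.2f s  (A = %.3g nm, offset = %.3g nm, n = %d)\n",
              x$tau, x$tau_se, x$amplitude, x$offset, x$n))
  invisible(x)
}

#' @export
tidy.bli_dissociation_fit <- function(x, ...) {
  tibble::tibble(term = c("tau", "amplitude", "offset"),
                 estimate = c(x$tau, x$amplitude, x$offset),
                 std.error = c(x$tau_se, NA, NA),
                 unit = c("s", "nm", "nm"))
}

#' Association kinetics and effective on-rate from a sensorgram
#'
#' Pseudo-first-order fit `A * (1 - exp(-k_obs t)) + offset` over the
#' association phase.  When the dissociation lifetime `tau` is known, the
#' effective on-rate is `(k_obs - 1/tau) / conc`; otherwise `k_obs / conc`
#' is reported and flagged as uncorrected.
#'
#' @param s A (corrected) sensorgram tibble.
#' @param conc Analyte concentration, M (> 0).
#' @param tau Optional dissociation lifetime, s.
#' @param min_samples Minimum association-phase length.
#' @return An object of class `bli_association_fit`: `k_obs` (s^-1),
#'   `k_obs_se`, `on_rate` (M^-1 s^-1), and flags `dissociation_corrected`
#'   and `non_saturating` (TRUE when the phase ends well short of
#'   saturation, so `k_obs` is poorly constrained).
#' @export
fit_association <- function(s, conc, tau = NULL, min_samples = 30) {
  check_sensorgram(s)
  if (!is.numeric(conc) || conc <= 0) abort("`conc` must be a positive concentration (M).")
  d <- s[s$phase == "association", ]
  if (nrow(d) < min_samples) abort("association phase has fewer than 30 samples.")
  t <- d$time - min(d$time)
  y <- d$signal
  fit <- minpack.lm::nlsLM(
    y ~ A * (1 - exp(-k * t)) + c0,
    data = data.frame(t = t, y = y),
    start = list(A = max(y) - y[1], k = 2 / max(t), c0 = y[1]),
    lower = c(A = 1e-9, k = 1e-9, c0 = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- summary(fit)$coefficients
  k_obs <- est["k", "Estimate"]
  corrected <- !is.null(tau)
  on_rate <- if (corrected) (k_obs - 1 / tau) / conc else k_obs / conc
  structure(
    list(k_obs = k_obs, k_obs_se = est["k", "Std. Error"],
         amplitude = est["A", "Estimate"],
         on_rate = on_rate, conc = conc,
         dissociation_corrected = corrected,
         non_saturating = k_obs * max(t) < 1,
         n = nrow(d)),
    class = "bli_association_fit")
}

#' @export
print.bli_association_fit <- function(x, ...) {
  cat(sprintf("<bli_association_fit>  k_obs = %.4g +/- %.2g s^-1  on-rate = %.3g M^-1 s^-1%s%s\n",
              x$k_obs, x$k_obs_se, x$on_rate,
              if (x$dissociation_corrected) "" else "  [not dissociation-corrected]",
              if (x$non_saturating) "  [non-saturating]" else ""))
  invisible(x)
}

#' @export
tidy.bli_association_fit <- function(x, ...) {
  tibble::tibble(term = c("k_obs", "on_rate"),
                 estimate = c(x$k_obs, x$on_rate),
                 std.error = c(x$k_obs_se, NA),
                 unit = c("s^-1", "M^-1 s^-1"))
}
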