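#' Chi-square objective for mode-force data
#'
#' `sum((mode_force - predicted)^2 / error^2)` over the mode points, the
#' objective minimized by every model fit in the package.
#'
#' @param points A mode-point tibble (see [rupture_modes()]) with columns
#'   `mean_loading_rate`, `mode_force`, `error`.
#' @param model_fn Function `(l_r, params) -> predicted mode force` where
#'   `params` is a named numeric vector.
#' @param params Named numeric parameter vector passed to `model_fn`.
#' @return The chi-square value (scalar, >= 0).
#' @export
chi_squared <- function(points, model_fn, params) {
  check_points(points)
  pred <- model_fn(points$mean_loading_rate, params)
  sum((points$mode_force - pred)^2 / points$error^2)
}

check_points <- function(points) {
  req <- c("mean_loading_rate", "mode_force", "error")
  if (!is.data.frame(points) || !all(req %in% names(points)))
    abort("`points` must have columns mean_loading_rate, mode_force, error.")
  if (any(points$error <= 0)) abort("zero or negative mode-point errors.")
  invisible(points)
}

#' Weighted Bell-Evans fit of a dynamic force spectrum
#'
#' Weighted linear least squares of the most-probable rupture force against
#' the natural log of the loading rate, with weights `1/error^2`.  The slope
#' is the force scale `f_beta`; the intercept gives the zero-force off-rate
#' via `k_off0 = exp(-intercept/f_beta) / f_beta`.  Parameter errors come
#' from standard linear-fit error propagation (delta method for `k_off0`).
#'
#' @param points A mode-point tibble with `mean_loading_rate`, `mode_force`,
#'   `error` (>= 3 points; should span at least a decade of loading rate).
#' @return An object of class `bell_evans_fit` supporting [tidy()] and
#'   [glance()], with fields `f_beta`, `k_off0`, their standard errors, and
#'   the chi-square of the fit.
#' @examples
#' wt <- single_bond_params(0.5, 13.5)
#' pts <- tibble::tibble(
#'   mean_loading_rate = c(25, 60, 150, 370),
#'   mode_force = bell_evans_mode_force(c(25, 60, 150, 370), wt),
#'   error = 1)
#' fit_bell_evans(pts)
#' @export
fit_bell_evans <- function(points) {
  check_points(points)
  if (nrow(points) < 3L) abort("fewer than 3 points.")
  span <- max(points$mean_loading_rate) / min(points$mean_loading_rate)
  if (span < 10) warn("Loading rates span less than one decade; the Bell-Evans fit may be poorly constrained.")
  w <- 1 / points$error^2
  fit <- lm(mode_force ~ log(mean_loading_rate), data = points, weights = w)
  b <- unname(coef(fit)[2])   # f_beta
  a <- unname(coef(fit)[1])
  if (b <= 0) abort("Bell-Evans slope is non-positive; data are not slip-bond-like.")
  V <- suppressWarnings(vcov(fit))  # perfect fits trigger a summary.lm note
  k0 <- exp(-a / b) / b
  # delta method for k_off0 = exp(-a/b)/b
  g <- c(-k0 / b, k0 * (a / b - 1) / b)
  se_k0 <- sqrt(drop(t(g) %*% V %*% g))
  chi2 <- sum(w * stats::residuals(fit)^2)
  structure(
    list(f_beta = b, f_beta_se = sqrt(V[2, 2]),
         k_off0 = k0, k_off0_se = se_k0,
         chi2 = chi2, df = nrow(points) - 2L, n = nrow(points),
         lm = fit),
    class = "bell_evans_fit")
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat(sprintf("<bell_evans_fit>  f_beta = %.2f +/- %.2f pN   k_off0 = %.3f +/- %.3f s^-1   chi2 = %.3g (df %d)\n",
              x$f_beta, x$f_beta_se, x$k_off0, x$k_off0_se, x$chi2, x$df))
  invisible(x)
}

#' @export
tidy.bell_evans_fit <- function(x, ...) {
  tibble::tibble(term = c("f_beta", "k_off0"),
                 estimate = c(x$f_beta, x$k_off0),
                 std.error = c(x$f_beta_se, x$k_off0_se),
                 unit = c("pN", "s^-1"))
}

#' @export
glance.bell_evans_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, n = x$n)
}

#' Derivative-free chi-square minimization with restarts
#'
#' Nelder-Mead simplex minimization of [chi_squared()] over the free
#' parameters (internally log-transformed, so all parameters are positive),
#' restarted from jittered starting points; the restarts must agree for the
#' fit to be flagged converged.  Fixed parameters are appended to the free
#' ones before each model evaluation.
#'
#' @inheritParams chi_squared
#' @param start Named numeric vector of starting values for the free
#'   parameters (all > 0).
#' @param fixed Optional named numeric vector of parameters held constant.
#' @param restarts Number of starts (>= 1); starts after the first are
#'   jittered by `jitter_sd` on the log scale.
#' @param jitter_sd Log-scale SD of the start jitter.
#' @param reltol Relative chi-square convergence tolerance of each simplex.
#' @param agree_tol Restarts "agree" when their best chi-squares match
#'   within this relative tolerance.
#' @param lower,upper Optional named bounds (original scale) on the free
#'   parameters; values outside receive a large penalty, keeping the
#'   simplex in the physically meaningful region.
#' @return An object of class `chi2_fit`: `estimate` (named vector),
#'   `chi2`, `converged`, `restarts_agree`, plus the inputs needed by
#'   [param_errors()].
#' @export
minimize_chi2 <- function(points, model_fn, start, fixed = NULL,
                          restarts = 3, jitter_sd = 0.1,
                          reltol = 1e-8, agree_tol = 1e-3,
                          lower = NULL, upper = NULL) {
  check_points(points)
  stopifnot(restarts >= 1, all(start > 0))
  obj <- function(logp) {
    free <- setNames(exp(logp), names(start))
    if (!is.null(lower) && any(free[names(lower)] < lower)) return(1e12)
    if (!is.null(upper) && any(free[names(upper)] > upper)) return(1e12)
    params <- c(free, fixed)
    val <- tryCatch(chi_squared(points, model_fn, params),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e12 else val
  }
  starts <- c(list(log(start)),
              lapply(seq_len(restarts - 1), function(i)
                log(start) + rnorm(length(start), 0, jitter_sd)))
  runs <- lapply(starts, function(s)
    optim(s, obj, method = "Nelder-Mead",
          control = list(reltol = reltol, abstol = 1e-12, maxit = 2000)))
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  agree <- all(abs(vals - min(vals)) <= agree_tol * max(1, min(vals)))
  converged <- best$convergence == 0
  if (!converged)
    warn("chi-square minimization did not converge within the iteration budget.")
  structure(
    list(estimate = setNames(exp(best$par), names(start)),
         chi2 = best$value, converged = converged, restarts_agree = agree,
         restart_chi2 = vals, fixed = fixed, model_fn = model_fn,
         points = points, n = nrow(points)),
    class = "chi2_fit")
}

#' @export
print.chi2_fit <- function(x, ...) {
  est <- paste(sprintf("%s = %.4g", names(x$estimate), x$estimate),
               collapse = ", ")
  cat(sprintf("<chi2_fit>  %s   chi2 = %.4g   converged: %s (restarts agree: %s)\n",
              est, x$chi2, x$converged, x$restarts_agree))
  invisible(x)
}

#' @export
tidy.chi2_fit <- function(x, ...) {
  se <- attr(x, "std.error")
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate),
                 std.error = if (is.null(se)) NA_real_ else unname(se))
}

#' @export
glance.chi2_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, n = x$n, converged = x$converged,
                 restarts_agree = x$restarts_agree)
}

#' Curvature-based parameter errors
#'
#' Estimates each free parameter's standard error from the local curvature
#' of the chi-square surface, `sigma^2 = 2 / (d^2 chi2 / d x^2)`, using
#' central second differences at four step sizes with a Richardson
#' consistency check.  Directions with non-positive curvature are flagged
#' unconstrained (`NA` error).
#'
#' @param fit A [minimize_chi2()] result (or a fit wrapping one).
#' @param rel_steps Relative finite-difference step sizes.
#' @return The fit object with a `std.error` attribute (named vector, `NA`
#'   where unconstrained) and `unconstrained` attribute (logical vector).
#' @export
param_errors <- function(fit, rel_steps = c(0.005, 0.01, 0.02, 0.04)) {
  stopifnot(inherits(fit, "chi2_fit"))
  est <- fit$estimate
  curv <- vapply(seq_along(est), function(i) {
    d2 <- vapply(rel_steps, function(rs) {
      h <- max(abs(est[i]) * rs, 1e-12)
      pp <- pm <- est
      pp[i] <- est[i] + h
      pm[i] <- est[i] - h
      f0 <- chi_squared(fit$points, fit$model_fn, c(est, fit$fixed))
      fp <- chi_squared(fit$points, fit$model_fn, c(pp, fit$fixed))
      fm <- chi_squared(fit$points, fit$model_fn, c(pm, fit$fixed))
      (fp - 2 * f0 + fm) / h^2
    }, numeric(1))
    # Richardson extrapolation on the (h, 2h) pairs; use the smaller-step pair
    r1 <- (4 * d2[1] - d2[2]) / 3
    r2 <- (4 * d2[2] - d2[3]) / 3
    if (is.finite(r1) && is.finite(r2) && r1 > 0 && r2 > 0 &&
        abs(r1 - r2) <= 0.2 * abs(r2)) r1 else stats::median(d2)
  }, numeric(1))
  unconstrained <- !(is.finite(curv) & curv > 0)
  se <- ifelse(unconstrained, NA_real_, sqrt(2 / curv))
  attr(fit, "std.error") <- setNames(se, names(est))
  attr(fit, "unconstrained") <- setNames(unconstrained, names(est))
  fit
}

#' Fit the force-dependent avidity model to a dynamic force spectrum
#'
#' Chi-square fit of the multi-state rebinding model's most-probable rupture
#' force to mode points, with the single-bond parameters typically fixed
#' from a prior Bell-Evans fit and the rebinding parameters (`C_eff0`,
#' `f_c`) free.  Model evaluation inside the fit uses the fast reduced-
#' tolerance integration path; the final report is re-evaluated at full
#' tolerance.  The result also carries the chi-square of the no-rebinding
#' variant, so a likelihood-ratio-style `Delta chi2` is always available --
#' when it is small the data cannot distinguish rebinding from none and the
#' fitted `C_eff0` should not be interpreted.
#'
#' @inheritParams minimize_chi2
#' @param template An [avidity_params()] object supplying every parameter
#'   not being fitted.
#' @param free Character vector of free parameters among
#'   `C_eff0`, `f_c`, `k_off0`, `f_beta`, `k_on`.
#' @param variant Model variant fitted (see [rupture_density()]).
#' @param eps Fast-path integration step control used inside the fit.
#' @return A `chi2_fit` with `std.error` attribute filled in, plus elements
#'   `params` (the fitted `avidity_params`), `chi2_no_rebinding` and
#'   `delta_chi2_no_rebinding`.
#' @export
fit_avidity <- function(points, template, free = c("C_eff0", "f_c"),
                        variant = "full", restarts = 3, eps = 0.02) {
  check_points(points)
  stopifnot(inherits(template, "avidity_params"))
  all_par <- c(k_off0 = template$bond$k_off0, f_beta = template$bond$f_beta,
               k_on = template$k_on, C_eff0 = template$C_eff0,
               f_c = template$f_c)
  free <- match.arg(free, names(all_par), several.ok = TRUE)
  start <- all_par[free]
  fixed <- all_par[setdiff(names(all_par), free)]
  model_fn <- function(l_r, params) {
    a <- avidity_params(
      single_bond_params(params[["k_off0"]], params[["f_beta"]]),
      k_on = params[["k_on"]], C_eff0 = params[["C_eff0"]],
      f_c = params[["f_c"]])
    predict_mode_force(l_r, a, variant = variant, eps = eps)
  }
  # physically meaningful search region: effective concentrations beyond
  # the tens-of-millimolar scale and kilopiconewton force scales are
  # outside any tethered-ligand geometry
  bounds <- c(C_eff0 = 0.05, f_c = 500, k_off0 = 1e3, f_beta = 1e3,
              k_on = 1e9)
  fit <- minimize_chi2(points, model_fn, start, fixed, restarts = restarts,
                       upper = bounds[free])
  # final report at full tolerance
  model_fn_full <- function(l_r, params) {
    a <- avidity_params(
      single_bond_params(params[["k_off0"]], params[["f_beta"]]),
      k_on = params[["k_on"]], C_eff0 = params[["C_eff0"]],
      f_c = params[["f_c"]])
    predict_mode_force(l_r, a, variant = variant, eps = 0.005)
  }
  fit$chi2 <- chi_squared(points, model_fn_full, c(fit$estimate, fit$fixed))
  fit <- param_errors(fit)
  pars <- c(fit$estimate, fit$fixed)
  fit$params <- avidity_params(
    single_bond_params(pars[["k_off0"]], pars[["f_beta"]],
                       template$bond$label),
    k_on = pars[["k_on"]], C_eff0 = pars[["C_eff0"]], f_c = pars[["f_c"]])
  nr_fn <- function(l_r, params) {
    a <- avidity_params(
      single_bond_params(params[["k_off0"]], params[["f_beta"]]),
      k_on = params[["k_on"]], C_eff0 = 0, f_c = params[["f_c"]])
    predict_mode_force(l_r, a, variant = "no_rebinding", eps = 0.005)
  }
  fit$chi2_no_rebinding <- chi_squared(points, nr_fn, pars)
  fit$delta_chi2_no_rebinding <- fit$chi2_no_rebinding - fit$chi2
  fit
}

#' Simultaneous fit of heterozygous and homozygous mutant spectra
#'
#' Joint chi-square fit of the four-state heterogeneous model to
#' heterozygous-dimer mode points and the three-state model to
#' homozygous-mutant mode points, sharing the mutant single-bond parameters
#' (`k_off0_mut`, `f_beta_mut`) across both datasets.  Wild-type bond and
#' elasticity parameters stay fixed at their previously fitted values.
#'
#' @param points_het,points_hom Mode-point tibbles for the heterozygous and
#'   homozygous-mutant conditions.
#' @param template A [hetero_avidity_params()] supplying the fixed wild-type
#'   bond (type 1), on-rates, shared concentration and compliance scales,
#'   and starting values for the mutant bond (type 2).
#' @inheritParams fit_avidity
#' @return A `chi2_fit` over `k_off0_mut`, `f_beta_mut` with `std.error`
#'   filled in and the fitted `hetero_avidity_params` in `$params`.
#' @export
fit_hetero_simultaneous <- function(points_het, points_hom, template,
                                    restarts = 3, eps = 0.02) {
  check_points(points_het)
  check_points(points_hom)
  stopifnot(inherits(template, "hetero_avidity_params"))
  start <- c(k_off0_mut = template$bond2$k_off0,
             f_beta_mut = template$bond2$f_beta)
  build <- function(params) {
    mut <- single_bond_params(params[["k_off0_mut"]], params[["f_beta_mut"]],
                              template$bond2$label)
    list(
      het = hetero_avidity_params(template$bond1, mut, template$k_on1,
                                  template$k_on2, template$C0,
                                  template$f_c1, template$f_c2),
      hom = avidity_params(mut, template$k_on2, template$C0, template$f_c2))
  }
  # joint objective: the two point sets are stacked, with a dataset tag
  points <- dplyr::bind_rows(
    dplyr::mutate(points_het, .dataset = "het"),
    dplyr::mutate(points_hom, .dataset = "hom"))
  model_fn_at <- function(eps) function(l_r, params) {
    mods <- build(params)
    het <- points$.dataset == "het"
    out <- numeric(length(l_r))
    out[het] <- predict_mode_force(l_r[het], mods$het, eps = eps)
    out[!het] <- predict_mode_force(l_r[!het], mods$hom, variant = "full",
                                    eps = eps)
    out
  }
  fit <- minimize_chi2(points, model_fn_at(eps), start, restarts = restarts)
  fit$model_fn <- model_fn_at(eps)
  fit$chi2 <- chi_squared(points, model_fn_at(0.005), fit$estimate)
  fit <- param_errors(fit)
  fit$params <- build(fit$estimate)$het
  fit
}
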