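#' Rupture-force probability density under linear loading
#'
#' Integrates the kinetic scheme of the double-stranded connection,
#' B2 <-> B1 -> U, under a linearly increasing force `F = l_r * t`.
#' The doubly-bound state loses bonds at `2 k2(F)` (two bonds sharing the
#' load), the singly-bound state ruptures at `k1(F)` (one bond bearing the
#' whole load) or rebinds at `C_eff(F) * k_on`.  The rupture density over
#' time is the unbinding flux `k1(t) B1(t)`; its maximum times the loading
#' rate is the most-probable rupture force.
#'
#' Model variants: `"full"` uses the Gaussian force-dependent effective
#' concentration; `"constant_ceff"` freezes `C_eff` at its zero-force value;
#' `"no_rebinding"` sets it to zero.  `share_load = FALSE` removes load
#' sharing (both off-rates carry the full-force exponent), which together
#' with `"no_rebinding"` gives a pure two-step single-bond cascade.
#'
#' @param l_r Loading rate, pN s^-1 (scalar, > 0).
#' @param a An [avidity_params()] object.
#' @param variant Model variant, see Details.
#' @param share_load Split the load across the two bonds in B2 (default TRUE).
#' @param engine `"lsoda"` (stiff-capable solver, rtol 1e-8 / atol 1e-12,
#'   the reference path) or `"rk"` (rate-adaptive fixed-order integrator,
#'   the fast path used inside fitting).
#' @param rtol,atol Tolerances for the `"lsoda"` engine.
#' @param n_grid Output grid size for the `"lsoda"` engine.
#'
#' @return An object of class `rupture_density`: a list with a `data` tibble
#'   (`time`, `B2`, `B1`, `survival`, `density`), the `loading_rate`, the
#'   refined `mode_time` (s) and `mode_force` (pN), and the model variant.
#'   The density integrates to 1 within 1e-3.
#' @examples
#' wt <- avidity_params(single_bond_params(0.5, 13.5), 6.2e4, 465e-6, 10)
#' rd <- rupture_density(22.5, wt)
#' rd$mode_force
#' @export
rupture_density <- function(l_r, a,
                            variant = c("full", "constant_ceff", "no_rebinding"),
                            share_load = TRUE,
                            engine = c("lsoda", "rk"),
                            rtol = 1e-8, atol = 1e-12, n_grid = 2000) {
  variant <- match.arg(variant)
  engine <- match.arg(engine)
  if (!is.numeric(l_r) || length(l_r) != 1L || !is.finite(l_r) || l_r <= 0)
    abort("`l_r` must be a single positive loading rate (pN s^-1).")
  vcode <- match(variant, c("full", "constant_ceff", "no_rebinding")) - 1L

  # fast pass locates the support of the density
  quick <- ode_rupture_cpp(l_r, a$bond$k_off0, a$bond$f_beta, a$k_on,
                           a$C_eff0, a$f_c, vcode, share_load,
                           eps = 0.05, s_min = 1e-7)
  mode_est <- quick$time[which.max(quick$density)]

  if (engine == "rk") {
    sol <- ode_rupture_cpp(l_r, a$bond$k_off0, a$bond$f_beta, a$k_on,
                           a$C_eff0, a$f_c, vcode, share_load,
                           eps = 0.005, s_min = 1e-7)
    dat <- tibble::tibble(time = sol$time, B2 = sol$B2, B1 = sol$B1,
                          survival = sol$B2 + sol$B1, density = sol$density)
  } else {
    # integrate to survival exhaustion; the grid is extended to 10x the mode
    # time with exact zeros where survival has already dropped below 1e-7
    # (off-rates grow without bound there and carry no probability).
    t_surv <- utils::tail(quick$time, 1)
    t_end <- max(t_surv, 10 * mode_est)
    times <- seq(0, t_end, length.out = n_grid + 1)
    solve_times <- times[times <= t_surv]
    rhs <- function(t, y, parms) {
      F <- l_r * t
      k1 <- a$bond$k_off0 * exp(F / a$bond$f_beta)
      k2 <- if (share_load) a$bond$k_off0 * exp(F / (2 * a$bond$f_beta)) else k1
      c_on <- switch(variant,
        full = a$C_eff0 * exp(-(F / a$f_c)^2) * a$k_on,
        constant_ceff = a$C_eff0 * a$k_on,
        no_rebinding = 0)
      list(c(c_on * y[2] - 2 * k2 * y[1],
             -(c_on + k1) * y[2] + 2 * k2 * y[1]))
    }
    sol <- deSolve::lsoda(c(B2 = 1, B1 = 0), solve_times, rhs, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0)
      abort("rupture-density integration failed: solver tolerance not met.")
    sol <- as.data.frame(sol)
    pad <- length(times) - nrow(sol)
    tm <- c(sol$time, times[times > t_surv])
    B2 <- c(pmax(sol$B2, 0), rep(0, pad))
    B1 <- c(pmax(sol$B1, 0), rep(0, pad))
    F <- l_r * tm
    dat <- tibble::tibble(
      time = tm, B2 = B2, B1 = B1, survival = B2 + B1,
      density = a$bond$k_off0 * exp(pmin(F / a$bond$f_beta, 700)) * B1)
  }

  finalize_density(dat, l_r, variant, a)
}

#' Rupture-force density of a heterogeneous connection
#'
#' As [rupture_density()], but for a connection whose two strands carry
#' bonds of different types (the four-state scheme B2 <-> {B12, B11} -> U).
#' B11 is the singly-bound state in which bond type 1 holds the load, B12
#' the state in which type 2 holds it; the off-rates are
#' `k_ij = k_off0[j] * exp(F / (i * f_beta[j]))` for `i` attached bonds of
#' type `j`, and rebinding uses the partner strand's on-rate with the shared
#' zero-force effective concentration.  The rupture density is
#' `k11 B11 + k12 B12`.
#'
#' @param l_r Loading rate, pN s^-1.
#' @param h A [hetero_avidity_params()] object.
#' @inheritParams rupture_density
#' @return An object of class `rupture_density` (with per-state occupancies
#'   `B2`, `B12`, `B11`).
#' @export
hetero_rupture_density <- function(l_r, h, engine = c("lsoda", "rk"),
                                   rtol = 1e-8, atol = 1e-12, n_grid = 2000) {
  engine <- match.arg(engine)
  if (!is.numeric(l_r) || length(l_r) != 1L || !is.finite(l_r) || l_r <= 0)
    abort("`l_r` must be a single positive loading rate (pN s^-1).")

  quick <- ode_rupture_het_cpp(l_r, h$bond1$k_off0, h$bond1$f_beta,
                               h$bond2$k_off0, h$bond2$f_beta,
                               h$k_on1, h$k_on2, h$C0, h$f_c1, h$f_c2,
                               eps = 0.05, s_min = 1e-7)
  mode_est <- quick$time[which.max(quick$density)]

  if (engine == "rk") {
    sol <- ode_rupture_het_cpp(l_r, h$bond1$k_off0, h$bond1$f_beta,
                               h$bond2$k_off0, h$bond2$f_beta,
                               h$k_on1, h$k_on2, h$C0, h$f_c1, h$f_c2,
                               eps = 0.005, s_min = 1e-7)
    dat <- tibble::tibble(time = sol$time, B2 = sol$B2, B12 = sol$B12,
                          B11 = sol$B11,
                          survival = sol$B2 + sol$B12 + sol$B11,
                          density = sol$density)
  } else {
    t_surv <- utils::tail(quick$time, 1)
    t_end <- max(t_surv, 10 * mode_est)
    times <- seq(0, t_end, length.out = n_grid + 1)
    solve_times <- times[times <= t_surv]
    rhs <- function(t, y, parms) {
      F <- l_r * t
      k21 <- h$bond1$k_off0 * exp(F / (2 * h$bond1$f_beta))
      k22 <- h$bond2$k_off0 * exp(F / (2 * h$bond2$f_beta))
      k11 <- h$bond1$k_off0 * exp(F / h$bond1$f_beta)
      k12 <- h$bond2$k_off0 * exp(F / h$bond2$f_beta)
      C1 <- h$C0 * exp(-(F / h$f_c1)^2)
      C2 <- h$C0 * exp(-(F / h$f_c2)^2)
      list(c(C2 * h$k_on1 * y[2] + C1 * h$k_on2 * y[3] - (k21 + k22) * y[1],
             -(C2 * h$k_on1 + k12) * y[2] + k21 * y[1],
             -(C1 * h$k_on2 + k11) * y[3] + k22 * y[1]))
    }
    sol <- deSolve::lsoda(c(B2 = 1, B12 = 0, B11 = 0), solve_times, rhs,
                          parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0)
      abort("rupture-density integration failed: solver tolerance not met.")
    sol <- as.data.frame(sol)
    pad <- length(times) - nrow(sol)
    tm <- c(sol$time, times[times > t_surv])
    B2 <- c(pmax(sol$B2, 0), rep(0, pad))
    B12 <- c(pmax(sol$B12, 0), rep(0, pad))
    B11 <- c(pmax(sol$B11, 0), rep(0, pad))
    S <- B2 + B12 + B11
    # density as -dS/dt by central differences: the flux form
    # k11*B11 + k12*B12 amplifies the solver's absolute error by the
    # (unboundedly large) weak-bond off-rate once that state is empty.
    dens <- numeric(length(tm))
    ii <- 2:(length(tm) - 1L)
    dens[ii] <- (S[ii - 1L] - S[ii + 1L]) / (tm[ii + 1L] - tm[ii - 1L])
    dat <- tibble::tibble(
      time = tm, B2 = B2, B12 = B12, B11 = B11,
      survival = S, density = pmax(dens, 0))
  }

  finalize_density(dat, l_r, "hetero", h)
}

finalize_density <- function(dat, l_r, variant, params) {
  mode_time <- refine_mode(dat$time, dat$density)
  total <- trapz(dat$time, dat$density)
  structure(
    list(data = dat, loading_rate = l_r, variant = variant,
         mode_time = mode_time, mode_force = mode_time * l_r,
         total_probability = total, params = params),
    class = "rupture_density"
  )
}

#' @export
print.rupture_density <- function(x, ...) {
  cat(sprintf("<rupture_density %s>  l_r = %.4g pN/s  mode force = %.4g pN  (mode time %.4g s, integral %.6f)\n",
              x$variant, x$loading_rate, x$mode_force, x$mode_time,
              x$total_probability))
  invisible(x)
}

# argmax on the solved grid followed by local parabolic refinement;
# the density is smooth and unimodal for slip bonds.
refine_mode <- function(t, d) {
  i <- which.max(d)
  if (i <= 1L || i >= length(d)) return(t[i])
  tt <- t[(i - 1):(i + 1)]
  dd <- d[(i - 1):(i + 1)]
  fit <- coef(lm(dd ~ tt + I(tt^2)))
  if (!is.finite(fit[3]) || fit[3] >= 0) return(t[i])
  as.numeric(-fit[2] / (2 * fit[3]))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Predicted most-probable rupture force over loading rates
#'
#' Vectorized mode-force prediction for the multi-state models, used as the
#' forward model inside chi-square fitting.  Uses the fast integration path;
#' `eps` controls the rate-adaptive step (smaller is more accurate).
#'
#' @param l_r Loading rates, pN s^-1.
#' @param params An [avidity_params()] or [hetero_avidity_params()] object.
#' @inheritParams rupture_density
#' @param eps Step-control parameter of the fast integrator.
#' @return Numeric vector of mode forces, pN.
#' @export
predict_mode_force <- function(l_r, params, variant = "full",
                               share_load = TRUE, eps = 0.02) {
  vapply(l_r, function(r) {
    if (inherits(params, "hetero_avidity_params")) {
      sol <- ode_rupture_het_cpp(r, params$bond1$k_off0, params$bond1$f_beta,
                                 params$bond2$k_off0, params$bond2$f_beta,
                                 params$k_on1, params$k_on2, params$C0,
                                 params$f_c1, params$f_c2,
                                 eps = eps, s_min = 1e-7)
    } else {
      vcode <- match(variant, c("full", "constant_ceff", "no_rebinding")) - 1L
      sol <- ode_rupture_cpp(r, params$bond$k_off0, params$bond$f_beta,
                             params$k_on, params$C_eff0, params$f_c,
                             vcode, share_load, eps = eps, s_min = 1e-7)
    }
    r * refine_mode(sol$time, sol$density)
  }, numeric(1))
}

#' Gillespie first-passage lifetimes at constant force
#'
#' Exact stochastic simulation of the chain B2 <-> B1 -> U with rates frozen
#' at force `F`; the independent oracle for the closed-form
#' [dimer_mean_lifetime()].
#'
#' @param n Number of trajectories.
#' @param F Constant force, pN.
#' @param a An [avidity_params()] object.
#' @return Numeric vector of `n` first-passage times, s.
#' @export
gillespie_lifetimes <- function(n, F, a) {
  check_force(F)
  stopifnot(length(F) == 1L, n >= 1)
  k1 <- bond_off_rate(F, a$bond)
  k2 <- shared_load_off_rate(F, a$bond)
  c_on <- rebinding_rate(ceff_at_force(F, a), a$k_on)
  gillespie_constant_cpp(as.integer(n), k1, k2, c_on)
}
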