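#' Hair-bundle mechanical parameters
#'
#' Parameters of the single-tip-link reduction of hair-bundle mechanics:
#' gating-spring stiffness `k_g`, the geometric factor `gamma` converting
#' bundle deflection to gating-spring extension, the resting tension, and
#' the slow-adaptation motor.  The motor climbs (increasing tension) at
#' `motor_climb` and slips at a rate proportional to tension; the slip
#' coefficient is calibrated so the zero-stimulus fixed point reproduces
#' the resting tension exactly: `slip_coefficient = motor_climb / F_rest`
#' (nm s^-1 pN^-1).  The nominal motor slip rate is recorded alongside.
#'
#' @param k_g Gating-spring stiffness, mN m^-1 (numerically equal to
#'   pN nm^-1; default 0.6).
#' @param gamma Geometric factor, dimensionless in (0, 1] (default 0.12).
#' @param F_rest Resting tension, pN (default 10).
#' @param motor_climb Motor climbing rate, um s^-1 (default 1.6).
#' @param motor_slip_rate Nominal motor slip rate, s^-1 (default 0.01).
#' @param adaptation Enable the slow-adaptation motor (default FALSE).
#' @return An object of class `bundle_params`; `motor_climb_nm_s` and
#'   `slip_coefficient` are derived fields in nm-based units.
#' @export
bundle_params <- function(k_g = 0.6, gamma = 0.12, F_rest = 10,
                          motor_climb = 1.6, motor_slip_rate = 0.01,
                          adaptation = FALSE) {
  if (k_g <= 0) abort("`k_g` must be > 0.")
  if (gamma <= 0 || gamma > 1) abort("`gamma` must be in (0, 1].")
  if (F_rest < 0) abort("`F_rest` must be >= 0.")
  climb_nm_s <- motor_climb * 1e3
  structure(
    list(k_g = k_g, gamma = gamma, F_rest = F_rest,
         motor_climb = motor_climb, motor_climb_nm_s = climb_nm_s,
         motor_slip_rate = motor_slip_rate,
         slip_coefficient = if (F_rest > 0) climb_nm_s / F_rest else 0,
         adaptation = isTRUE(adaptation)),
    class = "bundle_params")
}

#' @export
print.bundle_params <- function(x, ...) {
  cat(sprintf("<bundle_params>  k_g = %.3g mN/m  gamma = %.3g  F_rest = %.3g pN  adaptation: %s\n",
              x$k_g, x$gamma, x$F_rest,
              if (x$adaptation) sprintf("on (climb %.3g um/s, slip coeff %.3g nm/s/pN)",
                                        x$motor_climb, x$slip_coefficient) else "off"))
  invisible(x)
}

#' Sinusoidal bundle-deflection stimulus
#'
#' Displacement-controlled stimulation (stiff-probe limit): the bundle
#' deflection waveform `x(t) = amplitude * sin(2 pi frequency t + phase)`
#' is imposed directly.  Phase is randomized per simulation run unless
#' given.
#'
#' @param frequency Stimulus frequency, Hz (>= 0; 0 with amplitude 0 means
#'   constant resting tension).
#' @param amplitude Peak bundle deflection, nm (>= 0).
#' @param phase Optional fixed phase, radians; default randomized per run.
#' @param duration_cap Optional cap on simulated time, s; default ten times
#'   the zero-amplitude mean lifetime.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(frequency = 0, amplitude = 0, phase = NULL,
                              duration_cap = NULL) {
  if (frequency < 0 || amplitude < 0) abort("`frequency` and `amplitude` must be >= 0.")
  structure(list(frequency = frequency, amplitude = amplitude, phase = phase,
                 duration_cap = duration_cap),
            class = "stimulus_protocol")
}

#' Instantaneous tip-link tension
#'
#' `F_t = max(0, F_rest + gamma * k_g * (x - x_a))`: the gating spring does
#' not exert compressive force, so tension is clamped at zero.
#'
#' @param x Bundle deflection, nm (vectorized).
#' @param x_a Adaptation-motor position, nm.
#' @param b A [bundle_params()] object.
#' @return Tip-link tension, pN.
#' @examples
#' b <- bundle_params()
#' tip_link_force(0, 0, b)      # resting tension, 10 pN
#' tip_link_force(1000, 0, b)   # 72 pN above rest
#' @export
tip_link_force <- function(x, x_a = 0, b = bundle_params()) {
  pmax(0, b$F_rest + b$gamma * b$k_g * (x - x_a))
}

#' One adaptation-motor update
#'
#' Explicit-Euler update of the motor position over `dt`: climbing moves
#' `x_a` down (increasing tension) at the climbing rate; slipping moves it
#' up at `slip_coefficient * F_t`.  At `F_t = F_rest` with no stimulus the
#' two balance and `x_a` is stationary.  With adaptation disabled, `x_a`
#' is returned unchanged.
#'
#' @param x_a Motor position, nm.
#' @param F_t Current tip-link tension, pN.
#' @param dt Time step, s.
#' @param b A [bundle_params()] object.
#' @return Updated motor position, nm.
#' @export
motor_step <- function(x_a, F_t, dt, b = bundle_params()) {
  if (!b$adaptation) return(x_a)
  x_a + dt * (b$slip_coefficient * F_t - b$motor_climb_nm_s)
}

# time step satisfying max(rate)*dt < 0.01 and resolving the stimulus
choose_mc_dt <- function(p, a, b) {
  F_max <- b$F_rest + b$gamma * b$k_g * p$amplitude
  r_max <- max(bond_off_rate(F_max, a$bond),
               2 * shared_load_off_rate(F_max, a$bond),
               rebinding_rate(a$C_eff0, a$k_on))
  dt <- 0.01 / r_max
  if (p$frequency > 0 && p$amplitude > 0)
    dt <- min(dt, 1 / (20 * p$frequency))
  if (dt < 1e-9)
    abort(sprintf("time-step constraint unsatisfiable: required dt = %.3g s is below the 1 ns floor at these rates.", dt))
  dt
}

#' Monte Carlo tip-link lifetime under oscillatory stimulation
#'
#' Fixed-time-step stochastic simulation of the {B2, B1, U} chain driven by
#' the instantaneous tip-link tension of a sinusoidally deflected bundle.
#' Each step evaluates the tension, the force-dependent off-rates, the
#' force-dependent effective concentration and the rebinding rate, and
#' draws the state transition with probability `1 - exp(-rate * dt)`
#' (linearized when `rate * dt < 1e-3`).  The run ends when both strands
#' are unbound.  The time step is chosen so `max(rate) * dt < 0.01` and at
#' least 20 steps per stimulus cycle.
#'
#' @param protocol A [stimulus_protocol()].
#' @param a An [avidity_params()] object.
#' @param b A [bundle_params()] object.
#' @param n Number of runs.
#' @param seed Optional integer seed (stimulus phases and transitions).
#' @param dt Time step, s; default chosen automatically.
#' @param record_events Also return the per-run event log (times and kinds
#'   of B2->B1, B1->B2, B1->U transitions).
#' @param burn_in Deterministic motor burn-in, s, applied before time zero
#'   when adaptation is enabled (default ten motor time constants).  The
#'   connection is taken to form during ongoing stimulation -- consistent
#'   with phase randomization -- so the motor starts from its
#'   stimulus-adapted steady state rather than from rest.
#' @return A list of class `mc_result`: `lifetime` (s, length `n`),
#'   `capped` (logical; runs stopped at the duration cap), `mean`, `sem`
#'   (over uncapped runs), `dt`, `n_capped`, and optionally `events`
#'   (tibble `run`, `time`, `kind`).
#' @export
simulate_tip_link_lifetime <- function(protocol, a, b = bundle_params(),
                                       n = 1, seed = NULL, dt = NULL,
                                       record_events = FALSE,
                                       burn_in = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(a, "avidity_params"), inherits(b, "bundle_params"))
  dt <- dt %||% choose_mc_dt(protocol, a, b)
  t_cap <- protocol$duration_cap %||% (10 * dimer_mean_lifetime(b$F_rest, a))
  if (is.null(burn_in)) {
    burn_in <- if (b$adaptation && b$slip_coefficient > 0)
      10 / (b$slip_coefficient * b$gamma * b$k_g) else 0
  }
  run <- function() {
    phases <- if (is.null(protocol$phase)) runif(n, 0, 2 * pi) else
      rep_len(protocol$phase, n)
    bundle_mc_cpp(as.integer(n), protocol$frequency, protocol$amplitude,
                  phases, a$bond$k_off0, a$bond$f_beta, a$k_on, a$C_eff0,
                  a$f_c, b$k_g, b$gamma, b$F_rest, b$motor_climb_nm_s,
                  b$slip_coefficient, b$adaptation, dt, t_cap,
                  record_events, burn_in)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ok <- !res$capped
  out <- list(lifetime = res$lifetime, capped = res$capped,
              mean = mean(res$lifetime[ok]),
              sem = sd(res$lifetime[ok]) / sqrt(max(sum(ok), 1)),
              dt = dt, n = n, n_capped = sum(res$capped))
  if (record_events) {
    ev <- tibble::as_tibble(res$events)
    ev$kind <- c("unbind_B2_B1", "rebind_B1_B2", "rupture_B1_U")[ev$code]
    out$events <- ev[c("run", "time", "kind")]
  }
  structure(out, class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result>  n = %d  mean lifetime = %.3g +/- %.2g s (SEM)  dt = %.3g s  capped: %d\n",
              x$n, x$mean, x$sem, x$dt, x$n_capped))
  invisible(x)
}

#' Mean tip-link lifetime over a frequency-amplitude grid
#'
#' Runs [simulate_tip_link_lifetime()] with phase-randomized sinusoids for
#' every combination of stimulus frequency and amplitude, and summarises
#' each grid cell as mean lifetime with its SEM.  Runs that hit the
#' duration cap are excluded from the means and counted.  Fully
#' reproducible from the master seed.
#'
#' @param frequencies Stimulus frequencies, Hz.
#' @param amplitudes Peak deflections, nm.
#' @param a An [avidity_params()] object.
#' @param b A [bundle_params()] object.
#' @param n Runs per grid cell.
#' @param seed Master seed.
#' @param dt Optional fixed time step, s (default per-cell automatic).
#' @return A tibble: `frequency`, `amplitude`, `mean_lifetime`, `sem`, `n`,
#'   `n_capped`, `dt`.
#' @export
tip_link_lifetime_grid <- function(frequencies, amplitudes, a,
                                   b = bundle_params(), n = 500, seed = 1,
                                   dt = NULL) {
  grid <- tidyr::expand_grid(frequency = frequencies, amplitude = amplitudes)
  withr::with_seed(seed, {
    cells <- purrr::pmap_dfr(grid, function(frequency, amplitude) {
      p <- stimulus_protocol(frequency, amplitude)
      r <- simulate_tip_link_lifetime(p, a, b, n = n, dt = dt)
      tibble::tibble(frequency = frequency, amplitude = amplitude,
                     mean_lifetime = r$mean, sem = r$sem, n = n,
                     n_capped = r$n_capped, dt = r$dt)
    })
  })
  cells
}
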