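#' Specification for a synthetic rupture-force dataset
#'
#' Bundles everything a rupture-force generator needs: the kinetic ground
#' truth, the loading-rate conditions, events per condition, the
#' force-measurement noise and an explicit seed.  Identical specs with
#' identical seeds produce bitwise-identical datasets.
#'
#' The default measurement noise of 0.5 pN reflects nanometre-scale bead
#' tracking at a trap stiffness of ~0.1 pN nm^-1.
#'
#' @param condition Condition label.
#' @param params A [single_bond_params()], [avidity_params()] or
#'   [hetero_avidity_params()] object (the generating model).
#' @param loading_rates Loading rates, pN s^-1.
#' @param n_events Events per loading rate (scalar or per-rate vector, >= 1).
#' @param noise_sd Gaussian force-measurement noise SD, pN (>= 0).
#' @param seed Integer master seed (required).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(condition, params, loading_rates, n_events,
                           noise_sd = 0.5, seed) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` must be given explicitly.")
  if (!inherits(params, c("single_bond_params", "avidity_params", "hetero_avidity_params")))
    abort("`params` must be a kinetic parameter object.")
  if (any(loading_rates <= 0)) abort("Loading rates must be positive.")
  n_events <- rep_len(as.integer(n_events), length(loading_rates))
  if (any(n_events < 1)) abort("`n_events` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(condition = as.character(condition), params = params,
         loading_rates = as.numeric(loading_rates), n_events = n_events,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' Sample synthetic rupture forces from a kinetic model
#'
#' Draws rupture events from the generating model of a [generator_spec()]:
#' rupture times are sampled either by inverse-CDF lookup on the (closed-form
#' or numerically integrated) survival function, or by a per-step stochastic
#' chain; the measured force is `l_r * t` plus Gaussian measurement noise.
#' The two samplers are cross-validated against each other in the package
#' tests.
#'
#' @param spec A [generator_spec()].
#' @param method `"inverse_cdf"` (default) or `"step"` (stochastic chain;
#'   available for `avidity_params` models).
#' @param variant Model variant for `avidity_params` generators
#'   (see [rupture_density()]).
#' @return A tibble with one row per rupture event: `condition`,
#'   `loading_rate` (nominal group), `loading_rate_measured`, `force` (pN).
#' @examples
#' wt <- single_bond_params(0.5, 13.5, "2mM_Ca")
#' spec <- generator_spec("2mM_Ca", wt, c(22.7, 377.8), 50, seed = 1)
#' head(simulate_rupture_forces(spec))
#' @export
simulate_rupture_forces <- function(spec, method = c("inverse_cdf", "step"),
                                    variant = "full") {
  method <- match.arg(method)
  stopifnot(inherits(spec, "generator_spec"))
  p <- spec$params
  withr::with_seed(spec$seed, {
    out <- purrr::map2_dfr(spec$loading_rates, spec$n_events, function(lr, n) {
      t_rup <- sample_rupture_times(n, lr, p, method, variant)
      force <- pmax(lr * t_rup + rnorm(n, 0, spec$noise_sd), 0.01)
      tibble::tibble(condition = spec$condition, loading_rate = lr,
                     loading_rate_measured = lr, force = force)
    })
  })
  out
}

sample_rupture_times <- function(n, l_r, p, method = "inverse_cdf",
                                 variant = "full") {
  if (inherits(p, "single_bond_params")) {
    # single slip bond under linear loading: exact closed-form inversion of
    # the survival S(t) = exp(-(k0 f_beta / l_r) (exp(l_r t / f_beta) - 1))
    u <- runif(n)
    (p$f_beta / l_r) * log1p(-log(u) * l_r / (p$k_off0 * p$f_beta))
  } else if (inherits(p, "avidity_params")) {
    vcode <- match(variant, c("full", "constant_ceff", "no_rebinding")) - 1L
    if (method == "step") {
      step_rupture_cpp(as.integer(n), l_r, p$bond$k_off0, p$bond$f_beta,
                       p$k_on, p$C_eff0, p$f_c, vcode, TRUE)
    } else {
      sol <- ode_rupture_cpp(l_r, p$bond$k_off0, p$bond$f_beta, p$k_on,
                             p$C_eff0, p$f_c, vcode, TRUE,
                             eps = 0.005, s_min = 1e-7)
      invert_survival(sol$time, sol$B2 + sol$B1, n)
    }
  } else {
    if (method == "step")
      abort("The step sampler is not provided for heterogeneous models; use inverse_cdf.")
    sol <- ode_rupture_het_cpp(l_r, p$bond1$k_off0, p$bond1$f_beta,
                               p$bond2$k_off0, p$bond2$f_beta,
                               p$k_on1, p$k_on2, p$C0, p$f_c1, p$f_c2,
                               eps = 0.005, s_min = 1e-7)
    invert_survival(sol$time, sol$B2 + sol$B12 + sol$B11, n)
  }
}

# inverse-CDF sampling on a tabulated, monotone survival curve
invert_survival <- function(t, S, n) {
  S <- cummin(pmin(S, 1))
  keep <- c(TRUE, diff(S) < 0)
  u <- runif(n, min = min(S), max = 1)
  approx(x = S[keep], y = t[keep], xout = u, rule = 2)$y
}

#' Published study conditions for the synthetic generator
#'
#' The packaged table of experimental conditions with their published kinetic
#' parameters, loading-rate ranges and event counts, so the whole synthetic
#' analysis chain can be run from one place.  Parameters not printed for a
#' condition (per-rate event counts; the EC1-5 compliance scale) are filled
#' with documented stand-ins: event totals are split equally across loading
#' rates, and the EC1-5 entry uses the zero-force effective concentration
#' inferred from its biolayer-interferometry lifetime with a compliance
#' force scale small enough that rebinding vanishes above ~6 pN.
#'
#' @return A tibble with columns `condition`, `type` (single_bond / dimer /
#'   hetero), `params` (list-column of parameter objects), `loading_rates`
#'   (list-column, pN s^-1) and `n_events` (total events).
#' @export
tip_link_conditions <- function() {
  k_on <- 6.2e4
  wt <- single_bond_params(0.5, 13.5, "WT_2mM_Ca")
  wt50 <- single_bond_params(1.0, 13.5, "WT_50uM_Ca")   # lifetime halved at 50 uM
  mut <- single_bond_params(1.4, 1.8, "R113G")
  lr_single <- exp(seq(log(22.7), log(377.8), length.out = 6))
  lr_dimer <- exp(seq(log(0.39), log(95.6), length.out = 7))
  lr_mut <- exp(seq(log(0.39), log(95.6), length.out = 5))

  dimer <- function(bond, C_eff0, f_c) avidity_params(bond, k_on, C_eff0, f_c)

  tibble::tibble(
    condition = c("WT_single_2mM", "WT_single_50uM", "full_dimer_2mM",
                  "EC15_dimer_2mM", "dimer_30uM", "dimer_10uM",
                  "R113G_het", "R113G_hom"),
    type = c("single_bond", "single_bond", "dimer", "dimer", "dimer", "dimer",
             "hetero", "dimer"),
    params = list(
      wt, wt50,
      dimer(wt, 465e-6, 10),
      dimer(single_bond_params(0.5, 13.5, "EC1-5"), 170e-6, 2.5),
      dimer(single_bond_params(0.5, 13.5, "30uM_Ca"), 465e-6, 10),
      dimer(single_bond_params(2.6, 13.5, "10uM_Ca"), 465e-6, 2.9),
      hetero_avidity_params(wt, mut, k_on, k_on, 465e-6, 10, 10),
      dimer(mut, 465e-6, 10)
    ),
    loading_rates = list(lr_single, lr_single, lr_dimer, lr_dimer, lr_dimer,
                         lr_dimer, lr_mut, lr_mut),
    n_events = c(411L, 174L, 247L, 159L, 339L, 344L, 316L, 264L)
  )
}

#' Generator spec for one published condition
#'
#' @param condition A condition name from [tip_link_conditions()].
#' @param seed Integer master seed.
#' @param noise_sd Force-measurement noise SD, pN.
#' @return A [generator_spec()] with the condition's parameters, loading
#'   rates and per-rate event counts (total split equally across rates).
#' @export
condition_spec <- function(condition, seed, noise_sd = 0.5) {
  tab <- tip_link_conditions()
  i <- match(condition, tab$condition)
  if (is.na(i)) abort(sprintf("Unknown condition '%s'.", condition))
  lr <- tab$loading_rates[[i]]
  generator_spec(condition, tab$params[[i]], lr,
                 n_events = max(1L, round(tab$n_events[i] / length(lr))),
                 noise_sd = noise_sd, seed = seed)
}

#' Synthetic force-extension trace with a rupture
#'
#' Generates a worm-like-chain-shaped pulling trace for a DNA-protein tether
#' at constant pulling speed, sampled at the camera frame rate, ending in an
#' abrupt drop to baseline at the requested rupture force and followed by a
#' baseline noise tail.  The pulling speed is chosen so that the terminal
#' (linear) force regime has slope `l_r`.  The default contour length is a
#' ~2385-bp DNA tether (0.34 nm per bp) plus the protein construct.
#'
#' @param l_r Target terminal loading rate, pN s^-1.
#' @param rupture_force Rupture force, pN (must be in the WLC-valid regime).
#' @param Lc,Lp,K WLC parameters: contour length nm, persistence length nm,
#'   stretch modulus pN.
#' @param sampling_rate Frames per second (default 1400).
#' @param noise_sd Gaussian force noise SD, pN.
#' @param baseline_s Post-rupture baseline duration, s.
#' @param seed Optional seed for the noise.
#' @return A tibble (`time` s, `extension` nm, `force` pN) with attributes
#'   `sampling_rate` and `rupture_time`.
#' @export
simulate_fx_trace <- function(l_r, rupture_force, Lc = 850, Lp = 45, K = 1200,
                              sampling_rate = 1400, noise_sd = 0.5,
                              baseline_s = 0.2, seed = NULL) {
  if (rupture_force <= 0.5 || rupture_force > 150)
    abort("infeasible rupture force for the WLC tether model.")
  gen <- function() {
    F_grid <- seq(0.2, rupture_force, length.out = 4000)
    x_grid <- wlc_extension(F_grid, Lc, Lp, K)
    # terminal stiffness dF/dx sets the pulling speed for the target slope
    m <- length(F_grid)
    dFdx <- (F_grid[m] - F_grid[m - 20]) / (x_grid[m] - x_grid[m - 20])
    v <- l_r / dFdx
    t_grid <- (x_grid - x_grid[1]) / v
    t_rup <- t_grid[m]
    tm <- seq(0, t_rup + baseline_s, by = 1 / sampling_rate)
    ramp <- tm <= t_rup
    force <- numeric(length(tm))
    ext <- numeric(length(tm))
    force[ramp] <- approx(t_grid, F_grid, xout = tm[ramp])$y
    ext[ramp] <- approx(t_grid, x_grid, xout = tm[ramp])$y
    force[!ramp] <- 0
    ext[!ramp] <- x_grid[m] + v * (tm[!ramp] - t_rup)
    force <- force + rnorm(length(tm), 0, noise_sd)
    out <- tibble::tibble(time = tm, extension = ext, force = force)
    attr(out, "sampling_rate") <- sampling_rate
    attr(out, "rupture_time") <- t_rup
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Synthetic biolayer-interferometry sensorgram triplet
#'
#' Emulates one BLI experiment: an experimental sensor carrying the specific
#' binding signal, a biocytin-quenched drift-control sensor, and a
#' binding-control sensor (analyte lacking the binding domain).  The binding
#' signal is a pseudo-first-order association `A (1 - exp(-k_obs t))`
#' followed by single-exponential dissociation `exp(-t/tau)`; all sensors
#' share a linear drift and carry independent Gaussian noise.
#'
#' @param tau Dissociation lifetime, s.
#' @param k_obs Observed association rate, s^-1.
#' @param amplitude Binding-signal amplitude at saturation, nm.
#' @param drift Linear drift slope, nm s^-1.
#' @param noise_sd Gaussian signal noise SD, nm.
#' @param durations Named phase durations, s: baseline, association,
#'   dissociation.
#' @param sampling_rate Samples per second.
#' @param seed Optional seed.
#' @return A named list of three sensorgram tibbles (`experimental`,
#'   `drift_control`, `binding_control`), each with columns `time`, `signal`,
#'   `phase`.
#' @export
simulate_sensorgram <- function(tau, k_obs, amplitude = 0.4, drift = 2e-4,
                                noise_sd = 0.005,
                                durations = c(baseline = 60, association = 120,
                                              dissociation = 300),
                                sampling_rate = 5, seed = NULL) {
  stopifnot(tau > 0, k_obs > 0)
  gen <- function() {
    tm <- seq(0, sum(durations), by = 1 / sampling_rate)
    phase <- cut(tm, breaks = c(-Inf, durations[1],
                                durations[1] + durations[2], Inf),
                 labels = c("baseline", "association", "dissociation"))
    t_assoc <- pmax(tm - durations[1], 0)
    t_diss <- pmax(tm - durations[1] - durations[2], 0)
    A_end <- amplitude * (1 - exp(-k_obs * durations[2]))
    specific <- ifelse(phase == "baseline", 0,
                ifelse(phase == "association",
                       amplitude * (1 - exp(-k_obs * t_assoc)),
                       A_end * exp(-t_diss / tau)))
    mk <- function(sig) tibble::tibble(
      time = tm,
      signal = sig + drift * tm + rnorm(length(tm), 0, noise_sd),
      phase = as.character(phase))
    list(experimental = mk(specific), drift_control = mk(0),
         binding_control = mk(0))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
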