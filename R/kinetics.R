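#' Force-dependent off-rates of a slip bond
#'
#' `bond_off_rate()` is the off-rate of a single bond bearing the entire
#' force, `k1(F) = k_off0 * exp(F / f_beta)`.  `shared_load_off_rate()` is the
#' per-bond off-rate when two bonds split the load equally,
#' `k2(F) = k_off0 * exp(F / (2 f_beta))`.  Both reduce to `k_off0` at zero
#' force and increase strictly with force (slip-bond behaviour).
#'
#' @param F Applied force, pN.  Vectorized; must be >= 0.
#' @param p A [single_bond_params()] object.
#' @return Off-rate(s), s^-1.
#' @examples
#' wt <- single_bond_params(0.5, 13.5)
#' bond_off_rate(10, wt)          # ~1.05 s^-1
#' shared_load_off_rate(10, wt)   # ~0.72 s^-1
#' @export
bond_off_rate <- function(F, p) {
  check_force(F)
  p$k_off0 * exp(F / p$f_beta)
}

#' @rdname bond_off_rate
#' @export
shared_load_off_rate <- function(F, p) {
  check_force(F)
  p$k_off0 * exp(F / (2 * p$f_beta))
}

check_force <- function(F) {
  if (!is.numeric(F) || any(!is.finite(F)) || any(F < 0))
    abort("Force `F` must be finite and non-negative (pN).")
  invisible(F)
}

#' Mean lifetime of a single slip bond under constant force
#'
#' `tau(F) = tau0 * exp(-F / f_beta)`, the reciprocal of [bond_off_rate()].
#'
#' @inheritParams bond_off_rate
#' @return Mean lifetime(s), s.
#' @examples
#' wt <- single_bond_params(k_off0 = 1 / 1.9, f_beta = 13.5)
#' bond_mean_lifetime(10, wt)  # ~0.9 s
#' @export
bond_mean_lifetime <- function(F, p) {
  check_force(F)
  p$tau0 * exp(-F / p$f_beta)
}

#' Most-probable rupture force of a slip bond under linear loading
#'
#' The Evans-Ritchie dynamic-strength relation for a single slip bond pulled
#' at constant loading rate `l_r`:
#' `f* = f_beta * log(l_r / (f_beta * k_off0))`.
#' The value is returned unclamped; at very slow loading it can be negative,
#' and callers needing a physical force clamp at zero.
#'
#' @param l_r Loading rate(s), pN s^-1.  Must be > 0.
#' @param p A [single_bond_params()] object.
#' @return Most-probable rupture force(s), pN.
#' @export
bell_evans_mode_force <- function(l_r, p) {
  if (!is.numeric(l_r) || any(!is.finite(l_r)) || any(l_r <= 0))
    abort("Loading rate `l_r` must be finite and strictly positive (pN s^-1).")
  p$f_beta * log(l_r / (p$f_beta * p$k_off0))
}

#' Effective concentration under force
#'
#' The effective concentration of the unbound binding domains in the
#' singly-bound state decays as a Gaussian in force, reflecting elastic
#' separation of the free ends as tension on the remaining strand grows:
#' `C_eff(F) = C_eff0 * exp(-(F/f_c)^2)`.
#'
#' @inheritParams bond_off_rate
#' @param a An [avidity_params()] object.
#' @return Effective concentration(s), M.
#' @export
ceff_at_force <- function(F, a) {
  check_force(F)
  a$C_eff0 * exp(-(F / a$f_c)^2)
}

#' Concentration of one molecule confined to a sphere
#'
#' The geometric estimate of the effective concentration of a tethered
#' binding partner: exactly one molecule free to move in a sphere whose
#' radius is the length of the binding domain.  For the ~10 nm EC1-2 domain
#' this gives roughly 400 uM.
#'
#' @param radius_nm Sphere radius, nm.  Must be > 0.
#' @return Molar concentration of one molecule per sphere volume.
#' @examples
#' sphere_ceff(10) * 1e6   # ~396 uM
#' @export
sphere_ceff <- function(radius_nm) {
  if (!is.numeric(radius_nm) || any(!is.finite(radius_nm)) || any(radius_nm <= 0))
    abort("`radius_nm` must be finite and strictly positive.")
  vol_L <- (4 / 3) * pi * (radius_nm * 1e-9)^3 * 1e3  # m^3 -> litres
  1 / (.N_A * vol_L)
}

#' Pseudo-first-order rebinding rate
#'
#' The concentration-dependent binding rate `C * k_on` of an unbound pair
#' held at effective concentration `C`.
#'
#' @param C Effective concentration, M.  Must be >= 0.
#' @param k_on Solution on-rate, M^-1 s^-1.  Must be > 0.
#' @return Rebinding rate(s), s^-1.
#' @examples
#' rebinding_rate(400e-6, 6.2e4)  # ~25 s^-1
#' @export
rebinding_rate <- function(C, k_on) {
  if (!is.numeric(C) || any(!is.finite(C)) || any(C < 0))
    abort("`C` must be finite and non-negative (M).")
  if (!is.numeric(k_on) || any(!is.finite(k_on)) || any(k_on <= 0))
    abort("`k_on` must be finite and strictly positive (M^-1 s^-1).")
  C * k_on
}

#' Mean lifetime of the double-stranded connection at constant force
#'
#' Mean first-passage time from the doubly-bound state B2 to full rupture U
#' for the chain B2 <-> B1 -> U with rates frozen at force `F`:
#' B2 -> B1 at `2 k2(F)`, B1 -> B2 at `C_eff(F) k_on`, B1 -> U at `k1(F)`.
#' The closed form is
#' `tau(F) = (k1 + C_eff(F) k_on + 2 k2) / (2 k1 k2)`,
#' which at `F = 0` reduces to the zero-force result
#' `tau = (C_eff0 k_on + 3 k_off0) / (2 k_off0^2)` returned by
#' [zero_force_dimer_lifetime()].  The closed form is cross-validated against
#' a Gillespie first-passage simulation in the package tests.
#'
#' @inheritParams ceff_at_force
#' @return Mean lifetime(s), s.
#' @examples
#' wt <- avidity_params(single_bond_params(0.5, 13.5),
#'                      k_on = 6.2e4, C_eff0 = 465e-6, f_c = 10)
#' zero_force_dimer_lifetime(wt)    # ~61 s
#' dimer_mean_lifetime(10, wt)      # ~8.6 s
#' @export
dimer_mean_lifetime <- function(F, a) {
  check_force(F)
  k1 <- bond_off_rate(F, a$bond)
  k2 <- shared_load_off_rate(F, a$bond)
  c_on <- rebinding_rate(ceff_at_force(F, a), a$k_on)
  (k1 + c_on + 2 * k2) / (2 * k1 * k2)
}

#' @rdname dimer_mean_lifetime
#' @export
zero_force_dimer_lifetime <- function(a) {
  k0 <- a$bond$k_off0
  (a$C_eff0 * a$k_on + 3 * k0) / (2 * k0^2)
}

#' Invert the zero-force lifetime for the effective concentration
#'
#' Solves the zero-force mean-lifetime relation
#' `tau = (C_eff k_on + 3 k_off0) / (2 k_off0^2)` for `C_eff`, giving an
#' empirical effective concentration from a measured zero-force lifetime
#' (e.g. from biolayer interferometry):
#' `C_eff = (2 k_off0^2 tau - 3 k_off0) / k_on`.
#'
#' @param tau Measured zero-force mean lifetime, s.  Must exceed
#'   `3 / (2 k_off0)`, the no-rebinding lifetime, for a non-negative solution.
#' @param k_off0 Zero-force single-bond off-rate, s^-1.
#' @param k_on Solution on-rate, M^-1 s^-1.
#' @return Effective concentration, M.
#' @examples
#' invert_lifetime_to_ceff(63.3, 0.5, 6.2e4) * 1e6  # ~486 uM
#' @export
invert_lifetime_to_ceff <- function(tau, k_off0, k_on) {
  stopifnot(is.numeric(tau), is.numeric(k_off0), is.numeric(k_on),
            k_off0 > 0, k_on > 0)
  if (any(tau < 3 / (2 * k_off0) - 1e-12))
    abort("lifetime inconsistent with rebinding model: tau must be >= 3/(2*k_off0).")
  pmax(0, (2 * k_off0^2 * tau - 3 * k_off0) / k_on)
}
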