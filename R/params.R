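#' Single-bond slip-bond parameters
#'
#' Container for the Bell-model description of one PCDH15--CDH23 bond under
#' one buffer condition: the zero-force off-rate `k_off0` and the force scale
#' `f_beta`, the force that accelerates unbinding e-fold.  Derived quantities
#' are the zero-force mean lifetime `tau0 = 1/k_off0` and the distance to the
#' unbinding transition state `x_ts = kT/f_beta`.
#'
#' @param k_off0 Zero-force off-rate, s^-1.  Must be > 0.
#' @param f_beta Force scale, pN.  Must be > 0.
#' @param label Optional condition tag, e.g. `"2mM_Ca"` or `"R113G"`.
#'
#' @return An object of class `single_bond_params` with fields `k_off0`,
#'   `f_beta`, `label` and derived `tau0` (s) and `x_ts` (nm).
#' @examples
#' wt <- single_bond_params(k_off0 = 0.5, f_beta = 13.5, label = "2mM_Ca")
#' wt$tau0   # 2 s
#' @export
single_bond_params <- function(k_off0, f_beta, label = "") {
  stopifnot(is.numeric(k_off0), length(k_off0) == 1L,
            is.numeric(f_beta), length(f_beta) == 1L)
  if (!is.finite(k_off0) || k_off0 <= 0) abort("`k_off0` must be a positive finite rate (s^-1).")
  if (!is.finite(f_beta) || f_beta <= 0) abort("`f_beta` must be a positive finite force (pN).")
  structure(
    list(k_off0 = k_off0, f_beta = f_beta, label = as.character(label),
         tau0 = 1 / k_off0, x_ts = kT / f_beta),
    class = "single_bond_params"
  )
}

#' @export
print.single_bond_params <- function(x, ...) {
  cat(sprintf("<single_bond_params%s>  k_off0 = %.3g s^-1  f_beta = %.3g pN  (tau0 = %.3g s, x_ts = %.3g nm)\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$k_off0, x$f_beta, x$tau0, x$x_ts))
  invisible(x)
}

#' Avidity parameters of the double-stranded connection
#'
#' Single-bond parameters plus the quantities governing rebinding of the
#' transiently unbound strand: the solution on-rate `k_on`, the zero-force
#' effective concentration `C_eff0` of the free EC1-2 domains, and the
#' compliance force scale `f_c` of the Gaussian decay of the effective
#' concentration with force.  `f_c = sqrt(2 * kappa * kT)` for strand
#' stiffness `kappa`, so `kappa = f_c^2 / (2 kT)` is derived.
#'
#' @param bond A [single_bond_params()] object.
#' @param k_on Solution on-rate, M^-1 s^-1.  Must be > 0.
#' @param C_eff0 Zero-force effective concentration, M.  Must be >= 0.
#' @param f_c Compliance force scale, pN.  Must be > 0.
#'
#' @return An object of class `avidity_params` with derived strand stiffness
#'   `kappa` in pN nm^-1.
#' @examples
#' wt <- single_bond_params(0.5, 13.5)
#' dimer <- avidity_params(wt, k_on = 6.2e4, C_eff0 = 465e-6, f_c = 10)
#' @export
avidity_params <- function(bond, k_on, C_eff0, f_c) {
  if (!inherits(bond, "single_bond_params")) abort("`bond` must be a `single_bond_params` object.")
  stopifnot(is.numeric(k_on), is.numeric(C_eff0), is.numeric(f_c))
  if (!is.finite(k_on) || k_on <= 0) abort("`k_on` must be a positive finite rate (M^-1 s^-1).")
  if (!is.finite(C_eff0) || C_eff0 < 0) abort("`C_eff0` must be a non-negative concentration (M).")
  if (!is.finite(f_c) || f_c <= 0) abort("`f_c` must be a positive finite force (pN).")
  structure(
    list(bond = bond, k_on = k_on, C_eff0 = C_eff0, f_c = f_c,
         kappa = f_c^2 / (2 * kT)),
    class = "avidity_params"
  )
}

#' @export
print.avidity_params <- function(x, ...) {
  cat(sprintf("<avidity_params%s>  k_off0 = %.3g s^-1, f_beta = %.3g pN, k_on = %.3g M^-1 s^-1, C_eff0 = %.3g uM, f_c = %.3g pN\n",
              if (nzchar(x$bond$label)) paste0(" ", x$bond$label) else "",
              x$bond$k_off0, x$bond$f_beta, x$k_on, x$C_eff0 * 1e6, x$f_c))
  invisible(x)
}

#' Parameters of a heterogeneous (mixed-bond) connection
#'
#' Describes a connection whose two strands carry bonds of different types,
#' e.g. a tip link heterozygous for a deafness mutation: one wild-type and one
#' mutant PCDH15--CDH23 bond.  Bond type j = 1 is conventionally the wild
#' type, j = 2 the mutant.  The zero-force effective concentration `C0` is
#' shared; on-rates and compliance force scales may differ per type.
#'
#' @param bond1,bond2 [single_bond_params()] for bond types 1 and 2.
#' @param k_on1,k_on2 Per-type solution on-rates, M^-1 s^-1.
#' @param C0 Shared zero-force effective concentration, M.
#' @param f_c1,f_c2 Per-type compliance force scales, pN.
#'
#' @return An object of class `hetero_avidity_params`.
#' @export
hetero_avidity_params <- function(bond1, bond2, k_on1, k_on2, C0, f_c1, f_c2 = f_c1) {
  if (!inherits(bond1, "single_bond_params") || !inherits(bond2, "single_bond_params"))
    abort("`bond1` and `bond2` must be `single_bond_params` objects.")
  vals <- c(k_on1 = k_on1, k_on2 = k_on2, C0 = C0, f_c1 = f_c1, f_c2 = f_c2)
  if (any(!is.finite(vals)) || any(vals[c("k_on1", "k_on2", "f_c1", "f_c2")] <= 0) || C0 < 0)
    abort("All rates and force scales must be strictly positive; `C0` non-negative.")
  structure(
    list(bond1 = bond1, bond2 = bond2, k_on1 = k_on1, k_on2 = k_on2,
         C0 = C0, f_c1 = f_c1, f_c2 = f_c2),
    class = "hetero_avidity_params"
  )
}

#' @export
print.hetero_avidity_params <- function(x, ...) {
  cat(sprintf("<hetero_avidity_params>  type1: k_off0 = %.3g, f_beta = %.3g | type2: k_off0 = %.3g, f_beta = %.3g | C0 = %.3g uM\n",
              x$bond1$k_off0, x$bond1$f_beta, x$bond2$k_off0, x$bond2$f_beta, x$C0 * 1e6))
  invisible(x)
}

# ---- serialization -----------------------------------------------------------

#' Serialize kinetic parameters to and from flat JSON
#'
#' Parameters are stored as a flat key-value record with explicit units in
#' the key names (`k_off0_per_s`, `f_beta_pN`, `k_on_per_M_s`, `C_eff0_uM`,
#' `f_c_pN`), so a config file is unambiguous about units.  Concentrations
#' are converted between micromolar (file) and molar (in memory) here --
#' the only place that conversion happens.
#'
#' @param x A `single_bond_params`, `avidity_params` or
#'   `hetero_avidity_params` object.
#' @param path File to write to / read from.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   the reconstructed parameter object.
#' @export
write_params <- function(x, path) {
  rec <- params_to_record(x)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

params_to_record <- function(x) {
  if (inherits(x, "single_bond_params")) {
    list(type = "single_bond", label = x$label,
         k_off0_per_s = x$k_off0, f_beta_pN = x$f_beta)
  } else if (inherits(x, "avidity_params")) {
    list(type = "avidity", label = x$bond$label,
         k_off0_per_s = x$bond$k_off0, f_beta_pN = x$bond$f_beta,
         k_on_per_M_s = x$k_on, C_eff0_uM = x$C_eff0 * 1e6, f_c_pN = x$f_c)
  } else if (inherits(x, "hetero_avidity_params")) {
    list(type = "hetero_avidity",
         label1 = x$bond1$label, label2 = x$bond2$label,
         k_off0_1_per_s = x$bond1$k_off0, f_beta_1_pN = x$bond1$f_beta,
         k_off0_2_per_s = x$bond2$k_off0, f_beta_2_pN = x$bond2$f_beta,
         k_on_1_per_M_s = x$k_on1, k_on_2_per_M_s = x$k_on2,
         C0_uM = x$C0 * 1e6, f_c_1_pN = x$f_c1, f_c_2_pN = x$f_c2)
  } else {
    abort("Unknown parameter object.")
  }
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- switch(rec$type,
    single_bond = c("type", "label", "k_off0_per_s", "f_beta_pN"),
    avidity = c("type", "label", "k_off0_per_s", "f_beta_pN",
                "k_on_per_M_s", "C_eff0_uM", "f_c_pN"),
    hetero_avidity = c("type", "label1", "label2", "k_off0_1_per_s",
                       "f_beta_1_pN", "k_off0_2_per_s", "f_beta_2_pN",
                       "k_on_1_per_M_s", "k_on_2_per_M_s", "C0_uM",
                       "f_c_1_pN", "f_c_2_pN"),
    abort(sprintf("Unknown parameter record type: %s", rec$type))
  )
  extra <- setdiff(names(rec), known)
  if (length(extra) > 0)
    abort(sprintf("Unknown key(s) in parameter file: %s", paste(extra, collapse = ", ")))
  switch(rec$type,
    single_bond = single_bond_params(rec$k_off0_per_s, rec$f_beta_pN, rec$label),
    avidity = avidity_params(
      single_bond_params(rec$k_off0_per_s, rec$f_beta_pN, rec$label),
      k_on = rec$k_on_per_M_s, C_eff0 = rec$C_eff0_uM * 1e-6, f_c = rec$f_c_pN),
    hetero_avidity = hetero_avidity_params(
      single_bond_params(rec$k_off0_1_per_s, rec$f_beta_1_pN, rec$label1),
      single_bond_params(rec$k_off0_2_per_s, rec$f_beta_2_pN, rec$label2),
      k_on1 = rec$k_on_1_per_M_s, k_on2 = rec$k_on_2_per_M_s,
      C0 = rec$C0_uM * 1e-6, f_c1 = rec$f_c_1_pN, f_c2 = rec$f_c_2_pN)
  )
}
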