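#' @useDynLib dscfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

#' Gas constant
#'
#' Molar gas constant in SI units, used throughout the package.
#'
#' @format Numeric scalar, 8.3145 J mol^-1 K^-1.
#' @export
R_GAS <- 8.3145

# temperatures far outside the liquid-water range come out of poorly
# constrained fits (reference temperatures of several kK are legitimate
# fit output); warn, never fail
check_temperature <- function(T, what = "T", warn_range = FALSE) {
  if (any(!is.finite(T)) || any(T <= 0)) {
    abort(paste0("`", what, "` must be positive and finite (absolute K)."),
          class = "dscfit_domain_error")
  }
  if (warn_range && (any(T < 250) || any(T > 500))) {
    warn(paste0("`", what, "` outside 250-500 K; legitimate for poorly ",
                "constrained reference temperatures, but check units."),
         class = "dscfit_suspicious_temperature")
  }
  invisible(T)
}

#' Parameter sets for reversible and irreversible transition steps
#'
#' `eq_params()` describes a reversible (equilibrium) step by its melting
#' temperature `tm` (K, where the equilibrium constant is 1), the molar
#' enthalpy change `dh` at `tm` (J mol^-1), the temperature-independent
#' heat-capacity change `dcp` (J mol^-1 K^-1), and optionally an independent
#' van't Hoff enthalpy `dh_vh` (J mol^-1). When `dh_vh` is supplied it governs
#' the temperature dependence of the equilibrium constant (the sharpness of
#' the transition) while `dh` remains the calorimetric amplitude (peak area),
#' the classical treatment of non-two-state reversible peaks.
#'
#' `arr_params()` describes an irreversible step obeying the Arrhenius law by
#' its activation energy `e` (J mol^-1) and the reference temperature `tf` (K)
#' at which the rate constant equals 1 s^-1, plus the step enthalpy `dh`
#' referenced at `tf` and its `dcp`.
#'
#' All quantities are SI (K, J); I/O helpers convert from instrument units.
#'
#' @param tm,tf Reference temperatures (K): `K(tm) = 1`, `k(tf) = 1` s^-1.
#' @param dh Molar enthalpy change at the reference temperature (J mol^-1).
#' @param dcp Molar heat-capacity change (J mol^-1 K^-1), constant.
#' @param dh_vh Optional van't Hoff enthalpy (J mol^-1).
#' @param e Activation energy (J mol^-1).
#' @return A list with class `"dscfit_eq_params"` or `"dscfit_arr_params"`.
#' @examples
#' eq_params(tm = 345.03, dh = 516e3, dcp = 7.5e3)
#' arr_params(e = 418e3, tf = 337.6, dh = 337e3)
#' @export
eq_params <- function(tm, dh, dcp = 0, dh_vh = NULL) {
  check_temperature(tm, "tm", warn_range = TRUE)
  stopifnot(is.finite(dh), is.finite(dcp))
  if (!is.null(dh_vh)) stopifnot(is.finite(dh_vh))
  structure(list(tm = tm, dh = dh, dcp = dcp, dh_vh = dh_vh),
            class = "dscfit_eq_params")
}

#' @rdname eq_params
#' @export
arr_params <- function(e, tf, dh = 0, dcp = 0) {
  check_temperature(tf, "tf", warn_range = TRUE)
  stopifnot(is.finite(e), is.finite(dh), is.finite(dcp))
  structure(list(e = e, tf = tf, dh = dh, dcp = dcp),
            class = "dscfit_arr_params")
}

#' Enthalpy change at an arbitrary temperature
#'
#' With a temperature-independent heat-capacity change, the step enthalpy is
#' linear in temperature: dH(T) = dH(T_ref) + dCp (T - T_ref).
#'
#' @param dh_ref Enthalpy change at `t_ref` (J mol^-1).
#' @param dcp Heat-capacity change (J mol^-1 K^-1).
#' @param t_ref,T Reference and evaluation temperatures (K).
#' @return Enthalpy change at `T` (J mol^-1). Vectorised over `T`.
#' @examples
#' enthalpy_at(800e3, 5e3, t_ref = 360, T = 350)
#' @export
enthalpy_at <- function(dh_ref, dcp, t_ref, T) {
  check_temperature(t_ref, "t_ref")
  check_temperature(T)
  dh_ref + dcp * (T - t_ref)
}

# enthalpy governing K(T): the van't Hoff value when provided
k_enthalpy <- function(p) if (is.null(p$dh_vh)) p$dh else p$dh_vh

#' Equilibrium constant, Gibbs energy and Arrhenius rate constant
#'
#' `equilibrium_constant()` evaluates K(T) = exp(-dG(T) / (R T)) for a
#' reversible step, with dG(T) = dH(T) - T dS(T), dH(T) linear in T per
#' [enthalpy_at()] (referenced at `tm`), and dS(T) = dH(tm)/tm +
#' dCp log(T/tm) — the unique constant-dCp convention for which dG(tm) = 0 and
#' hence K(tm) = 1. When a van't Hoff enthalpy is present it replaces the
#' calorimetric enthalpy inside K(T) (and dG keeps K(tm) = 1).
#'
#' `rate_constant()` evaluates the Arrhenius law in its one-temperature form
#' k(T) = exp(-(E/R) (1/T - 1/tf)), so that k(tf) = 1 s^-1 exactly.
#'
#' `gibbs_energy()` returns dG(T) = -R T log K(T).
#'
#' @param p An [eq_params()] (for K, dG) or [arr_params()] (for k) object.
#' @param T Temperature (K); vectorised.
#' @return Dimensionless K, dG in J mol^-1, or k in s^-1.
#' @examples
#' p <- eq_params(tm = 345.03, dh = 516e3)
#' equilibrium_constant(p, 345.03)  # exactly 1
#' rate_constant(arr_params(e = 418e3, tf = 337.6), 337.6)  # exactly 1
#' @export
equilibrium_constant <- function(p, T) {
  stopifnot(inherits(p, "dscfit_eq_params"))
  exp(-gibbs_energy(p, T) / (R_GAS * T))
}

#' @rdname equilibrium_constant
#' @export
gibbs_energy <- function(p, T) {
  stopifnot(inherits(p, "dscfit_eq_params"))
  check_temperature(T)
  dh_k <- k_enthalpy(p)
  dH <- dh_k + p$dcp * (T - p$tm)
  dS <- dh_k / p$tm + p$dcp * log(T / p$tm)
  dH - T * dS
}

#' @rdname equilibrium_constant
#' @export
rate_constant <- function(p, T) {
  stopifnot(inherits(p, "dscfit_arr_params"))
  check_temperature(T)
  exp(-(p$e / R_GAS) * (1 / T - 1 / p$tf))
}
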