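#' Transition steps of an unfolding chain
#'
#' An unfolding model is an ordered chain of transition steps: state 0 is the
#' native protein N and state s is reached after crossing step s. Three step
#' kinds are supported:
#'
#' * `step_equilibrium()` — a reversible step governed by an equilibrium
#'   constant K(T) ([eq_params()]), assumed fast relative to the scan.
#' * `step_irreversible()` — a kinetically controlled one-way step governed by
#'   an Arrhenius rate constant k(T) ([arr_params()]).
#' * `step_two_rate()` — a reversible step resolved into explicit forward and
#'   reverse Arrhenius rate constants (the first step of the general
#'   Lumry-Eyring three-state model); only valid as the first step of a chain.
#'
#' @param tm,tf,tf_fwd,tf_rev Reference temperatures (K).
#' @param dh Step enthalpy change (J mol^-1) at the step's reference
#'   temperature (`tm` for equilibrium steps, `tf` for irreversible ones,
#'   `tf_fwd` for two-rate steps). May be negative (exothermic step, e.g. the
#'   high-temperature aggregation peak).
#' @param dcp Step heat-capacity change (J mol^-1 K^-1).
#' @param dh_vh Optional van't Hoff enthalpy (J mol^-1), equilibrium steps only.
#' @param e,e_fwd,e_rev Activation energies (J mol^-1).
#' @return A `dscfit_step` object.
#' @seealso [unfolding_model()]
#' @export
step_equilibrium <- function(tm, dh, dcp = 0, dh_vh = NULL) {
  structure(list(kind = "equilibrium",
                 params = eq_params(tm, dh, dcp, dh_vh)),
            class = "dscfit_step")
}

#' @rdname step_equilibrium
#' @export
step_irreversible <- function(e, tf, dh, dcp = 0) {
  structure(list(kind = "irreversible",
                 params = arr_params(e, tf, dh, dcp)),
            class = "dscfit_step")
}

#' @rdname step_equilibrium
#' @export
step_two_rate <- function(e_fwd, tf_fwd, e_rev, tf_rev, dh, dcp = 0) {
  structure(list(kind = "two_rate",
                 fwd = arr_params(e_fwd, tf_fwd, dh, dcp),
                 rev = arr_params(e_rev, tf_rev)),
            class = "dscfit_step")
}

#' Build an unfolding model
#'
#' Assembles a validated unfolding model from a preset letter or an explicit
#' chain of steps, plus a linear instrumental baseline B0 + B1 T.
#'
#' Presets (pass `steps = "A"` etc. together with the named parameters the
#' preset needs, or build the chain explicitly):
#'
#' * **A** — reversible two-state, `N <-> D`: one equilibrium step.
#' * **B** — irreversible two-state, `N -> D`: one irreversible step.
#' * **C** — partially reversible three-state with fast first-step
#'   equilibrium, `N <-> I -> D`: equilibrium then irreversible.
#' * **D** — general Lumry-Eyring three-state, `N <-> I -> D` with explicit
#'   forward/reverse rates: two-rate then irreversible.
#'
#' Chains may append further irreversible steps (possibly with negative
#' enthalpy, modelling an exothermic high-temperature peak such as
#' aggregation). Chains whose first apparent peak is modelled by more than two
#' steps trigger a warning (conservative step-count rule) but are accepted.
#'
#' @param steps A preset letter `"A"`, `"B"`, `"C"`, `"D"`, or a list of
#'   [step_equilibrium()]/[step_irreversible()]/[step_two_rate()] objects.
#' @param b0 Baseline intercept (J mol^-1 K^-1).
#' @param b1 Baseline slope (J mol^-1 K^-2).
#' @param ... For presets: the step objects, in order, as unnamed arguments.
#' @return An `unfolding_model` object: list of steps plus baseline.
#' @examples
#' # model B for DbjA-like one-step irreversible unfolding
#' unfolding_model(list(step_irreversible(e = 418e3, tf = 337.6, dh = 337e3,
#'                                        dcp = 5.4e3)))
#' @export
unfolding_model <- function(steps, ..., b0 = 0, b1 = 0) {
  if (is.character(steps) && length(steps) == 1) {
    steps <- match.arg(steps, c("A", "B", "C", "D"))
    parts <- list(...)
    expected <- switch(steps,
      A = "equilibrium", B = "irreversible",
      C = c("equilibrium", "irreversible"),
      D = c("two_rate", "irreversible"))
    if (length(parts) != length(expected)) {
      abort(sprintf("Preset %s needs %d step object(s): %s.", steps,
                    length(expected), paste(expected, collapse = ", ")))
    }
    kinds <- vapply(parts, function(s) s$kind, character(1))
    if (!identical(kinds, expected)) {
      abort(sprintf("Preset %s expects step kinds (%s), got (%s).", steps,
                    paste(expected, collapse = ", "),
                    paste(kinds, collapse = ", ")))
    }
    preset <- steps
    steps <- parts
  } else {
    preset <- NULL
  }
  if (!is.list(steps) || length(steps) == 0) {
    abort("A model needs at least one transition step.")
  }
  if (!all(vapply(steps, inherits, logical(1), "dscfit_step"))) {
    abort("All elements of `steps` must be dscfit_step objects.")
  }
  kinds <- vapply(steps, function(s) s$kind, character(1))
  if (any(kinds[-1] == "two_rate") ||
      (length(kinds) > 1 && any(kinds[-1] == "equilibrium"))) {
    abort("Only the first step may be of kind two_rate or equilibrium.")
  }
  if (kinds[1] == "two_rate" && length(kinds) == 1) {
    abort("A two_rate first step needs at least one subsequent irreversible step.")
  }
  stopifnot(is.finite(b0), is.finite(b1))
  # conservative rule: first apparent peak = at most two steps; anything with
  # >2 positive-enthalpy steps before a sign change is treated as suspect
  dhs <- vapply(steps, step_dh, numeric(1))
  first_peak_len <- match(TRUE, dhs < 0, nomatch = length(dhs) + 1) - 1
  if (first_peak_len > 2) {
    warn("More than two steps model the first apparent peak; risk of over-fitting.",
         class = "dscfit_overfit_warning")
  }
  structure(list(steps = steps, b0 = b0, b1 = b1, preset = preset),
            class = "unfolding_model")
}

step_dh <- function(s) {
  if (s$kind == "two_rate") s$fwd$dh else s$params$dh
}

step_dcp <- function(s) {
  if (s$kind == "two_rate") s$fwd$dcp else s$params$dcp
}

n_states <- function(model) length(model$steps) + 1L

#' @export
print.unfolding_model <- function(x, ...) {
  kinds <- vapply(x$steps, function(s) s$kind, character(1))
  cat("<unfolding_model>",
      if (!is.null(x$preset)) paste0(" preset ", x$preset), "\n", sep = "")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    if (s$kind == "equilibrium") {
      p <- s$params
      cat(sprintf("  step %d equilibrium: Tm = %.2f K, dH = %.1f kJ/mol%s, dCp = %.2f kJ/mol/K\n",
                  i, p$tm, p$dh / 1e3,
                  if (!is.null(p$dh_vh)) sprintf(" (dHvH = %.1f kJ/mol)", p$dh_vh / 1e3) else "",
                  p$dcp / 1e3))
    } else if (s$kind == "irreversible") {
      p <- s$params
      cat(sprintf("  step %d irreversible: E = %.1f kJ/mol, Tf = %.1f K, dH = %.1f kJ/mol, dCp = %.2f kJ/mol/K\n",
                  i, p$e / 1e3, p$tf, p$dh / 1e3, p$dcp / 1e3))
    } else {
      cat(sprintf("  step %d two-rate: E1 = %.1f kJ/mol, Tf1 = %.1f K, E-1 = %.1f kJ/mol, Tf-1 = %.1f K, dH = %.1f kJ/mol, dCp = %.2f kJ/mol/K\n",
                  i, s$fwd$e / 1e3, s$fwd$tf, s$rev$e / 1e3, s$rev$tf,
                  s$fwd$dh / 1e3, s$fwd$dcp / 1e3))
    }
  }
  cat(sprintf("  baseline: B0 = %.2f kJ/mol/K, B1 = %.4f kJ/mol/K^2\n",
              x$b0 / 1e3, x$b1 / 1e3))
  invisible(x)
}

# cumulative enthalpy H_s(T) of state s relative to N, and cumulative dCp;
# returns list(H = matrix [length(T) x n_states], dcp_cum = numeric)
state_enthalpies <- function(model, T) {
  m <- length(model$steps)
  H <- matrix(0, length(T), m + 1L)
  dcp_cum <- numeric(m + 1L)
  for (s in seq_len(m)) {
    st <- model$steps[[s]]
    if (st$kind == "equilibrium") {
      p <- st$params
      dH <- p$dh + p$dcp * (T - p$tm)
    } else if (st$kind == "irreversible") {
      p <- st$params
      dH <- p$dh + p$dcp * (T - p$tf)
    } else {
      p <- st$fwd
      dH <- p$dh + p$dcp * (T - p$tf)
    }
    H[, s + 1L] <- H[, s] + dH
    dcp_cum[s + 1L] <- dcp_cum[s] + step_dcp(st)
  }
  list(H = H, dcp_cum = dcp_cum)
}
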