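# run code with a temporarily seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Native-state decay factor over a linear ramp
#'
#' For a one-way Arrhenius step, the fraction of native protein surviving a
#' linear ramp from `t_from` to `t_to` at rate `v` is
#' X = exp(-(1/|v|) * integral of k(T) dT along the path). The decay factor
#' satisfies X(T, T) = 1 and the path-reversal identity
#' X(t_from, t_to, -v) = X(t_to, t_from, v): cooling back over the same path
#' costs the same fraction as heating over it.
#'
#' @param p An [arr_params()] object.
#' @param t_from,t_to Path endpoints (K).
#' @param v Signed scan rate (K s^-1); its sign must match the path direction.
#' @return Dimensionless survival fraction in (0, 1].
#' @examples
#' p <- arr_params(e = 300e3, tf = 360)
#' decay_factor_irreversible(p, 293.15, 342, 1 / 60)
#' @export
decay_factor_irreversible <- function(p, t_from, t_to, v) {
  stopifnot(inherits(p, "dscfit_arr_params"))
  check_temperature(c(t_from, t_to))
  if (v == 0) abort("Scan rate `v` must be non-zero.")
  if (t_from == t_to) return(1)
  if (sign(t_to - t_from) != sign(v)) {
    abort("Path direction must match the sign of the scan rate.")
  }
  intk <- stats::integrate(function(T) rate_constant(p, T),
                           lower = min(t_from, t_to), upper = max(t_from, t_to),
                           rel.tol = 1e-10, abs.tol = 0)$value
  exp(-intk / abs(v))
}

# state names x_n, x_i / x_i1..., x_d for an m-step chain
state_names <- function(model) {
  m <- length(model$steps)
  if (m == 1) return(c("x_n", "x_d"))
  mids <- if (m == 2) "x_i" else paste0("x_i", seq_len(m - 1))
  c("x_n", mids, "x_d")
}

# flatten a model's step chain into the form the C++ propagator expects
chain_spec <- function(model) {
  first <- model$steps[[1]]
  rest <- model$steps[-1]
  irr_e <- vapply(rest, function(s) s$params$e, numeric(1))
  irr_tf <- vapply(rest, function(s) s$params$tf, numeric(1))
  if (first$kind == "equilibrium") {
    p <- first$params
    list(kind1 = 0L, eq_tm = p$tm, eq_dhk = k_enthalpy(p), eq_dcpk = p$dcp,
         irr_e = irr_e, irr_tf = irr_tf)
  } else if (first$kind == "irreversible") {
    list(kind1 = 1L, irr_e = c(first$params$e, irr_e),
         irr_tf = c(first$params$tf, irr_tf))
  } else {
    list(kind1 = 2L, tr_e1 = first$fwd$e, tr_tf1 = first$fwd$tf,
         tr_em1 = first$rev$e, tr_tfm1 = first$rev$tf,
         irr_e = irr_e, irr_tf = irr_tf)
  }
}

segment_grid <- function(t_start, t_end, grid_step) {
  n <- max(2L, ceiling(abs(t_end - t_start) / grid_step) + 1L)
  seq(t_start, t_end, length.out = n)
}

# Core multi-segment propagation. `segments` is a list of
# list(grid = temperatures (K, monotone along the ramp), v = signed rate).
# Returns one list(x, dx) per segment: full state fractions and their
# temperature derivatives at the grid nodes. Continuity is enforced by
# carrying the terminal ODE state into the next segment.
propagate_chain <- function(model, segments, rtol = 1e-8, atol = 1e-12,
                            warn_start = TRUE) {
  m <- length(model$steps)
  first <- model$steps[[1]]
  out <- vector("list", length(segments))

  if (m == 1 && first$kind == "equilibrium") {
    # fully reversible two-state: algebraic, history-free
    p <- first$params
    if (warn_start &&
        equilibrium_constant(p, segments[[1]]$grid[1]) > 1 / 0.999 - 1) {
      warn("More than 0.1% of protein is non-native at the program start.",
           class = "dscfit_assumption_warning")
    }
    for (i in seq_along(segments)) {
      Tg <- segments[[i]]$grid
      K <- equilibrium_constant(p, Tg)
      xd <- K / (1 + K)
      dhk <- k_enthalpy(p) + p$dcp * (Tg - p$tm)
      xdp <- (K / (1 + K)^2) * dhk / (R_GAS * Tg^2)
      out[[i]] <- list(x = cbind(1 - xd, xd), dx = cbind(-xdp, xdp))
    }
    return(out)
  }

  spec <- chain_spec(model)
  nst <- m + 1L
  # initial condition: all protein native (an equilibrium first step
  # redistributes N <-> I instantly at the start temperature)
  x0 <- c(1, numeric(nst - 1L))
  if (spec$kind1 == 0L) {
    K0 <- equilibrium_constant(first$params, segments[[1]]$grid[1])
    if (warn_start && K0 > 1 / 0.999 - 1) {
      warn("More than 0.1% of protein is non-native at the program start.",
           class = "dscfit_assumption_warning")
    }
    x0[1] <- 1 / (1 + K0)
    x0[2] <- K0 / (1 + K0)
  }
  for (i in seq_along(segments)) {
    Tg <- segments[[i]]$grid
    res <- chain_propagate_cpp(spec, Tg, segments[[i]]$v, x0, rtol, atol,
                               max_subdiv = 100000L)
    x0 <- res$x[nrow(res$x), ]   # full fractions carry across segments
    out[[i]] <- res
  }
  out
}

# heat-capacity synthesis from states + derivatives at temperatures T
cp_from_states <- function(model, T, x, dx, baseline = TRUE) {
  se <- state_enthalpies(model, T)
  cp <- rowSums(dx * se$H) + as.vector(x %*% se$dcp_cum)
  if (baseline) cp <- cp + model$b0 + model$b1 * T
  cp
}

#' Simulate state fractions along a temperature program
#'
#' Propagates the fractions of every chain state through each segment of a
#' temperature program, with continuity at segment boundaries. The reversible
#' two-state model is history-free and evaluated in closed form; all kinetic
#' chains are integrated as linear ODE systems in temperature with the signed
#' scan rate, so the equilibrium-shift term of the fast-equilibrium model
#' automatically reverses its effect on cooling, and reheated runs inherit the
#' full heat-cool history of the native fraction.
#'
#' @param model An [unfolding_model()].
#' @param program A [temperature_program()].
#' @param grid_step Output grid spacing (K); default 0.1.
#' @param rtol,atol Integration tolerances (relative / absolute on fractions).
#' @return A tibble with class `dsc_trajectory`: columns `segment`, `role`,
#'   `rate`, `temperature` and one `x_*` fraction column per state; the
#'   analytic temperature derivatives of the fractions are carried in the
#'   `"deriv"` attribute for heat-capacity synthesis.
#' @export
simulate_fractions <- function(model, program, grid_step = 0.1,
                               rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(model, "unfolding_model"), inherits(program, "dsc_program"))
  snames <- state_names(model)
  segments <- lapply(seq_len(nrow(program)), function(i) list(
    grid = segment_grid(program$t_start[i], program$t_end[i], grid_step),
    v = program$rate[i]))
  res <- propagate_chain(model, segments, rtol, atol)
  tabs <- lapply(seq_along(res), function(i) {
    tab <- tibble(segment = i, role = program$role[i], rate = program$rate[i],
                  temperature = segments[[i]]$grid)
    x <- res[[i]]$x
    for (s in seq_along(snames)) tab[[snames[s]]] <- x[, s]
    tab
  })
  traj <- dplyr::bind_rows(tabs)
  deriv <- do.call(rbind, lapply(res, `[[`, "dx"))
  colnames(deriv) <- snames
  attr(traj, "deriv") <- deriv
  attr(traj, "n_states") <- length(snames)
  class(traj) <- unique(c("dsc_trajectory", class(traj)))
  traj
}

#' Apparent molar heat capacity from a state trajectory
#'
#' Synthesises the apparent molar heat capacity
#' Cp(T) = B0 + B1 T + d/dT \[ sum_s x_s(T) H_s(T) \],
#' where H_s(T) is the cumulative enthalpy of state s relative to the native
#' state (each step's enthalpy referenced at its own Tm or Tf). The derivative
#' is expanded analytically as sum_s H_s dx_s/dT + sum_s x_s dCp_cum,s, so the
#' excess-heat term uses the exact ODE derivatives rather than numerical
#' differencing. For the one-step irreversible model this reduces exactly to
#' B0 + B1 T + (1 - x_n) dCp + (k/v) x_n dH(T); for the reversible two-state
#' model it reduces to the classical expression, with an optional van't Hoff
#' enthalpy controlling the sharpness term while the calorimetric enthalpy
#' sets the amplitude.
#'
#' @param model The [unfolding_model()] that produced the trajectory.
#' @param trajectory A `dsc_trajectory` from [simulate_fractions()].
#' @param roles Which segment roles to evaluate (default the heating scans).
#' @return A tibble with columns `segment`, `role`, `temperature`, `cp`
#'   (J mol^-1 K^-1).
#' @export
apparent_heat_capacity <- function(model, trajectory,
                                   roles = c("first", "reheat")) {
  stopifnot(inherits(model, "unfolding_model"),
            inherits(trajectory, "dsc_trajectory"))
  nst <- attr(trajectory, "n_states")
  if (is.null(nst) || nst != n_states(model)) {
    abort("Trajectory does not match the model (different state count).")
  }
  keep <- trajectory$role %in% roles
  Tg <- trajectory$temperature[keep]
  X <- as.matrix(trajectory[keep, state_names(model), drop = FALSE])
  dX <- attr(trajectory, "deriv")[keep, , drop = FALSE]
  tibble(segment = trajectory$segment[keep], role = trajectory$role[keep],
         temperature = Tg, cp = cp_from_states(model, Tg, X, dX))
}

#' Simulate DSC thermograms for a reheating experiment
#'
#' Composes [simulate_fractions()] and [apparent_heat_capacity()] over a full
#' temperature program and emits one thermogram per *heating* segment (cooling
#' is simulated for state propagation but not recorded, as a DSC instrument
#' records heating scans). Optional Gaussian noise is added per point with a
#' fixed seed for reproducibility.
#'
#' @inheritParams simulate_fractions
#' @param noise_sd Noise standard deviation (J mol^-1 K^-1), >= 0.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param experiment,protein Metadata labels for the output table.
#' @return A [dsc_scans()] tibble with one scan per heating segment.
#' @examples
#' m <- unfolding_model(list(step_irreversible(418e3, 337.6, 337e3, 5.4e3)))
#' prog <- heat_cool_reheat(293.15, 335, rate = 1 / 60, t_end = 360)
#' sim <- simulate_thermogram(m, prog, noise_sd = 500, seed = 1)
#' @export
simulate_thermogram <- function(model, program, grid_step = 0.1,
                                noise_sd = 0, seed = NULL,
                                experiment = "sim", protein = NA_character_) {
  stopifnot(noise_sd >= 0)
  traj <- simulate_fractions(model, program, grid_step)
  cp <- apparent_heat_capacity(model, traj)
  first_rows <- program$role == "first"
  t_prime <- if (any(first_rows)) max(program$t_end[first_rows]) else NA_real_
  scans <- dplyr::transmute(
    cp,
    experiment = experiment, protein = protein, role = .data$role,
    scan_rate = abs(program$rate[.data$segment]),
    t_prime = ifelse(.data$role == "reheat", t_prime, NA_real_),
    temperature = .data$temperature, cp = .data$cp)
  if (noise_sd > 0) {
    scans$cp <- scans$cp +
      with_seed(seed, stats::rnorm(nrow(scans), sd = noise_sd))
  }
  dsc_scans(scans)
}
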