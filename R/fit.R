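# ---- parameter flattening -------------------------------------------------
# Fits are parameterized in laboratory units (kJ, K) for conditioning;
# energies and enthalpies in kJ/mol, heat capacities in kJ/mol/K.

flatten_model <- function(model) {
  vals <- numeric(0); kinds <- character(0)
  add <- function(name, value, kind) {
    vals[name] <<- value; kinds[name] <<- kind
  }
  for (i in seq_along(model$steps)) {
    s <- model$steps[[i]]
    if (s$kind == "equilibrium") {
      p <- s$params
      add(paste0("tm", i), p$tm, "tm")
      add(paste0("dh", i), p$dh / 1e3, "dh")
      if (!is.null(p$dh_vh)) add(paste0("dhvh", i), p$dh_vh / 1e3, "dhvh")
      add(paste0("dcp", i), p$dcp / 1e3, "dcp")
    } else if (s$kind == "irreversible") {
      p <- s$params
      add(paste0("e", i), p$e / 1e3, "e")
      add(paste0("tf", i), p$tf, "tf")
      add(paste0("dh", i), p$dh / 1e3, "dh")
      add(paste0("dcp", i), p$dcp / 1e3, "dcp")
    } else {
      add(paste0("e", i), s$fwd$e / 1e3, "e")
      add(paste0("tf", i), s$fwd$tf, "tf")
      add(paste0("e_rev", i), s$rev$e / 1e3, "e")
      add(paste0("tf_rev", i), s$rev$tf, "tf")
      add(paste0("dh", i), s$fwd$dh / 1e3, "dh")
      add(paste0("dcp", i), s$fwd$dcp / 1e3, "dcp")
    }
  }
  list(values = vals, kinds = kinds)
}

build_model <- function(template, par) {
  steps <- vector("list", length(template$steps))
  for (i in seq_along(template$steps)) {
    kind <- template$steps[[i]]$kind
    g <- function(stem) unname(par[paste0(stem, i)])
    steps[[i]] <- if (kind == "equilibrium") {
      step_equilibrium(tm = g("tm"), dh = g("dh") * 1e3, dcp = g("dcp") * 1e3,
                       dh_vh = if (!is.null(template$steps[[i]]$params$dh_vh))
                         g("dhvh") * 1e3)
    } else if (kind == "irreversible") {
      step_irreversible(e = g("e") * 1e3, tf = g("tf"), dh = g("dh") * 1e3,
                        dcp = g("dcp") * 1e3)
    } else {
      step_two_rate(e_fwd = g("e") * 1e3, tf_fwd = g("tf"),
                    e_rev = g("e_rev") * 1e3, tf_rev = g("tf_rev"),
                    dh = g("dh") * 1e3, dcp = g("dcp") * 1e3)
    }
  }
  unfolding_model(steps)
}

default_bounds <- function(kinds) {
  lo <- c(tm = 250, tf = 250, e = 0.5, dh = -6000, dhvh = 1, dcp = -100,
          b0 = -Inf, b1 = -Inf)
  hi <- c(tm = 500, tf = 6000, e = 6000, dh = 6000, dhvh = 6000, dcp = 100,
          b0 = Inf, b1 = Inf)
  list(lower = unname(lo[kinds]), upper = unname(hi[kinds]))
}

par_units <- function(kinds) {
  u <- c(tm = "K", tf = "K", e = "kJ/mol", dh = "kJ/mol", dhvh = "kJ/mol",
         dcp = "kJ/mol/K", b0 = "kJ/mol/K", b1 = "kJ/mol/K^2")
  unname(u[kinds])
}

# ---- prediction plan ------------------------------------------------------
# Every scan maps to a propagation "job": a first scan is a single heating
# segment over its own data temperatures; a reheat is a full heat (to its
# t_prime) - cool - reheat propagation, with internal node grids on the
# unrecorded segments and the data temperatures as nodes on the reheat.

build_jobs <- function(data, internal_step = 1) {
  idx <- scan_index(data)
  rates <- sort(unique(idx$scan_rate))
  group_of <- function(rate) match(rate, rates)
  jobs <- list()
  for (e in unique(data$experiment)) {
    rows_e <- which(data$experiment == e)
    t0 <- min(data$temperature[rows_e])
    first_rows <- rows_e[data$role[rows_e] == "first"]
    if (length(first_rows) > 0) {
      Tf <- data$temperature[first_rows]
      v <- data$scan_rate[first_rows][1]
      jobs[[length(jobs) + 1L]] <- list(
        segments = list(list(grid = Tf, v = v)),
        emit = list(list(seg = 1L, nodes = seq_along(Tf), rows = first_rows,
                         group = group_of(v))))
    }
    rh_rows <- rows_e[data$role[rows_e] == "reheat"]
    for (tp in unique(data$t_prime[rh_rows])) {
      rows <- rh_rows[data$t_prime[rh_rows] == tp]
      Tr <- data$temperature[rows]
      v <- data$scan_rate[rows][1]
      pre <- if (Tr[1] > t0 + 1e-9) {
        g <- segment_grid(t0, Tr[1], internal_step)
        g[-length(g)]
      } else numeric(0)
      reheat_grid <- c(pre, Tr)
      jobs[[length(jobs) + 1L]] <- list(
        segments = list(
          list(grid = segment_grid(t0, tp, internal_step), v = v),
          list(grid = segment_grid(tp, t0, internal_step), v = -v),
          list(grid = reheat_grid, v = v)),
        emit = list(list(seg = 3L, nodes = length(pre) + seq_along(Tr),
                         rows = rows, group = group_of(v))))
    }
  }
  list(jobs = jobs, rates = rates, n_groups = length(rates))
}

predict_from_par <- function(template, par, plan, data,
                             rtol = 1e-6, atol = 1e-10) {
  model <- suppressWarnings(build_model(template, par))
  b0 <- par[paste0("b0_g", seq_len(plan$n_groups))] * 1e3
  b1 <- par[paste0("b1_g", seq_len(plan$n_groups))] * 1e3
  pred <- numeric(nrow(data))
  for (job in plan$jobs) {
    res <- propagate_chain(model, job$segments, rtol, atol, warn_start = FALSE)
    for (em in job$emit) {
      Tn <- job$segments[[em$seg]]$grid[em$nodes]
      cp <- cp_from_states(model, Tn,
                           res[[em$seg]]$x[em$nodes, , drop = FALSE],
                           res[[em$seg]]$dx[em$nodes, , drop = FALSE],
                           baseline = FALSE)
      pred[em$rows] <- cp + b0[em$group] + b1[em$group] * Tn
    }
  }
  pred
}

# ---- global fit -----------------------------------------------------------

#' Globally fit an unfolding model to first and reheated scans
#'
#' Minimises the unweighted sum of squared differences between observed and
#' modelled apparent heat capacity over *all* scans simultaneously — first
#' runs and reheats, possibly at several scan rates. Thermodynamic and
#' kinetic parameters are global; the linear baseline (B0, B1) is shared
#' within a scan-rate group (a first run and its reheats). Reheat curves are
#' always generated through the full heat-cool-reheat propagation of the
#' native fraction, never fitted as independent curves — this is what makes
#' reheats informative about irreversibility and the heat-capacity change.
#'
#' Optimisation uses bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]) with a deterministic multistart over log-spaced
#' scalings of the energy-like parameters (activation energies, enthalpies)
#' to mitigate the multimodality of kinetic unfolding objectives. The fit is
#' deterministic given the data and initial values.
#'
#' @param data A [dsc_scans()] table.
#' @param model An [unfolding_model()] providing the structure and initial
#'   parameter values; its baseline seeds every scan-rate group's baseline.
#' @param fixed Character vector of parameter names to hold fixed (see
#'   `tidy()` for the naming scheme: `tm1`, `dh1`, `dcp1`, `e2`, `tf2`,
#'   `b0_g1`, ...).
#' @param lower,upper Optional named vectors overriding default bounds
#'   (laboratory units: kJ, K).
#' @param n_starts Number of multistart points (default 5).
#' @param maxit Maximum LM iterations per start.
#' @param internal_step Node spacing (K) on unrecorded heat/cool segments.
#' @param ssr_target Optional early-stopping threshold: once a start reaches
#'   this sum of squared residuals (kJ^2 units), remaining starts are
#'   skipped. [compare_models()] sets it from the data's noise floor.
#' @return A `dsc_fit` object; see [tidy.dsc_fit()], [glance.dsc_fit()],
#'   [refold_statistics()].
#' @export
global_fit <- function(data, model, fixed = character(), lower = NULL,
                       upper = NULL, n_starts = 5, maxit = 100,
                       internal_step = 1, ssr_target = NULL) {
  stopifnot(inherits(data, "dsc_scans"), inherits(model, "unfolding_model"))
  flat <- flatten_model(model)
  plan <- build_jobs(data, internal_step)
  for (g in seq_len(plan$n_groups)) {
    flat$values[paste0("b0_g", g)] <- model$b0 / 1e3
    flat$values[paste0("b1_g", g)] <- model$b1 / 1e3
    flat$kinds[paste0("b0_g", g)] <- "b0"
    flat$kinds[paste0("b1_g", g)] <- "b1"
  }
  pnames <- names(flat$values)
  bounds <- default_bounds(flat$kinds)
  names(bounds$lower) <- names(bounds$upper) <- pnames
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper
  bad <- flat$values < bounds$lower | flat$values > bounds$upper
  if (any(bad)) {
    abort(paste0("Initial values outside bounds: ",
                 paste(pnames[bad], collapse = ", "), "."))
  }
  free <- setdiff(pnames, fixed)
  if (length(free) == 0) abort("At least one parameter must be free.")
  obs_kJ <- data$cp / 1e3

  resid_fun <- function(p_free) {
    par <- flat$values
    par[free] <- p_free
    pred <- tryCatch(predict_from_par(flat, par, plan, data),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) {
      # infeasible excursion: huge constant residuals make LM reject the
      # trial step rather than aborting the whole start
      return(rep(1e6, length(obs_kJ)))
    }
    obs_kJ - pred / 1e3
  }
  # flat carries values/kinds; build_model needs the step structure too
  flat$steps <- model$steps

  energy_like <- free[flat$kinds[free] %in% c("e", "dh", "dhvh")]
  factors <- if (n_starts > 1) {
    fs <- exp(seq(log(0.6), log(1.6), length.out = n_starts - 1))
    c(1, fs[order(-abs(log(fs)))])  # most diverse starts first
  } else 1
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxit, ftol = 1e-10,
                                     ptol = 1e-10)
  best <- NULL
  start_ssr <- numeric(0)
  n_stale <- 0L
  for (f in factors) {
    p0 <- flat$values[free]
    p0[energy_like] <- pmin(pmax(p0[energy_like] * f,
                                 bounds$lower[energy_like]),
                            bounds$upper[energy_like])
    ans <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun,
                         lower = bounds$lower[free],
                         upper = bounds$upper[free], control = ctrl),
      error = function(e) NULL)
    if (is.null(ans)) { start_ssr <- c(start_ssr, NA_real_); next }
    ssr <- ans$deviance
    start_ssr <- c(start_ssr, ssr)
    prev_best <- if (is.null(best)) Inf else best$deviance
    if (is.null(best) || ssr < best$deviance) best <- ans
    n_stale <- if (best$deviance > 0.98 * prev_best) n_stale + 1L else 0L
    if (!is.null(ssr_target)) {
      if (best$deviance <= ssr_target) break
      # diminishing returns: two consecutive starts without material
      # improvement signal a converged (if imperfect) solution
      if (length(start_ssr) >= 3 && n_stale >= 2) break
    }
  }
  if (is.null(best)) abort("All optimization starts failed.")

  par <- flat$values
  par[free] <- best$par
  pred <- predict_from_par(flat, par, plan, data)
  resid <- data$cp - pred
  n <- nrow(data); p <- length(free)
  df <- n - p
  sigma_kJ <- sqrt(best$deviance / max(df, 1))
  # linearized covariance from the LM approximation J'J at the optimum
  vcov <- tryCatch({
    V <- sigma_kJ^2 * solve(best$hessian)
    dimnames(V) <- list(free, free)
    V
  }, error = function(e) NULL)
  se <- if (is.null(vcov)) stats::setNames(rep(NA_real_, p), free)
        else sqrt(pmax(diag(vcov), 0))
  half <- stats::qt(0.975, max(df, 1)) * se

  estimates <- tibble(
    term = pnames,
    estimate = unname(par),
    std.error = unname(se[pnames]),
    conf.low = unname(par - half[pnames]),
    conf.high = unname(par + half[pnames]),
    unit = par_units(flat$kinds),
    free = pnames %in% free)

  fitted_tab <- dplyr::mutate(as_tibble(data), .fitted = pred,
                              .resid = resid)
  per_scan <- dplyr::summarise(
    dplyr::group_by(fitted_tab, .data$experiment, .data$role, .data$t_prime),
    ssr = sum(.data$.resid^2), sd = stats::sd(.data$.resid),
    n = dplyr::n(), .groups = "drop")

  structure(list(
    template = flat, par = par, free = free,
    model = suppressWarnings(build_model(flat, par)),
    baselines = tibble(group = seq_len(plan$n_groups),
                       scan_rate = plan$rates,
                       b0 = unname(par[paste0("b0_g", seq_len(plan$n_groups))] * 1e3),
                       b1 = unname(par[paste0("b1_g", seq_len(plan$n_groups))] * 1e3)),
    estimates = estimates, vcov = vcov,
    data = data, plan = plan, fitted = fitted_tab, per_scan = per_scan,
    ssr = sum(resid^2), sigma = sigma_kJ * 1e3, df.residual = df,
    converged = best$info %in% 1:4, info = best$info,
    message = best$message, start_ssr = start_ssr,
    rsstrace = best$rsstrace, n_iter = best$niter), class = "dsc_fit")
}

#' @export
print.dsc_fit <- function(x, ...) {
  cat("<dsc_fit> global fit over", nrow(x$per_scan), "scan(s),",
      nrow(x$data), "points\n")
  cat(sprintf("  residual SD %.3g kJ/mol/K | SSR %.4g | %s (info %d)\n",
              x$sigma / 1e3, x$ssr,
              if (x$converged) "converged" else "NOT converged", x$info))
  est <- x$estimates[x$estimates$free, ]
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-8s %12.4g +/- %-10.3g %s\n", est$term[i], est$estimate[i],
                est$estimate[i] - est$conf.low[i], est$unit[i]))
  }
  invisible(x)
}

#' Predicted curves from a fitted model
#'
#' Regenerates the per-scan model curves from the stored parameter estimates
#' through the full heat-cool-reheat propagation; bit-identical to the
#' `.fitted` column stored in the fit.
#'
#' @param object A `dsc_fit`.
#' @param ... Unused.
#' @return Numeric vector of model Cp values (J mol^-1 K^-1), aligned with
#'   the rows of the fitted data.
#' @export
predict.dsc_fit <- function(object, ...) {
  predict_from_par(object$template, object$par, object$plan, object$data)
}

#' Parameter confidence intervals
#'
#' Linearized 95% confidence intervals at the optimum: half-width equals the
#' t quantile at the residual degrees of freedom times the standard error
#' from the Jacobian approximation of the covariance. Parameters whose
#' covariance is unavailable (rank-deficient Jacobian) carry `NA` and are
#' flagged, not numbered.
#'
#' @param fit A `dsc_fit`.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `half_width`, `unit`, `available`.
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dsc_fit"))
  est <- fit$estimates[fit$estimates$free, ]
  if (!identical(level, 0.95)) {
    half <- stats::qt(1 - (1 - level) / 2, max(fit$df.residual, 1)) *
      est$std.error
    est$conf.low <- est$estimate - half
    est$conf.high <- est$estimate + half
  }
  dplyr::mutate(est,
    half_width = (.data$conf.high - .data$conf.low) / 2,
    available = is.finite(.data$std.error))[
      , c("term", "estimate", "conf.low", "conf.high", "half_width",
          "unit", "available")]
}

#' Evaluate a model on scan data without fitting
#'
#' Computes the model's predicted curves (through the full heat-cool-reheat
#' propagation) and residuals against the data, with no parameter
#' optimisation. Useful for judging how a model fitted to one subset of the
#' data (e.g. first runs only) predicts another (the reheats), mirroring the
#' demonstration that scan-rate-only fits fail to account for reheating.
#'
#' @param data A [dsc_scans()] table.
#' @param model An [unfolding_model()] (parameters as to be evaluated; its
#'   `b0`/`b1` are used for every scan-rate group).
#' @return A `dsc_fit`-like object (class `dsc_fit`) with predictions,
#'   residuals and per-scan statistics; parameter uncertainties are absent.
#' @export
evaluate_model <- function(data, model) {
  stopifnot(inherits(data, "dsc_scans"), inherits(model, "unfolding_model"))
  flat <- flatten_model(model)
  plan <- build_jobs(data, 1)
  for (g in seq_len(plan$n_groups)) {
    flat$values[paste0("b0_g", g)] <- model$b0 / 1e3
    flat$values[paste0("b1_g", g)] <- model$b1 / 1e3
    flat$kinds[paste0("b0_g", g)] <- "b0"
    flat$kinds[paste0("b1_g", g)] <- "b1"
  }
  flat$steps <- model$steps
  pnames <- names(flat$values)
  pred <- predict_from_par(flat, flat$values, plan, data)
  resid <- data$cp - pred
  fitted_tab <- dplyr::mutate(as_tibble(data), .fitted = pred, .resid = resid)
  per_scan <- dplyr::summarise(
    dplyr::group_by(fitted_tab, .data$experiment, .data$role, .data$t_prime),
    ssr = sum(.data$.resid^2), sd = stats::sd(.data$.resid),
    n = dplyr::n(), .groups = "drop")
  structure(list(
    template = flat, par = flat$values, free = character(0), model = model,
    baselines = tibble(group = seq_len(plan$n_groups), scan_rate = plan$rates,
                       b0 = model$b0, b1 = model$b1),
    estimates = tibble(term = pnames, estimate = unname(flat$values),
                       std.error = NA_real_, conf.low = NA_real_,
                       conf.high = NA_real_, unit = par_units(flat$kinds),
                       free = FALSE),
    vcov = NULL, data = data, plan = plan, fitted = fitted_tab,
    per_scan = per_scan, ssr = sum(resid^2),
    sigma = stats::sd(resid), df.residual = nrow(data),
    converged = TRUE, info = 0L, message = "evaluation only",
    start_ssr = numeric(0), n_iter = 0L), class = "dsc_fit")
}

# ---- initialization heuristics -------------------------------------------

#' Shape-based initial model for a preset
#'
#' Builds a starting [unfolding_model()] from the shape of the first run:
#' reference temperatures (Tm, Tf) are initialised at the apparent peak
#' temperature, enthalpies from the baseline-corrected peak area, the
#' heat-capacity change from the pre/post baseline offset, and the
#' activation energy from the peak width (E ~ e R Tp^2 Cpmax / area for an
#' irreversible peak, where e is Euler's number). These are deliberately
#' rough: they seed [global_fit()]'s multistart.
#'
#' @param data A [dsc_scans()] table.
#' @param preset Model preset letter.
#' @return An [unfolding_model()].
#' @export
init_model <- function(data, preset = c("A", "B", "C", "D")) {
  preset <- match.arg(preset)
  first <- dplyr::filter(as_tibble(data), .data$role == "first")
  first <- first[first$experiment == first$experiment[1], ]
  pk <- find_peak(first)
  v <- first$scan_rate[1]
  Tg <- first$temperature
  excess <- first$cp - (pk$baseline[1] + pk$baseline[2] * Tg)
  tp <- pk$tp; cmax <- pk$height
  # split the excess area into endo- and exothermic parts: an appended
  # negative (aggregation-like) step cancels area and must not deflate the
  # main-peak enthalpy estimate
  trapz <- function(y) sum(diff(Tg) * (y[-1] + y[-length(y)]) / 2)
  pos_area <- trapz(pmax(excess, 0))
  neg_area <- trapz(pmin(excess, 0))
  post <- Tg >= pk$foot
  dcp0 <- if (sum(post) >= 3) min(max(mean(excess[post]), 0), 0.3 * cmax) else 0
  dh0 <- max(pos_area - dcp0 * (max(Tg) - tp), 0.5 * pos_area, 50e3)
  has_exo <- neg_area < -max(5 * pk$noise * (max(Tg) - min(Tg)) / 4,
                             0.05 * pos_area)
  e_b <- exp(1) * R_GAS * tp^2 * cmax / dh0
  k_tp <- v * e_b / (R_GAS * tp^2)           # k at the peak, model-B shape
  tf_b <- 1 / (1 / tp + (R_GAS / e_b) * log(k_tp))
  dhvh0 <- 4 * R_GAS * tp^2 * cmax / dh0
  b0 <- pk$baseline[1]; b1 <- pk$baseline[2]
  # second-step seed: exothermic high-temperature step if the tail dips,
  # otherwise a mild irreversible drain inside the first peak
  step2 <- if (has_exo) {
    step_irreversible(e = 100e3, tf = max(Tg) + 40, dh = 1.5 * neg_area)
  } else {
    step_irreversible(e = 150e3, tf = tp + 20, dh = 0.15 * dh0)
  }
  suppressWarnings(switch(preset,
    A = unfolding_model(list(
      step_equilibrium(tm = tp, dh = dh0, dcp = dcp0, dh_vh = dhvh0)),
      b0 = b0, b1 = b1),
    B = unfolding_model(list(
      step_irreversible(e = e_b, tf = tf_b, dh = dh0, dcp = dcp0)),
      b0 = b0, b1 = b1),
    C = unfolding_model(list(
      step_equilibrium(tm = tp, dh = dh0, dcp = dcp0), step2),
      b0 = b0, b1 = b1),
    D = unfolding_model(list(
      step_two_rate(e_fwd = e_b, tf_fwd = tf_b,
                    e_rev = 50e3,
                    tf_rev = 1 / (1 / tp + (R_GAS / 50e3) *
                                    log(max(0.3 * k_tp, 1e-8))),
                    dh = dh0, dcp = dcp0), step2),
      b0 = b0, b1 = b1)))
}

# ---- model comparison -----------------------------------------------------

#' Fit and rank candidate unfolding models
#'
#' Fits each candidate preset to the same data and ranks them by
#' reheat-consistent fit quality. A candidate is *rejected* when its reheat
#' residuals betray it (reheat residual SD at least `sd_ratio_threshold`
#' times the first-run residual SD, or reheat bias above the signal
#' threshold — the same criteria as [flag_alternative_refolding()]). Among
#' the surviving candidates, any fit whose SSR is within `ssr_margin` of the
#' best surviving SSR is considered adequate, and the adequate candidate
#' with the fewest free parameters is selected — the simplest model that
#' accounts for both the first runs and the reheats.
#'
#' @param data A [dsc_scans()] table including reheats.
#' @param candidates Preset letters to try.
#' @param inits Optional named list of initial [unfolding_model()]s per
#'   preset; defaults to shape-based heuristics ([init_model]).
#' @param n_starts,maxit Passed to [global_fit()].
#' @param sd_ratio_threshold,signal_threshold Rejection thresholds.
#' @param ssr_margin Relative SSR slack for the parsimony rule.
#' @return A tibble (one row per candidate, ranked; attribute `"fits"` holds
#'   the `dsc_fit` objects) with the selected model flagged.
#' @export
compare_models <- function(data, candidates = c("A", "B", "C", "D"),
                           inits = NULL, n_starts = 4, maxit = 100,
                           sd_ratio_threshold = 2, signal_threshold = 0.05,
                           ssr_margin = 1.2) {
  fits <- list()
  rows <- list()
  # noise floor from second differences within each scan: a start that
  # reaches ~this SSR has explained everything but the noise, so further
  # multistart points are unnecessary
  floor_kJ2 <- sum(vapply(split(data$cp / 1e3, scan_key(data)), function(cp) {
    if (length(cp) < 5) return(0)
    length(cp) * (stats::sd(diff(cp, differences = 2)) / sqrt(6))^2
  }, numeric(1)))
  for (cand in candidates) {
    m0 <- if (!is.null(inits[[cand]])) inits[[cand]] else init_model(data, cand)
    fit <- tryCatch(
      global_fit(data, m0, n_starts = n_starts, maxit = maxit,
                 ssr_target = 1.5 * floor_kJ2),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[cand]] <- tibble(model = cand, n_par = NA_integer_,
                             ssr = Inf, sd_first = NA_real_,
                             sd_reheat = NA_real_, sd_ratio = NA_real_,
                             aic = NA_real_, rejected = TRUE,
                             reason = "fit failed")
      next
    }
    fits[[cand]] <- fit
    rs <- tryCatch(refold_statistics(fit), error = function(e) NULL)
    fl <- if (!is.null(rs)) {
      flag_alternative_refolding(rs, signal_threshold, sd_ratio_threshold)
    } else list(flag = FALSE, rationale = "")
    n <- nrow(data); k <- length(fit$free)
    rows[[cand]] <- tibble(
      model = cand, n_par = k, ssr = fit$ssr,
      sd_first = if (!is.null(rs)) rs$sd[rs$group == "first"] else NA_real_,
      sd_reheat = if (!is.null(rs)) rs$sd[rs$group == "reheat"] else NA_real_,
      sd_ratio = if (!is.null(rs)) attr(rs, "sd_ratio") else NA_real_,
      aic = n * log(fit$ssr / n) + 2 * k,
      rejected = fl$flag,
      reason = if (fl$flag) fl$rationale else "")
  }
  rep <- dplyr::bind_rows(rows)
  ok <- which(!rep$rejected & is.finite(rep$ssr))
  if (length(ok) == 0) ok <- which(is.finite(rep$ssr) & rep$ssr < Inf)
  sel <- NA_character_
  if (length(ok) > 0) {
    best_ssr <- min(rep$ssr[ok])
    adequate <- ok[rep$ssr[ok] <= ssr_margin * best_ssr]
    sel <- rep$model[adequate[order(rep$n_par[adequate],
                                    rep$ssr[adequate])][1]]
  }
  rep$selected <- rep$model == sel
  rep <- rep[order(rep$rejected, -rep$selected, rep$ssr), ]
  attr(rep, "fits") <- fits
  rep
}
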