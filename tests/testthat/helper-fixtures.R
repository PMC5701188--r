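# shared fixtures built in code; everything seeded and cheap

RG <- 8.3145

# brute-force fixed-step (0.001 K) explicit integration of
# dx_n/dT = -(k/v) x_n, independent of the package's propagation path;
# explicit midpoint keeps the oracle's own bias below the comparison level
euler_xn <- function(e, tf, t_from, t_to, v, h = 1e-3, x0 = 1) {
  n <- ceiling(abs(t_to - t_from) / h)
  h <- (t_to - t_from) / n
  k <- function(T) exp(-(e / RG) * (1 / T - 1 / tf))
  x <- x0
  T <- t_from
  for (i in seq_len(n)) {
    xm <- x - (k(T) / v) * x * (h / 2)
    x <- x - (k(T + h / 2) / v) * xm * h
    T <- T + h
  }
  x
}

# quadrature decay factor, independent of the package implementation
quad_decay <- function(e, tf, t1, t2, v) {
  k <- function(T) exp(-(e / RG) * (1 / T - 1 / tf))
  exp(-stats::integrate(k, min(t1, t2), max(t1, t2),
                        rel.tol = 1e-12)$value / abs(v))
}

# a first scan plus reheats from the given terminal temperatures, one
# experiment per reheat (the full scan is its own experiment)
gen_experiment_set <- function(model, tps, t_end, noise = 500, seed = 1,
                               v = 1 / 60, grid = 0.25, t0 = 293.15) {
  full <- simulate_thermogram(model, heat_cool_reheat(t0, t_end, v,
                                                      reheat = FALSE),
                              grid, noise, seed, experiment = "e0")
  out <- list(full)
  for (i in seq_along(tps)) {
    out[[i + 1]] <- simulate_thermogram(
      model, heat_cool_reheat(t0, tps[i], v, t_end = t_end),
      grid, noise, seed + 1000 * i, experiment = paste0("e", i))
  }
  dsc_scans(dplyr::bind_rows(out))
}

# perturb a model's parameters multiplicatively (energies/enthalpies) and
# additively (temperatures), for recovery-style fits
perturb_model <- function(model, f_energy = 1.1, d_temp = 2) {
  cfg <- model_to_config(model)
  cfg$steps <- lapply(cfg$steps, function(s) {
    for (nm in intersect(names(s), c("dh_kJ", "dh_vh_kJ", "e_kJ",
                                     "e_fwd_kJ", "e_rev_kJ"))) {
      s[[nm]] <- s[[nm]] * f_energy
    }
    for (nm in intersect(names(s), c("tm_K", "tf_K", "tf_fwd_K", "tf_rev_K"))) {
      s[[nm]] <- s[[nm]] + d_temp
    }
    s
  })
  suppressWarnings(config_to_model(cfg))
}
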