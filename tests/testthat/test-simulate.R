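test_that("decay factor matches quadrature and path reversal", {
  p <- arr_params(300e3, 360)
  expect_equal(decay_factor_irreversible(p, 320, 320, 1 / 60), 1)
  x <- decay_factor_irreversible(p, 293.15, 342, 1 / 60)
  expect_equal(x, quad_decay(300e3, 360, 293.15, 342, 1 / 60),
               tolerance = 1e-9)
  expect_equal(x, 0.37644, tolerance = 1e-4)
  expect_error(decay_factor_irreversible(p, 300, 320, 0), "non-zero")
  expect_error(decay_factor_irreversible(p, 300, 320, -1 / 60), "direction")
  set.seed(7)
  for (i in 1:50) {
    e <- runif(1, 5e4, 5e5); tf <- runif(1, 320, 380)
    t1 <- runif(1, 280, 330); t2 <- t1 + runif(1, 1, 60)
    v <- runif(1, 0.2, 4) / 60
    pp <- arr_params(e, tf)
    expect_equal(decay_factor_irreversible(pp, t2, t1, -v),
                 decay_factor_irreversible(pp, t1, t2, v), tolerance = 1e-10)
  }
})

test_that("the reversible two-state model is history-free on reheat", {
  m <- table2_preset("SpA")
  prog <- heat_cool_reheat(293.15, 353.15, 4 / 60)
  traj <- suppressWarnings(simulate_fractions(m, prog))
  cp <- apparent_heat_capacity(m, traj)
  first <- cp[cp$role == "first", ]
  reheat <- cp[cp$role == "reheat", ]
  expect_equal(reheat$cp, first$cp, tolerance = 1e-12)
  expect_equal(traj$x_d[traj$role == "first"],
               with(traj[traj$role == "first", ], {
                 K <- equilibrium_constant(
                   eq_params(328.44, 102.4e3, 1.38e3, 169e3), temperature)
                 K / (1 + K)
               }), tolerance = 1e-12)
})

test_that("irreversible cool-from-T' native fraction equals X(T',T0,v)^2", {
  e <- 418e3; tf <- 337.6; v <- 1 / 60; t0 <- 293.15
  m <- unfolding_model(list(step_irreversible(e, tf, 337e3)))
  for (tp in c(327, 332, 338)) {
    prog <- temperature_program(list(
      list(t_start = t0, t_end = tp, rate = v, role = "first"),
      list(t_start = tp, t_end = t0, rate = -v, role = "cool")))
    traj <- simulate_fractions(m, prog)
    X <- decay_factor_irreversible(arr_params(e, tf), t0, tp, v)
    expect_equal(dplyr::last(traj$x_n), X^2, tolerance = 1e-8)
  }
})

test_that("propagation matches brute-force fixed-step integration", {
  # independent oracle: 0.001 K explicit Euler of dx_n/dT = -(k/v) x_n
  m <- unfolding_model(list(step_irreversible(300e3, 360, 800e3)))
  prog <- heat_cool_reheat(293.15, 345, 1 / 60, t_end = 355)
  traj <- simulate_fractions(m, prog)
  firsts <- which(traj$role == "first")
  for (Tq in c(330, 340, 345)) {
    row <- firsts[which.min(abs(traj$temperature[firsts] - Tq))]
    expect_equal(traj$x_n[row],
                 euler_xn(300e3, 360, 293.15, traj$temperature[row], 1 / 60),
                 tolerance = 1e-6)
  }
  # and on the reheat, through the full heat-cool history
  x_cool <- euler_xn(300e3, 360, 293.15, 345, 1 / 60)^2
  reheats <- which(traj$role == "reheat")
  row <- reheats[which.min(abs(traj$temperature[reheats] - 340))]
  expect_equal(traj$x_n[row],
               x_cool * euler_xn(300e3, 360, 293.15,
                                 traj$temperature[row], 1 / 60),
               tolerance = 1e-6)
})

test_that("fractions are conserved and bounded for every model class", {
  progs <- list(heat_cool_reheat(293.15, 335, 1 / 60, t_end = 350),
                heat_cool_reheat(298.15, 350, 2 / 60, t_end = 360))
  models <- list(
    B = table2_preset("DbjA"),
    C = table2_preset("DhaA"),
    D = table2_preset("DhaA115"),
    lys = table2_preset("lysozyme"))
  for (nm in names(models)) {
    for (prog in progs) {
      traj <- suppressWarnings(simulate_fractions(models[[nm]], prog))
      xs <- as.matrix(traj[, grep("^x_", names(traj))])
      expect_true(all(xs > -1e-9 & xs < 1 + 1e-9), info = nm)
      expect_lt(max(abs(rowSums(xs) - 1)), 1e-9, label = paste(nm, "sum"))
      # continuity at segment boundaries
      ends <- cumsum(rle(traj$segment)$lengths)
      for (b in ends[-length(ends)]) {
        expect_lt(max(abs(xs[b, ] - xs[b + 1, ])), 1e-8)
      }
    }
  }
})

test_that("heat capacity reduces to the one-step closed form", {
  # Cp = B0 + B1 T + (1 - x_n) dCp + (k/v) x_n dH(T) for model B
  e <- 418e3; tf <- 337.6; dh <- 337e3; dcp <- 5.4e3; v <- 1 / 60
  m <- unfolding_model(list(step_irreversible(e, tf, dh, dcp)),
                       b0 = 20e3, b1 = 50)
  prog <- heat_cool_reheat(293.15, 345, v, reheat = FALSE)
  traj <- simulate_fractions(m, prog)
  cp <- apparent_heat_capacity(m, traj)
  Tg <- traj$temperature
  k <- rate_constant(arr_params(e, tf), Tg)
  closed <- 20e3 + 50 * Tg + (1 - traj$x_n) * dcp +
    (k / v) * traj$x_n * (dh + dcp * (Tg - tf))
  expect_equal(cp$cp, closed, tolerance = 1e-7)
})

test_that("the reversible model reduces to the classical two-state form", {
  # van't Hoff enthalpy drives the sharpness, calorimetric the amplitude:
  # Cp_excess = dHcal(T) K dHvh / ((1+K)^2 R T^2) + x_d dCp
  tm <- 328.44; dhc <- 102.4e3; dhvh <- 169e3; dcp <- 1.38e3
  m <- unfolding_model(list(step_equilibrium(tm, dhc, dcp, dhvh)),
                       b0 = 5e3, b1 = 10)
  prog <- heat_cool_reheat(298.15, 358.15, 4 / 60, reheat = FALSE)
  traj <- suppressWarnings(simulate_fractions(m, prog))
  cp <- apparent_heat_capacity(m, traj)
  Tg <- traj$temperature
  K <- equilibrium_constant(eq_params(tm, dhc, dcp, dhvh), Tg)
  dhvh_T <- dhvh + dcp * (Tg - tm)
  dhc_T <- dhc + dcp * (Tg - tm)
  closed <- 5e3 + 10 * Tg + (K / (1 + K)) * dcp +
    dhc_T * K * dhvh_T / ((1 + K)^2 * R_GAS * Tg^2)
  expect_equal(cp$cp, closed, tolerance = 1e-9)
})

test_that("total calorimetric area equals the enthalpy for a completed scan", {
  m <- unfolding_model(list(step_irreversible(300e3, 360, 800e3)))
  s <- simulate_thermogram(m, heat_cool_reheat(293.15, 373.15, 1 / 60,
                                               reheat = FALSE))
  area <- sum(diff(s$temperature) * (s$cp[-1] + s$cp[-nrow(s)]) / 2)
  expect_equal(area, 800e3, tolerance = 5e-3)
})

test_that("model D reduces to models B and C in its limiting regimes", {
  # k_-1 ~ 0 with enthalpy on the first step: B's kinetics, I and D
  # calorimetrically identical
  mB <- unfolding_model(list(step_irreversible(418e3, 337.6, 337e3, 5.4e3)))
  mD <- suppressWarnings(unfolding_model(list(
    step_two_rate(418e3, 337.6, 500e3, 5000, 337e3, 5.4e3),
    step_irreversible(100e3, 400, 0))))
  pr <- heat_cool_reheat(293.15, 335, 1 / 60, t_end = 350)
  cB <- apparent_heat_capacity(mB, simulate_fractions(mB, pr))
  cD <- apparent_heat_capacity(mD, simulate_fractions(mD, pr))
  expect_lt(max(abs(cB$cp - cD$cp)) / max(abs(cB$cp)), 1e-6)

  # first-step rates fast (x 1e4 of the resolved scale): fast-equilibrium
  # model with K = k1/k-1, dH_K = E1 - E-1
  Tm <- 323.8; dh <- 338e3; E1 <- 500e3; Em1 <- E1 - dh; kfast <- 100
  tf1 <- 1 / (1 / Tm + R_GAS * log(kfast) / E1)
  tfm1 <- 1 / (1 / Tm + R_GAS * log(kfast) / Em1)
  mC <- unfolding_model(list(step_equilibrium(Tm, dh, 0),
                             step_irreversible(75e3, 436, 70e3)))
  mDC <- suppressWarnings(unfolding_model(list(
    step_two_rate(E1, tf1, Em1, tfm1, dh, 0),
    step_irreversible(75e3, 436, 70e3))))
  pr2 <- heat_cool_reheat(293.15, 323.15, 1 / 60, t_end = 350)
  cC <- apparent_heat_capacity(mC, simulate_fractions(mC, pr2, 0.1))
  cDC <- apparent_heat_capacity(mDC, simulate_fractions(mDC, pr2, 0.1))
  expect_lt(max(abs(cC$cp - cDC$cp)) / max(cC$cp), 5e-3)
})

test_that("reheat peak height is non-increasing in the terminal temperature", {
  m <- table2_preset("DbjA")
  heights <- vapply(c(322, 326, 330, 334, 338), function(tp) {
    s <- simulate_thermogram(m, heat_cool_reheat(293.15, tp, 1 / 60,
                                                 t_end = 348.15))
    r <- s[s$role == "reheat", ]
    max(r$cp - (r$cp[1] + 0 * r$temperature))
  }, numeric(1))
  expect_true(all(diff(heights) < 1e-6))
})

test_that("reheat baseline sits x_d(T0) dCp above the first run", {
  dcp <- 5.4e3
  m <- table2_preset("DbjA")
  prog <- heat_cool_reheat(293.15, 330, 1 / 60, t_end = 348.15)
  traj <- simulate_fractions(m, prog)
  cp <- apparent_heat_capacity(m, traj)
  xd0 <- traj$x_d[traj$role == "reheat"][1]
  shift <- cp$cp[cp$role == "reheat"][1] - cp$cp[cp$role == "first"][1]
  expect_gt(xd0, 0.05)  # partial denaturation actually happened
  expect_equal(shift, xd0 * dcp, tolerance = 1e-6)
})

test_that("simulated thermograms are seeded and deterministic", {
  m <- unfolding_model(list(step_irreversible(300e3, 360, 800e3)))
  prog <- heat_cool_reheat(293.15, 353.15, 1 / 60)
  s1 <- simulate_thermogram(m, prog, noise_sd = 2.1e3, seed = 5)
  s2 <- simulate_thermogram(m, prog, noise_sd = 2.1e3, seed = 5)
  expect_identical(s1$cp, s2$cp)
  s3 <- simulate_thermogram(m, prog, noise_sd = 2.1e3, seed = 6)
  expect_false(identical(s1$cp, s3$cp))
  # cooling emits no thermogram
  expect_setequal(unique(s1$role), c("first", "reheat"))
  # noiseless model-A reheat identical to first scan (SpA is ~0.2%
  # unfolded at 20 degC under its fitted model, hence the start warning)
  sA <- suppressWarnings(
    simulate_thermogram(table2_preset("SpA"),
                        heat_cool_reheat(293.15, 353.15, 4 / 60)))
  expect_equal(sA$cp[sA$role == "reheat"], sA$cp[sA$role == "first"],
               tolerance = 1e-12)
  # full transition leaves essentially no reheat excess signal
  sB <- simulate_thermogram(m, heat_cool_reheat(293.15, 373.15, 1 / 60))
  first_peak <- max(sB$cp[sB$role == "first"])
  expect_lt(max(sB$cp[sB$role == "reheat"]), 1e-3 * first_peak)
})
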