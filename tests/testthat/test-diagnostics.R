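test_that("matched-model residual groups have equal spread, no flag", {
  m <- table2_preset("SpA")
  sc <- suppressWarnings(   # SpA is ~0.2% unfolded at the start temperature
    gen_experiment_set(m, 343, 358, noise = 100, seed = 21, v = 4 / 60,
                       grid = 0.4))
  fit <- global_fit(sc, perturb_model(m, 1.05, 0.5), n_starts = 1)
  rep <- refold_statistics(fit)
  expect_lt(attr(rep, "sd_ratio"), 1.5)
  expect_gt(attr(rep, "sd_ratio"), 0.6)
  fl <- flag_alternative_refolding(rep)
  expect_false(fl$flag)
})

test_that("refold_statistics needs a reheat and splits groups correctly", {
  m <- unfolding_model(list(step_irreversible(300e3, 360, 800e3)))
  sc <- simulate_thermogram(m, heat_cool_reheat(293.15, 373.15, 1 / 60,
                                                reheat = FALSE),
                            grid_step = 0.5, noise_sd = 500, seed = 2)
  fit <- global_fit(sc, m, n_starts = 1, maxit = 20)
  expect_error(refold_statistics(fit), "reheat")
})

test_that("the lipase-like refolding cases raise the flag", {
  init <- unfolding_model(list(step_irreversible(280e3, 362, 700e3)))
  # 50% reheat area: residual SD ratio ~4 (as reported for the simulation)
  rc50 <- make_refolding_case(0.5, seed = 42, grid_step = 0.2)
  f50 <- global_fit(rc50, init, n_starts = 1)
  r50 <- refold_statistics(f50)
  expect_gt(attr(r50, "sd_ratio"), 2)
  expect_lt(attr(r50, "sd_ratio"), 6)
  expect_true(flag_alternative_refolding(r50)$flag)
  expect_match(flag_alternative_refolding(r50)$rationale, "SD ratio")
  # 10% reheat area: the ratio stays clearly elevated above the
  # matched-model level (~1), though under this window it sits near the
  # flag threshold rather than safely beyond it
  rc10 <- make_refolding_case(0.1, seed = 43, grid_step = 0.2)
  f10 <- global_fit(rc10, init, n_starts = 1)
  r10 <- refold_statistics(f10)
  expect_gt(attr(r10, "sd_ratio"), 1.35)
  expect_lt(attr(r10, "sd_ratio"), 2.5)
})

test_that("flag logic is a deterministic function of the statistics", {
  rep <- structure(
    tibble::tibble(group = c("first", "reheat"), mean = c(0, 0),
                   mean_abs = c(1, 1), sd = c(1, 1), n = c(10, 10)),
    sd_ratio = 1.0, peak_height = 100, class = c("refold_report", "tbl_df",
                                                 "tbl", "data.frame"))
  expect_false(flag_alternative_refolding(rep)$flag)
  attr(rep, "sd_ratio") <- 2.5
  expect_true(flag_alternative_refolding(rep)$flag)
  attr(rep, "sd_ratio") <- 1.0
  rep$mean[2] <- 6  # 6% of the peak amplitude
  expect_true(flag_alternative_refolding(rep)$flag)
})

test_that("reversibility classes follow the native-fraction boundaries", {
  # identical scans: fully reversible
  m <- table2_preset("SpA")
  sA <- suppressWarnings(
    simulate_thermogram(m, heat_cool_reheat(293.15, 348.15, 4 / 60),
                        grid_step = 0.2))
  cls <- classify_reversibility(sA[sA$role == "first", ],
                                sA[sA$role == "reheat", ])
  expect_equal(cls$class, "A")
  expect_equal(cls$fraction, 1, tolerance = 1e-6)

  # one-step irreversible, reheat from the foot: nothing survives
  mB <- table2_preset("DbjA")
  foot <- suppressWarnings(suggest_reheat_temperatures(
    simulate_thermogram(mB, heat_cool_reheat(293.15, 348.15, 1 / 60,
                                             reheat = FALSE),
                        grid_step = 0.2)))$temperature[3]
  sB <- simulate_thermogram(mB, heat_cool_reheat(293.15, foot, 1 / 60,
                                                 t_end = 348.15),
                            grid_step = 0.2)
  clsB <- classify_reversibility(sB[sB$role == "first", ],
                                 sB[sB$role == "reheat", ])
  expect_equal(clsB$class, "B")
  expect_lt(clsB$fraction, 0.05)
  X <- decay_factor_irreversible(arr_params(418e3, 337.6), 293.15, foot,
                                 1 / 60)
  expect_lt(X^2, 0.05)  # consistent with the decay-factor oracle

  # partially reversible: DhaA-like reheat from 323.15 K conserves ~80%;
  # the scan range stops below the second apparent transition so the
  # comparison concerns the first peak only
  mC <- table2_preset("DhaA")
  firstC <- simulate_thermogram(mC, heat_cool_reheat(293.15, 333.15, 1 / 60,
                                                     reheat = FALSE),
                                grid_step = 0.2)
  sC <- simulate_thermogram(mC, heat_cool_reheat(293.15, 323.15, 1 / 60,
                                                 t_end = 333.15),
                            grid_step = 0.2)
  clsC <- classify_reversibility(firstC,
                                 sC[sC$role == "reheat", ])
  expect_equal(clsC$class, "C")
  expect_equal(clsC$fraction, 0.8, tolerance = 0.15)

  # mismatched scan rates are refused
  s2 <- sA
  s2$scan_rate <- 1 / 60
  expect_error(classify_reversibility(sA[sA$role == "first", ],
                                      s2[s2$role == "reheat", ]),
               "identical scan rates")
})

test_that("reheat planning returns peak, midpoint and foot", {
  # symmetric synthetic peak centred at 330 K with foot at 340 K
  Tg <- seq(300, 360, by = 0.25)
  cp <- 50e3 * exp(-((Tg - 330) / 4.2)^2)
  s <- dsc_scans(tibble::tibble(experiment = "s", protein = NA, role = "first",
                                scan_rate = 1 / 60, t_prime = NA,
                                temperature = Tg, cp = cp))
  pts <- suggest_reheat_temperatures(s)
  expect_equal(pts$point, c("III", "IV", "V"))
  expect_equal(pts$temperature[1], 330, tolerance = 0.3)
  expect_equal(pts$temperature[3], 338.3, tolerance = 1)  # exp(-x^2) < 2%
  expect_equal(pts$temperature[2],
               mean(pts$temperature[c(1, 3)]), tolerance = 1e-9)

  # flat thermogram: no peak to plan around
  flat <- dsc_scans(tibble::tibble(experiment = "f", protein = NA,
                                   role = "first", scan_rate = 1 / 60,
                                   t_prime = NA, temperature = Tg,
                                   cp = 10e3 + 5 * Tg))
  expect_error(suggest_reheat_temperatures(flat),
               class = "dscfit_no_peak_error")
})

test_that("reheat peak-height decline is steepest between points III and V", {
  m <- table2_preset("DhaA")
  first <- simulate_thermogram(m, heat_cool_reheat(293.15, 335.15, 1 / 60,
                                                   reheat = FALSE),
                               grid_step = 0.25)
  pts <- suggest_reheat_temperatures(first)
  tps <- seq(310, 334, by = 3)
  hts <- vapply(tps, function(tp) {
    s <- simulate_thermogram(m, heat_cool_reheat(293.15, tp, 1 / 60,
                                                 t_end = 335.15),
                             grid_step = 0.25)
    find_peak_height <- tryCatch(
      dscfit:::find_peak(s[s$role == "reheat", ])$height,
      error = function(e) 0)
    find_peak_height
  }, numeric(1))
  frac <- hts / dscfit:::find_peak(first)$height
  expect_true(all(diff(frac) < 1e-6))  # monotone non-increasing
  # steepest decline after the summit (between III and V)
  slopes <- -diff(frac) / diff(tps)
  mids <- (tps[-1] + tps[-length(tps)]) / 2
  in_window <- mids >= pts$temperature[1] & mids <= pts$temperature[3]
  expect_true(any(in_window))
  expect_equal(which.max(slopes), which(in_window)[which.max(slopes[in_window])])
})
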