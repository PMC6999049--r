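test_that("scenario validation rejects unphysical parameters", {
  expect_error(ojip_scenario(B = 1.2), "B must")
  expect_error(ojip_scenario(p = -0.1), "p must")
  expect_error(ojip_scenario(k_L = 0), "positive")
  expect_error(ojip_scenario(F_M_level = 400), "exceed")
  expect_error(ojip_scenario(noise_sd = -1), "non-negative")
  expect_error(ojip_scenario(antenna_loss = 1), "antenna_loss")
  expect_error(simulate_ojip(list(B = 0)), "ojip_scenario")
})

test_that("the J step rises monotonically with the blocked fraction", {
  v_j <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(b) {
    jip_parameters(simulate_ojip(ojip_scenario(B = b)))$v_j
  }, numeric(1))
  expect_true(all(diff(v_j) > 0))
})

test_that("simulation is reproducible under a seed and converges under step halving", {
  sc <- ojip_scenario(B = 0.3, noise_sd = 0.02)
  a <- simulate_ojip(sc, seed = 99)
  b <- simulate_ojip(sc, seed = 99)
  expect_identical(a$fluor, b$fluor)
  c <- simulate_ojip(sc, seed = 100)
  expect_false(identical(a$fluor, c$fluor))

  clean <- ojip_scenario(B = 0.3)
  f1 <- simulate_ojip(clean, substep_ms = 0.5)$fluor
  f2 <- simulate_ojip(clean, substep_ms = 0.25)$fluor
  expect_lt(max(abs(f1 - f2) / f1), 1e-3)
})

test_that("antenna loss scales the fluxes but no normalised ratio", {
  intact <- jip_parameters(simulate_ojip(ojip_scenario(B = 0.2)))
  damaged <- jip_parameters(simulate_ojip(ojip_scenario(B = 0.2, antenna_loss = 0.4)))
  expect_equal(damaged$abs_cs, 0.6 * intact$abs_cs, tolerance = 1e-9)
  expect_equal(damaged$tr0_cs, 0.6 * intact$tr0_cs, tolerance = 1e-9)
  expect_equal(damaged$v_j, intact$v_j, tolerance = 1e-12)
  expect_equal(damaged$phi_po, intact$phi_po, tolerance = 1e-12)
})

test_that("PSI-side controls act as designed: pool size sets amplitude, activation sets timing", {
  amp <- vapply(c(10, 30, 60), function(s) {
    1 - jip_parameters(simulate_ojip(ojip_scenario(S_PSI = s)))$v_i
  }, numeric(1))
  expect_true(all(diff(amp) > 0))

  ht <- vapply(c(0.01, 0.02, 0.05), function(k) {
    tr <- simulate_ojip(ojip_scenario(k_FNR = k))
    wip_half_time(normalize_curves(tr))$half_time_ms
  }, numeric(1))
  expect_true(all(diff(ht) < 0))
})

test_that("MR generator limits behave as programmed", {
  flat <- simulate_mr(fast_amp = 0, slow_amp = 0)
  expect_true(all(abs(flat$refl - 1) < 1e-12))
  mv <- simulate_mr(slow_amp = 0)
  tail_level <- mv$refl[which.max(mv$time_ms)]
  expect_equal(tail_level, 1 - 0.04, tolerance = 1e-6)
  expect_error(simulate_mr(fast_amp = -1), "non-negative")
  expect_error(simulate_mr(k_fast = 0), "positive")
})

test_that("dose-series generator hits its defining points", {
  ser <- simulate_dose_series(i50 = 60, noise_sd = 0)
  expect_equal(unique(ser$response[ser$dose == 60]),
               unique(ser$response[ser$dose == 0]) / 2)
  steep <- simulate_dose_series(i50 = 60, hill_slope = 200, noise_sd = 0,
                                doses = c(0, 30, 59, 61, 120))
  expect_equal(steep$response[steep$dose == 30],
               steep$response[steep$dose == 0], tolerance = 1e-9)
  expect_lt(max(steep$response[steep$dose == 120]), 1e-6)
  expect_error(simulate_dose_series(i50 = -1), "positive")
  expect_error(simulate_dose_series(doses = c(10, 20)), "include 0")

  noisy1 <- simulate_dose_series(noise_sd = 0.05, seed = 4)
  noisy2 <- simulate_dose_series(noise_sd = 0.05, seed = 4)
  expect_identical(noisy1$response, noisy2$response)
})

test_that("the synthetic lesion table covers every class and is reproducible", {
  tbl <- simulate_lesion_table(seed = 1)
  expect_true(all(c("+", "++", "+++") %in% tbl$level))
  expect_true(all(c(0.99, 1.00, 3.00, 3.01) %in% tbl$diameter_mm))
  expect_identical(tbl, simulate_lesion_table(seed = 1))
  expect_false(identical(tbl$diameter_mm, simulate_lesion_table(seed = 2)$diameter_mm))
})
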