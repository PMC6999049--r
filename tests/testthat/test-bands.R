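test_that("normalised curves hit their defining landmarks exactly", {
  tr <- simulate_ojip(ojip_scenario(B = 0.2), label = "s", group = "g")
  cv <- normalize_curves(tr)
  at <- function(curve, t_us) {
    d <- cv[cv$curve == curve, ]
    interp_val <- approx(d$time_us, d$value, t_us)$y
    interp_val
  }
  expect_equal(at("W_OJ", 2000), 1, tolerance = 1e-9)
  expect_equal(at("W_OJ", 20), 0, tolerance = 1e-9)
  expect_equal(at("W_OK", 300), 1, tolerance = 1e-9)
  expect_equal(at("W_OK", 20), 0, tolerance = 1e-9)
  expect_equal(at("W_OI", 30000), 1, tolerance = 1e-9)
  expect_equal(at("V_t", 20), 0, tolerance = 1e-9)

  # V_t = W_OJ * V_J pointwise
  st <- ojip_steps(tr)
  v_j <- (st$F_J - st$F_O) / (st$F_M - st$F_O)
  vt <- cv$value[cv$curve == "V_t"]
  woj <- cv$value[cv$curve == "W_OJ"]
  expect_equal(vt, woj * v_j, tolerance = 1e-12)

  # the part of W_OI above 1 lies inside the I-P window and starts near 1
  upper <- w_oi_upper(cv)
  expect_true(all(upper$value >= 1))
  expect_true(all(upper$time_us >= 30e3 & upper$time_us <= 530e3))
})

test_that("degenerate landmark amplitudes disable only the affected curve", {
  t_us <- ojip_time_grid()
  f <- 500 + 2000 * (1 - exp(-t_us / 5e4))
  f[t_us <= 300] <- 500 # flat through the K step: F_K == F_O
  tr <- as_transient(t_us, f, label = "flat", group = "g")
  expect_warning(cv <- normalize_curves(tr), "W_OK undefined")
  expect_true(all(is.na(cv$value[cv$curve == "W_OK"])))
  expect_true(all(is.finite(cv$value[cv$curve == "V_t"])))
})

test_that("difference kinetics vanish for identical inputs and localise a constructed bump", {
  tr <- simulate_ojip(ojip_scenario(B = 0.2), label = "a", group = "g")
  cv <- normalize_curves(tr)
  d0 <- difference_kinetics(cv, cv)
  expect_true(all(abs(d0$delta) < 1e-12))

  # push V_t up by 0.1 on 1-3 ms only
  bump <- cv |>
    dplyr::mutate(value = ifelse(
      curve == "V_t" & time_us >= 1000 & time_us <= 3000,
      value + 0.1, value
    ))
  d1 <- difference_kinetics(bump, cv)
  bs <- band_summary(d1)
  j <- bs[bs$band == "J", ]
  expect_equal(j$value, 0.1, tolerance = 1e-9)
  expect_true(j$time_us >= 1000 && j$time_us <= 3000)
  expect_equal(bs$value[bs$band == "L"], 0, tolerance = 1e-12)
  expect_equal(bs$value[bs$band == "J_2ms"], 0.1, tolerance = 1e-9)

  # disjoint grids are refused
  shifted <- dplyr::mutate(cv, time_us = time_us + 1e7)
  expect_error(difference_kinetics(cv, shifted), "disjoint")
})

test_that("a blocked subpopulation raises the J difference but not the L band", {
  ctrl <- normalize_curves(simulate_ojip(ojip_scenario(B = 0, p = 0.25),
                                         label = "c", group = "mock"))
  trt <- normalize_curves(simulate_ojip(ojip_scenario(B = 0.5, p = 0.25),
                                        label = "t", group = "gt"))
  bs <- band_summary(difference_kinetics(trt, ctrl))
  j_peak <- bs$value[bs$band == "J"]
  l_band <- bs$value[bs$band == "L"]
  expect_gt(j_peak, 0.1)
  # with equal connectivity the L band stays small relative to the J response
  expect_lt(abs(l_band), 0.1)
  expect_gt(j_peak, 3 * abs(l_band))
})

test_that("the I-P half-time estimator is exact on constructed fixtures", {
  expect_equal(
    wip_half_time(wip_curve(c(30, 50), c(0.4, 0.6)))$half_time_ms, 40
  )
  # exponential rise: crossing at 30 + tau ln 2
  tau <- 100
  tms <- seq(30, 530, by = 2)
  exp_fix <- wip_curve(tms, 1 - exp(-(tms - 30) / tau))
  ht <- wip_half_time(exp_fix)
  expect_true(ht$crossed)
  expect_equal(ht$half_time_ms, 30 + tau * log(2), tolerance = 0.005)
  # monotone but never reaching half rise
  flat <- wip_half_time(wip_curve(tms, 0.45 * (tms - 30) / 500))
  expect_false(flat$crossed)
  expect_true(is.na(flat$half_time_ms))
})

test_that("half-times are invariant to uniform signal rescaling", {
  tr <- simulate_ojip(ojip_scenario(), label = "x", group = "g")
  h1 <- wip_half_time(normalize_curves(tr))
  h2 <- wip_half_time(normalize_curves(dplyr::mutate(tr, fluor = fluor * 7.3)))
  expect_equal(h1$half_time_ms, h2$half_time_ms, tolerance = 1e-9)
})
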