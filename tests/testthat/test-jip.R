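test_that("the hand-evaluated parameter record is reproduced", {
  r <- jip_compute(data.frame(
    F_O = 500, F_K = 900, F_J = 1500, F_I = 2100, F_M = 2500,
    m0_per_ms = 1, t_FM_ms = 500, s_m_ms = 50
  ))
  expect_equal(r$phi_po, 0.8)
  expect_equal(r$phi_do, 0.2)
  expect_equal(r$v_j, 0.5)
  expect_equal(r$v_i, 0.8)
  expect_equal(r$psi_eo, 0.5)
  expect_equal(r$phi_eo, 0.4)
  expect_equal(r$delta_ro, 0.4)
  expect_equal(r$phi_ro, 0.16)
  expect_equal(r$rc_over_abs, 0.4)
  expect_equal(r$gamma_rc, 0.4 / 1.4)
  expect_equal(r$pi_abs, 1.6)
  expect_equal(r$pi_total, 1.6 * 0.4 / 0.6)
  expect_equal(r$sm_over_tfm, 0.1)
  # flux bookkeeping under the F_O proxy
  expect_equal(r$abs_cs, 500)
  expect_equal(r$tr0_cs, 400)
  expect_equal(r$et0_cs, 200)
  expect_equal(r$di0_cs, 100)
  expect_equal(r$rc_cs, 200)
  expect_false(r$j_saturated)
  # the F_M proxy rescales the cross-section fluxes only
  r2 <- jip_compute(
    data.frame(F_O = 500, F_J = 1500, F_I = 2100, F_M = 2500, m0_per_ms = 1),
    abs_cs_proxy = "F_M"
  )
  expect_equal(r2$abs_cs, 2500)
  expect_equal(r2$pi_abs, r$pi_abs)
})

test_that("algebraic identities hold to numerical precision on random records", {
  r <- jip_compute(random_step_records(500, seed = 7))
  expect_true(all(abs(r$phi_po + r$phi_do - 1) < 1e-12))
  expect_true(all(abs(r$phi_eo - r$phi_po * r$psi_eo) < 1e-12))
  expect_true(all(abs(r$phi_ro - r$phi_po * (1 - r$v_i)) < 1e-12))
  expect_true(all(abs(r$abs_cs - (r$tr0_cs + r$di0_cs)) < 1e-12))
  ok <- !r$j_saturated
  expect_true(all(abs(r$pi_total[ok] -
                        r$pi_abs[ok] * r$delta_ro[ok] / (1 - r$delta_ro[ok])) < 1e-12))
  expect_true(all(r$gamma_rc >= 0 & r$gamma_rc < 1))
  expect_true(all(r$v_j >= 0 & r$v_j <= 1 & r$v_i >= 0 & r$v_i <= 1))
})

test_that("raising the J step monotonically degrades electron transport", {
  f_j <- seq(900, 2300, by = 100)
  r <- jip_compute(data.frame(
    F_O = 500, F_J = f_j, F_I = 2400, F_M = 2500, m0_per_ms = 1
  ), j_sat_tol = 1e-9)
  expect_true(all(diff(r$psi_eo) < 0))
  expect_true(all(diff(r$phi_eo) < 0))
  expect_true(all(diff(r$pi_abs) < 0))
  # occupancy versus a fixed control rises with the J step
  ctrl_v_j <- 0.3
  r_j <- (r$v_j - ctrl_v_j) / (1 - ctrl_v_j)
  expect_true(all(diff(r_j) > 0))
})

test_that("J-step saturation zeroes the performance index and flags the record", {
  r <- jip_compute(data.frame(
    F_O = 500, F_J = 2500, F_I = 2500, F_M = 2500, m0_per_ms = 1
  ))
  expect_true(r$j_saturated)
  expect_equal(r$psi_eo, 0)
  expect_equal(r$pi_abs, 0)
  expect_equal(r$pi_total, 0)
  expect_true(is.na(r$delta_ro))
})

test_that("group comparison computes R_J and the Q_A-reducing fraction", {
  base <- jip_compute(data.frame(
    F_O = c(500, 520, 480, 500, 510, 490),
    F_J = c(1300, 1340, 1260, 1900, 1920, 1880),
    F_I = 2100, F_M = c(2500, 2520, 2480, 2500, 2520, 2480),
    m0_per_ms = 1
  ))
  base$label <- sprintf("s%d", 1:6)
  base$group <- rep(c("mock", "treated"), each = 3)
  cmp <- compare_groups(base, control = "mock")
  v_c <- mean(base$v_j[base$group == "mock"])
  v_t <- mean(base$v_j[base$group == "treated"])
  expect_equal(cmp$r_j, (v_t - v_c) / (1 - v_c))
  expect_equal(cmp$qa_reducing_fraction,
               (mean(base$rc_cs[4:6]) / mean(base$rc_cs[1:3])) *
                 (mean(base$abs_cs[4:6]) / mean(base$abs_cs[1:3])))
  expect_equal(cmp$non_qa_reducing_fraction, 1 - cmp$qa_reducing_fraction)

  # identity comparison: same records in both groups
  same <- dplyr::mutate(base[1:3, ], group = "mock")
  dup <- dplyr::mutate(base[1:3, ], group = "copy")
  idc <- compare_groups(dplyr::bind_rows(same, dup), control = "mock")
  expect_equal(idc$r_j, 0)
  rel <- relative_to_control(dplyr::bind_rows(same, dup), control = "mock")
  expect_true(all(abs(rel$relative - 1) < 1e-12))

  # occupancy is clipped into [0, 1] with the raw value retained
  low <- dplyr::bind_rows(
    dplyr::mutate(base[4:6, ], group = "mock"),
    dplyr::mutate(base[1:3, ], group = "less")
  )
  cmp_low <- compare_groups(low, control = "mock")
  expect_lt(cmp_low$r_j_raw, 0)
  expect_equal(cmp_low$r_j, 0)

  expect_error(compare_groups(base, control = "absent"), "not present")
  expect_error(compare_groups(base[base$group == "mock", ], control = "mock"),
               "no treatment groups")
})

test_that("textbook occupancy arithmetic holds", {
  mk <- function(v_j, group, label) {
    jc <- jip_compute(data.frame(F_O = 0, F_J = v_j, F_I = 0.9, F_M = 1,
                                 m0_per_ms = 1), j_sat_tol = 1e-9)
    dplyr::mutate(jc, group = group, label = label)
  }
  tbl <- dplyr::bind_rows(mk(0.4, "mock", "a"), mk(0.7, "t", "b"))
  expect_equal(compare_groups(tbl, control = "mock")$r_j, 0.5)
  tbl2 <- dplyr::bind_rows(mk(0.4, "mock", "a"), mk(1.0, "t", "b"))
  expect_equal(compare_groups(tbl2, control = "mock")$r_j, 1.0)
})

test_that("per-sample occupancy reports dispersion around the group value", {
  base <- jip_compute(data.frame(
    F_O = 500, F_J = c(1300, 1350, 1900, 1950), F_I = 2100, F_M = 2500,
    m0_per_ms = 1
  ))
  base$label <- sprintf("s%d", 1:4)
  base$group <- c("mock", "mock", "t", "t")
  occ <- sample_occupancy(base, control = "mock")
  expect_equal(nrow(occ), 2)
  v_c <- mean(base$v_j[1:2])
  expect_equal(occ$r_j_raw, (base$v_j[3:4] - v_c) / (1 - v_c))
})

test_that("saturation-pulse quenching parameters follow the standard definitions", {
  q <- quench_parameters(200, 1000, 400, 600, par = 110)
  expect_equal(q$fv_over_fm, 0.8)
  expect_equal(q$yield, 1 / 3)
  expect_equal(q$q_p, 0.5)
  expect_equal(q$etr, 110 * 0.84 * 0.5 / 3)

  sat <- quench_parameters(200, 1000, 600, 600)
  expect_equal(sat$yield, 0)
  expect_equal(sat$q_p, 0)
  expect_equal(sat$etr, 0)

  expect_error(quench_parameters(200, 1000, 700, 600), "F_S")
  expect_error(quench_parameters(1000, 200, 400, 600), "F_M > F_O")

  # Oxborough-Baker estimate lowers F_O' (widening the qP denominator)
  ob <- quench_parameters(200, 1000, 400, 600, oxborough_baker = TRUE)
  expect_equal(ob$f_o_prime, 200 / (0.8 + 200 / 600))
  expect_lt(ob$q_p, q$q_p)
})

test_that("relative variable fluorescence endpoints and arithmetic", {
  expect_equal(v_rel(1500, 500, 2500), 0.5)
  expect_equal(v_rel(500, 500, 2500), 0)
  expect_equal(v_rel(2500, 500, 2500), 1)
  expect_equal(v_rel(0.8, 0.29, 1), (0.8 - 0.29) / (1 - 0.29))
  expect_error(v_rel(1, 2, 2), "degenerate")
})
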