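#' Relative variable fluorescence
#'
#' `V_t = (F_t - F_O) / (F_M - F_O)`: the fraction of the maximal variable
#' fluorescence reached at time t.
#'
#' @param f_t fluorescence at time t.
#' @param f_o minimal fluorescence (all reaction centers open).
#' @param f_m maximal fluorescence.
#' @return numeric vector.
#' @export
v_rel <- function(f_t, f_o, f_m) {
  if (any(f_m <= f_o)) abort("degenerate transient: F_M must exceed F_O")
  (f_t - f_o) / (f_m - f_o)
}

#' JIP-test parameters from a step/area record
#'
#' Computes the quantum efficiencies, flux ratios, phenomenological fluxes
#' per cross-section, reaction-center density and performance indexes of the
#' JIP-test from landmark fluorescences. This is the low-level entry point
#' taking a step record directly (see [jip_parameters()] for the
#' transient-in, parameters-out wrapper); it is vectorised over rows.
#'
#' Required columns: `F_O`, `F_J`, `F_M` and `m0_per_ms`. Optional: `F_K`,
#' `F_L`, `F_I`, `t_FM_ms`, `s_m_ms` (the parameters needing them are `NA`
#' when absent), `label`, `group`.
#'
#' The absorption flux per cross-section has no estimator of its own on a
#' fluorescence trace; the standard proxy `ABS/CS ~ F_O` is used by default
#' (`"F_M"` is the common alternative) and the choice is recorded in the
#' output.
#'
#' When the J-step reaches the peak (classical Q_B-site inhibitor
#' saturation, e.g. DCMU), the electron-transport probability psi_Eo
#' vanishes and the performance indexes degenerate: rows with
#' `psi_Eo <= j_sat_tol` are flagged `j_saturated`, their `pi_abs` and
#' `pi_total` are 0 and `delta_Ro` is undefined (`NA`).
#'
#' @param steps data frame of step values (and areas), one row per sample.
#' @param abs_cs_proxy fluorescence proxy for ABS/CS: `"F_O"` or `"F_M"`.
#' @param j_sat_tol saturation tolerance on psi_Eo (default 0.05, about the
#'   resolution of variable fluorescence on a fast fluorometer transient).
#' @return a tibble, one row per input row, with the step columns plus
#'   `v_l`, `v_k`, `v_j`, `v_i`, `f_k_over_f_j`, `phi_po`, `psi_eo`,
#'   `phi_eo`, `phi_do`, `phi_ro`, `delta_ro`, `rc_over_abs`, `gamma_rc`,
#'   `abs_cs`, `tr0_cs`, `et0_cs`, `di0_cs`, `rc_cs`, `sm_over_tfm`,
#'   `pi_abs`, `pi_total`, `j_saturated`, `abs_cs_proxy`.
#' @examples
#' jip_compute(data.frame(F_O = 500, F_J = 1500, F_I = 2100, F_M = 2500,
#'                        m0_per_ms = 1))
#' @export
jip_compute <- function(steps, abs_cs_proxy = c("F_O", "F_M"), j_sat_tol = 0.05) {
  abs_cs_proxy <- match.arg(abs_cs_proxy)
  need <- c("F_O", "F_J", "F_M", "m0_per_ms")
  missing_cols <- setdiff(need, names(steps))
  if (length(missing_cols) > 0) {
    abort(paste0("jip_compute() needs columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(steps$F_M <= steps$F_O)) {
    abort("degenerate step record: F_M must exceed F_O in every row")
  }
  opt <- function(col) if (col %in% names(steps)) steps[[col]] else NA_real_
  out <- tibble::as_tibble(steps)
  f_o <- steps$F_O; f_m <- steps$F_M; f_v <- f_m - f_o
  v_j <- (steps$F_J - f_o) / f_v
  v_i <- (opt("F_I") - f_o) / f_v
  v_k <- (opt("F_K") - f_o) / f_v
  v_l <- (opt("F_L") - f_o) / f_v
  m0 <- steps$m0_per_ms
  phi_po <- 1 - f_o / f_m
  psi_eo <- 1 - v_j
  saturated <- psi_eo <= j_sat_tol
  delta_ro <- ifelse(saturated, NA_real_, (1 - v_i) / (1 - v_j))
  rc_over_abs <- phi_po * (v_j / m0)
  abs_cs <- if (abs_cs_proxy == "F_O") f_o else f_m
  tr0_cs <- phi_po * abs_cs
  pi_abs <- ifelse(saturated, 0,
                   rc_over_abs * (phi_po / (1 - phi_po)) * (psi_eo / (1 - psi_eo)))
  pi_total <- ifelse(saturated | is.na(delta_ro) | delta_ro >= 1, 0,
                     pi_abs * delta_ro / (1 - delta_ro))
  out$v_l <- v_l
  out$v_k <- v_k
  out$v_j <- v_j
  out$v_i <- v_i
  out$f_k_over_f_j <- opt("F_K") / steps$F_J
  out$phi_po <- phi_po
  out$psi_eo <- psi_eo
  out$phi_eo <- phi_po * psi_eo
  out$phi_do <- f_o / f_m
  out$phi_ro <- phi_po * (1 - v_i)
  out$delta_ro <- delta_ro
  out$rc_over_abs <- rc_over_abs
  out$gamma_rc <- rc_over_abs / (1 + rc_over_abs)
  out$abs_cs <- abs_cs
  out$tr0_cs <- tr0_cs
  out$et0_cs <- phi_po * psi_eo * abs_cs
  out$di0_cs <- abs_cs - tr0_cs
  out$rc_cs <- rc_over_abs * abs_cs
  out$sm_over_tfm <- opt("s_m_ms") / opt("t_FM_ms")
  out$pi_abs <- pi_abs
  out$pi_total <- pi_total
  out$j_saturated <- saturated
  out$abs_cs_proxy <- abs_cs_proxy
  out
}

#' Full JIP-test record from raw transients
#'
#' Convenience wrapper: extracts the landmark steps ([ojip_steps()]) and
#' areas ([ojip_areas()]) of every sample and feeds them to
#' [jip_compute()].
#'
#' @param x a transient tibble (one or more samples).
#' @param rule interpolation rule for the landmarks.
#' @inheritParams jip_compute
#' @return a tibble with one row per sample holding the complete step, area
#'   and JIP-test parameter record.
#' @examples
#' jip_parameters(simulate_ojip())
#' @export
jip_parameters <- function(x, abs_cs_proxy = c("F_O", "F_M"),
                           rule = c("linear", "log-time"), j_sat_tol = 0.05) {
  rule <- match.arg(rule)
  steps <- ojip_steps(x, rule = rule)
  areas <- ojip_areas(x, steps = steps)
  jip_compute(
    dplyr::left_join(steps, areas, by = c("label", "group")),
    abs_cs_proxy = match.arg(abs_cs_proxy), j_sat_tol = j_sat_tol
  )
}

#' Between-group inhibitor occupancy and reaction-center statistics
#'
#' For each treatment group versus the control group this computes, from the
#' group means:
#' the Q_B-site occupancy
#' `R_J = (V_J(treatment) - V_J(control)) / (1 - V_J(control))`
#' (the fraction of PSII reaction centers whose Q_B site is filled by the
#' inhibitor; reported raw and clipped to the occupancy range 0..1),
#' the fraction of Q_A-reducing centers
#' `(RC/CS_t / RC/CS_c) * (ABS/CS_t / ABS/CS_c)` and its complement.
#'
#' @param jip a per-sample JIP record from [jip_parameters()] (or
#'   [jip_compute()] with `label`/`group` columns).
#' @param control name of the control group.
#' @return a tibble with one row per treatment group: sample counts, group
#'   mean `v_j` of both sides, `r_j_raw`, `r_j` (clipped), the Q_A-reducing
#'   and non-Q_A-reducing fractions.
#' @seealso [relative_to_control()] for the spider-plot table,
#'   [sample_occupancy()] for per-sample R_J dispersion.
#' @export
compare_groups <- function(jip, control = "mock") {
  check_groups(jip, control)
  means <- jip |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      v_j = mean(.data$v_j), rc_cs = mean(.data$rc_cs),
      abs_cs = mean(.data$abs_cs), .groups = "drop"
    )
  ctrl <- means[means$group == control, ]
  if (ctrl$v_j >= 1) abort("control group has saturated V_J; R_J is undefined")
  means |>
    dplyr::filter(.data$group != control) |>
    dplyr::transmute(
      group = .data$group,
      control = control,
      n_treated = .data$n,
      n_control = ctrl$n,
      v_j_treated = .data$v_j,
      v_j_control = ctrl$v_j,
      r_j_raw = (.data$v_j - ctrl$v_j) / (1 - ctrl$v_j),
      r_j = clamp(.data$r_j_raw, 0, 1),
      qa_reducing_fraction =
        (.data$rc_cs / ctrl$rc_cs) * (.data$abs_cs / ctrl$abs_cs),
      non_qa_reducing_fraction = 1 - .data$qa_reducing_fraction
    )
}

#' Treatment parameters as fractions of the control mean
#'
#' The spider-plot view: every numeric JIP parameter of each treatment
#' group expressed as the ratio of its group mean to the control group mean
#' (control = 1).
#'
#' @inheritParams compare_groups
#' @param params character vector of parameter columns; defaults to all
#'   numeric JIP columns present.
#' @return a long tibble: `group`, `parameter`, `control_mean`,
#'   `treated_mean`, `relative`.
#' @export
relative_to_control <- function(jip, control = "mock", params = NULL) {
  check_groups(jip, control)
  default_params <- c(
    "F_O", "F_M", "v_k", "v_j", "v_i", "f_k_over_f_j", "phi_po", "psi_eo",
    "phi_eo", "phi_do", "phi_ro", "delta_ro", "gamma_rc", "abs_cs", "tr0_cs",
    "et0_cs", "di0_cs", "rc_cs", "s_m_ms", "sm_over_tfm", "pi_abs", "pi_total"
  )
  params <- params %||% intersect(default_params, names(jip))
  long <- jip |>
    dplyr::select(dplyr::all_of(c("group", params))) |>
    tidyr::pivot_longer(-"group", names_to = "parameter", values_to = "value") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$group, .data$parameter) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop")
  ctrl <- long |>
    dplyr::filter(.data$group == control) |>
    dplyr::select("parameter", control_mean = "mean")
  long |>
    dplyr::filter(.data$group != control) |>
    dplyr::left_join(ctrl, by = "parameter") |>
    dplyr::transmute(
      group = .data$group, parameter = .data$parameter,
      control_mean = .data$control_mean, treated_mean = .data$mean,
      relative = .data$mean / .data$control_mean
    )
}

#' Per-sample Q_B-site occupancy against the control mean
#'
#' The headline R_J of [compare_groups()] is a ratio of group means; this
#' companion reports each treated sample's own R_J against the control-mean
#' V_J, for dispersion assessment.
#'
#' @inheritParams compare_groups
#' @return a tibble: `label`, `group`, `r_j_raw`, `r_j`.
#' @export
sample_occupancy <- function(jip, control = "mock") {
  check_groups(jip, control)
  v_j_ctrl <- mean(jip$v_j[jip$group == control])
  if (v_j_ctrl >= 1) abort("control group has saturated V_J; R_J is undefined")
  jip |>
    dplyr::filter(.data$group != control) |>
    dplyr::transmute(
      label = .data$label, group = .data$group,
      r_j_raw = (.data$v_j - v_j_ctrl) / (1 - v_j_ctrl),
      r_j = clamp(.data$r_j_raw, 0, 1)
    )
}

check_groups <- function(jip, control) {
  if (!all(c("group", "v_j") %in% names(jip))) {
    abort("expected a per-sample JIP record with 'group' and 'v_j' columns")
  }
  if (nrow(jip) == 0) abort("empty JIP record")
  if (!control %in% jip$group) {
    abort(sprintf("control group '%s' not present", control))
  }
  if (all(jip$group == control)) {
    abort("no treatment groups to compare against the control")
  }
  invisible(TRUE)
}

#' Saturation-pulse quenching parameters
#'
#' Standard pulse-amplitude-modulation definitions from the dark-adapted
#' extremes (F_O, F_M) and light-adapted steady state and pulse maximum
#' (F_S, F_M'): maximal PSII quantum yield `F_V/F_M`, effective quantum
#' yield `Yield = (F_M' - F_S)/F_M'`, photochemical quenching
#' `qP = (F_M' - F_S)/(F_M' - F_O')` and the apparent electron transport
#' rate `ETR = Yield * PAR * absorptance * PSII fraction`.
#'
#' The light-adapted minimal fluorescence F_O' is rarely measured; by
#' default it is taken equal to F_O, with the Oxborough-Baker estimate
#' `F_O' = F_O / (F_V/F_M + F_O/F_M')` available via `oxborough_baker`.
#'
#' @param f_o,f_m dark-adapted minimal and maximal fluorescence.
#' @param f_s,f_m_prime light-adapted steady-state and pulse-maximal
#'   fluorescence.
#' @param par actinic photon flux density, µmol m^-2 s^-1.
#' @param absorptance leaf/suspension absorptance fraction (default 0.84).
#' @param psii_fraction fraction of absorbed quanta reaching PSII (0.5).
#' @param f_o_prime explicit F_O' (overrides both defaults).
#' @param oxborough_baker estimate F_O' from F_O, F_V/F_M and F_M'.
#' @return a tibble: `fv_over_fm`, `yield`, `q_p`, `etr`, `f_o_prime`.
#' @examples
#' quench_parameters(200, 1000, 400, 600, par = 110)
#' @export
quench_parameters <- function(f_o, f_m, f_s, f_m_prime, par = 110,
                              absorptance = 0.84, psii_fraction = 0.5,
                              f_o_prime = NULL, oxborough_baker = FALSE) {
  if (any(f_m <= f_o) || any(f_o <= 0)) abort("need F_M > F_O > 0")
  if (any(f_m_prime < f_s)) abort("F_M' must be at least F_S")
  fv_fm <- (f_m - f_o) / f_m
  if (is.null(f_o_prime)) {
    f_o_prime <- if (oxborough_baker) {
      f_o / (fv_fm + f_o / f_m_prime)
    } else {
      f_o
    }
  }
  yield <- (f_m_prime - f_s) / f_m_prime
  q_p <- (f_m_prime - f_s) / (f_m_prime - f_o_prime)
  tibble::tibble(
    fv_over_fm = fv_fm, yield = yield, q_p = q_p,
    etr = yield * par * absorptance * psii_fraction,
    f_o_prime = f_o_prime
  )
}
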