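#' Extract the OJIP landmark values of a transient
#'
#' Reads the canonical step fluorescences off the induction curve: the
#' origin F_O at 20 µs, the L- and K-step values at 150 and 300 µs, F_J at
#' 2 ms, F_I at 30 ms, the 270 µs point used by the initial-slope estimate
#' M_0, and the recorded peak F_M (= F_P) with its time t_FM. F_M is the
#' maximum of the *samples* (the maximal recorded intensity), not of the
#' interpolant; ties take the first occurrence. Landmarks between samples
#' are interpolated with [fluor_at()].
#'
#' A flat trace (F_M equal to F_O) has no variable fluorescence and is
#' rejected; a peak at or before 2 ms is physiologically suspicious and
#' triggers a warning, not an error.
#'
#' @param x a transient tibble (one or more samples).
#' @param rule interpolation rule passed to [fluor_at()].
#' @return a tibble with one row per sample: `label`, `group`, `F_O`,
#'   `F_L`, `F_K`, `F_J`, `F_I`, `F_M`, `F_V`, `F_270`, `t_FM_ms`.
#' @examples
#' tr <- simulate_ojip()
#' ojip_steps(tr)
#' @export
ojip_steps <- function(x, rule = c("linear", "log-time")) {
  rule <- match.arg(rule)
  per_sample(x, function(d) ojip_steps_one(d, rule))
}

ojip_steps_one <- function(d, rule) {
  t_origin <- max(20, min(d$time_us))
  landmark <- function(t_us) {
    if (t_us < min(d$time_us) || t_us > max(d$time_us)) return(NA_real_)
    interp_signal(d$time_us, d$fluor, t_us, rule)
  }
  f_o <- landmark(t_origin)
  i_max <- which.max(d$fluor) # first occurrence on ties
  f_m <- d$fluor[i_max]
  t_fm_ms <- d$time_us[i_max] / 1e3
  if (f_m <= f_o) {
    abort(sprintf(
      "degenerate transient '%s': no variable fluorescence (F_M <= F_O)",
      d$label[1]
    ))
  }
  if (t_fm_ms <= 2) {
    warn(sprintf(
      "transient '%s': peak at %g ms (<= 2 ms) is not a physiological O-J-I-P rise",
      d$label[1], t_fm_ms
    ))
  }
  tibble::tibble(
    F_O = f_o, F_L = landmark(150), F_K = landmark(300),
    F_J = landmark(2000), F_I = landmark(30000),
    F_M = f_m, F_V = f_m - f_o, F_270 = landmark(270),
    t_FM_ms = t_fm_ms
  )
}

#' Complementary area, normalised areas and initial slope of a transient
#'
#' `Area` is the complementary area above the induction curve,
#' trapezoid-integrated over the raw sample grid from onset to the peak time
#' t_FM with fluorescence capped at F_M (noise can push single samples above
#' the recorded maximum); times are in ms. Derived from it are
#' `S_m = Area / (F_M - F_O)` (multiple-turnover normalised area, ms),
#' the approximated initial slope `M_0 = 4 (F_270us - F_O) / (F_M - F_O)`
#' (1/ms), and the single-turnover area `S_s = V_J / M_0` (ms).
#'
#' The step record defaults to [ojip_steps()] of the same transient but can
#' be supplied, e.g. to analyse a pre-normalised curve where F_O and F_M are
#' known exactly.
#'
#' @param x a transient tibble.
#' @param steps step record as returned by [ojip_steps()]; recomputed when
#'   `NULL`.
#' @return a tibble with one row per sample: `label`, `group`, `area`,
#'   `s_m_ms`, `m0_per_ms`, `s_s_ms`.
#' @export
ojip_areas <- function(x, steps = NULL) {
  steps <- steps %||% ojip_steps(x)
  x |>
    per_sample(function(d) {
      st <- steps[steps$label == d$label[1] & steps$group == d$group[1], ]
      if (nrow(st) != 1) {
        abort(sprintf("no (or ambiguous) step record for sample '%s'", d$label[1]))
      }
      ojip_areas_one(d, st)
    })
}

ojip_areas_one <- function(d, st) {
  if (st$F_M <= st$F_O) {
    abort(sprintf("degenerate transient '%s': F_M <= F_O", d$label[1]))
  }
  t_ms <- d$time_us / 1e3
  keep <- t_ms <= st$t_FM_ms
  tt <- t_ms[keep]
  ff <- pmin(d$fluor[keep], st$F_M)
  gap <- st$F_M - ff
  area <- sum(diff(tt) * (gap[-1] + gap[-length(gap)]) / 2)
  s_m <- area / (st$F_M - st$F_O)
  m0 <- 4 * (st$F_270 - st$F_O) / (st$F_M - st$F_O)
  v_j <- (st$F_J - st$F_O) / (st$F_M - st$F_O)
  tibble::tibble(
    area = area, s_m_ms = s_m, m0_per_ms = m0,
    s_s_ms = if (m0 > 0) v_j / m0 else NA_real_
  )
}
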