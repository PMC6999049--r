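#' Double-normalised induction kinetics
#'
#' Normalises the induction curve between pairs of landmarks, producing the
#' standard analysis curves on the transient's own time grid:
#' `V_t = (F_t - F_O)/(F_M - F_O)`,
#' `W_OK = (F_t - F_O)/(F_K - F_O)`,
#' `W_OJ = (F_t - F_O)/(F_J - F_O)`,
#' `W_OI = (F_t - F_O)/(F_I - F_O)` and
#' `W_IP = (F_t - F_I)/(F_P - F_I)`.
#' Each W curve is 0 at its lower landmark and 1 at its defining upper
#' landmark. A vanishing denominator (e.g. F_K = F_O) makes that one curve
#' `NA` with a warning; the others are still computed.
#'
#' @param x a transient tibble (one or more samples).
#' @param steps optional precomputed [ojip_steps()] record.
#' @param rule interpolation rule for the landmarks.
#' @return a long tibble: `label`, `group`, `time_us`, `curve`
#'   (`"V_t"`, `"W_OK"`, `"W_OJ"`, `"W_OI"`, `"W_IP"`), `value`.
#' @seealso [difference_kinetics()], [wip_half_time()], [w_oi_upper()]
#' @export
normalize_curves <- function(x, steps = NULL,
                             rule = c("linear", "log-time")) {
  rule <- match.arg(rule)
  steps <- steps %||% ojip_steps(x, rule = rule)
  per_sample(x, function(d) {
    st <- steps[steps$label == d$label[1] & steps$group == d$group[1], ]
    if (nrow(st) != 1) {
      abort(sprintf("no (or ambiguous) step record for sample '%s'", d$label[1]))
    }
    ratio <- function(lo, hi, name) {
      den <- hi - lo
      if (!is.finite(den) || den == 0) {
        warn(sprintf(
          "sample '%s': %s undefined (zero landmark amplitude)", d$label[1], name
        ))
        return(rep(NA_real_, nrow(d)))
      }
      (d$fluor - lo) / den
    }
    tibble::tibble(
      time_us = rep(d$time_us, 5),
      curve = rep(c("V_t", "W_OK", "W_OJ", "W_OI", "W_IP"), each = nrow(d)),
      value = c(
        ratio(st$F_O, st$F_M, "V_t"),
        ratio(st$F_O, st$F_K, "W_OK"),
        ratio(st$F_O, st$F_J, "W_OJ"),
        ratio(st$F_O, st$F_I, "W_OI"),
        ratio(st$F_I, st$F_M, "W_IP")
      )
    )
  })
}

#' The part of W_OI above 1 (the I-P rise)
#'
#' Restricts the W_OI curve to values >= 1 inside the I-P analysis range;
#' the maximal amplitude of this branch reflects the size of the PSI
#' end-electron-acceptor pool.
#'
#' @param curves a long curve tibble from [normalize_curves()].
#' @param range_ms analysis window, default 30-530 ms.
#' @return the filtered long tibble (curve `"W_OI"` only).
#' @export
w_oi_upper <- function(curves, range_ms = c(30, 530)) {
  curves |>
    dplyr::filter(
      .data$curve == "W_OI", .data$value >= 1,
      .data$time_us >= range_ms[1] * 1e3, .data$time_us <= range_ms[2] * 1e3
    )
}

#' Treated-minus-control difference kinetics
#'
#' Computes the difference curves that expose the L-band, K-band and J-peak:
#' `dV_t`, `dW_OK` and `dW_OJ`, treated minus control, on the union of the
#' two time grids (each side interpolated linearly, and averaged across its
#' samples first when a side carries several). The overlap of the two time
#' ranges is used; disjoint ranges are an error.
#'
#' @param treated,control long curve tibbles from [normalize_curves()].
#' @param curves_to_diff which curves to difference.
#' @return a long tibble: `curve`, `time_us`, `treated`, `control`, `delta`.
#' @export
difference_kinetics <- function(treated, control,
                                curves_to_diff = c("V_t", "W_OK", "W_OJ")) {
  purrr::map_dfr(curves_to_diff, function(cv) {
    tr <- dplyr::filter(treated, .data$curve == cv, is.finite(.data$value))
    ct <- dplyr::filter(control, .data$curve == cv, is.finite(.data$value))
    if (nrow(tr) == 0 || nrow(ct) == 0) {
      abort(sprintf("curve '%s' missing from one side", cv))
    }
    lo <- max(min(tr$time_us), min(ct$time_us))
    hi <- min(max(tr$time_us), max(ct$time_us))
    if (lo >= hi) abort("treated and control time ranges are disjoint")
    grid <- sort(unique(c(tr$time_us, ct$time_us)))
    grid <- grid[grid >= lo & grid <= hi]
    mean_curve <- function(side) {
      side |>
        dplyr::group_by(.data$label) |>
        dplyr::reframe(value = interp_signal(.data$time_us, .data$value, grid),
                       time_us = grid) |>
        dplyr::group_by(.data$time_us) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop")
    }
    tm <- mean_curve(tr)
    cm <- mean_curve(ct)
    tibble::tibble(
      curve = paste0("d", cv), time_us = grid,
      treated = tm$value, control = cm$value,
      delta = tm$value - cm$value
    )
  })
}

#' Band extrema of difference kinetics
#'
#' Summarises the difference curves of [difference_kinetics()] at the
#' standard bands: the L-band (largest-magnitude `dW_OK` within 100-300 µs,
#' a connectivity/grouping indicator), the K-band (largest-magnitude
#' `dW_OJ` within 200-500 µs, an oxygen-evolving-complex indicator) and the
#' J-region of `dV_t` (1-3 ms). Because the J-peak is usually quoted at the
#' 2 ms step itself, the value of `dV_t` exactly at 2 ms is reported as an
#' additional row.
#'
#' @param diff a difference-curve tibble from [difference_kinetics()].
#' @param l_window_us,k_window_us,j_window_us band search windows (µs).
#' @return a tibble: `band`, `curve`, `time_us`, `value` (signed extremum of
#'   largest magnitude within the window).
#' @export
band_summary <- function(diff, l_window_us = c(100, 300),
                         k_window_us = c(200, 500),
                         j_window_us = c(1000, 3000)) {
  pick <- function(cv, win, band) {
    d <- dplyr::filter(diff, .data$curve == cv,
                       .data$time_us >= win[1], .data$time_us <= win[2])
    if (nrow(d) == 0) {
      return(tibble::tibble(band = band, curve = cv,
                            time_us = NA_real_, value = NA_real_))
    }
    i <- which.max(abs(d$delta))
    tibble::tibble(band = band, curve = cv,
                   time_us = d$time_us[i], value = d$delta[i])
  }
  at2ms <- dplyr::filter(diff, .data$curve == "dV_t")
  j2 <- if (nrow(at2ms) > 0 && min(at2ms$time_us) <= 2000 && max(at2ms$time_us) >= 2000) {
    tibble::tibble(
      band = "J_2ms", curve = "dV_t", time_us = 2000,
      value = interp_signal(at2ms$time_us, at2ms$delta, 2000)
    )
  } else {
    tibble::tibble(band = "J_2ms", curve = "dV_t",
                   time_us = NA_real_, value = NA_real_)
  }
  dplyr::bind_rows(
    pick("dW_OK", l_window_us, "L"),
    pick("dW_OJ", k_window_us, "K"),
    pick("dV_t", j_window_us, "J"),
    j2
  )
}

#' Half-rise time of the I-P phase
#'
#' The time at which the W_IP curve first crosses 0.5 upward within the I-P
#' analysis window, linearly interpolated between the bracketing samples. A
#' larger half-time indicates a lower conduction rate towards the PSI
#' end-electron acceptors. Curves that never reach 0.5 in the window are
#' flagged (`crossed = FALSE`, `half_time_ms = NA`).
#'
#' @param curves a long curve tibble containing a `"W_IP"` curve (from
#'   [normalize_curves()], or constructed directly).
#' @param range_ms analysis window, default 30-530 ms.
#' @return a tibble: `label`, `group`, `half_time_ms`, `crossed`.
#' @export
wip_half_time <- function(curves, range_ms = c(30, 530)) {
  wip <- dplyr::filter(curves, .data$curve == "W_IP")
  if (nrow(wip) == 0) abort("no W_IP curve in input")
  per_sample(wip, function(d) {
    d <- d[d$time_us >= range_ms[1] * 1e3 & d$time_us <= range_ms[2] * 1e3 &
             is.finite(d$value), ]
    d <- d[order(d$time_us), ]
    up <- which(d$value[-1] >= 0.5 & d$value[-nrow(d)] < 0.5)
    if (nrow(d) > 0 && d$value[1] >= 0.5) {
      # already above half at the window start: treat the start as the crossing
      return(tibble::tibble(half_time_ms = d$time_us[1] / 1e3, crossed = TRUE))
    }
    if (length(up) == 0) {
      return(tibble::tibble(half_time_ms = NA_real_, crossed = FALSE))
    }
    i <- up[1]
    t0 <- d$time_us[i]; t1 <- d$time_us[i + 1]
    w0 <- d$value[i]; w1 <- d$value[i + 1]
    tibble::tibble(
      half_time_ms = (t0 + (0.5 - w0) / (w1 - w0) * (t1 - t0)) / 1e3,
      crossed = TRUE
    )
  })
}
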