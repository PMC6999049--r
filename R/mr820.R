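#' Normalise an MR trace to its onset value
#'
#' Adds `refl_rel = MR/MR_0`, with MR_0 the signal interpolated at 0.7 ms
#' (the first reliable measurement after actinic onset).
#'
#' @param trace an MR trace tibble (see [as_mr_trace()]).
#' @param t0_ms onset reference time, default 0.7 ms.
#' @return the trace with an added `refl_rel` column.
#' @export
normalize_mr <- function(trace, t0_ms = 0.7) {
  per_sample(trace, function(d) {
    mr0 <- interp_signal(d$time_ms, d$refl, t0_ms)
    dplyr::mutate(d, refl_rel = .data$refl / mr0)
  })
}

#' Characteristic features of MR 820 nm kinetics
#'
#' A typical modulated-reflection induction curve has two phases: a fast
#' decrease from `MR_0` (0.7 ms) to a minimum `MR_min` as plastocyanin and
#' P700 become oxidised, and a slow increase to `MR_max` as intersystem
#' electrons re-reduce them. Extracted per sample:
#' `MR_0` (interpolated at the start of the fast window), `MR_min` and its
#' time within the fast window, `MR_max` and its time after `t_min` up to
#' `slow_end_ms`, and the relative amplitudes
#' `fast = (MR_0 - MR_min)/MR_0`, `slow = (MR_max - MR_min)/MR_0`.
#'
#' Degenerate slow phases are classified: `"re-reduction"` when the slow
#' amplitude exceeds `slow_tol`, otherwise `"decline"` when the signal keeps
#' falling after `t_min` (complete disconnection of the photosystems, the
#' DCMU phenotype) or `"plateau"` when it stays at `MR_min` (PSI-acceptor
#' bypass, the methyl-viologen phenotype).
#'
#' `MR_min` is an extremum statistic, so an optional running-median smoother
#' (`smooth_window`, odd number of points, default off) is offered for noisy
#' traces.
#'
#' @param trace an MR trace tibble.
#' @param fast_window_ms search window for the fast-phase minimum,
#'   default `c(0.7, 200)` ms.
#' @param slow_end_ms end of the slow-phase window, default 2000 ms.
#' @param slow_tol relative amplitude below which the slow phase is called
#'   absent, default 0.005.
#' @param smooth_window odd running-median window in points; 0 disables.
#' @return a tibble, one row per sample: `label`, `group`, `mr_0`,
#'   `mr_min`, `t_min_ms`, `mr_max`, `t_max_ms`, `fast_amplitude`,
#'   `slow_amplitude`, `slow_phase`.
#' @examples
#' mr_features(simulate_mr())
#' @export
mr_features <- function(trace, fast_window_ms = c(0.7, 200),
                        slow_end_ms = 2000, slow_tol = 0.005,
                        smooth_window = 0) {
  per_sample(trace, function(d) {
    if (min(d$time_ms) > fast_window_ms[1] * (1 + 1e-9) ||
        max(d$time_ms) < slow_end_ms * (1 - 1e-9)) {
      abort(sprintf(
        "sample '%s' does not cover the analysis window [%g, %g] ms",
        d$label[1], fast_window_ms[1], slow_end_ms
      ))
    }
    y <- d$refl
    if (smooth_window >= 3) {
      y <- stats::runmed(y, k = smooth_window %/% 2 * 2 + 1, endrule = "median")
    }
    mr0 <- interp_signal(d$time_ms, y, fast_window_ms[1])
    fast <- which(d$time_ms >= fast_window_ms[1] & d$time_ms <= fast_window_ms[2])
    i_min <- fast[which.min(y[fast])]
    mr_min <- y[i_min]
    t_min <- d$time_ms[i_min]
    slow <- which(d$time_ms > t_min & d$time_ms <= slow_end_ms)
    if (length(slow) == 0) slow <- i_min
    i_max <- slow[which.max(y[slow])]
    # on a monotone decline every later point is below MR_min; the slow
    # amplitude is then zero, not negative
    mr_max <- max(y[i_max], mr_min)
    slow_amp <- (mr_max - mr_min) / mr0
    tail_val <- interp_signal(d$time_ms, y, slow_end_ms)
    phase <- if (slow_amp > slow_tol) {
      "re-reduction"
    } else if (tail_val < mr_min - slow_tol * mr0) {
      "decline"
    } else {
      "plateau"
    }
    tibble::tibble(
      mr_0 = mr0, mr_min = mr_min, t_min_ms = t_min,
      mr_max = mr_max, t_max_ms = d$time_ms[i_max],
      fast_amplitude = (mr0 - mr_min) / mr0,
      slow_amplitude = slow_amp,
      slow_phase = phase
    )
  })
}
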