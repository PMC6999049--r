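#' Scenario for the mechanistic OJIP transient generator
#'
#' The generator is a deliberately minimal three-state model of the PSII
#' acceptor side whose only job is to produce ordered, tunable O-J-I-P
#' structure. Two reaction-center subpopulations are propagated:
#'
#' * a fraction `B` with the Q_B site blocked by an inhibitor: their Q_A is
#'   reduced at the light-driven rate `k_L` and never reoxidised, so they
#'   close with a single exponential (the DCMU phenotype at `B = 1`);
#' * the active fraction `1 - B`: Q_A- is reoxidised at `k_AB` while the
#'   oxidised plastoquinone pool (size `N_PQ` electron equivalents per RC)
#'   lasts; the pool is re-oxidised by a PSI-side drain that switches on
#'   with rate `k_FNR` (ferredoxin-NADP-reductase activation) and draws on
#'   an end-acceptor pool of `S_PSI` equivalents at specific rate `k_red`.
#'
#' The J step therefore rises with `B`, the I level with the drain
#' activation state, the I-P amplitude with `S_PSI`, and the I-P timing
#' with `k_FNR`. Fluorescence follows the closed fraction `C` through the
#' antenna-connectivity transform `(1 - p) C / (1 - p C)` between `F_O_level`
#' and `F_M_level`, both attenuated by `antenna_loss` (antenna damage scales
#' the whole signal without touching any normalised ratio). Multiplicative
#' Gaussian noise of relative standard deviation `noise_sd` is applied last.
#'
#' @param B fraction of reaction centers with a blocked Q_B site (0-1).
#' @param p antenna connectivity probability (0-1).
#' @param k_L light-driven Q_A reduction rate, 1/ms (2/ms corresponds to
#'   saturating red actinic light of a plant-efficiency analyser).
#' @param k_AB Q_A- to Q_B reoxidation rate, 1/ms.
#' @param N_PQ oxidised plastoquinone pool size, equivalents per RC.
#' @param S_PSI PSI end-electron-acceptor pool size, equivalents per RC.
#' @param k_FNR activation rate of the PSI-side drain, 1/ms.
#' @param k_red specific re-oxidation rate of the PQ pool by the activated
#'   drain, 1/ms per remaining acceptor equivalent.
#' @param F_O_level,F_M_level fluorescence extremes, instrument units.
#' @param antenna_loss multiplicative attenuation of both levels (0-1).
#' @param noise_sd relative Gaussian noise standard deviation.
#' @return a validated `ojip_scenario` list.
#' @seealso [simulate_ojip()]
#' @export
ojip_scenario <- function(B = 0, p = 0.25, k_L = 2, k_AB = 2.5, N_PQ = 10,
                          S_PSI = 30, k_FNR = 0.02, k_red = 0.012,
                          F_O_level = 500, F_M_level = 2500,
                          antenna_loss = 0, noise_sd = 0) {
  sc <- list(
    B = B, p = p, k_L = k_L, k_AB = k_AB, N_PQ = N_PQ, S_PSI = S_PSI,
    k_FNR = k_FNR, k_red = k_red, F_O_level = F_O_level,
    F_M_level = F_M_level, antenna_loss = antenna_loss, noise_sd = noise_sd
  )
  bad <- !vapply(sc, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                 logical(1))
  if (any(bad)) {
    abort(paste0("non-finite scenario fields: ", paste(names(sc)[bad], collapse = ", ")))
  }
  if (B < 0 || B > 1) abort("B must lie in [0, 1]")
  if (p < 0 || p > 1) abort("p must lie in [0, 1]")
  if (antenna_loss < 0 || antenna_loss >= 1) abort("antenna_loss must lie in [0, 1)")
  if (any(c(k_L, k_AB, k_FNR, k_red, N_PQ, S_PSI) <= 0)) {
    abort("rates and pool sizes must be positive")
  }
  if (F_M_level <= F_O_level) abort("F_M_level must exceed F_O_level")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  structure(sc, class = "ojip_scenario")
}

#' @export
print.ojip_scenario <- function(x, ...) {
  cat("OJIP generator scenario\n")
  cat(sprintf("  blocked fraction B = %.3g, connectivity p = %.3g\n", x$B, x$p))
  cat(sprintf("  k_L = %.3g/ms, k_AB = %.3g/ms, N_PQ = %.3g eq\n",
              x$k_L, x$k_AB, x$N_PQ))
  cat(sprintf("  PSI drain: S_PSI = %.3g eq, k_FNR = %.3g/ms, k_red = %.3g/ms/eq\n",
              x$S_PSI, x$k_FNR, x$k_red))
  cat(sprintf("  F levels %g-%g (antenna loss %.3g), noise %.3g\n",
              x$F_O_level, x$F_M_level, x$antenna_loss, x$noise_sd))
  invisible(x)
}

#' Instrument-like OJIP sampling grid
#'
#' Dense uniform sampling at early times (default 10 µs steps to 300 µs, as
#' in a plant-efficiency analyser) followed by log-spaced samples to the end
#' of the recording.
#'
#' @param dense_step_us,dense_until_us early uniform sampling step and end.
#' @param t_max_us end of the recording (default 2 s).
#' @param n_log number of log-spaced samples after the dense segment.
#' @return numeric vector of times, µs.
#' @export
ojip_time_grid <- function(dense_step_us = 10, dense_until_us = 300,
                           t_max_us = 2e6, n_log = 220) {
  c(
    seq(dense_step_us, dense_until_us, by = dense_step_us),
    exp(seq(log(dense_until_us * 1.04), log(t_max_us), length.out = n_log))
  )
}

#' Simulate an OJIP fluorescence transient
#'
#' Integrates the three-state acceptor-side model of [ojip_scenario()] on
#' the sampling grid and returns a transient tibble ready for the analysis
#' pipeline. Integration is deterministic fixed-step stepping with
#' per-substep exponential (analytic) updates of each state given the
#' momentarily frozen couplings; this is unconditionally stable on the
#' log-spaced grid and converges under substep halving (see `substep_ms`).
#' With a seed the noisy output is bit-reproducible.
#'
#' @param scenario an [ojip_scenario()].
#' @param time_us sampling grid, µs (default [ojip_time_grid()]).
#' @param label,group identifiers for the output tibble.
#' @param seed integer seed for the noise; `NULL` leaves the RNG alone.
#' @param substep_ms target integration substep at late times, ms; the
#'   substep never exceeds this nor the local grid spacing.
#' @return a transient tibble (`label`, `group`, `time_us`, `fluor`).
#' @examples
#' tr <- simulate_ojip(ojip_scenario(B = 0.5), seed = 1)
#' @export
simulate_ojip <- function(scenario = ojip_scenario(), time_us = ojip_time_grid(),
                          label = "sim", group = "sim", seed = NULL,
                          substep_ms = 0.5) {
  if (!inherits(scenario, "ojip_scenario")) {
    abort("`scenario` must be built with ojip_scenario()")
  }
  if (min(time_us) <= 0) abort("sampling grid must start after light onset")
  sc <- scenario
  t_ms <- time_us / 1e3
  # soft widths for pool depletion: a pool behaves linearly below `w`
  w_pq <- 0.25
  closed <- numeric(length(t_ms))
  C <- 0; P <- sc$N_PQ; A <- sc$S_PSI
  t_prev <- 0
  for (i in seq_along(t_ms)) {
    gap <- t_ms[i] - t_prev
    nsub <- max(4L, ceiling(gap / substep_ms))
    dt <- gap / nsub
    for (j in seq_len(nsub)) {
      t0 <- t_prev + (j - 1) * dt
      act <- 1 - exp(-sc$k_FNR * (t0 + dt / 2))
      s_room <- clamp((sc$N_PQ - P) / w_pq, 0, 1) # drain needs reduced PQ
      f2 <- sc$k_red * act * s_room * A           # PQH2 -> PSI flux
      # oxidised-PQ pool: dP/dt = f2 - k_AB C min(P, w)/w, piecewise exact
      # (linear drawdown above the soft width, exponential relaxation below)
      lam <- sc$k_AB * C / w_pq
      p0 <- P
      if (lam < 1e-12) {
        P <- p0 + f2 * dt # no reoxidation flux while every trap is open
      } else if (p0 > w_pq) {
        rate <- f2 - sc$k_AB * C
        if (rate >= 0) {
          P <- p0 + rate * dt
        } else {
          t_cross <- (p0 - w_pq) / (-rate)
          if (t_cross >= dt) {
            P <- p0 + rate * dt
          } else {
            p_inf <- f2 / lam
            P <- p_inf + (w_pq - p_inf) * exp(-lam * (dt - t_cross))
          }
        }
      } else {
        p_inf <- f2 / lam
        P <- p_inf + (p0 - p_inf) * exp(-lam * dt)
      }
      P <- clamp(P, 0, sc$N_PQ)
      # closed fraction with the substep-averaged reoxidation coupling
      s_p <- (clamp(p0 / w_pq, 0, 1) + clamp(P / w_pq, 0, 1)) / 2
      mu <- sc$k_L + sc$k_AB * s_p
      C <- sc$k_L / mu + (C - sc$k_L / mu) * exp(-mu * dt)
      # PSI acceptor pool drains exponentially at the activated rate
      s_room2 <- (s_room + clamp((sc$N_PQ - P) / w_pq, 0, 1)) / 2
      A <- A * exp(-sc$k_red * act * s_room2 * dt)
    }
    cb <- 1 - exp(-sc$k_L * t_ms[i])           # blocked subpopulation, closed form
    closed[i] <- sc$B * cb + (1 - sc$B) * C
    t_prev <- t_ms[i]
  }
  conn <- closed * (1 - sc$p) / (1 - sc$p * closed)
  atten <- 1 - sc$antenna_loss
  f <- atten * (sc$F_O_level + (sc$F_M_level - sc$F_O_level) * conn)
  if (sc$noise_sd > 0) {
    noise <- function() f * (1 + rnorm(length(f), 0, sc$noise_sd))
    f <- if (is.null(seed)) noise() else withr::with_seed(seed, noise())
    f <- pmax(f, 0)
  }
  as_transient(time_us, f, label = label, group = group)
}

#' Simulate a two-phase MR 820 nm trace
#'
#' Parametric modulated-reflection kinetics: a fast oxidation decay anchored
#' at the first reliable measurement time (0.7 ms, so the programmed curve
#' equals 1 there) and a logistic slow re-reduction rise,
#' `MR/MR_0(t) = 1 - fast_amp (1 - e^(-k_fast (t - 0.7)))
#'             + slow_amp / (1 + e^(-k_slow (t - t_onset_slow)))`.
#' `slow_amp = 0` gives the methyl-viologen-like plateau at `1 - fast_amp`;
#' both amplitudes 0 give a constant trace.
#'
#' @param fast_amp,slow_amp relative amplitudes of the two phases (>= 0).
#' @param k_fast,k_slow rate constants, 1/ms (> 0).
#' @param t_onset_slow centre of the slow logistic rise, ms.
#' @param noise_sd relative Gaussian noise standard deviation.
#' @param time_ms sampling grid, ms (default log-spaced 0.7-2000 ms).
#' @param scale instrument-units scale factor applied to the whole trace.
#' @param label,group identifiers.
#' @param seed integer seed for the noise.
#' @return an MR trace tibble (`label`, `group`, `time_ms`, `refl`).
#' @export
simulate_mr <- function(fast_amp = 0.04, k_fast = 0.05, slow_amp = 0.06,
                        k_slow = 0.02, t_onset_slow = 400, noise_sd = 0,
                        time_ms = exp(seq(log(0.7), log(2000), length.out = 400)),
                        scale = 1, label = "sim", group = "sim", seed = NULL) {
  if (fast_amp < 0 || slow_amp < 0) abort("amplitudes must be non-negative")
  if (k_fast <= 0 || k_slow <= 0) abort("rate constants must be positive")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  rel <- 1 - fast_amp * (1 - exp(-k_fast * pmax(time_ms - 0.7, 0))) +
    slow_amp * plogis(k_slow * (time_ms - t_onset_slow))
  y <- scale * rel
  if (noise_sd > 0) {
    noise <- function() y * (1 + rnorm(length(y), 0, noise_sd))
    y <- if (is.null(seed)) noise() else withr::with_seed(seed, noise())
    y <- pmax(y, .Machine$double.eps)
  }
  as_mr_trace(time_ms, y, label = label, group = group)
}

#' Simulate a dose-response series
#'
#' Log-logistic inhibition of a control-level response:
#' `response = control_level / (1 + (dose/i50)^hill_slope)`, with replicate
#' structure and multiplicative Gaussian noise.
#'
#' @param i50 half-inhibitory dose (> 0), µM.
#' @param hill_slope log-logistic slope (> 0).
#' @param doses dose levels, must include 0 (the control).
#' @param replicates replicate measurements per dose.
#' @param control_level uninhibited response level.
#' @param noise_sd relative Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return a tibble: `dose`, `replicate`, `response`.
#' @export
simulate_dose_series <- function(i50 = 60, hill_slope = 1.2,
                                 doses = c(0, 10, 30, 60, 100, 200),
                                 replicates = 5, control_level = 100,
                                 noise_sd = 0, seed = NULL) {
  if (i50 <= 0 || hill_slope <= 0) abort("i50 and hill_slope must be positive")
  if (!0 %in% doses) abort("doses must include 0 (the control)")
  if (any(doses < 0)) abort("doses must be non-negative")
  grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(replicates))
  mean_resp <- control_level / (1 + (grid$dose / i50)^hill_slope)
  draw <- function() mean_resp * (1 + rnorm(nrow(grid), 0, noise_sd))
  resp <- if (noise_sd == 0) {
    mean_resp
  } else if (is.null(seed)) {
    draw()
  } else {
    withr::with_seed(seed, draw())
  }
  dplyr::mutate(grid, response = pmax(resp, 0))
}

#' Simulate a lesion-diameter phytotoxicity table
#'
#' A species-by-concentration grid of synthetic lesion diameters with
#' concentration-dependent severity, guaranteed to cover all three
#' pathogenicity classes and to include the boundary-adjacent diameters
#' 0.99, 1.00, 3.00 and 3.01 mm.
#'
#' @param seed integer seed.
#' @param n_species number of synthetic species.
#' @param concentrations treatment concentrations, µM.
#' @return a tibble: `species`, `concentration_um`, `diameter_mm`, `level`.
#' @export
simulate_lesion_table <- function(seed = 1, n_species = 8,
                                  concentrations = c(100, 500, 1000)) {
  grid <- tidyr::expand_grid(
    species = sprintf("synthetic_sp%02d", seq_len(n_species)),
    concentration_um = concentrations
  )
  draw <- function() {
    sens <- rlnorm(n_species, meanlog = 0, sdlog = 0.6)
    base <- 0.8 * sens[match(grid$species, unique(grid$species))]
    d <- base * (grid$concentration_um / 100)^0.45 *
      exp(rnorm(nrow(grid), 0, 0.15))
    round(pmax(d, 0.05), 2)
  }
  diam <- withr::with_seed(seed, draw())
  out <- dplyr::mutate(grid, diameter_mm = diam)
  boundary <- tibble::tibble(
    species = "synthetic_boundary",
    concentration_um = c(100, 100, 100, 100),
    diameter_mm = c(0.99, 1.00, 3.00, 3.01)
  )
  out <- dplyr::bind_rows(out, boundary)
  dplyr::mutate(out, level = classify_pathogenicity(.data$diameter_mm))
}
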