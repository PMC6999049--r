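# shared fixtures: closed-form transients with known landmark values

# saturating exponential rise F(t) = f_o + df * (1 - exp(-t/tau)) sampled on
# an instrument-like grid (dense early, log-spaced late)
exp_transient <- function(tau_ms, f_o = 500, df = 2000, t_max_ms = 2000,
                          label = "exp", group = "mock") {
  t_us <- ojip_time_grid(t_max_us = t_max_ms * 1e3)
  as_transient(t_us, f_o + df * (1 - exp(-t_us / (tau_ms * 1e3))),
               label = label, group = group)
}

# straight ramp from (0, f_o) to (t_fm, f_m), then flat; the grid contains
# the kink time exactly so trapezoid integration of the line is exact
ramp_transient <- function(f_o = 500, f_m = 2500, t_fm_ms = 100,
                           label = "ramp", group = "mock") {
  t_us <- c(seq(10, 300, by = 10),
            seq(400, t_fm_ms * 1e3, length.out = 200),
            t_fm_ms * 1e3 * c(1.25, 1.5, 2))
  f <- ifelse(t_us <= t_fm_ms * 1e3,
              f_o + (f_m - f_o) * t_us / (t_fm_ms * 1e3), f_m)
  as_transient(t_us, f, label = label, group = group)
}

# random but valid step/area records for identity sweeps
random_step_records <- function(n, seed = 42) {
  withr::with_seed(seed, {
    f_o <- runif(n, 200, 1000)
    f_m <- f_o * runif(n, 2.5, 6)
    v_j <- runif(n, 0.2, 0.9)
    v_i <- v_j + (1 - v_j) * runif(n, 0.1, 0.95)
    v_270 <- v_j * runif(n, 0.2, 0.8)
    f_v <- f_m - f_o
    tibble::tibble(
      label = sprintf("r%04d", seq_len(n)), group = "random",
      F_O = f_o, F_K = f_o + f_v * v_270, F_J = f_o + f_v * v_j,
      F_I = f_o + f_v * v_i, F_M = f_m, F_270 = f_o + f_v * v_270,
      m0_per_ms = 4 * v_270,
      t_FM_ms = runif(n, 100, 800), s_m_ms = runif(n, 5, 80)
    )
  })
}

# long-format W_IP curve table built directly from (time_ms, value) pairs
wip_curve <- function(time_ms, value, label = "wip", group = "mock") {
  tibble::tibble(label = label, group = group, time_us = time_ms * 1e3,
                 curve = "W_IP", value = value)
}

write_temp_tsv <- function(df, name, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, name)
  readr::write_tsv(df, path)
  path
}
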