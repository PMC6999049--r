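# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# interpolate a sampled signal at arbitrary times; `rule` selects linear
# interpolation in time or in log(time) (both exact at sample points)
interp_signal <- function(time, value, t_out, rule = c("linear", "log-time")) {
  rule <- match.arg(rule)
  if (any(t_out < min(time) - 1e-9) || any(t_out > max(time) + 1e-9)) {
    abort(sprintf(
      "interpolation time outside sampled range [%g, %g]",
      min(time), max(time)
    ))
  }
  t_out <- clamp(t_out, min(time), max(time))
  if (rule == "linear") {
    approx(time, value, xout = t_out, ties = "ordered")$y
  } else {
    approx(log(time), value, xout = log(t_out), ties = "ordered")$y
  }
}

# standard error of the mean
se_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

# run `fn` once per sample of a multi-sample trace table, preserving the
# (label, group) identifiers; `fn` receives a single-sample tibble
per_sample <- function(x, fn) {
  x |>
    dplyr::group_by(.data$label, .data$group) |>
    dplyr::group_modify(function(d, key) {
      res <- fn(dplyr::mutate(d, label = key$label, group = key$group,
                              .before = 1))
      res[setdiff(names(res), c("label", "group"))]
    }) |>
    dplyr::ungroup()
}

time_unit_factor <- function(unit, target = c("us", "ms")) {
  target <- match.arg(target)
  to_us <- switch(unit,
    us = 1,
    ms = 1e3,
    s = 1e6,
    abort(sprintf("unknown time unit '%s' (use us, ms or s)", unit))
  )
  if (target == "us") to_us else to_us / 1e3
}
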