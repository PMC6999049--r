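#' Run the full batch analysis over a sample manifest
#'
#' Manifest-driven driver reproducing the standard multi-concentration
#' inhibitor analysis: per-sample JIP records, group comparisons normalised
#' to the control, band difference curves, I-P half-times, MR features and
#' dose-response summaries, with per-sample quality logging and
#' deterministic outputs.
#'
#' The manifest (a data frame, or the path of a TSV) has one row per input
#' file with columns `path`, `type` (one of `"ojip"`, `"mr"`, `"dose"`,
#' `"lesion"`), `label`, `group`, and optionally `time_unit` (default
#' `"ms"`). Samples that fail to read or analyse are logged and skipped; the
#' run fails only when a whole required group is empty. With `out_dir` set,
#' every result table is also written as TSV (numbers at full precision).
#'
#' @param manifest data frame or TSV path as described above.
#' @param control_group name of the control group for the comparisons.
#' @param out_dir optional output directory for the TSV tables.
#' @param abs_cs_proxy,rule,j_sat_tol passed to [jip_parameters()].
#' @param band_windows_us list with `l`, `k`, `j` windows for
#'   [band_summary()].
#' @param mr_fast_window_ms,mr_slow_end_ms passed to [mr_features()].
#' @return an `ojip_run` list: `samples` (per-sample JIP records),
#'   `comparisons` ([compare_groups()]), `relative`
#'   ([relative_to_control()]), `occupancy` ([sample_occupancy()]),
#'   `curves`, `differences`, `bands`, `wip`, `mr`, `dose`, `i50`,
#'   `lesions`, `log` and `config`.
#' @export
run_pipeline <- function(manifest, control_group = "mock", out_dir = NULL,
                         abs_cs_proxy = c("F_O", "F_M"),
                         rule = c("linear", "log-time"), j_sat_tol = 0.05,
                         band_windows_us = list(l = c(100, 300),
                                                k = c(200, 500),
                                                j = c(1000, 3000)),
                         mr_fast_window_ms = c(0.7, 200),
                         mr_slow_end_ms = 2000) {
  abs_cs_proxy <- match.arg(abs_cs_proxy)
  rule <- match.arg(rule)
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("path", "type", "label", "group")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest needs columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"time_unit" %in% names(manifest)) manifest$time_unit <- "ms"
  config <- list(
    control_group = control_group, abs_cs_proxy = abs_cs_proxy, rule = rule,
    j_sat_tol = j_sat_tol, band_windows_us = band_windows_us,
    mr_fast_window_ms = mr_fast_window_ms, mr_slow_end_ms = mr_slow_end_ms
  )
  config$hash <- rlang::hash(config)

  log_rows <- list()
  note <- function(level, item, message) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      level = level, item = item, message = message
    )
  }

  load_rows <- function(type, reader) {
    rows <- manifest[manifest$type == type, ]
    purrr::pmap(rows, function(path, type, label, group, time_unit, ...) {
      tryCatch(
        withCallingHandlers(
          reader(path, label = label, group = group, time_unit = time_unit),
          warning = function(w) {
            note("warning", label, conditionMessage(w))
            invokeRestart("muffleWarning")
          }
        ),
        error = function(e) {
          note("error", label, paste("skipped:", conditionMessage(e)))
          NULL
        }
      )
    }) |>
      purrr::compact()
  }

  # --- fluorescence transients -------------------------------------------
  transients <- load_rows("ojip", read_transient)
  samples <- comparisons <- relative <- occupancy <- NULL
  curves <- differences <- bands <- wip <- NULL
  if (length(transients) > 0) {
    all_tr <- dplyr::bind_rows(transients)
    samples <- purrr::map(transients, function(tr) {
      tryCatch(
        withCallingHandlers(
          jip_parameters(tr, abs_cs_proxy = abs_cs_proxy, rule = rule,
                         j_sat_tol = j_sat_tol),
          warning = function(w) {
            note("warning", tr$label[1], conditionMessage(w))
            invokeRestart("muffleWarning")
          }
        ),
        error = function(e) {
          note("error", tr$label[1], paste("skipped:", conditionMessage(e)))
          NULL
        }
      )
    }) |>
      purrr::compact() |>
      dplyr::bind_rows()
    if (nrow(samples) == 0) abort("every fluorescence sample failed analysis")
    sources <- manifest[manifest$type == "ojip", c("label", "group", "path")]
    samples <- dplyr::left_join(samples, sources, by = c("label", "group"))
    samples$config_hash <- config$hash

    keep <- dplyr::semi_join(all_tr, samples, by = c("label", "group"))
    curves <- normalize_curves(keep, rule = rule)
    wip <- wip_half_time(curves)
    groups <- unique(samples$group)
    if (!control_group %in% groups) {
      abort(sprintf("control group '%s' has no analysable samples", control_group))
    }
    treated_groups <- setdiff(groups, control_group)
    if (length(treated_groups) == 0) {
      warn("manifest contains only the control group; no comparisons computed")
    } else {
      comparisons <- compare_groups(samples, control = control_group)
      relative <- relative_to_control(samples, control = control_group)
      occupancy <- sample_occupancy(samples, control = control_group)
      ctrl_curves <- dplyr::filter(curves, .data$group == control_group)
      differences <- purrr::map_dfr(treated_groups, function(g) {
        d <- difference_kinetics(
          dplyr::filter(curves, .data$group == g), ctrl_curves
        )
        dplyr::mutate(d, group = g, .before = 1)
      })
      bands <- differences |>
        dplyr::group_by(.data$group) |>
        dplyr::group_modify(function(d, key) {
          band_summary(d, l_window_us = band_windows_us$l,
                       k_window_us = band_windows_us$k,
                       j_window_us = band_windows_us$j)
        }) |>
        dplyr::ungroup()
    }
  }

  # --- MR traces ----------------------------------------------------------
  mr_traces <- load_rows("mr", read_mr_trace)
  mr <- NULL
  if (length(mr_traces) > 0) {
    mr <- purrr::map(mr_traces, function(tr) {
      tryCatch(
        mr_features(tr, fast_window_ms = mr_fast_window_ms,
                    slow_end_ms = mr_slow_end_ms),
        error = function(e) {
          note("error", tr$label[1], paste("skipped:", conditionMessage(e)))
          NULL
        }
      )
    }) |>
      purrr::compact() |>
      dplyr::bind_rows()
  }

  # --- dose-response ------------------------------------------------------
  dose <- i50 <- NULL
  dose_rows <- manifest[manifest$type == "dose", ]
  if (nrow(dose_rows) > 0) {
    per_series <- purrr::pmap(dose_rows, function(path, type, label, group, ...) {
      tryCatch({
        ser <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
        fit <- fit_i50(ser)
        list(
          summary = dplyr::mutate(percent_inhibition(ser), label = label,
                                  group = group, .before = 1),
          fit = dplyr::mutate(glance(fit), label = label, group = group,
                              .before = 1)
        )
      }, error = function(e) {
        note("error", label, paste("skipped:", conditionMessage(e)))
        NULL
      })
    }) |>
      purrr::compact()
    if (length(per_series) > 0) {
      dose <- dplyr::bind_rows(purrr::map(per_series, "summary"))
      i50 <- dplyr::bind_rows(purrr::map(per_series, "fit"))
    }
  }

  # --- lesion tables ------------------------------------------------------
  lesions <- NULL
  lesion_rows <- manifest[manifest$type == "lesion", ]
  if (nrow(lesion_rows) > 0) {
    lesions <- purrr::pmap(lesion_rows, function(path, type, label, group, ...) {
      tryCatch(
        dplyr::mutate(read_lesion_table(path), source = label, .before = 1),
        error = function(e) {
          note("error", label, paste("skipped:", conditionMessage(e)))
          NULL
        }
      )
    }) |>
      purrr::compact() |>
      dplyr::bind_rows()
  }

  log_tbl <- if (length(log_rows) > 0) {
    dplyr::bind_rows(log_rows)
  } else {
    tibble::tibble(level = character(), item = character(), message = character())
  }
  run <- structure(
    list(
      samples = samples, comparisons = comparisons, relative = relative,
      occupancy = occupancy, curves = curves, differences = differences,
      bands = bands, wip = wip, mr = mr, dose = dose, i50 = i50,
      lesions = lesions, log = log_tbl, config = config
    ),
    class = "ojip_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    samples = run$samples, comparisons = run$comparisons,
    relative = run$relative, occupancy = run$occupancy, curves = run$curves,
    differences = run$differences, band_summary = run$bands, wip = run$wip,
    mr_features = run$mr, dose_summary = run$dose, i50 = run$i50,
    lesions = run$lesions, log = run$log
  )
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]]) && nrow(tables[[nm]]) > 0) {
      readr::write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  invisible(out_dir)
}

#' @export
print.ojip_run <- function(x, ...) {
  n <- function(t) if (is.null(t)) 0 else nrow(t)
  cat("OJIP pipeline run\n")
  cat(sprintf("  fluorescence samples: %d (groups: %s)\n", n(x$samples),
              if (n(x$samples)) paste(unique(x$samples$group), collapse = ", ")
              else "-"))
  cat(sprintf("  comparisons: %d   MR samples: %d   dose series: %d   lesions: %d\n",
              n(x$comparisons), n(x$mr), n(x$i50), n(x$lesions)))
  cat(sprintf("  log entries: %d   config hash: %s\n", n(x$log), x$config$hash))
  invisible(x)
}

#' Pairwise linear correlations across a concentration series
#'
#' For group-level summaries spanning several inhibitor concentrations this
#' reports the linear fit (slope, intercept) and Pearson correlation of the
#' standard diagnostic pairs: V_J, PI_ABS and S_m/t_FM against the
#' electron-transport quantum yield phi_Eo, and S_m/t_FM against the
#' occupancy R_J (a strongly negative correlation indicates that
#' reaction-center closure tracks Q_B-site occupancy).
#'
#' @param df a data frame with one row per concentration level carrying the
#'   variables being correlated (e.g. group means joined with
#'   [compare_groups()] output).
#' @param pairs two-column character matrix (x, y variable names); defaults
#'   to the four diagnostic pairs, restricted to available columns.
#' @return a tibble: `x`, `y`, `slope`, `intercept`, `pearson_r`, `n`,
#'   `note` (`"ok"` or `"zero_variance"`).
#' @export
correlation_report <- function(df, pairs = NULL) {
  default_pairs <- rbind(
    c("phi_eo", "v_j"),
    c("phi_eo", "pi_abs"),
    c("phi_eo", "sm_over_tfm"),
    c("r_j", "sm_over_tfm")
  )
  if (is.null(pairs)) {
    pairs <- default_pairs[default_pairs[, 1] %in% names(df) &
                             default_pairs[, 2] %in% names(df), , drop = FALSE]
  }
  if (nrow(df) < 3) abort("need at least 3 concentration levels")
  if (nrow(pairs) == 0) abort("no requested variable pair is present in `df`")
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    xv <- df[[pairs[i, 1]]]
    yv <- df[[pairs[i, 2]]]
    ok <- is.finite(xv) & is.finite(yv)
    xv <- xv[ok]; yv <- yv[ok]
    if (length(xv) < 3 || sd(xv) == 0 || sd(yv) == 0) {
      return(tibble::tibble(
        x = pairs[i, 1], y = pairs[i, 2], slope = NA_real_,
        intercept = NA_real_, pearson_r = NA_real_, n = length(xv),
        note = "zero_variance"
      ))
    }
    fit <- lm(yv ~ xv)
    tibble::tibble(
      x = pairs[i, 1], y = pairs[i, 2],
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      pearson_r = cor(xv, yv), n = length(xv), note = "ok"
    )
  })
}
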