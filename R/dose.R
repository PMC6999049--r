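#' Percent inhibition per dose
#'
#' Aggregates replicate responses per dose (arithmetic mean with standard
#' error) and expresses each dose as percent inhibition of the control
#' (dose 0): `100 (1 - mean(dose)/mean(control))`.
#'
#' @param series a long dose-response tibble with columns `dose` and
#'   `response` (see [simulate_dose_series()] for the layout).
#' @return a tibble: `dose`, `n`, `mean_response`, `se_response`,
#'   `inhibition_pct`, `se_pct`.
#' @export
percent_inhibition <- function(series) {
  check_dose_series(series)
  agg <- series |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_response = mean(.data$response),
      se_response = se_mean(.data$response),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$dose)
  ctrl <- agg$mean_response[agg$dose == 0]
  if (ctrl <= 0) abort("control mean response must be positive")
  dplyr::mutate(
    agg,
    inhibition_pct = 100 * (1 - .data$mean_response / ctrl),
    se_pct = 100 * .data$se_response / ctrl
  )
}

check_dose_series <- function(series) {
  if (!all(c("dose", "response") %in% names(series))) {
    abort("a dose series needs 'dose' and 'response' columns")
  }
  if (any(series$dose < 0)) abort("doses must be non-negative")
  if (!0 %in% series$dose) abort("the series must include the dose-0 control")
  invisible(TRUE)
}

#' Estimate the half-inhibitory concentration I50
#'
#' Fits a two-parameter log-logistic model
#' `response = top / (1 + (dose/I50)^h)` by least squares
#' (Levenberg-Marquardt), with the upper asymptote `top` fixed at the
#' control mean and the lower at zero; `I50` is then the dose producing half
#' the control response. A model-free linear-interpolation estimate of the
#' 50%-inhibition crossing on the dose axis is always computed alongside as
#' a cross-check and as the fallback when the fit cannot be performed.
#'
#' When no dose reaches 50% inhibition (or responses increase with dose) the
#' estimate is flagged: `flag` is `"ok"`, `"no_crossing"` (fit performed but
#' not bracketed by the data) or `"no_inhibition"` (`NA` estimate).
#'
#' @param series a long dose-response tibble (`dose`, `response`).
#' @return an object of class `i50_fit`: access the estimate with
#'   `$i50`, the interpolation cross-check with `$i50_interp`, and use
#'   [generics::tidy()], [generics::glance()], [ggplot2::autoplot()] or
#'   `print()` on it.
#' @examples
#' fit <- fit_i50(simulate_dose_series(i50 = 60, noise_sd = 0.05, seed = 7))
#' glance(fit)
#' @export
fit_i50 <- function(series) {
  check_dose_series(series)
  summ <- percent_inhibition(series)
  top <- summ$mean_response[summ$dose == 0]
  nonzero <- summ[summ$dose > 0, ]

  # model-free estimate: first crossing of 50% inhibition, linear in dose
  interp <- i50_interpolate(summ)

  increasing <- nrow(nonzero) >= 2 &&
    all(diff(nonzero$mean_response) >= 0) &&
    max(summ$inhibition_pct) < 25
  flag <- if (increasing) {
    "no_inhibition"
  } else if (is.na(interp)) {
    "no_crossing"
  } else {
    "ok"
  }

  fit <- NULL
  i50 <- NA_real_
  slope <- NA_real_
  if (flag != "no_inhibition" && nrow(nonzero) >= 2) {
    start_i50 <- if (is.na(interp)) stats::median(nonzero$dose) else interp
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ top / (1 + (dose / i50)^h),
        data = series[series$dose > 0, ],
        start = list(i50 = start_i50, h = 1),
        lower = c(i50 = 1e-9, h = 0.05),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      i50 <- unname(coef(fit)[["i50"]])
      slope <- unname(coef(fit)[["h"]])
    } else if (!is.na(interp)) {
      i50 <- interp
    }
  }
  structure(
    list(
      i50 = i50, hill_slope = slope, top = top,
      i50_interp = interp, flag = flag, fit = fit,
      objective = if (!is.null(fit)) sum(stats::residuals(fit)^2) else NA_real_,
      summary = summ, data = tibble::as_tibble(series)
    ),
    class = "i50_fit"
  )
}

i50_interpolate <- function(summ) {
  s <- summ[order(summ$dose), ]
  above <- which(s$inhibition_pct >= 50)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(s$dose[1])
  x0 <- s$dose[i - 1]; x1 <- s$dose[i]
  y0 <- s$inhibition_pct[i - 1]; y1 <- s$inhibition_pct[i]
  x0 + (50 - y0) / (y1 - y0) * (x1 - x0)
}

#' @export
print.i50_fit <- function(x, ...) {
  cat("Log-logistic dose-response fit (upper asymptote fixed at control mean)\n")
  cat(sprintf("  I50       : %s\n",
              if (is.na(x$i50)) "not estimable" else sprintf("%.4g", x$i50)))
  cat(sprintf("  hill slope: %s\n",
              if (is.na(x$hill_slope)) "-" else sprintf("%.4g", x$hill_slope)))
  cat(sprintf("  top       : %.4g   interpolated I50: %s   flag: %s\n",
              x$top,
              if (is.na(x$i50_interp)) "-" else sprintf("%.4g", x$i50_interp),
              x$flag))
  invisible(x)
}

#' @rdname fit_i50
#' @param x an `i50_fit` object.
#' @param ... unused.
#' @method tidy i50_fit
#' @export
tidy.i50_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(
      term = c("i50", "h"), estimate = c(x$i50, x$hill_slope),
      std.error = NA_real_
    ))
  }
  sf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sf),
    estimate = sf[, "Estimate"],
    std.error = sf[, "Std. Error"]
  )
}

#' @rdname fit_i50
#' @method glance i50_fit
#' @export
glance.i50_fit <- function(x, ...) {
  tibble::tibble(
    i50 = x$i50, hill_slope = x$hill_slope, top = x$top,
    i50_interp = x$i50_interp, rss = x$objective,
    n = nrow(x$data), flag = x$flag
  )
}

#' Classify lesion diameters into pathogenicity levels
#'
#' Three-level scheme for necrotic/chlorotic leaf lesions:
#' `+` (low) for diameters under 1 mm, `++` (moderate) from 1 to 3 mm
#' inclusive, `+++` (high) above 3 mm.
#'
#' @param diameter_mm lesion diameter(s), mm; must be positive (`NA` passes
#'   through).
#' @return character vector of `"+"`, `"++"`, `"+++"`.
#' @examples
#' classify_pathogenicity(c(0.61, 2.24, 3.06, 3.88))
#' @export
classify_pathogenicity <- function(diameter_mm) {
  if (any(diameter_mm <= 0, na.rm = TRUE)) {
    abort("lesion diameters must be positive")
  }
  dplyr::case_when(
    is.na(diameter_mm) ~ NA_character_,
    diameter_mm < 1 ~ "+",
    diameter_mm <= 3 ~ "++",
    TRUE ~ "+++"
  )
}

#' Read a lesion-diameter table
#'
#' Tab-separated table with at least `species`, `concentration_um` and
#' `diameter_mm` columns (optional `family`, `se_mm`, `level`).
#'
#' @param path file path.
#' @return a tibble; when a printed `level` column is present it is kept as
#'   `level`, and the classifier's call is always added as `level_computed`.
#' @export
read_lesion_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("species", "concentration_um", "diameter_mm")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("lesion table needs columns: ", paste(missing_cols, collapse = ", ")))
  }
  dplyr::mutate(x, level_computed = classify_pathogenicity(.data$diameter_mm))
}

#' Published gliotoxin phytotoxicity survey
#'
#' The bundled lesion-diameter table for gliotoxin applied at 100, 500 and
#' 1000 µM to detached leaves of ten monocotyledonous and dicotyledonous
#' species (mean of >= 15 leaves +/- SE, lesions scored at 96 h), with the
#' published pathogenicity level for each row.
#'
#' @return a tibble: `family`, `species`, `concentration_um`, `diameter_mm`,
#'   `se_mm`, `level`, `level_computed`.
#' @examples
#' lesions <- gliotoxin_lesions()
#' all(lesions$level == lesions$level_computed)
#' @export
gliotoxin_lesions <- function() {
  read_lesion_table(
    system.file("extdata", "gliotoxin_lesion_diameters.tsv",
                package = "ojipr", mustWork = TRUE)
  )
}
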