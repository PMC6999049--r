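#' Build a validated fluorescence transient
#'
#' A transient is a tidy record of one (or several, row-bound) fast
#' chlorophyll-a fluorescence induction measurements: elapsed time since the
#' onset of actinic illumination and the fluorescence signal, plus sample
#' (`label`) and treatment (`group`) identifiers. All downstream landmark
#' times (20 µs, 150 µs, 300 µs, 270 µs, 2 ms, 30 ms) are absolute from
#' light onset.
#'
#' Validation enforces: strictly increasing time, first sample at or before
#' 50 µs (so the 20 µs origin point is bracketed or is the first sample),
#' at least 10 points, and finite non-negative fluorescence.
#'
#' @param time_us elapsed time since light onset, microseconds.
#' @param fluor fluorescence intensity, instrument units.
#' @param label sample identifier.
#' @param group treatment identifier (e.g. `"mock"`, `"GT_100uM"`).
#' @return a tibble with columns `time_us`, `fluor`, `label`, `group`.
#' @examples
#' tr <- as_transient(c(10, 20, 50, 100, 200, 300, 500, 1000, 2000, 5000),
#'                    c(500, 510, 560, 640, 780, 900, 1100, 1400, 1700, 2100))
#' @export
as_transient <- function(time_us, fluor, label = "sample", group = "mock") {
  time_us <- as.numeric(time_us)
  fluor <- as.numeric(fluor)
  if (length(time_us) != length(fluor)) {
    abort("time and fluorescence must have the same length")
  }
  if (length(time_us) < 10) {
    abort(sprintf("a transient needs at least 10 points, got %d", length(time_us)))
  }
  bad <- which(diff(time_us) <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "time must be strictly increasing; first violation at row %d (t = %g us)",
      bad[1] + 1L, time_us[bad[1] + 1L]
    ))
  }
  if (time_us[1] > 50) {
    abort(sprintf(
      "first sample at %g us; the trace must start at or before 50 us", time_us[1]
    ))
  }
  if (any(!is.finite(fluor)) || any(fluor < 0)) {
    abort("fluorescence values must be finite and non-negative")
  }
  tibble::tibble(
    label = as.character(label), group = as.character(group),
    time_us = time_us, fluor = fluor
  )
}

#' Build a validated modulated 820 nm reflection trace
#'
#' @param time_ms elapsed time since actinic onset, milliseconds. The first
#'   sample must be at or before 0.7 ms, the first reliable MR measurement.
#' @param refl modulated reflection signal, instrument units (positive).
#' @inheritParams as_transient
#' @return a tibble with columns `time_ms`, `refl`, `label`, `group`.
#' @export
as_mr_trace <- function(time_ms, refl, label = "sample", group = "mock") {
  time_ms <- as.numeric(time_ms)
  refl <- as.numeric(refl)
  if (length(time_ms) != length(refl)) {
    abort("time and reflection must have the same length")
  }
  bad <- which(diff(time_ms) <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "time must be strictly increasing; first violation at row %d (t = %g ms)",
      bad[1] + 1L, time_ms[bad[1] + 1L]
    ))
  }
  if (time_ms[1] > 0.7) {
    abort(sprintf(
      "first sample at %g ms; the MR trace must start at or before 0.7 ms",
      time_ms[1]
    ))
  }
  if (any(!is.finite(refl)) || any(refl <= 0)) {
    abort("MR values must be finite and positive")
  }
  tibble::tibble(
    label = as.character(label), group = as.character(group),
    time_ms = time_ms, refl = refl
  )
}

# shared two-column delimited reader: returns a numeric matrix-like tibble,
# dropping rows with non-numeric fields (warning) and reporting the dialect
read_two_columns <- function(path, delim = NULL, col_time = 1, col_signal = 2) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty file: %s", path))
  if (is.null(delim)) {
    first <- lines[[1]]
    delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  }
  raw <- utils::read.table(
    text = lines, sep = delim, header = FALSE,
    colClasses = "character", fill = TRUE, strip.white = TRUE,
    comment.char = "#", quote = "\""
  )
  if (ncol(raw) < max(col_time, col_signal)) {
    abort(sprintf(
      "%s: need %d columns, found %d", path, max(col_time, col_signal), ncol(raw)
    ))
  }
  tv <- suppressWarnings(as.numeric(raw[[col_time]]))
  sv <- suppressWarnings(as.numeric(raw[[col_signal]]))
  # a leading header row shows up as non-numeric in both columns
  start <- 1L
  if (is.na(tv[1]) && is.na(sv[1])) start <- 2L
  tv <- tv[seq(start, length(tv))]
  sv <- sv[seq(start, length(sv))]
  keep <- is.finite(tv) & is.finite(sv)
  dropped <- sum(!keep)
  if (dropped > 0) {
    warn(sprintf("%s: %d rows dropped (non-numeric fields)", basename(path), dropped))
  }
  list(time = tv[keep], signal = sv[keep])
}

#' Read a fluorescence transient from a delimited text file
#'
#' Accepts two-column comma-, tab- or whitespace-delimited text with an
#' optional header row. Rows with non-numeric fields are dropped with a
#' warning giving the count; duplicated or decreasing time stamps are a hard
#' error naming the first offending row.
#'
#' @param path file path.
#' @param time_unit unit of the time column: `"ms"` (default for
#'   continuous-excitation fluorometer exports), `"us"` or `"s"`.
#' @param delim field delimiter; `NULL` guesses tab, comma or whitespace.
#' @param col_time,col_signal column indices of time and fluorescence.
#' @inheritParams as_transient
#' @return a validated transient tibble (time converted to µs).
#' @seealso [as_transient()], [write_transient()]
#' @export
read_transient <- function(path, time_unit = "ms", delim = NULL,
                           col_time = 1, col_signal = 2,
                           label = NULL, group = "mock") {
  cols <- read_two_columns(path, delim, col_time, col_signal)
  if (length(cols$time) < 10) {
    abort(sprintf("%s: fewer than 10 valid rows (%d)", path, length(cols$time)))
  }
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  as_transient(
    cols$time * time_unit_factor(time_unit, "us"), cols$signal,
    label = label, group = group
  )
}

#' Read a modulated 820 nm reflection trace from a delimited text file
#'
#' @inheritParams read_transient
#' @param time_unit unit of the time column, default `"ms"`.
#' @return a validated MR trace tibble (time in ms).
#' @export
read_mr_trace <- function(path, time_unit = "ms", delim = NULL,
                          col_time = 1, col_signal = 2,
                          label = NULL, group = "mock") {
  cols <- read_two_columns(path, delim, col_time, col_signal)
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  as_mr_trace(
    cols$time * time_unit_factor(time_unit, "ms"), cols$signal,
    label = label, group = group
  )
}

#' Write a transient (or MR trace) back to delimited text
#'
#' Values are written at full double precision so that a read/write/read
#' cycle round-trips numerically.
#'
#' @param x a transient or MR trace tibble.
#' @param path output file path.
#' @param time_unit unit for the written time column.
#' @param delim field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_transient <- function(x, path, time_unit = "us", delim = "\t") {
  if ("time_us" %in% names(x)) {
    tm <- x$time_us / time_unit_factor(time_unit, "us")
    sig <- x$fluor
  } else {
    tm <- x$time_ms / time_unit_factor(time_unit, "ms")
    sig <- x$refl
  }
  # %.17g guarantees bit-exact numeric round-trips through text
  out <- tibble::tibble(time = sprintf("%.17g", tm),
                        signal = sprintf("%.17g", sig))
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Interpolate a transient at given times
#'
#' Returns the fluorescence value at arbitrary times inside the sampled
#' range: exact at sample points, piecewise linear between them. Linear
#' interpolation in time is the default (instrument sampling is dense at
#' early times); linear-in-log-time is available via `rule`.
#'
#' @param x a single-sample transient tibble.
#' @param t_us time(s) since onset, µs; must lie inside the sampled range.
#' @param rule `"linear"` (in time, default) or `"log-time"`.
#' @return numeric vector of interpolated fluorescence values.
#' @examples
#' tr <- as_transient(c(10, 30, 60, 100, 200, 400, 800, 1500, 3000, 6000),
#'                    c(100, 300, 420, 500, 640, 800, 980, 1200, 1500, 1800))
#' fluor_at(tr, 20)  # midpoint of the first bracket
#' @export
fluor_at <- function(x, t_us, rule = c("linear", "log-time")) {
  stopifnot(is.data.frame(x), "time_us" %in% names(x))
  if ("label" %in% names(x) && dplyr::n_distinct(x$label, x$group) > 1) {
    abort("fluor_at() expects a single sample; filter to one label first")
  }
  interp_signal(x$time_us, x$fluor, t_us, rule = match.arg(rule))
}
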