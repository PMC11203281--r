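SERIES_KINDS <- c("optical_density", "transmittance_pct", "heat_flow",
                  "integrated_enthalpy", "ratio")

#' Create a temperature series
#'
#' The basic data container of the package: an ordered set of (temperature,
#' value) measurements with a declared kind.  Temperatures must be strictly
#' increasing after sorting (duplicate temperatures are an error, not
#' averaged: silent averaging would hide instrument-export problems).  The
#' analysis is shift-invariant in temperature, so the unit is recorded as a
#' label only and never converted.
#'
#' @param temperature numeric vector of temperatures; sorted ascending on
#'   construction.
#' @param value numeric vector of measured values, same length as
#'   `temperature`.
#' @param kind one of `"optical_density"`, `"transmittance_pct"`,
#'   `"heat_flow"`, `"integrated_enthalpy"`, `"ratio"`.
#' @param unit temperature unit label (default `"C"`); informational only.
#' @param label free-text label recorded in derived objects.
#' @param Tm lower reference temperature for integration; defaults to the
#'   first (lowest) temperature.
#' @return An object of class `temperature_series` with fields `temperature`,
#'   `value`, `kind`, `unit`, `label`, `Tm`.
#' @examples
#' s <- temperature_series(c(20, 25, 30), c(0.1, 0.5, 0.9), "optical_density")
#' s
#' @export
temperature_series <- function(temperature, value, kind, unit = "C",
                               label = "", Tm = NULL) {
  kind <- match.arg(kind, SERIES_KINDS)
  if (!is.numeric(temperature) || !is.numeric(value))
    stopf("temperature and value must be numeric")
  if (length(temperature) != length(value))
    stopf("temperature and value differ in length (%d vs %d)",
          length(temperature), length(value))
  if (length(temperature) < 3)
    stopf("a temperature series needs at least 3 points, got %d",
          length(temperature))
  if (!all(is.finite(temperature)) || !all(is.finite(value)))
    stopf("all temperatures and values must be finite")
  ord <- order(temperature)
  temperature <- temperature[ord]
  value <- value[ord]
  dup <- which(diff(temperature) == 0)
  if (length(dup))
    stopf("duplicate temperature value: %g", temperature[dup[1]])
  if (kind == "transmittance_pct") {
    over <- max(0, max(value) - 100, -min(value))
    if (over > 1e-9 * 100)
      warning("transmittance values outside [0, 100] by ", signif(over, 3))
  }
  Tm <- Tm %||% temperature[1]
  if (Tm < temperature[1] || Tm > temperature[length(temperature)])
    stopf("Tm = %g lies outside the temperature range [%g, %g]",
          Tm, temperature[1], temperature[length(temperature)])
  structure(list(temperature = temperature, value = value, kind = kind,
                 unit = unit, label = label, Tm = Tm),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("<temperature_series> %s, %d points, T in [%g, %g] %s\n",
              x$kind, length(x$temperature), x$temperature[1],
              x$temperature[length(x$temperature)], x$unit))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  cat(sprintf("  value range [%g, %g]\n", min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.temperature_series <- function(x, ...) {
  data.frame(temperature = x$temperature, value = x$value)
}

#' @export
length.temperature_series <- function(x) length(x$temperature)

#' Read a temperature series from CSV
#'
#' Expects the package CSV dialect: a header line `temperature,value`, comma
#' separator, dot decimal, UTF-8, with optional `#`-prefixed comment lines.
#' Rows may appear in any order; they are sorted ascending by temperature.
#'
#' @param path path to a CSV file.
#' @param kind series kind, see [temperature_series()].
#' @param unit temperature unit label.
#' @return A [temperature_series()].
#' @export
read_temperature_series <- function(path, kind, unit = "C") {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  df <- read.csv(path, comment.char = "#", strip.white = TRUE,
                 colClasses = "character")
  if (!all(c("temperature", "value") %in% names(df)))
    stopf("%s: expected header 'temperature,value', got '%s'",
          path, paste(names(df), collapse = ","))
  if (nrow(df) < 3)
    stopf("%s: at least 3 data rows required, got %d", path, nrow(df))
  suppressWarnings({
    temp <- as.numeric(df$temperature)
    val <- as.numeric(df$value)
  })
  bad <- which(is.na(temp) | is.na(val))
  if (length(bad))
    stopf("%s: non-numeric cell in data row %d", path, bad[1])
  temperature_series(temp, val, kind = kind, unit = unit,
                     label = basename(path))
}

#' Write a temperature series to CSV
#'
#' Emits the same dialect [read_temperature_series()] reads; the series kind
#' and unit are recorded in `#` comment lines.
#'
#' @param s a [temperature_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_temperature_series <- function(s, path) {
  stopifnot(inherits(s, "temperature_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", s$kind), con)
  writeLines(sprintf("# unit: %s", s$unit), con)
  writeLines("temperature,value", con)
  writeLines(sprintf("%.15g,%.15g", s$temperature, s$value), con)
  invisible(path)
}

#' Smooth a temperature series
#'
#' Optional pre-smoothing for noisy instrument curves, mainly useful before
#' numerical differentiation (which amplifies noise).  The temperature grid
#' and series kind are preserved.
#'
#' @param s a [temperature_series()].
#' @param method `"none"`, `"moving_average"` (centered, window shrinks
#'   symmetrically at the edges) or `"savitzky_golay"`
#'   (via [signal::sgolayfilt()]).
#' @param window odd window length, `<= length(s)`.
#' @param order polynomial order for Savitzky--Golay, `< window`.
#' @return A smoothed [temperature_series()] on the same grid.
#' @export
smooth_series <- function(s, method = c("none", "moving_average",
                                        "savitzky_golay"),
                          window = 5, order = 2) {
  stopifnot(inherits(s, "temperature_series"))
  method <- match.arg(method)
  if (method == "none") return(s)
  n <- length(s$temperature)
  if (window %% 2 == 0) stopf("smoothing window must be odd, got %d", window)
  if (window > n)
    stopf("smoothing window %d exceeds series length %d", window, n)
  y <- s$value
  if (window == 1) {
    ys <- y
  } else if (method == "moving_average") {
    k <- (window - 1) / 2
    ys <- vapply(seq_len(n), function(i) {
      kk <- min(k, i - 1, n - i)
      mean(y[(i - kk):(i + kk)])
    }, numeric(1))
  } else {
    if (order >= window)
      stopf("savitzky_golay order (%d) must be < window (%d)", order, window)
    ys <- as.numeric(signal::sgolayfilt(y, p = order, n = window))
  }
  out <- s
  out$value <- ys
  out$label <- sprintf("%s [%s w=%d]", s$label, method, window)
  out
}
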