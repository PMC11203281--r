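#' Convert an optical-density curve to percent transmittance
#'
#' Applies the normalization Tt(T) = (1 - (D - baseline)/D0) * 100, mapping
#' the observed turbidity amplitude onto a 0--100 percent transmittance
#' scale.  With the defaults (baseline = min(D), D0 = max(D) - min(D)) the
#' result spans the full \[0, 100\] range, which makes turbidimetric curves
#' directly comparable with normalized calorimetric integrals from
#' [to_normalized_integral()].
#'
#' @param d a [temperature_series()] of kind `"optical_density"`.
#' @param D0 observed amplitude of optical-density changes; default
#'   `max(value) - baseline`.  Must be positive.
#' @param baseline optical-density baseline subtracted before scaling;
#'   default `min(value)`.
#' @return A `temperature_series` of kind `"transmittance_pct"`.  Values are
#'   clipped to \[0, 100\] only when the overshoot is within numerical noise
#'   (1e-9 of the scale); larger overshoots are kept as-is and flagged via
#'   attribute `"range_warning"`.
#' @export
to_transmittance <- function(d, D0 = NULL, baseline = NULL) {
  stopifnot(inherits(d, "temperature_series"))
  if (d$kind != "optical_density")
    stopf("to_transmittance() expects an optical_density series, got %s",
          d$kind)
  baseline <- baseline %||% min(d$value)
  D0 <- D0 %||% (max(d$value) - baseline)
  if (D0 <= 0)
    stopf("amplitude D0 must be positive (got %g); constant series have no transition amplitude", D0)
  tt <- (1 - (d$value - baseline) / D0) * 100
  tol <- 1e-9 * 100
  over <- max(0, max(tt) - 100, -min(tt))
  warn <- FALSE
  if (over <= tol) {
    tt <- pmin(pmax(tt, 0), 100)
  } else if (over > tol) {
    warn <- TRUE
  }
  out <- suppressWarnings(
    temperature_series(d$temperature, tt, "transmittance_pct", unit = d$unit,
                       label = sprintf("Tt(%s)", d$label), Tm = d$Tm))
  attr(out, "range_warning") <- warn
  out
}

#' Cumulative integral of a heat-flow curve
#'
#' Computes S(T) = integral of Cp from the reference temperature `Tm` to T,
#' the integrated enthalpy underlying the inverse phase portrait.  The
#' trapezoid rule (default, O(h^2) accurate, exact for linear integrands) or
#' the left-endpoint rectangle rule may be used.
#'
#' @param cp a [temperature_series()] of kind `"heat_flow"`.
#' @param Tm lower integration limit; must lie inside the temperature range.
#'   Defaults to the series' `Tm` (normally the first temperature).
#' @param method `"trapezoid"` or `"rectangle"`.
#' @return A `temperature_series` of kind `"integrated_enthalpy"` on the same
#'   grid, with S(Tm) = 0.  If Cp >= 0 everywhere, S is non-decreasing.
#' @export
cumulative_integral <- function(cp, Tm = NULL,
                                method = c("trapezoid", "rectangle")) {
  stopifnot(inherits(cp, "temperature_series"))
  if (cp$kind != "heat_flow")
    stopf("cumulative_integral() expects a heat_flow series, got %s", cp$kind)
  method <- match.arg(method)
  Tv <- cp$temperature
  y <- cp$value
  n <- length(Tv)
  Tm <- Tm %||% cp$Tm
  if (Tm < Tv[1] || Tm > Tv[n])
    stopf("Tm = %g outside the temperature range [%g, %g]", Tm, Tv[1], Tv[n])
  C <- if (method == "trapezoid") {
    as.numeric(pracma::cumtrapz(Tv, y))
  } else {
    c(0, cumsum(y[-n] * diff(Tv)))
  }
  # integral from T[1] to Tm, subtracted so S(Tm) = 0 even off-grid
  i <- findInterval(Tm, Tv, rightmost.closed = TRUE)
  offset <- if (method == "trapezoid") {
    yTm <- y[i] + (y[min(i + 1, n)] - y[i]) *
      if (i < n) (Tm - Tv[i]) / (Tv[i + 1] - Tv[i]) else 0
    C[i] + 0.5 * (y[i] + yTm) * (Tm - Tv[i])
  } else {
    C[i] + y[i] * (Tm - Tv[i])
  }
  temperature_series(Tv, C - offset, "integrated_enthalpy", unit = cp$unit,
                     label = sprintf("S(%s)", cp$label), Tm = Tm)
}

#' Normalize an integrated-enthalpy curve onto the transmittance scale
#'
#' Applies st(T) = (1 - S/S0) * 100, the calorimetric analogue of
#' [to_transmittance()], so that a normalized DSC integral can be overlaid
#' directly on a turbidimetric transmittance curve.
#'
#' @param s a [temperature_series()] of kind `"integrated_enthalpy"`.
#' @param S0 total enthalpy amplitude; default `S(T_last) - S(T_first)`.
#'   Must be positive.
#' @return A `temperature_series` of kind `"transmittance_pct"`; 100 percent
#'   where S = 0 and 0 percent where S = S0.
#' @export
to_normalized_integral <- function(s, S0 = NULL) {
  stopifnot(inherits(s, "temperature_series"))
  if (s$kind != "integrated_enthalpy")
    stopf("to_normalized_integral() expects an integrated_enthalpy series, got %s",
          s$kind)
  n <- length(s$temperature)
  S0 <- S0 %||% (s$value[n] - s$value[1])
  if (S0 <= 0) stopf("amplitude S0 must be positive, got %g", S0)
  st <- (1 - s$value / S0) * 100
  suppressWarnings(
    temperature_series(s$temperature, st, "transmittance_pct", unit = s$unit,
                       label = sprintf("st(%s)", s$label), Tm = s$Tm))
}
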