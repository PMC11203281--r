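new_phase_portrait <- function(temperature, x, v, mode, provenance = list()) {
  stopifnot(length(temperature) == length(x), length(x) == length(v))
  non_monotone <- any(diff(x) < 0)
  structure(list(temperature = temperature, x = x, v = v, mode = mode,
                 provenance = provenance, non_monotone_x = non_monotone),
            class = "phase_portrait")
}

#' Direct phase portrait by numerical differentiation
#'
#' Plots the finite-difference derivative dD/dT of a measured curve against
#' the curve itself, removing explicit temperature.  Central differences are
#' used on interior points (exact for affine data on any grid) with
#' one-sided two-point differences at both ends; optional pre-smoothing is
#' available because differentiation amplifies measurement noise.
#'
#' @param s a [temperature_series()] of at least 3 points.
#' @param diff `"central"` (default) or `"forward"` differencing.
#' @param smoothing `NULL` (none, the default) or a list with elements
#'   `method`, `window`, `order` passed to [smooth_series()].
#' @return A `phase_portrait` with `mode = "direct"`, state `x` equal to the
#'   (optionally smoothed) values, rate `v` equal to the derivative, and the
#'   numerical settings recorded in `provenance`.
#' @export
direct_portrait <- function(s, diff = c("central", "forward"),
                            smoothing = NULL) {
  stopifnot(inherits(s, "temperature_series"))
  diff <- match.arg(diff)
  if (length(s$temperature) < 3)
    stopf("direct portrait needs at least 3 points, got %d",
          length(s$temperature))
  if (!is.null(smoothing))
    s <- smooth_series(s, method = smoothing$method,
                       window = smoothing$window %||% 5,
                       order = smoothing$order %||% 2)
  Tv <- s$temperature; y <- s$value; n <- length(Tv)
  v <- numeric(n)
  if (diff == "central") {
    i <- 2:(n - 1)
    v[i] <- (y[i + 1] - y[i - 1]) / (Tv[i + 1] - Tv[i - 1])
    v[1] <- (y[2] - y[1]) / (Tv[2] - Tv[1])
    v[n] <- (y[n] - y[n - 1]) / (Tv[n] - Tv[n - 1])
  } else {
    i <- 1:(n - 1)
    v[i] <- (y[i + 1] - y[i]) / (Tv[i + 1] - Tv[i])
    v[n] <- v[n - 1]
  }
  new_phase_portrait(Tv, y, v, "direct",
                     provenance = list(source = s$label, kind = s$kind,
                                       diff = diff,
                                       smoothing = smoothing %||% "none"))
}

#' Inverse phase portrait by numerical integration
#'
#' Plots the measured heat flow Cp(T) against its cumulative integral
#' S(T) = integral of Cp from Tm.  Because Cp is itself the derivative of S
#' by construction, the pair (S, Cp) is a phase portrait obtained without
#' numerical differentiation — integration smooths rather than amplifies
#' measurement noise, which is the accuracy advantage of the inverse method.
#'
#' @param cp a [temperature_series()] of kind `"heat_flow"`.
#' @param Tm lower integration limit; see [cumulative_integral()].
#' @param method integration rule, `"trapezoid"` or `"rectangle"`.
#' @param flip_sign set `TRUE` for DSC sign conventions where transition
#'   peaks point downwards; negates Cp before use.  Default `FALSE`.
#' @return A `phase_portrait` with `mode = "inverse"`, `x = S(T)` (zero at
#'   Tm, non-decreasing when Cp >= 0) and `v = Cp(T)`.  Non-monotone `x`
#'   (negative Cp excursions) is permitted and flagged in `non_monotone_x`.
#' @export
inverse_portrait <- function(cp, Tm = NULL,
                             method = c("trapezoid", "rectangle"),
                             flip_sign = FALSE) {
  stopifnot(inherits(cp, "temperature_series"))
  method <- match.arg(method)
  if (flip_sign) cp$value <- -cp$value
  s <- cumulative_integral(cp, Tm = Tm, method = method)
  new_phase_portrait(cp$temperature, s$value, cp$value, "inverse",
                     provenance = list(source = cp$label, kind = cp$kind,
                                       integration = method,
                                       Tm = s$Tm, flip_sign = flip_sign))
}

#' Exact phase portrait of an analytic model
#'
#' Evaluates a stage model (or two-stage product model) and its analytic
#' temperature derivative on a grid — no finite differences — giving the
#' ground-truth portrait: a parabola through the origin for the sigmoid, the
#' line v = (D0 - x)/tau for exponential saturation.
#'
#' @param m a [stage_params()] or [two_stage_model()].
#' @param grid numeric vector of temperatures (strictly increasing).
#' @return A `phase_portrait` with `mode = "direct"` and exact `x`, `v`.
#' @export
portrait_of_model <- function(m, grid) {
  if (any(diff(grid) <= 0)) stopf("grid must be strictly increasing")
  x <- if (inherits(m, "stage_params")) {
    switch(m$form,
           sigmoid = eval_sigmoid(m, grid),
           exp_saturation = eval_exp_saturation(m, grid))
  } else if (inherits(m, "two_stage_model")) {
    eval_two_stage(m, grid)
  } else {
    stopf("unsupported model class: %s", paste(class(m), collapse = "/"))
  }
  v <- model_derivative(m, grid)
  new_phase_portrait(grid, x, v, "direct",
                     provenance = list(source = "analytic model",
                                       model = class(m)[1]))
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("<phase_portrait> mode %s, %d points\n", x$mode,
              length(x$x)))
  cat(sprintf("  x in [%g, %g]; v in [%g, %g]\n", min(x$x), max(x$x),
              min(x$v), max(x$v)))
  if (x$non_monotone_x) cat("  note: state x is not monotone in T\n")
  invisible(x)
}

#' @export
as.data.frame.phase_portrait <- function(x, ...) {
  data.frame(temperature = x$temperature, x = x$x, v = x$v, mode = x$mode)
}

#' @export
plot.phase_portrait <- function(x, ...) {
  lab <- if (x$mode == "direct") c("D", "dD/dT") else c("S", "Cp")
  plot(x$x, x$v, xlab = lab[1], ylab = lab[2],
       main = sprintf("%s phase portrait", x$mode), ...)
  invisible(x)
}

#' Write a phase portrait to CSV
#'
#' Columns `temperature,x,v,mode` in the package CSV dialect.
#'
#' @param p a `phase_portrait`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_portrait <- function(p, path) {
  stopifnot(inherits(p, "phase_portrait"))
  write.csv(as.data.frame(p), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
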