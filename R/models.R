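#' Parameters of a single transition stage
#'
#' A single stage of a thermally driven phase transition is described by one
#' of two analytic forms:
#' \describe{
#'   \item{sigmoid}{D(T) = D0 exp((T-T0)/tau) / (1 + exp((T-T0)/tau)) — the
#'     logistic step describing an abrupt, jump-like stage.  Its phase
#'     portrait dD/dT vs D is a parabola with roots at D = 0 and D = D0.}
#'   \item{exp_saturation}{D(T) = D0 (1 - exp(-(T-T0)/tau)) — smooth
#'     saturation describing gradual coil compaction.  Its phase portrait is
#'     the straight line dD/dT = (D0 - D)/tau.}
#' }
#'
#' @param form `"sigmoid"` or `"exp_saturation"`.
#' @param D0 amplitude of the measured quantity, > 0.
#' @param T0 characteristic (transition) temperature.
#' @param tau steepness constant, > 0, in temperature units.
#' @return An object of class `stage_params`.
#' @export
stage_params <- function(form = c("sigmoid", "exp_saturation"), D0, T0, tau) {
  form <- match.arg(form)
  if (!is.numeric(D0) || length(D0) != 1 || !is.finite(D0) || D0 <= 0)
    stopf("D0 must be a single positive number, got %s", format(D0))
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stopf("tau must be a single positive number, got %s", format(tau))
  if (!is.numeric(T0) || length(T0) != 1 || !is.finite(T0))
    stopf("T0 must be a single finite number")
  structure(list(form = form, D0 = D0, T0 = T0, tau = tau),
            class = "stage_params")
}

#' @export
print.stage_params <- function(x, ...) {
  cat(sprintf("<stage_params> %s: D0 = %g, T0 = %g, tau = %g\n",
              x$form, x$D0, x$T0, x$tau))
  invisible(x)
}

#' Two-stage transition model
#'
#' The product model D(T) = D0 * (1 - exp(-(T-T01)/tau1)) /
#' (1 + exp(-(T-T02)/tau2)) combining an exponential-saturation stage
#' (smooth coil compaction) with a logistic sigmoid stage (abrupt
#' destruction of interpolymer associates).  Stages are named by functional
#' form (`exp_stage`, `sig_stage`), never ordinally.
#'
#' @param T01,tau1 characteristic temperature and steepness of the
#'   exponential-saturation stage (`tau1 > 0`).
#' @param T02,tau2 transition temperature and steepness of the sigmoid stage
#'   (`tau2 > 0`).
#' @param D0 overall amplitude, > 0.
#' @return An object of class `two_stage_model`.
#' @export
two_stage_model <- function(T01, tau1, T02, tau2, D0 = 1) {
  if (tau1 <= 0 || tau2 <= 0) stopf("tau1 and tau2 must be positive")
  if (D0 <= 0) stopf("D0 must be positive")
  structure(list(exp_stage = list(T0 = T01, tau = tau1),
                 sig_stage = list(T0 = T02, tau = tau2),
                 D0 = D0),
            class = "two_stage_model")
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat("<two_stage_model> D(T) = D0 (1 - exp(-(T-T01)/tau1)) / (1 + exp(-(T-T02)/tau2))\n")
  cat(sprintf("  exp_stage: T01 = %g, tau1 = %g\n",
              x$exp_stage$T0, x$exp_stage$tau))
  cat(sprintf("  sig_stage: T02 = %g, tau2 = %g\n",
              x$sig_stage$T0, x$sig_stage$tau))
  cat(sprintf("  D0 = %g\n", x$D0))
  invisible(x)
}

#' Evaluate the sigmoid stage model
#'
#' D(T) = D0 exp((T-T0)/tau) / (1 + exp((T-T0)/tau)), computed in the
#' numerically stable logistic form ([stats::plogis()]); strictly increasing
#' with limits 0 and D0.
#'
#' @param p a [stage_params()] with `form = "sigmoid"`.
#' @param temps numeric vector of temperatures.
#' @return Numeric vector of model values.
#' @export
eval_sigmoid <- function(p, temps) {
  stopifnot(inherits(p, "stage_params"), p$form == "sigmoid")
  p$D0 * stats::plogis((temps - p$T0) / p$tau)
}

#' Evaluate the exponential-saturation stage model
#'
#' D(T) = D0 (1 - exp(-(T-T0)/tau)).  The value is negative for T < T0 and
#' deliberately left unclipped: the model is only ever fitted on tail
#' regions where T > T0.
#'
#' @inheritParams eval_sigmoid
#' @param p a [stage_params()] with `form = "exp_saturation"`.
#' @export
eval_exp_saturation <- function(p, temps) {
  stopifnot(inherits(p, "stage_params"), p$form == "exp_saturation")
  p$D0 * (1 - exp(-(temps - p$T0) / p$tau))
}

#' Evaluate the two-stage product model
#'
#' Equal, pointwise, to the product of the exponential-saturation factor and
#' a unit-amplitude logistic sigmoid, times the overall amplitude D0.
#'
#' @param m a [two_stage_model()].
#' @param temps numeric vector of temperatures.
#' @return Numeric vector of model values.
#' @export
eval_two_stage <- function(m, temps) {
  stopifnot(inherits(m, "two_stage_model"))
  m$D0 * (1 - exp(-(temps - m$exp_stage$T0) / m$exp_stage$tau)) *
    stats::plogis((temps - m$sig_stage$T0) / m$sig_stage$tau)
}

# Analytic temperature derivative of a stage model or two-stage model.
model_derivative <- function(m, temps) {
  if (inherits(m, "stage_params")) {
    if (m$form == "sigmoid") {
      u <- stats::plogis((temps - m$T0) / m$tau)
      m$D0 * u * (1 - u) / m$tau
    } else {
      m$D0 / m$tau * exp(-(temps - m$T0) / m$tau)
    }
  } else if (inherits(m, "two_stage_model")) {
    e <- 1 - exp(-(temps - m$exp_stage$T0) / m$exp_stage$tau)
    de <- exp(-(temps - m$exp_stage$T0) / m$exp_stage$tau) / m$exp_stage$tau
    u <- stats::plogis((temps - m$sig_stage$T0) / m$sig_stage$tau)
    du <- u * (1 - u) / m$sig_stage$tau
    m$D0 * (de * u + e * du)
  } else {
    stopf("unsupported model class: %s", paste(class(m), collapse = "/"))
  }
}

#' Exact portrait parabola of a sigmoid stage
#'
#' The sigmoid stage is the unique solution of the parabolic portrait
#' equation dD/dT = a2 D^2 + a1 D + a0 with a2 = -1/(tau D0), a1 = 1/tau,
#' a0 = 0 (D = 0 is a fixed point, so the parabola passes through the
#' origin; the second root is D = D0).  The portrait vertex sits at
#' D = D0/2 with maximal rate D0/(4 tau).
#'
#' @param p a [stage_params()] with `form = "sigmoid"`.
#' @return Named numeric vector `c(a2, a1, a0)`.
#' @export
sigmoid_portrait_coeffs <- function(p) {
  stopifnot(inherits(p, "stage_params"), p$form == "sigmoid")
  c(a2 = -1 / (p$tau * p$D0), a1 = 1 / p$tau, a0 = 0)
}

# Deterministic initial values for the sigmoid fit: T0 from the
# half-amplitude crossing, tau from the 25-75 percent quartile width
# (which equals 2 tau ln 3 for an exact logistic), D0 from the amplitude.
sigmoid_start <- function(Tv, y) {
  lo <- min(y); hi <- max(y)
  amp <- hi - lo
  crossing <- function(frac) {
    target <- lo + frac * amp
    i <- which(y >= target)[1]
    if (is.na(i) || i == 1) return(Tv[1])
    # linear interpolation between the bracketing samples
    Tv[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (Tv[i] - Tv[i - 1])
  }
  T0 <- crossing(0.5)
  tau <- (crossing(0.75) - crossing(0.25)) / (2 * log(3))
  if (!is.finite(tau) || tau <= 0) tau <- diff(range(Tv)) / 10
  list(D0 = hi, T0 = T0, tau = tau)
}

#' Fit the sigmoid stage model to a temperature series
#'
#' Nonlinear least squares of the logistic sigmoid via
#' [minpack.lm::nlsLM()].  Initialization is deterministic (half-amplitude
#' crossing for T0, quartile width for tau, observed amplitude for D0) with
#' up to three deterministic perturbed restarts; no randomness is involved.
#'
#' @param s a [temperature_series()] with positive amplitude.  Monotone
#'   decreasing data are rejected: the model is increasing.
#' @param bounds optional list with elements `lower` and/or `upper`, each a
#'   named numeric vector over `D0`, `T0`, `tau`.
#' @return A list of class `stage_fit`: `params` ([stage_params()]),
#'   `rmse`, `r2`, `fitted`, `converged`.
#' @export
fit_sigmoid <- function(s, bounds = NULL) {
  stopifnot(inherits(s, "temperature_series"))
  Tv <- s$temperature; y <- s$value
  if (max(y) - min(y) <= 0) stopf("series has zero amplitude, cannot fit")
  d <- diff(y)
  if (all(d <= 0) && any(d < 0))
    stopf("series is monotone decreasing; the sigmoid stage model is increasing")
  st <- sigmoid_start(Tv, y)
  lower <- c(D0 = 1e-12, T0 = -Inf, tau = 1e-12)
  upper <- c(D0 = Inf, T0 = Inf, tau = Inf)
  if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
  if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  starts <- list(
    st,
    list(D0 = st$D0, T0 = st$T0, tau = st$tau * 2),
    list(D0 = st$D0, T0 = st$T0 + st$tau, tau = st$tau / 2),
    list(D0 = st$D0 * 1.2, T0 = st$T0 - st$tau, tau = st$tau))
  fit <- NULL
  for (s0 in starts) {
    s0$tau <- max(s0$tau, lower[["tau"]])
    s0$D0 <- max(s0$D0, lower[["D0"]])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ D0 * plogis((Tv - T0) / tau),
                        data = list(Tv = Tv, y = y),
                        start = s0, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stopf("sigmoid fit failed to converge after %d deterministic starts (n = %d, amplitude = %g)",
          length(starts), length(y), max(y) - min(y))
  cf <- coef(fit)
  fitted <- cf[["D0"]] * stats::plogis((Tv - cf[["T0"]]) / cf[["tau"]])
  res <- y - fitted
  tss <- sum((y - mean(y))^2)
  structure(list(
    params = stage_params("sigmoid", D0 = cf[["D0"]], T0 = cf[["T0"]],
                          tau = cf[["tau"]]),
    rmse = sqrt(mean(res^2)),
    r2 = if (tss > 0) 1 - sum(res^2) / tss else 1,
    fitted = fitted, converged = TRUE), class = "stage_fit")
}

#' Fit the exponential-saturation model to the tail of a series
#'
#' Restricts the series to temperatures at or above `tail_start` — in the
#' decomposition pipeline, the temperature range whose portrait fragment is
#' linear — and fits D0 (1 - exp(-(T-T0)/tau)) by nonlinear least squares.
#' Initialization is a log-linear regression of log(D0_guess - y) on T.
#'
#' @param s a [temperature_series()].
#' @param tail_start lowest temperature included in the fit; at least 5
#'   points must remain.
#' @return A list of class `stage_fit`, as for [fit_sigmoid()], with
#'   `params$form == "exp_saturation"` and an extra field `tail_start`.
#' @export
fit_exp_tail <- function(s, tail_start) {
  stopifnot(inherits(s, "temperature_series"))
  keep <- s$temperature >= tail_start
  if (sum(keep) < 5)
    stopf("only %d points at T >= %g; at least 5 required for the tail fit",
          sum(keep), tail_start)
  Tv <- s$temperature[keep]; y <- s$value[keep]
  D0g <- max(y) + 0.05 * max(abs(y), 1e-12)
  z <- log(pmax(D0g - y, 1e-12 * max(abs(y), 1)))
  lf <- stats::lm.fit(cbind(1, Tv), z)
  slope <- lf$coefficients[2]
  taug <- if (is.finite(slope) && slope < 0) -1 / slope else diff(range(Tv))
  T0g <- (lf$coefficients[1] - log(D0g)) * taug
  if (!is.finite(T0g)) T0g <- Tv[1] - taug
  starts <- list(
    list(D0 = D0g, T0 = T0g, tau = taug),
    list(D0 = D0g, T0 = Tv[1] - taug / 2, tau = taug / 2),
    list(D0 = D0g * 1.2, T0 = Tv[1] - taug, tau = taug * 2))
  fit <- NULL
  for (s0 in starts) {
    s0$tau <- max(s0$tau, 1e-9)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ D0 * (1 - exp(-(Tv - T0) / tau)),
                        data = list(Tv = Tv, y = y),
                        start = s0,
                        lower = c(D0 = 1e-12, T0 = -Inf, tau = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stopf("exponential tail fit failed to converge (tail_start = %g, n = %d)",
          tail_start, length(y))
  cf <- coef(fit)
  fitted <- cf[["D0"]] * (1 - exp(-(Tv - cf[["T0"]]) / cf[["tau"]]))
  res <- y - fitted
  tss <- sum((y - mean(y))^2)
  structure(list(
    params = stage_params("exp_saturation", D0 = cf[["D0"]], T0 = cf[["T0"]],
                          tau = cf[["tau"]]),
    rmse = sqrt(mean(res^2)),
    r2 = if (tss > 0) 1 - sum(res^2) / tss else 1,
    fitted = fitted, tail_start = tail_start, converged = TRUE),
    class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat(sprintf("<stage_fit> %s: D0 = %.5g, T0 = %.5g, tau = %.5g (RMSE %.3g, R2 %.5f)\n",
              x$params$form, x$params$D0, x$params$T0, x$params$tau,
              x$rmse, x$r2))
  invisible(x)
}
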