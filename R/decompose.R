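#' Stage decomposition of a phase-transition curve
#'
#' The central fitting function of the package.  Given a measured curve —
#' an optical-density turbidity curve (analyzed through its direct phase
#' portrait) or a DSC heat-flow curve (analyzed through its inverse
#' portrait) — it determines how many stages the phase transition has and,
#' when the portrait contains both a parabolic and a linear fragment,
#' recovers the parameters of the two-stage product model by the
#' division-based procedure:
#'
#' 1. build the phase portrait and segment it ([segment_portrait()]);
#' 2. if no linear fragment is present, report the stage count (fitting a
#'    single sigmoid stage to the whole curve when the portrait is
#'    parabolic) and stop;
#' 3. otherwise map the (temperature-wise last) linear fragment back to its
#'    temperature range and fit the exponential-saturation model there
#'    ([fit_exp_tail()]);
#' 4. divide the data by the exponential fit, dropping points where the fit
#'    is below `ratio_floor * D0` (division near zero explodes);
#' 5. fit the sigmoid stage to the ratio curve ([fit_sigmoid()]);
#' 6. assemble the two-stage model, with overall amplitude equal to the
#'    product of the two fitted amplitudes;
#' 7. when `refine = TRUE` (the default), polish all five parameters by a
#'    joint nonlinear least-squares fit of the product model to the full
#'    curve, initialized at the staged estimates.  The division procedure
#'    is what makes this polish well-posed: fitting the product model from
#'    scratch has no reliable starting point.
#'
#' The `separation_ok` flag records the method's applicability criterion:
#' the two stages' characteristic temperatures must be separated by more
#' than `separation_factor` times the geometric mean of the two widths
#' sqrt(tau1 tau2); overlapping stages cannot be cleanly divided apart.
#'
#' @param s a [temperature_series()] of at least 20 points with positive
#'   amplitude.  Kind `"heat_flow"` is required when
#'   `portrait_mode = "inverse"`; in that case the decomposed curve is the
#'   cumulative integral S(T).
#' @param cfg a [segment_config()].
#' @param portrait_mode `"direct"` (differentiate the curve) or
#'   `"inverse"` (integrate a heat-flow curve).
#' @param ratio_floor fraction of the exponential-fit amplitude below which
#'   ratio points are excluded (default 0.05).
#' @param separation_factor multiplier in the applicability criterion
#'   (default 2).
#' @param refine polish the assembled two-stage model by a joint nonlinear
#'   least-squares fit (default `TRUE`).
#' @param smoothing optional smoothing config for the direct portrait, see
#'   [direct_portrait()].
#' @return An object of class `stage_decomposition` with fields `series`,
#'   `data_curve`, `portrait`, `segments`, `stage_count`, `model`
#'   ([two_stage_model()] or `NULL`), `exp_fit`, `sigmoid_fit`,
#'   `ratio_series`, `quality` (overall RMSE and R-squared of the
#'   reassembled model), `separation_ok`, `settings`.
#' @seealso [predict.stage_decomposition()], [plot.stage_decomposition()],
#'   [decomposition_report()]
#' @examples
#' m <- two_stage_model(T01 = 22, tau1 = 10, T02 = 30, tau2 = 1.2, D0 = 1)
#' spec <- simulation_spec(
#'   stages = list(
#'     list(form = "exp_saturation", amplitude = 1, T0 = 22, tau = 10),
#'     list(form = "sigmoid", amplitude = 1, T0 = 30, tau = 1.2)),
#'   T_start = 10, T_stop = 45, T_step = 0.1)
#' d <- generate_turbidity(spec)
#' fit <- stage_decompose(d)
#' fit
#' coef(fit)
#' @export
stage_decompose <- function(s, cfg = segment_config(),
                            portrait_mode = c("direct", "inverse"),
                            ratio_floor = 0.05, separation_factor = 2,
                            refine = TRUE, smoothing = NULL) {
  stopifnot(inherits(s, "temperature_series"))
  portrait_mode <- match.arg(portrait_mode)
  if (length(s$temperature) < 20)
    stopf("stage decomposition needs at least 20 points, got %d",
          length(s$temperature))
  if (max(s$value) - min(s$value) <= 0)
    stopf("series has zero amplitude")
  if (portrait_mode == "inverse") {
    if (s$kind != "heat_flow")
      stopf("inverse portrait mode requires a heat_flow series, got %s",
            s$kind)
    portrait <- inverse_portrait(s)
    data_curve <- cumulative_integral(s)
  } else {
    portrait <- direct_portrait(s, smoothing = smoothing)
    data_curve <- s
  }
  segs <- segment_portrait(portrait, cfg)
  n_stages <- count_stages(segs)
  kinds <- vapply(segs, `[[`, character(1), "kind")
  settings <- list(portrait_mode = portrait_mode, ratio_floor = ratio_floor,
                   separation_factor = separation_factor, config = cfg)

  base <- list(series = s, data_curve = data_curve, portrait = portrait,
               segments = segs, stage_count = n_stages, model = NULL,
               exp_fit = NULL, sigmoid_fit = NULL, ratio_series = NULL,
               quality = NULL, separation_ok = NA, settings = settings)

  lin <- which(kinds == "linear")
  if (length(lin) == 0) {
    # single-stage (or purely parabolic) transition: fit one sigmoid to the
    # whole curve as the stage model, no two-stage decomposition
    if (any(kinds == "parabolic")) {
      base$sigmoid_fit <- tryCatch(fit_sigmoid(data_curve),
                                   error = function(e) NULL)
      if (!is.null(base$sigmoid_fit)) {
        res <- data_curve$value - base$sigmoid_fit$fitted
        tss <- sum((data_curve$value - mean(data_curve$value))^2)
        base$quality <- list(rmse = sqrt(mean(res^2)),
                             r2 = if (tss > 0) 1 - sum(res^2) / tss else 1)
      }
    }
    return(structure(base, class = "stage_decomposition"))
  }

  # exponential stage from the last (highest-temperature) linear fragment
  tail_seg <- segs[[lin[which.max(vapply(lin, function(k)
    segs[[k]]$T_range[2], numeric(1)))]]]
  tail_start <- tail_seg$T_range[1]
  exp_fit <- tryCatch(fit_exp_tail(data_curve, tail_start),
                      error = function(e)
                        stopf("exponential stage fit failed: %s",
                              conditionMessage(e)))
  exp_vals <- eval_exp_saturation(exp_fit$params, data_curve$temperature)
  keep <- exp_vals >= ratio_floor * exp_fit$params$D0
  if (sum(keep) < 10)
    stopf("ratio curve too short: only %d points where the exponential fit exceeds %g of its amplitude",
          sum(keep), ratio_floor)
  ratio_series <- temperature_series(
    data_curve$temperature[keep], data_curve$value[keep] / exp_vals[keep],
    "ratio", unit = s$unit, label = sprintf("%s / exp fit", s$label))
  sig_fit <- tryCatch(fit_sigmoid(ratio_series),
                      error = function(e)
                        stopf("sigmoid stage fit on the ratio curve failed: %s",
                              conditionMessage(e)))

  model <- two_stage_model(T01 = exp_fit$params$T0, tau1 = exp_fit$params$tau,
                           T02 = sig_fit$params$T0, tau2 = sig_fit$params$tau,
                           D0 = exp_fit$params$D0 * sig_fit$params$D0)
  if (refine) {
    Tv <- data_curve$temperature; yv <- data_curve$value
    pol <- tryCatch(
      minpack.lm::nlsLM(
        yv ~ D0 * (1 - exp(-(Tv - T01) / tau1)) * plogis((Tv - T02) / tau2),
        data = list(Tv = Tv, yv = yv),
        start = list(D0 = model$D0, T01 = model$exp_stage$T0,
                     tau1 = model$exp_stage$tau, T02 = model$sig_stage$T0,
                     tau2 = model$sig_stage$tau),
        lower = c(D0 = 1e-12, T01 = -Inf, tau1 = 1e-9, T02 = -Inf,
                  tau2 = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(pol)) {
      cf <- coef(pol)
      model <- two_stage_model(T01 = cf[["T01"]], tau1 = cf[["tau1"]],
                               T02 = cf[["T02"]], tau2 = cf[["tau2"]],
                               D0 = cf[["D0"]])
    }
  }
  fitted <- eval_two_stage(model, data_curve$temperature)
  res <- data_curve$value - fitted
  tss <- sum((data_curve$value - mean(data_curve$value))^2)
  sep <- (model$sig_stage$T0 - model$exp_stage$T0) >
    separation_factor * sqrt(model$exp_stage$tau * model$sig_stage$tau)

  base$model <- model
  base$exp_fit <- exp_fit
  base$sigmoid_fit <- sig_fit
  base$ratio_series <- ratio_series
  base$quality <- list(rmse = sqrt(mean(res^2)),
                       r2 = if (tss > 0) 1 - sum(res^2) / tss else 1)
  base$separation_ok <- sep
  structure(base, class = "stage_decomposition")
}

#' @export
print.stage_decomposition <- function(x, ...) {
  cat(sprintf("<stage_decomposition> %s portrait, %d stage(s)\n",
              x$settings$portrait_mode, x$stage_count))
  if (!is.null(x$model)) {
    cat(sprintf("  exp_stage: T01 = %.4g, tau1 = %.4g\n",
                x$model$exp_stage$T0, x$model$exp_stage$tau))
    cat(sprintf("  sig_stage: T02 = %.4g, tau2 = %.4g\n",
                x$model$sig_stage$T0, x$model$sig_stage$tau))
    cat(sprintf("  D0 = %.4g; overall RMSE = %.3g, R2 = %.5f\n",
                x$model$D0, x$quality$rmse, x$quality$r2))
    cat(sprintf("  separation_ok: %s\n", x$separation_ok))
  } else if (!is.null(x$sigmoid_fit)) {
    p <- x$sigmoid_fit$params
    cat(sprintf("  single sigmoid stage: D0 = %.4g, T0 = %.4g, tau = %.4g\n",
                p$D0, p$T0, p$tau))
  }
  invisible(x)
}

#' @export
summary.stage_decomposition <- function(object, ...) {
  print(object)
  cat("\nPortrait segmentation:\n")
  print(object$segments)
  invisible(object)
}

#' Model coefficients of a stage decomposition
#'
#' @param object a [stage_decompose()] result.
#' @param ... unused.
#' @return Named numeric vector: `T01`, `tau1`, `T02`, `tau2`, `D0` for a
#'   two-stage fit; `T0`, `tau`, `D0` for a single sigmoid stage.
#' @export
coef.stage_decomposition <- function(object, ...) {
  if (!is.null(object$model)) {
    c(T01 = object$model$exp_stage$T0, tau1 = object$model$exp_stage$tau,
      T02 = object$model$sig_stage$T0, tau2 = object$model$sig_stage$tau,
      D0 = object$model$D0)
  } else if (!is.null(object$sigmoid_fit)) {
    p <- object$sigmoid_fit$params
    c(T0 = p$T0, tau = p$tau, D0 = p$D0)
  } else {
    stopf("no fitted model in this decomposition")
  }
}

#' Predict from a fitted stage decomposition
#'
#' Evaluates the fitted curve model (two-stage product, or single sigmoid
#' stage) at new temperatures.
#'
#' @param object a [stage_decompose()] result with a fitted model.
#' @param newdata numeric vector of temperatures, or a data frame with a
#'   `temperature` column; default: the data temperatures.
#' @param ... unused.
#' @return Numeric vector of model values.
#' @export
predict.stage_decomposition <- function(object, newdata = NULL, ...) {
  temps <- if (is.null(newdata)) {
    object$data_curve$temperature
  } else if (is.data.frame(newdata)) {
    newdata$temperature
  } else {
    as.numeric(newdata)
  }
  if (!is.null(object$model)) {
    eval_two_stage(object$model, temps)
  } else if (!is.null(object$sigmoid_fit)) {
    eval_sigmoid(object$sigmoid_fit$params, temps)
  } else {
    stopf("no fitted model in this decomposition")
  }
}

#' @export
residuals.stage_decomposition <- function(object, ...) {
  object$data_curve$value - predict(object)
}

#' @export
fitted.stage_decomposition <- function(object, ...) predict(object)

#' Plot a stage decomposition
#'
#' Two panels: the data curve with the fitted model, and the phase portrait
#' with fragments colored by kind (parabolic, linear, intermediate).
#'
#' @param x a [stage_decompose()] result.
#' @param ... passed to the underlying plot calls.
#' @export
plot.stage_decomposition <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  dc <- x$data_curve
  plot(dc$temperature, dc$value, xlab = sprintf("T [%s]", dc$unit),
       ylab = dc$kind, main = "curve and fitted model", ...)
  has_model <- !is.null(x$model) || !is.null(x$sigmoid_fit)
  if (has_model)
    lines(dc$temperature, predict(x), col = "red", lwd = 2)
  cols <- c(parabolic = "blue", linear = "grey40", intermediate = "orange")
  p <- x$portrait
  plot(p$x, p$v, type = "n",
       xlab = if (p$mode == "direct") "D" else "S",
       ylab = if (p$mode == "direct") "dD/dT" else "Cp",
       main = sprintf("%s portrait (%d stages)", p$mode, x$stage_count))
  for (s in x$segments) {
    idx <- s$span[1]:s$span[2]
    points(p$x[idx], p$v[idx], col = cols[[s$kind]], pch = 20)
  }
  legend("topleft", legend = names(cols), col = cols, pch = 20, bty = "n")
  invisible(x)
}

#' Simulate replicate curves from a fitted decomposition
#'
#' Draws `nsim` noisy replicates of the fitted model curve on the data
#' grid, with iid Gaussian noise at the residual standard deviation.
#'
#' @param object a [stage_decompose()] result with a fitted model.
#' @param nsim number of replicates.
#' @param seed integer seed (required for reproducibility).
#' @param ... unused.
#' @return A matrix with one column per replicate.
#' @export
simulate.stage_decomposition <- function(object, nsim = 1, seed = 1, ...) {
  mu <- predict(object)
  sdres <- sd(residuals(object))
  with_seed(seed, {
    matrix(rnorm(length(mu) * nsim, mean = mu, sd = sdres),
           ncol = nsim)
  })
}

#' JSON decomposition report
#'
#' Model parameters, per-step fit quality, the separation-applicability
#' flag and the stage count, as JSON.
#'
#' @param d a [stage_decompose()] result.
#' @param path optional output path.
#' @return JSON string (invisibly when `path` is given).
#' @export
decomposition_report <- function(d, path = NULL) {
  stopifnot(inherits(d, "stage_decomposition"))
  rep <- list(
    portrait_mode = d$settings$portrait_mode,
    stage_count = d$stage_count,
    separation_ok = d$separation_ok,
    model = if (!is.null(d$model)) {
      list(T01 = d$model$exp_stage$T0, tau1 = d$model$exp_stage$tau,
           T02 = d$model$sig_stage$T0, tau2 = d$model$sig_stage$tau,
           D0 = d$model$D0)
    },
    exp_fit = if (!is.null(d$exp_fit))
      list(rmse = d$exp_fit$rmse, r2 = d$exp_fit$r2,
           tail_start = d$exp_fit$tail_start),
    sigmoid_fit = if (!is.null(d$sigmoid_fit))
      list(rmse = d$sigmoid_fit$rmse, r2 = d$sigmoid_fit$r2,
           params = unclass(d$sigmoid_fit$params)[c("D0", "T0", "tau")]),
    overall = d$quality,
    segments = lapply(d$segments, function(s)
      list(kind = s$kind, T_range = s$T_range, r2 = s$r2)))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
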