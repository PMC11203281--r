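#' Specification of a synthetic measurement
#'
#' Describes the stage structure, temperature grid, noise level and seed of
#' a synthetic turbidity curve or thermogram.  The generators are the
#' fixture source for every validation test in the package: noiseless
#' generation reproduces the analytic model exactly (no hidden
#' discretization), and a fixed seed gives bit-identical output.
#'
#' @param stages list of stage descriptions, each a list with `form`
#'   (`"sigmoid"` or `"exp_saturation"`), `amplitude` (> 0; an optical
#'   density for turbidity, a transition enthalpy for thermograms), `T0`
#'   and `tau` (> 0).
#' @param T_start,T_stop,T_step temperature grid (step > 0).
#' @param noise_sd standard deviation of additive iid Gaussian measurement
#'   noise, in absolute units (>= 0).
#' @param seed integer seed for the noise generator.
#' @param baseline constant instrumental baseline added to the signal.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(stages, T_start, T_stop, T_step,
                            noise_sd = 0, seed = 1, baseline = 0) {
  if (length(stages) < 1) stopf("at least one stage is required")
  for (st in stages) {
    if (!all(c("form", "amplitude", "T0", "tau") %in% names(st)))
      stopf("each stage needs fields form, amplitude, T0, tau")
    if (!st$form %in% c("sigmoid", "exp_saturation"))
      stopf("unknown stage form: %s", st$form)
    if (st$amplitude <= 0)
      stopf("stage amplitude must be positive, got %g", st$amplitude)
    if (st$tau <= 0) stopf("stage tau must be positive, got %g", st$tau)
  }
  if (T_step <= 0) stopf("T_step must be positive")
  if (T_stop <= T_start) stopf("T_stop must exceed T_start")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(stages = stages, T_start = T_start, T_stop = T_stop,
                 T_step = T_step, noise_sd = noise_sd,
                 seed = as.integer(seed), baseline = baseline),
            class = "simulation_spec")
}

#' Read a simulation specification from YAML
#'
#' The YAML file mirrors the fields of [simulation_spec()].
#'
#' @param path path to a YAML file.
#' @return A [simulation_spec()].
#' @export
read_simulation_spec <- function(path) {
  if (!file.exists(path)) stopf("spec file not found: %s", path)
  y <- yaml::read_yaml(path)
  simulation_spec(stages = y$stages,
                  T_start = y$T_start, T_stop = y$T_stop, T_step = y$T_step,
                  noise_sd = y$noise_sd %||% 0, seed = y$seed %||% 1,
                  baseline = y$baseline %||% 0)
}

spec_grid <- function(spec) seq(spec$T_start, spec$T_stop, by = spec$T_step)

# Analytic turbidity model of a spec: a single stage of either form, a sum
# of sigmoid steps, or the two-stage product (one exp_saturation stage and
# one sigmoid stage).
turbidity_model_value <- function(spec, temps) {
  forms <- vapply(spec$stages, `[[`, character(1), "form")
  if (length(spec$stages) == 1) {
    st <- spec$stages[[1]]
    p <- stage_params(st$form, D0 = st$amplitude, T0 = st$T0, tau = st$tau)
    if (st$form == "sigmoid") eval_sigmoid(p, temps)
    else eval_exp_saturation(p, temps)
  } else if (all(forms == "sigmoid")) {
    mu <- 0
    for (st in spec$stages)
      mu <- mu + st$amplitude * stats::plogis((temps - st$T0) / st$tau)
    mu
  } else if (length(spec$stages) == 2 &&
             sort(forms)[1] == "exp_saturation" && sort(forms)[2] == "sigmoid") {
    e <- spec$stages[[which(forms == "exp_saturation")]]
    s <- spec$stages[[which(forms == "sigmoid")]]
    m <- two_stage_model(T01 = e$T0, tau1 = e$tau, T02 = s$T0, tau2 = s$tau,
                         D0 = e$amplitude * s$amplitude)
    eval_two_stage(m, temps)
  } else {
    stopf("a turbidity spec needs a single stage, all-sigmoid stages, or exactly one exp_saturation and one sigmoid stage")
  }
}

#' Generate a synthetic turbidity curve
#'
#' Optical density D(T) = baseline + model value + iid Gaussian noise, with
#' the model a single sigmoid/exponential stage or the two-stage product
#' (one exponential-saturation stage times one sigmoid).  With
#' `noise_sd = 0` the output equals the analytic model exactly.
#'
#' @param spec a [simulation_spec()].
#' @return A [temperature_series()] of kind `"optical_density"`.
#' @export
generate_turbidity <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  temps <- spec_grid(spec)
  mu <- spec$baseline + turbidity_model_value(spec, temps)
  y <- if (spec$noise_sd > 0) {
    with_seed(derive_seed(spec$seed, "turbidity"),
              mu + rnorm(length(mu), sd = spec$noise_sd))
  } else mu
  temperature_series(temps, y, "optical_density",
                     label = sprintf("synthetic turbidity (seed %d)",
                                     spec$seed))
}

#' Generate a synthetic DSC thermogram
#'
#' Heat flow Cp(T) = baseline + sum over stages of
#' amplitude * u (1 - u) / tau, with u the logistic of (T - T0)/tau — the
#' exact derivative of a sigmoid step, so that the cumulative integral of a
#' noiseless thermogram is exactly the sum of sigmoid steps and every
#' integration-based test has a closed-form oracle.  The peak of each stage
#' sits at T0 with height amplitude/(4 tau); the integral over an infinite
#' range equals the stage amplitude (transition enthalpy).  Only sigmoid
#' stages are allowed: an exponential-saturation stage has an unbounded
#' integral.
#'
#' @param spec a [simulation_spec()] with sigmoid stages only.
#' @return A [temperature_series()] of kind `"heat_flow"`.
#' @export
generate_thermogram <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  forms <- vapply(spec$stages, `[[`, character(1), "form")
  if (any(forms != "sigmoid"))
    stopf("thermogram specs allow sigmoid stages only (an exp_saturation stage has an unbounded integral)")
  temps <- spec_grid(spec)
  mu <- spec$baseline
  for (st in spec$stages) {
    u <- stats::plogis((temps - st$T0) / st$tau)
    mu <- mu + st$amplitude * u * (1 - u) / st$tau
  }
  y <- if (spec$noise_sd > 0) {
    with_seed(derive_seed(spec$seed, "thermogram"),
              mu + rnorm(length(mu), sd = spec$noise_sd))
  } else mu
  temperature_series(temps, y, "heat_flow",
                     label = sprintf("synthetic thermogram (seed %d)",
                                     spec$seed))
}

#' Generate a consistent turbidity/thermogram pair
#'
#' Both outputs share the same sigmoid stage parameters: the turbidity
#' curve is the sum of sigmoid steps, and the thermogram is its exact
#' analytic temperature derivative (per-stage amplitude playing the role of
#' transition enthalpy).  Noise on the two curves comes from distinct
#' deterministic substreams of the one seed, so pairing does not correlate
#' the noise.  Integrating the thermogram and normalizing both curves onto
#' the transmittance scale reproduces the same underlying transition, which
#' closes the turbidimetry--calorimetry consistency loop used in testing.
#'
#' @param spec a [simulation_spec()] with sigmoid stages only.
#' @return A list with elements `turbidity` (optical density) and
#'   `thermogram` (heat flow).
#' @export
generate_paired <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  forms <- vapply(spec$stages, `[[`, character(1), "form")
  if (any(forms != "sigmoid"))
    stopf("paired generation requires sigmoid stages only")
  list(turbidity = generate_turbidity(spec),
       thermogram = generate_thermogram(spec))
}
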