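# Shared synthetic fixtures.  The two-stage reference model combines an
# exponential-saturation stage (T01 = 22, tau1 = 10) with a sigmoid stage
# (T02 = 30, tau2 = 1.2) at unit amplitude -- the published model-curve
# parameter set used throughout validation.

two_stage_ref <- function() two_stage_model(T01 = 22, tau1 = 10,
                                            T02 = 30, tau2 = 1.2, D0 = 1)

two_stage_spec <- function(noise_sd = 0, seed = 1,
                           T_start = 10, T_stop = 45, T_step = 0.1) {
  simulation_spec(
    stages = list(
      list(form = "exp_saturation", amplitude = 1, T0 = 22, tau = 10),
      list(form = "sigmoid", amplitude = 1, T0 = 30, tau = 1.2)),
    T_start = T_start, T_stop = T_stop, T_step = T_step,
    noise_sd = noise_sd, seed = seed)
}

sigmoid_spec <- function(D0 = 1, T0 = 30, tau = 1.2, noise_sd = 0, seed = 1,
                         T_start = 18, T_stop = 42, T_step = 0.05) {
  simulation_spec(
    stages = list(list(form = "sigmoid", amplitude = D0, T0 = T0,
                       tau = tau)),
    T_start = T_start, T_stop = T_stop, T_step = T_step,
    noise_sd = noise_sd, seed = seed)
}

# Heat-flow series whose integral is the given model curve: samples of the
# model's analytic temperature derivative, optionally with seeded noise.
model_thermogram <- function(m, grid, noise_sd = 0, seed = 1) {
  v <- portrait_of_model(m, grid)$v
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(length(v), sd = noise_sd)
  }
  temperature_series(grid, v, "heat_flow")
}

# Independent closed-form derivative of the sigmoid stage, written out
# directly (not via package internals) to serve as an oracle.
model_derivative_oracle <- function(p, grid) {
  u <- 1 / (1 + exp(-(grid - p$T0) / p$tau))
  p$D0 * u * (1 - u) / p$tau
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
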