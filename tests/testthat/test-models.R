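test_that("sigmoid stage evaluates to its closed-form anchors", {
  p <- stage_params("sigmoid", D0 = 1, T0 = 34.8, tau = 1.45)
  expect_equal(eval_sigmoid(p, 34.8), 0.5)
  # one steepness constant above T0: e/(1+e)
  expect_equal(eval_sigmoid(p, 36.25), exp(1) / (1 + exp(1)),
               tolerance = 1e-12)
  expect_equal(eval_sigmoid(p, 34.8 - 40 * 1.45), 0, tolerance = 1e-12)
  expect_equal(eval_sigmoid(p, 34.8 + 40 * 1.45), 1, tolerance = 1e-12)
  expect_true(all(diff(eval_sigmoid(p, seq(20, 50, 0.1))) > 0))
})

test_that("exponential-saturation stage evaluates to its closed form", {
  p <- stage_params("exp_saturation", D0 = 1.63, T0 = 22, tau = 10)
  expect_equal(eval_exp_saturation(p, 22), 0)
  expect_equal(eval_exp_saturation(p, 32), 1.63 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(eval_exp_saturation(p, 22 + 40 * 10), 1.63,
               tolerance = 1e-12)
  # left of T0 the value is negative and deliberately unclipped
  expect_lt(eval_exp_saturation(p, 20), 0)
})

test_that("the two-stage model is the product of its factors", {
  m <- two_stage_ref()
  expect_equal(eval_two_stage(m, 30), (1 - exp(-0.8)) * 0.5,
               tolerance = 1e-12)
  expect_equal(eval_two_stage(m, 30 + 400), 1, tolerance = 1e-12)
  temps <- seq(10, 45, 0.5)
  pe <- stage_params("exp_saturation", D0 = 1, T0 = 22, tau = 10)
  ps <- stage_params("sigmoid", D0 = 1, T0 = 30, tau = 1.2)
  expect_equal(eval_two_stage(m, temps),
               eval_exp_saturation(pe, temps) * eval_sigmoid(ps, temps),
               tolerance = 1e-12)
})

test_that("sigmoid portrait coefficients follow -1/(tau D0), 1/tau, 0", {
  expect_equal(sigmoid_portrait_coeffs(stage_params("sigmoid", 1, 30, 1.2)),
               c(a2 = -1 / 1.2, a1 = 1 / 1.2, a0 = 0))
  expect_equal(sigmoid_portrait_coeffs(stage_params("sigmoid", 1, 34.8, 1.45)),
               c(a2 = -1 / 1.45, a1 = 1 / 1.45, a0 = 0))
  p <- stage_params("sigmoid", D0 = 2.7, T0 = 10, tau = 0.7)
  expect_equal(unname(sigmoid_portrait_coeffs(p)[3]), 0)
})

test_that("the sigmoid solves its parabolic portrait ODE over random parameters", {
  set.seed(2024)
  for (i in 1:100) {
    D0 <- runif(1, 0.1, 5)
    T0 <- runif(1, -20, 80)
    tau <- runif(1, 0.2, 15)
    p <- stage_params("sigmoid", D0 = D0, T0 = T0, tau = tau)
    grid <- seq(T0 - 10 * tau, T0 + 10 * tau, length.out = 400)
    co <- sigmoid_portrait_coeffs(p)
    D <- eval_sigmoid(p, grid)
    dDdT <- model_derivative_oracle(p, grid)
    resid <- dDdT - (co["a2"] * D^2 + co["a1"] * D + co["a0"])
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("the exponential stage satisfies its linear portrait relation", {
  p <- stage_params("exp_saturation", D0 = 1.63, T0 = 22, tau = 10)
  grid <- seq(22, 80, 0.5)
  D <- eval_exp_saturation(p, grid)
  dDdT <- (p$D0 / p$tau) * exp(-(grid - p$T0) / p$tau)  # closed form
  expect_lt(max(abs(dDdT - (p$D0 - D) / p$tau)), 1e-10)
})

test_that("sigmoid fitting recovers generating parameters", {
  grid <- seq(20, 40, 0.1)
  p <- stage_params("sigmoid", D0 = 1, T0 = 30, tau = 1.2)
  clean <- temperature_series(grid, eval_sigmoid(p, grid),
                              "optical_density")
  f <- fit_sigmoid(clean)
  expect_equal(f$params$D0, 1, tolerance = 1e-6)
  expect_equal(f$params$T0, 30, tolerance = 1e-6)
  expect_equal(f$params$tau, 1.2, tolerance = 1e-6)

  set.seed(21)
  noisy <- temperature_series(grid, eval_sigmoid(p, grid) +
                                rnorm(length(grid), sd = 0.01),
                              "optical_density")
  fn <- fit_sigmoid(noisy)
  expect_lt(abs(fn$params$T0 - 30) / 30, 0.05)
  expect_lt(abs(fn$params$tau - 1.2) / 1.2, 0.05)
  expect_lt(abs(fn$params$D0 - 1), 0.05)

  dec <- temperature_series(grid, rev(eval_sigmoid(p, grid)),
                            "optical_density")
  expect_error(fit_sigmoid(dec), "decreasing")
})

test_that("exponential tail fitting recovers parameters from tails", {
  grid <- seq(22, 70, 0.5)
  p <- stage_params("exp_saturation", D0 = 1.63, T0 = 22, tau = 10)
  s <- temperature_series(grid, eval_exp_saturation(p, grid),
                          "optical_density")
  f <- fit_exp_tail(s, tail_start = 30)
  expect_equal(f$params$D0, 1.63, tolerance = 1e-8)
  expect_equal(f$params$T0, 22, tolerance = 1e-6)
  expect_equal(f$params$tau, 10, tolerance = 1e-6)

  # on the two-stage curve, well beyond the sigmoid jump (T02 + 6.7 tau2,
  # where the sigmoid factor is within 0.13% of 1) the tail is nearly
  # pure exponential saturation
  d <- generate_turbidity(two_stage_spec())
  ft <- fit_exp_tail(d, tail_start = 38)
  expect_lt(abs(ft$params$T0 - 22) / 22, 0.1)
  expect_lt(abs(ft$params$tau - 10) / 10, 0.1)

  expect_error(fit_exp_tail(s, tail_start = 69.5), "at least 5")
})

test_that("two-stage decomposition recovers the generating parameters", {
  d <- generate_turbidity(two_stage_spec())
  fit <- stage_decompose(d)
  expect_equal(fit$stage_count, 2)
  cf <- coef(fit)
  expect_lt(abs(cf[["T01"]] - 22) / 22, 0.1)
  expect_lt(abs(cf[["tau1"]] - 10) / 10, 0.1)
  expect_lt(abs(cf[["T02"]] - 30) / 30, 0.1)
  expect_lt(abs(cf[["tau2"]] - 1.2) / 1.2, 0.1)
  expect_true(fit$separation_ok)
  # reassembled model reproduces the noiseless data to well under 1% of D0
  expect_lt(fit$quality$rmse, 0.01)
  expect_equal(predict(fit, 45), eval_two_stage(fit$model, 45))
  expect_lt(max(abs(residuals(fit))), 0.05)
})

test_that("a single-stage sigmoid yields stage count 1 and no product model", {
  d <- generate_turbidity(sigmoid_spec())
  fit <- stage_decompose(d)
  expect_equal(fit$stage_count, 1)
  expect_null(fit$model)
  expect_false(is.null(fit$sigmoid_fit))
  expect_equal(fit$sigmoid_fit$params$T0, 30, tolerance = 1e-3)
})

test_that("overlapping stages are flagged as not separable", {
  spec <- simulation_spec(
    stages = list(
      list(form = "exp_saturation", amplitude = 1, T0 = 22, tau = 10),
      list(form = "sigmoid", amplitude = 1, T0 = 27, tau = 1.2)),
    T_start = 10, T_stop = 45, T_step = 0.1)
  fit <- stage_decompose(generate_turbidity(spec))
  # T02 - T01 = 5 < 2 sqrt(tau1 tau2) ~ 6.93
  expect_false(fit$separation_ok)
})

test_that("parameter recovery degrades gracefully under noise", {
  true <- c(T01 = 22, tau1 = 10, T02 = 30, tau2 = 1.2)
  errs <- matrix(NA_real_, nrow = 20, ncol = 4,
                 dimnames = list(NULL, names(true)))
  # for noisy curves the portrait is built with pre-smoothing, the
  # package's documented answer to noise-amplifying differentiation
  sm <- list(method = "savitzky_golay", window = 11, order = 2)
  for (seed in 1:20) {
    d <- generate_turbidity(two_stage_spec(noise_sd = 0.02, seed = seed))
    fit <- tryCatch(stage_decompose(d, smoothing = sm),
                    error = function(e) NULL)
    if (is.null(fit) || is.null(fit$model)) next
    cf <- coef(fit)[names(true)]
    errs[seed, ] <- abs(cf - true) / true
  }
  med <- apply(errs, 2, median, na.rm = TRUE)
  expect_true(all(med < 0.2))
})

test_that("decomposition rejects unusable inputs", {
  s <- temperature_series(1:10, rep(c(0, 1), 5)[1:10], "optical_density")
  expect_error(stage_decompose(s), "at least 20")
  flat <- temperature_series(seq(1, 30), rep(1, 30), "optical_density")
  expect_error(stage_decompose(flat), "amplitude")
  d <- generate_turbidity(two_stage_spec())
  expect_error(stage_decompose(d, portrait_mode = "inverse"), "heat_flow")
})

test_that("decomposition report serializes the fitted model", {
  fit <- stage_decompose(generate_turbidity(two_stage_spec()))
  js <- jsonlite::fromJSON(decomposition_report(fit))
  expect_equal(js$stage_count, 2)
  expect_true(js$separation_ok)
  expect_equal(js$model$T01, 22, tolerance = 0.1)
  expect_named(js$model, c("T01", "tau1", "T02", "tau2", "D0"))
})
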