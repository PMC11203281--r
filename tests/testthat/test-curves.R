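test_that("CSV reading sorts, validates and reports bad rows", {
  p <- write_csv_fixture(data.frame(temperature = c(30, 20, 25),
                                    value = c(0.9, 0.1, 0.5)))
  s <- read_temperature_series(p, "optical_density")
  expect_equal(s$temperature, c(20, 25, 30))
  expect_equal(s$value, c(0.1, 0.5, 0.9))
  expect_equal(s$kind, "optical_density")

  dup <- write_csv_fixture(data.frame(temperature = c(20, 20, 25),
                                      value = c(0.1, 0.2, 0.3)))
  expect_error(read_temperature_series(dup, "optical_density"), "20")

  short <- write_csv_fixture(data.frame(temperature = c(20, 25),
                                        value = c(0.1, 0.2)))
  expect_error(read_temperature_series(short, "optical_density"),
               "at least 3")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("temperature,value", "20,0.1", "25,abc", "30,0.3"), bad)
  expect_error(read_temperature_series(bad, "optical_density"), "row 2")
})

test_that("CSV writer round-trips through the reader, comments ignored", {
  s <- temperature_series(c(20, 25.5, 30), c(0.125, 0.5, 0.875),
                          "heat_flow", unit = "K")
  p <- tempfile(fileext = ".csv")
  write_temperature_series(s, p)
  expect_true(startsWith(readLines(p, n = 1), "#"))
  s2 <- read_temperature_series(p, "heat_flow", unit = "K")
  expect_equal(s2$temperature, s$temperature)
  expect_equal(s2$value, s$value)
})

test_that("transmittance transform maps amplitude onto the 0-100% scale", {
  Tv <- 1:5
  y <- c(0.2, 0.2, 1.2, 0.2, 0.2)   # baseline 0.2, one point at baseline+D0
  tt <- to_transmittance(temperature_series(Tv, y, "optical_density"))
  expect_equal(tt$value, c(100, 100, 0, 100, 100))
  expect_equal(tt$kind, "transmittance_pct")

  y2 <- c(0.2, 0.7, 1.2, 0.7, 0.2)  # midpoints at baseline + D0/2
  tt2 <- to_transmittance(temperature_series(Tv, y2, "optical_density"))
  expect_equal(tt2$value[c(2, 4)], c(50, 50))

  # sigmoid sample: the half-amplitude point sits at T0
  p <- stage_params("sigmoid", D0 = 1, T0 = 30, tau = 1.2)
  grid <- seq(18, 42, 0.5)           # includes T = 30 exactly
  d <- temperature_series(grid, eval_sigmoid(p, grid), "optical_density")
  tt3 <- to_transmittance(d, D0 = 1, baseline = 0)
  expect_equal(tt3$value[grid == 30], 50, tolerance = 1e-12)

  expect_error(
    to_transmittance(temperature_series(Tv, rep(1, 5), "optical_density")),
    "amplitude")
  expect_error(to_transmittance(d, D0 = -1), "positive")
})

test_that("transmittance transform is an affine bijection", {
  set.seed(7)
  y <- cumsum(abs(rnorm(40))) + 2
  d <- temperature_series(seq_along(y), y, "optical_density")
  tt <- to_transmittance(d)
  baseline <- min(y); D0 <- max(y) - min(y)
  y_back <- baseline + D0 * (1 - tt$value / 100)
  expect_equal(y_back, y, tolerance = 1e-12)
})

test_that("cumulative integral satisfies the basic quadrature identities", {
  Tv <- seq(20, 30, 0.5)
  cp <- temperature_series(Tv, rep(2, length(Tv)), "heat_flow")
  s <- cumulative_integral(cp, Tm = 20, method = "trapezoid")
  expect_equal(s$value[length(Tv)], 20)
  expect_equal(s$value[1], 0)
  expect_equal(s$kind, "integrated_enthalpy")

  # trapezoid is exact for a linear integrand
  Tv2 <- seq(0, 1, length.out = 41)
  cp2 <- temperature_series(Tv2, Tv2, "heat_flow")
  s2 <- cumulative_integral(cp2, method = "trapezoid")
  expect_equal(s2$value[41], 0.5, tolerance = 1e-15)

  expect_error(cumulative_integral(cp, Tm = 19), "outside")
  # S(Tm) = 0 for both rules; S non-decreasing for Cp >= 0
  for (m in c("trapezoid", "rectangle")) {
    si <- cumulative_integral(cp, Tm = 25, method = m)
    expect_equal(si$value[Tv == 25], 0)
    expect_true(all(diff(si$value) >= 0))
  }
})

test_that("trapezoid integration of a sigmoid derivative converges at O(h^2)", {
  p <- stage_params("sigmoid", D0 = 1, T0 = 30, tau = 1.2)
  err <- sapply(c(0.2, 0.1), function(h) {
    grid <- seq(18, 42, h)
    cp <- temperature_series(grid, model_derivative_oracle(p, grid),
                             "heat_flow")
    s <- cumulative_integral(cp)
    exact <- eval_sigmoid(p, grid) - eval_sigmoid(p, grid[1])
    max(abs(s$value - exact))
  })
  expect_lt(err[2], 1e-4)
  expect_gte(err[1] / err[2], 3)   # halving h gains at least a factor 3
})

test_that("normalized integral hits the 100/50/0 anchors", {
  Tv <- seq(0, 10, 1)
  s <- temperature_series(Tv, Tv, "integrated_enthalpy")  # S: 0 .. 10
  st <- to_normalized_integral(s)
  expect_equal(st$value[1], 100)
  expect_equal(st$value[Tv == 5], 50)
  expect_equal(st$value[11], 0)
  expect_error(to_normalized_integral(s, S0 = 0), "positive")
})

test_that("smoothing preserves grid and reduces noise", {
  Tv <- seq(0, 2 * pi, length.out = 201)
  clean <- sin(Tv)
  set.seed(11)
  noisy <- clean + rnorm(201, sd = 0.1)
  s <- temperature_series(Tv, noisy, "optical_density")

  expect_equal(smooth_series(s, "moving_average", window = 1)$value, noisy)
  const <- temperature_series(Tv, rep(4, 201), "optical_density")
  expect_equal(smooth_series(const, "moving_average", window = 9)$value,
               rep(4, 201))

  for (m in c("moving_average", "savitzky_golay")) {
    sm <- smooth_series(s, m, window = 7, order = 2)
    expect_equal(sm$temperature, Tv)
    expect_lt(var(sm$value - clean), var(noisy - clean))
  }
  expect_error(smooth_series(s, "moving_average", window = 4), "odd")
  expect_error(smooth_series(s, "moving_average", window = 301), "length")
})

test_that("series construction rejects malformed inputs", {
  expect_error(temperature_series(c(1, 2), c(1, 2), "optical_density"),
               "at least 3")
  expect_error(temperature_series(c(1, 2, 2), c(1, 2, 3), "optical_density"),
               "duplicate")
  expect_error(temperature_series(c(1, 2, NA), c(1, 2, 3), "optical_density"),
               "finite")
  expect_warning(temperature_series(1:3, c(-5, 50, 108), "transmittance_pct"),
                 "outside")
})
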