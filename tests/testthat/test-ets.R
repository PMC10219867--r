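test_that("initialisation recovers level, trend and seasonal structure", {
  # constant series: no trend, no seasonality
  init <- ets_init(rep(7, 96), ets_spec("additive", m = 24))
  expect_equal(init$level, 7)
  expect_equal(init$trend, 0)
  expect_equal(init$seasonal, rep(0, 24))

  # exactly periodic series decomposes exactly
  v <- c(10, 30, 20, 40)
  init <- ets_init(rep(v, 5), ets_spec("additive", m = 4))
  expect_equal(init$level, mean(v))
  expect_equal(init$trend, 0)
  expect_equal(init$seasonal, v - mean(v))

  # hand-evaluated multiplicative case
  init <- ets_init(c(10, 20, 10, 20, 10, 20), ets_spec("multiplicative", m = 2))
  expect_equal(init$level, 15)
  expect_equal(init$trend, 0)
  expect_equal(init$seasonal, c(2 / 3, 4 / 3))

  # normalisation invariants
  set.seed(5)
  y <- 50 + 10 * sin(2 * pi * (1:120) / 24) + rnorm(120)
  ia <- ets_init(y, ets_spec("additive", m = 24))
  im <- ets_init(y, ets_spec("multiplicative", m = 24))
  expect_equal(sum(ia$seasonal), 0)
  expect_equal(mean(im$seasonal), 1)
})

test_that("initialisation rejects short or non-positive input", {
  expect_error(ets_init(rep(5, 40), ets_spec("additive", m = 24)),
               "insufficient history")
  expect_error(ets_init(c(rep(5, 47), 0), ets_spec("multiplicative", m = 24)),
               "strictly positive")
})

test_that("an exact fixed point of the recursion leaves states untouched", {
  spec <- ets_spec("additive", m = 2)
  init <- list(level = 15, trend = 0, seasonal = c(-5, 5))
  y <- rep(c(10, 20), 20)
  for (a in c(0.1, 0.9)) {
    traj <- ets_smooth(y, spec, ets_params(a, 0.3, 0.7), init)
    expect_equal(traj$residual, rep(0, 40))
    expect_equal(traj$level, rep(15, 40))
    expect_equal(attr(traj, "s_final"), c(-5, 5))
  }
  # constant series fixed point
  traj <- ets_smooth(rep(3, 10), ets_spec("additive", m = 2),
                     ets_params(0.5, 0.5, 0.5),
                     list(level = 3, trend = 0, seasonal = c(0, 0)))
  expect_equal(traj$residual, rep(0, 10))
})

test_that("smoothing matches the independent recursion oracle on all variants", {
  set.seed(91)
  y <- pmax(50 + 12 * sin(2 * pi * (1:500) / 24) + rnorm(500, 0, 4), 1)
  for (variant in c("additive", "multiplicative", "damped")) {
    spec <- ets_spec(variant, m = 24)
    init <- ets_init(y, spec)
    phi <- if (variant == "damped") 0.92 else NULL
    params <- ets_params(0.35, 0.08, 0.2, phi)
    traj <- ets_smooth(y, spec, params, init)
    orc <- hw_oracle(y, 24, 0.35, 0.08, 0.2, if (is.null(phi)) 1 else phi,
                     init$level, init$trend, init$seasonal, variant)
    expect_equal(traj$level, orc$level, tolerance = 1e-10)
    expect_equal(traj$trend, orc$trend, tolerance = 1e-10)
    expect_equal(traj$seasonal, orc$seasonal, tolerance = 1e-10)
    expect_equal(traj$residual, orc$residuals, tolerance = 1e-10)
  }
})

test_that("multiplicative recursion flags a degenerate state", {
  spec <- ets_spec("multiplicative", m = 2)
  init <- list(level = 1, trend = -1, seasonal = c(1, 1)) # level+trend = 0
  expect_error(ets_smooth(c(1, 2, 3, 4), spec, ets_params(0.5, 0.5, 0.5), init),
               "zero")
})

test_that("forecast equations evaluate exactly", {
  # additive: l + k b + s
  spec <- ets_spec("additive", m = 24)
  params <- ets_params(0.2, 0.1, 0.1)
  s <- rep(0, 24); s[2] <- 10
  state <- list(level = 70, trend = 1, seasonal = s)
  fc <- edcast:::forecast_from_state(spec, params, state, 3)
  expect_equal(fc$yhat[2], 70 + 2 * 1 + 10)

  # constant model: h copies of the constant
  fit <- ets_fit(hourly_ts(rep(42, 120)), ets_spec("additive", m = 24))
  expect_equal(ets_forecast(fit, 24)$yhat, rep(42, 24))

  # damped forecasts converge to l + b phi / (1 - phi) + s
  spec <- ets_spec("damped", m = 24)
  params <- ets_params(0.2, 0.1, 0.1, phi = 0.9)
  state <- list(level = 100, trend = 5, seasonal = rep(0, 24))
  fc <- edcast:::forecast_from_state(spec, params, state, 500)
  expect_equal(fc$yhat[500], 100 + 5 * 0.9 / (1 - 0.9), tolerance = 1e-6)
  # bounded at every horizon, while additive trend grows linearly
  expect_lt(max(fc$yhat), 100 + 5 * 0.9 / (1 - 0.9) + 1e-6)
  fc_add <- edcast:::forecast_from_state(ets_spec("additive", m = 24),
                                         ets_params(0.2, 0.1, 0.1),
                                         state, 500)
  expect_equal(diff(fc_add$yhat[400:500]), rep(5, 100))
})

test_that("noiseless periodic series are forecast with zero error", {
  pattern <- c(30, 25, 22, 20, 20, 24, 35, 50, 62, 70, 74, 72,
               66, 60, 55, 52, 50, 49, 48, 46, 42, 38, 34, 32)
  y <- rep(pattern, 8)
  for (variant in c("additive", "multiplicative", "damped")) {
    fit <- ets_fit(hourly_ts(y), ets_spec(variant, m = 24))
    fc <- ets_forecast(fit, 24)
    expect_equal(fc$yhat, pattern, tolerance = 1e-4)
  }
})

test_that("additive forecasts are shift-equivariant, multiplicative scale-equivariant", {
  set.seed(12)
  y <- 40 + 15 * sin(2 * pi * (1:240) / 24) + rnorm(240, 0, 2)
  f0 <- ets_forecast(ets_fit(hourly_ts(y), ets_spec("additive")), 24)$yhat
  f_shift <- ets_forecast(ets_fit(hourly_ts(y + 100), ets_spec("additive")),
                          24)$yhat
  expect_equal(f_shift, f0 + 100, tolerance = 1e-3)

  g0 <- ets_forecast(ets_fit(hourly_ts(y), ets_spec("multiplicative")),
                     24)$yhat
  g_scale <- ets_forecast(ets_fit(hourly_ts(3 * y),
                                  ets_spec("multiplicative")), 24)$yhat
  expect_equal(g_scale, 3 * g0, tolerance = 1e-2)
})

test_that("multiplicative fits tolerate zeros through the offset policy", {
  set.seed(3)
  y <- rpois(240, rep(c(0.3, 0.3, 2, 8, 10, 6), each = 4))
  expect_true(any(y == 0))
  fit <- ets_fit(hourly_ts(y), ets_spec("multiplicative", m = 24))
  fc <- ets_forecast(fit, 24)
  expect_true(all(fc$yhat >= 0))
  expect_equal(fit$offset, 0.5)
})

test_that("tidy and glance summarise a fit", {
  fit <- ets_fit(hourly_ts(rep(c(10, 20), 30)), ets_spec("damped", m = 2))
  td <- tidy(fit)
  expect_setequal(td$term, c("alpha", "beta", "gamma", "phi"))
  g <- glance(fit)
  expect_equal(g$n_train, 60)
  expect_equal(g$variant, "damped")
})
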