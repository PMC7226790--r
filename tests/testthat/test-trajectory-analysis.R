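test_that("a synthetic damped cosine is quantified to known accuracy", {
  t <- seq(0, 40, by = 0.01)
  x <- exp(-0.1 * t) * cos(2 * pi * 0.5 * t)
  tr <- data.frame(t = t, Taut = x)
  om <- oscillation_metrics(tr, "Taut")
  expect_lt(abs(om$frequency - 0.5) / 0.5, 0.02)
  expect_lt(abs(om$decay_rate - (-0.1)) / 0.1, 0.05)
  expect_true(all(diff(om$peak_times) > 0))
  expect_lt(om$amplitude_ratio, 0.5)
})

test_that("a constant series yields a null oscillation result", {
  tr <- data.frame(t = seq(0, 10, by = 0.05), Taut = rep(3, 201))
  om <- oscillation_metrics(tr, "Taut")
  expect_identical(om$frequency, 0)
  expect_identical(om$n_peaks, 0L)
  expect_identical(om$amplitude_ratio, 0)
  expect_error(oscillation_metrics(tr[1:10, ], "Taut"), "64")
  expect_error(oscillation_metrics(tr, "bogus"), "unknown compartment")
})

test_that("metrics are deterministic functions of the trajectory", {
  p <- tab1_params()
  tr <- em_simulate(p, default_init(), seq(0, 30, by = 1e-3), seed = 9)
  m1 <- oscillation_metrics(tr, "Taut", window = c(5, 30))
  m2 <- oscillation_metrics(tr, "Taut", window = c(5, 30))
  expect_identical(m1, m2)
})

test_that("deterministic oscillations damp while stochastic paths sustain", {
  p <- tab1_params()
  tr_ode <- simulate_ode(p, default_init(), seq(0, 100, by = 0.02))
  om_ode <- oscillation_metrics(tr_ode, "Taut", window = c(10, 100))
  expect_lt(om_ode$amplitude_ratio, 0.5)
  tr_sde <- em_simulate(p, default_init(), seq(0, 100, by = 1e-3), seed = 17)
  om_sde <- oscillation_metrics(tr_sde, "Taut", window = c(10, 100))
  expect_gte(om_sde$amplitude_ratio, 0.5)
})

test_that("the stochastic oscillation frequency sits at the linear resonance", {
  p <- regime_point(delta = 2.22e-6)
  ss <- find_interior_steady_state(p)
  f_res <- abs(Im(ss$eigenvalues[1])) / (2 * pi)
  tr <- em_simulate(p, ss$state, seq(0, 200, by = 1e-3), seed = 3)
  om <- oscillation_metrics(tr, "Taut", window = c(20, 200))
  expect_lt(abs(om$frequency - f_res) / f_res, 0.25)
})

test_that("ensemble bands behave degenerately for one path and cover the ODE", {
  p <- tab1_params()
  times <- seq(0, 2, by = 1e-3)
  tr <- simulate_ode(p, default_init(), seq(0, 2, by = 0.05))
  ens1 <- sde_ensemble(p, default_init(), times, n_real = 1, seed = 2,
                       record_every = 50)
  bs1 <- band_statistics(ens1, tr)
  expect_equal(bs1$mean_band_width, 0)
  expect_true(all(bs1$band$inside %in% c(TRUE, FALSE)))
  ens <- sde_ensemble(p, default_init(), seq(0, 30, by = 1e-3), n_real = 200,
                      seed = 8, record_every = 250)
  tr30 <- simulate_ode(p, default_init(), ens$t)
  bs <- band_statistics(ens, tr30, after = 5)
  expect_gte(bs$coverage, 0.6)
  # late-time band width approaches the stationary linear-noise prediction
  cv <- stationary_covariance(p)
  late <- utils::tail(bs$band, 40)
  width <- mean(late$upper - late$lower) / 2
  expect_lt(abs(width - sqrt(cv$var_Taut)) / sqrt(cv$var_Taut), 0.2)
})

test_that("scale-and-offset fitting recovers known transformations", {
  p <- tab1_params()
  tr <- simulate_ode(p, default_init(), seq(0, 60, by = 0.05))
  attr(tr, "params") <- p
  # noiseless counts manufactured from the model curve at k = 3, offset 5
  curve <- function(day)
    3 * stats::approx(tr$t, tr$Taut, xout = pmax(day - 5, 0), rule = 2)$y
  cfg <- eau_config(noise_sd = 0,
                    days = c(0, 6, 8, 10, 12, 15, 20, 26, 33, 40))
  counts <- generate_eau_counts(cfg, mean_curve = curve)
  fit <- fit_scale_to_counts(tr, counts)
  expect_lt(abs(fit$k - 3) / 3, 0.01)
  expect_lt(abs(fit$offset - 5), 0.25)
  expect_equal(fit$params$lambda_in, fit$k * p$lambda_in)
  # identical series: k = 1, offset 0, essentially zero residual
  cfg0 <- eau_config(noise_sd = 0, days = c(5, 10, 15, 20, 30, 40))
  counts0 <- generate_eau_counts(cfg0, mean_curve = function(day)
    stats::approx(tr$t, tr$Taut, xout = day, rule = 2)$y)
  fit0 <- fit_scale_to_counts(tr, counts0, offset_range = c(0, 10))
  expect_lt(abs(fit0$k - 1), 0.01)
  expect_lt(abs(fit0$offset), 0.25)
  expect_lt(fit0$residual, 1)  # only integer rounding of counts remains
  # on noisy synthetic data the fit dominates the untransformed model
  counts_n <- generate_eau_counts(eau_config(noise_sd = 0.3))
  fitn <- fit_scale_to_counts(tr, counts_n)
  agg <- stats::aggregate(cd4_count ~ day, as.data.frame(counts_n), mean)
  sse0 <- sum((agg$cd4_count -
               stats::approx(tr$t, tr$Taut, xout = agg$day, rule = 2)$y)^2)
  expect_lt(fitn$residual^2 * nrow(agg), sse0 + 1e-9)
  expect_error(fit_scale_to_counts(tr, counts_n[counts_n$day == 0, ]),
               "4 distinct days")
})
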