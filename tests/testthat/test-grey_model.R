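test_that("fit_gm11 recovers the closed-form parameters of geometric series", {
  # a geometric series with ratio q satisfies the grey difference equation
  # exactly with a = -2(q-1)/(q+1), u = 2 x0(1) / (q+1)
  for (q in c(1.02, 1.05, 1.08, 1.10, 1.15)) {
    s <- 100 * q^(0:9)
    fit <- fit_gm11(s)
    expect_equal(fit$a, -2 * (q - 1) / (q + 1), tolerance = 1e-9)
    expect_equal(fit$u, 2 * 100 / (q + 1), tolerance = 1e-9)
    expect_lt(max(abs(fit$residuals)), 1e-9 * max(s))
  }
  # independent oracle: brute-force least squares on the design matrix
  set.seed(9)
  s <- 100 * 1.06^(0:11) * exp(rnorm(12, 0, 0.03))
  fit <- fit_gm11(s)
  x1 <- cumsum(s)
  B <- cbind(-(x1[-1] + x1[-12]) / 2, 1)
  beta <- solve(t(B) %*% B, t(B) %*% s[-1])
  expect_equal(fit$a, beta[1, 1], tolerance = 1e-10)
  expect_equal(fit$u, beta[2, 1], tolerance = 1e-10)
})

test_that("fit_gm11 rejects degenerate inputs", {
  expect_error(fit_gm11(c(100, 100, 100, 100)), "degenerate")
  expect_error(fit_gm11(c(100, 105, 110)), "at least 4")
  expect_error(fit_gm11(c(100, 0, 110, 120)), "strictly positive")
  expect_warning(fit_gm11(c(100, 140, 120, 160, 180)), "not monotone")
})

test_that("gm11 accumulation and fitted-series structure hold", {
  s <- make_grey_consistent_series(-0.07, 120, 80, 9)
  fit <- fit_gm11(s)
  expect_equal(fit$x1, cumsum(s))
  expect_equal(fit$fitted[1], s[1])
  expect_equal(length(fit$fitted), length(s))
})

test_that("scale equivariance: a invariant, u and forecasts scale", {
  set.seed(3)
  s <- 50 * 1.07^(0:9) * exp(rnorm(10, 0, 0.02))
  f1 <- fit_gm11(s)
  f2 <- fit_gm11(1000 * s)
  expect_equal(f2$a, f1$a, tolerance = 1e-10)
  expect_equal(f2$u, 1000 * f1$u, tolerance = 1e-6)
  expect_equal(gm11_forecast(f2, 4)$point, 1000 * gm11_forecast(f1, 4)$point,
               tolerance = 1e-8)
  d1 <- gm11_diagnose(f1); d2 <- gm11_diagnose(f2)
  expect_equal(d2$C, d1$C, tolerance = 1e-10)
  expect_equal(d2$P, d1$P)
  expect_equal(d2$grade, d1$grade)
})

test_that("gm11_forecast is monotone in the direction implied by a", {
  s <- make_grey_consistent_series(-0.06, 100, 90, 8)   # a < 0: growth
  fit <- fit_gm11(s)
  fc <- gm11_forecast(fit, 6)
  expect_true(all(diff(fc$point) > 0))
  s_dec <- make_grey_consistent_series(0.06, 300, 200, 8)  # a > 0: decay
  fc_dec <- gm11_forecast(suppressWarnings(fit_gm11(s_dec)), 6)
  expect_true(all(diff(fc_dec$point) < 0))
  # one-step-ahead of a q = 1.05 geometric series within 0.5% of 100 q^N
  fit_g <- fit_gm11(100 * 1.05^(0:9))
  expect_equal(gm11_forecast(fit_g, 1)$point, 100 * 1.05^10, tolerance = 5e-3)
  expect_error(gm11_forecast(fit, 0), "horizon")
  fc_y <- gm11_forecast(fit, 3, start_year = 2023)
  expect_equal(fc_y$year, 2023:2025)
})

test_that("gm11_diagnose grades a perfect fit level 1", {
  fit <- fit_gm11(make_grey_consistent_series(-0.05, 100, 100, 8))
  d <- gm11_diagnose(fit)
  expect_equal(d$C, 0, tolerance = 1e-9)
  expect_equal(d$P, 1)
  expect_equal(d$grade, 1L)
  expect_true(d$extrapolation_allowed)
})

test_that("gm11_grade reproduces the band table with the worse-of rule", {
  expect_equal(gm11_grade(0.30, 0.96), 1L)
  expect_equal(gm11_grade(0.40, 0.90), 2L)
  expect_equal(gm11_grade(0.55, 0.75), 3L)
  expect_equal(gm11_grade(0.70, 0.50), 4L)
  # disagreeing bands take the worse grade
  expect_equal(gm11_grade(0.30, 0.75), 3L)
  expect_equal(gm11_grade(0.60, 0.99), 3L)
  expect_equal(gm11_grade(0.10, 0.10), 4L)
  # brute-force check over the full band table
  C_rep <- c(0.1, 0.4, 0.55, 0.9); C_band <- 1:4
  P_rep <- c(0.99, 0.9, 0.75, 0.3); P_band <- 1:4
  for (i in 1:4) for (j in 1:4) {
    expect_equal(gm11_grade(C_rep[i], P_rep[j]), max(C_band[i], P_band[j]))
  }
  expect_error(gm11_grade(-0.1, 0.5), "C >= 0")
})

test_that("heavy-noise series grade poorly and block extrapolation", {
  noisy <- make_noise_series(n = 14, seed = 2024)
  fit <- suppressWarnings(fit_gm11(noisy))
  d <- gm11_diagnose(fit)
  expect_gte(d$grade, 3L)
  expect_false(d$extrapolation_allowed)
})

test_that("sample-sd option changes C but not the structure", {
  set.seed(8)
  s <- 100 * 1.06^(0:9) * exp(rnorm(10, 0, 0.05))
  fit <- suppressWarnings(fit_gm11(s))
  dp <- gm11_diagnose(fit, "population")
  ds <- gm11_diagnose(fit, "sample")
  expect_equal(ds$C, dp$C, tolerance = 1e-6)  # ratio: denominators cancel
  expect_true(ds$grade %in% 1:4)
})
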