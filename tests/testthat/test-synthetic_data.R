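test_that("default config yields an 11x20 panel passing strict validation", {
  panel <- generate_panel(synthetic_config(seed = 1))
  expect_equal(nrow(panel), 220)
  expect_equal(length(unique(panel$region_id)), 11)
  expect_equal(sort(unique(panel$year)), 2003:2022)
  expect_true(all(panel$stratum == "whole"))
  expect_silent(validate_panel(as.data.frame(panel), strict = TRUE))
  # pooled average annual growth echoes the configured 7.8%/yr profile
  tot <- aggregate(nurses ~ year, as.data.frame(panel), sum)
  g <- average_annual_growth_rate(tot$nurses[1], tot$nurses[20], 19)
  expect_lt(abs(g - 0.078), 0.01)
})

test_that("generation is deterministic and region substreams are stable", {
  a <- generate_panel(synthetic_config(seed = 7))
  b <- generate_panel(synthetic_config(seed = 7))
  expect_identical(as.data.frame(a), as.data.frame(b))
  # adding a region leaves the existing regions' draws untouched
  big <- generate_panel(synthetic_config(n_regions = 12, seed = 7))
  keep <- as.data.frame(big)[big$region_id %in% unique(a$region_id), ]
  rownames(keep) <- NULL
  expect_identical(keep, as.data.frame(a))
})

test_that("zero dispersion and zero noise give equal densities", {
  cfg <- synthetic_config(density_sigma = 0, noise_sd = 0, growth_sd = 0,
                          round_counts = FALSE, seed = 3)
  panel <- generate_panel(cfg)
  g <- panel_gini(panel, "population")
  expect_true(all(abs(g$gini) < 1e-12))
  # with integer rounding (the publishing convention) Gini is ~0 within
  # rounding tolerance, not exactly 0
  gr <- panel_gini(generate_panel(synthetic_config(density_sigma = 0,
                                                   noise_sd = 0, growth_sd = 0,
                                                   seed = 3)), "population")
  expect_true(all(gr$gini < 1e-3))
})

test_that("increasing density dispersion increases mean population Gini", {
  mean_gini <- function(sig) {
    g <- vapply(1:20, function(s) {
      p <- generate_panel(synthetic_config(density_sigma = sig, seed = s,
                                           years = 2003:2006, n_regions = 11))
      panel_gini(p, "population")$gini[1]
    }, 0)
    mean(g)
  }
  m <- vapply(c(0.1, 0.3, 0.6), mean_gini, 0)
  expect_true(all(diff(m) > 0))
})

test_that("ratio trajectories are respected at the endpoints", {
  cfg <- synthetic_config(noise_sd = 0, growth_sd = 0, seed = 2)
  ind <- derive_indicators(generate_panel(cfg))
  first <- ind[ind$year == 2003, ]
  last <- ind[ind$year == 2022, ]
  expect_equal(mean(first$nurses_per_doctor), 0.70, tolerance = 0.01)
  expect_equal(mean(last$nurses_per_doctor), 1.27, tolerance = 0.01)
  expect_equal(mean(first$nurses_per_bed), 0.41, tolerance = 0.01)
  expect_equal(mean(last$nurses_per_bed), 0.46, tolerance = 0.01)
  expect_true(all(ind$nurse_share > 0 & ind$nurse_share < 1))
})

test_that("make_two_point_fixture is an exact closed-form oracle", {
  fx <- make_two_point_fixture(0.5, 0)
  expect_equal(fx$expected_gini, 0.5)
  cv <- build_lorenz(fx$basis_weight, fx$resource)
  expect_equal(cv$points$cum_basis_share, c(0, 0.5, 1))
  expect_equal(gini_paper(cv), 0.5, tolerance = 1e-14)
  fx2 <- make_two_point_fixture(0.7, 0.3)
  expect_equal(fx2$expected_gini, 0.4)
  fx3 <- make_two_point_fixture(0.4, 0.4)
  expect_equal(gini_paper(build_lorenz(fx3$basis_weight, fx3$resource)), 0,
               tolerance = 1e-14)
  expect_error(make_two_point_fixture(0.3, 0.5), "ranked ascending")
  expect_error(make_two_point_fixture(1.2, 0.5), "w must")
})

test_that("make_grey_consistent_series round-trips through fit_gm11", {
  s <- make_grey_consistent_series(-0.05, 100, 100, 8)
  fit <- fit_gm11(s)
  expect_equal(fit$a, -0.05, tolerance = 1e-9)
  expect_equal(fit$u, 100, tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  expect_error(make_grey_consistent_series(-0.05, 100, 100, 3), "N must")
  expect_error(make_grey_consistent_series(0, 100, 100, 8), "degenerate")
  expect_error(make_grey_consistent_series(0.5, 10, 30, 10), "non-positive")
})

test_that("config validation rejects impossible parameters", {
  expect_error(synthetic_config(n_regions = 1, seed = 1))
  expect_error(synthetic_config(nurse_share_path = c(0.5, 1.2), seed = 1))
  expect_error(synthetic_config(seed = NULL), "seed")
})
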