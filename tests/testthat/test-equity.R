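test_that("build_lorenz produces the expected cumulative-share geometry", {
  # perfect equality: the diagonal
  cv <- build_lorenz(c(1, 1), c(5, 5))
  expect_equal(cv$points$cum_basis_share, c(0, 0.5, 1))
  expect_equal(cv$points$cum_resource_share, c(0, 0.5, 1))
  # maximal two-region inequality
  cv <- build_lorenz(c(1, 1), c(0, 10))
  expect_equal(cv$points$cum_resource_share, c(0, 0, 1))
  # three equal regions, nurses 1,2,3
  cv <- build_lorenz(c(1, 1, 1), c(1, 2, 3))
  expect_equal(cv$points$cum_basis_share, c(0, 1, 2, 3) / 3)
  expect_equal(cv$points$cum_resource_share, c(0, 1 / 6, 1 / 2, 1))
  # curve invariants under random input
  set.seed(11)
  for (i in 1:25) {
    rg <- random_regions()
    cv <- build_lorenz(rg$weights, rg$resource)
    p <- cv$points
    expect_equal(p$cum_basis_share[1], 0)
    expect_equal(p$cum_resource_share[nrow(p)], 1)
    expect_true(all(diff(p$cum_basis_share) >= 0))
    expect_true(all(diff(p$cum_resource_share) >= -1e-15))
    expect_true(all(p$cum_resource_share <= p$cum_basis_share + 1e-12))
  }
  expect_error(build_lorenz(c(1, 1), c(0, 0)), "total resource")
  expect_error(build_lorenz(c(1, -1), c(1, 1)), "basis weights")
  expect_error(build_lorenz(c(1, 1), c(-1, 2)), "resource")
})

test_that("gini_paper matches frozen closed-form values", {
  expect_equal(gini_paper(build_lorenz(c(1, 1), c(5, 5))), 0)
  expect_equal(gini_paper(build_lorenz(c(1, 1), c(0, 10))), 0.5)
  expect_equal(gini_paper(build_lorenz(c(1, 1, 1), c(1, 2, 3))), 2 / 9)
  expect_equal(gini_trapezoid(build_lorenz(c(1, 1), c(0, 10))), 0.5)
})

test_that("the two Gini routes agree and are permutation invariant", {
  set.seed(23)
  for (i in 1:50) {
    rg <- random_regions()
    for (basis in c("population", "area")) {
      cv <- build_lorenz(rg$weights, rg$resource, basis = basis)
      expect_lt(abs(gini_paper(cv) - gini_trapezoid(cv)), 1e-12)
    }
    perm <- sample(length(rg$weights))
    cv1 <- build_lorenz(rg$weights, rg$resource)
    cv2 <- build_lorenz(rg$weights[perm], rg$resource[perm])
    expect_equal(gini_paper(cv2), gini_paper(cv1))
  }
})

test_that("Gini and Theil obey the transfer principle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    w <- rep(1, n)
    res <- round(rlnorm(n, log(100), 0.7)) + 1
    g0 <- gini_paper(build_lorenz(w, res))
    t0 <- theil_total(res)
    # move resource from the densest to the sparsest region
    hi <- which.max(res); lo <- which.min(res)
    amt <- (res[hi] - res[lo]) * 0.3
    res2 <- res; res2[hi] <- res2[hi] - amt; res2[lo] <- res2[lo] + amt
    expect_lte(gini_paper(build_lorenz(w, res2)), g0 + 1e-12)
    expect_lte(theil_total(res2), t0 + 1e-12)
  }
})

test_that("classify_gini implements the fairness bands", {
  expect_equal(as.character(classify_gini(c(0, 0.19, 0.2, 0.29, 0.3, 0.39,
                                            0.4, 0.6, 0.61, 0.9))),
               c("absolute_fairness", "absolute_fairness",
                 "moderate_fairness", "moderate_fairness",
                 "relative_fairness", "relative_fairness",
                 "inequality_warning", "inequality_warning",
                 "high_inequality", "high_inequality"))
  expect_error(classify_gini(1), "\\[0, 1\\)")
  expect_error(classify_gini(-0.1), "\\[0, 1\\)")
})

test_that("theil_total matches frozen values and scale invariance", {
  expect_equal(theil_total(c(20, 20, 20)), 0)
  # (1/3)(0.5 ln 0.5 + 0.5 ln 0.5 + 2 ln 2)
  expect_equal(theil_total(c(10, 10, 40)),
               (2 * 0.5 * log(0.5) + 2 * log(2)) / 3)
  expect_equal(round(theil_total(c(10, 10, 40)), 5), 0.23105)
  set.seed(5)
  x <- rlnorm(12, log(50), 0.6)
  for (c0 in c(0.1, 7, 1e3)) {
    expect_equal(theil_total(c0 * x), theil_total(x))
  }
  # zero counts contribute 0 (x ln x -> 0 limit)
  expect_equal(theil_total(c(0, 10, 20)),
               (1 * log(1) + 2 * log(2)) / 3)
  expect_error(theil_total(c(0, 0)), "all counts are zero")
})

test_that("theil_decompose satisfies the additive identity", {
  # one group: all inequality is within
  td <- theil_decompose(c(10, 10, 40), rep("g", 3))
  expect_equal(td$between, 0)
  expect_equal(td$within, td$total)
  # internally equal groups: all inequality is between
  td <- theil_decompose(c(10, 10, 40, 40), c("a", "a", "b", "b"))
  expect_equal(td$within, 0)
  expect_equal(td$total, td$within + td$between, tolerance = 1e-14)
  # direct evaluation of the decomposition formulas on (10,10,40)|{1,2},{3}
  cnt <- c(10, 10, 40); grp <- c("p1", "p1", "p2")
  td <- theil_decompose(cnt, grp)
  S <- c(20, 40) / 60; P <- c(2, 1) / 3
  TB <- sum(S * log(S / P))
  Tw <- S[1] * theil_total(c(10, 10)) + S[2] * 0
  expect_equal(td$between, TB)
  expect_equal(td$within, Tw)
  expect_equal(td$total, theil_total(cnt))
  expect_lt(abs(td$total - (td$within + td$between)), 1e-12)
  expect_equal(td$contribution_within + td$contribution_between, 1)
  expect_error(theil_decompose(c(1, 2), c("a", NA)), "unassigned")
})

test_that("decomposition components stay non-negative over random groupings", {
  set.seed(47)
  for (i in 1:40) {
    rg <- random_regions()
    m <- sample(1:4, 1)
    grp <- sample(letters[1:m], length(rg$resource), replace = TRUE)
    if (sum(rg$resource) == 0) next
    td <- theil_decompose(rg$resource, grp)
    expect_gte(td$within, -1e-12)
    expect_gte(td$between, -1e-12)
    expect_lt(abs(td$total - (td$within + td$between)), 1e-12)
    if (td$total > 0) {
      expect_equal(td$contribution_within + td$contribution_between, 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("panel_gini and panel_theil aggregate per year", {
  panel <- generate_panel(synthetic_config(seed = 4))
  g <- panel_gini(panel, "population")
  expect_equal(nrow(g), 20)
  expect_true(all(g$gini >= 0 & g$gini < 1))
  groups <- setNames(rep(c("north", "south"), length.out = 11),
                     sprintf("region_%02d", 1:11))
  th <- panel_theil(panel, groups = groups)
  expect_equal(nrow(th), 20)
  expect_true(all(abs(th$total - (th$within + th$between)) < 1e-12))
  expect_error(panel_theil(panel, groups = groups[-1]), "does not cover")
})
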