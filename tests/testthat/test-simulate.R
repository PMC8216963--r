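test_that("Poisson simulator matches its moments and handles edge cases", {
  w <- pp_window(0, 200, 0, 200)
  expect_equal(n_points(simulate_poisson_pattern(0, w, seed = 1)), 0L)
  expect_error(simulate_poisson_pattern(-1, w), "non-negative")

  p1 <- simulate_poisson_pattern(0.01, w, seed = 42)
  p2 <- simulate_poisson_pattern(0.01, w, seed = 42)
  expect_identical(p1, p2)

  # Monte-Carlo mean count: 500 replicates of a rate-400 process
  set.seed(7)
  counts <- replicate(500, n_points(simulate_poisson_pattern(0.01, w)))
  se <- sd(counts) / sqrt(500)
  expect_lt(abs(mean(counts) - 400), 3 * se)
})

test_that("Thomas simulator reproduces expected counts and clustering", {
  w <- pp_window(0, 1000, 0, 500)
  expect_error(simulate_thomas_pattern(0, 5, 10, w), "positive")

  # expected count = kappa * mu_off * area = 5000
  set.seed(3)
  counts <- replicate(20, n_points(simulate_thomas_pattern(5e-4, 10, 20, w)))
  se <- sd(counts) / sqrt(20)
  expect_lt(abs(mean(counts) - 5000), 3 * se)

  # strong small-scale clustering: mean univariate pcf at r = 5 well above 1
  wsq <- pp_window(0, 300, 0, 300)
  set.seed(8)
  g5 <- replicate(20, {
    p <- simulate_thomas_pattern(5e-4, 5, 20, wsq)
    unname(estimate_bivariate_pcf(p, p, r = 5))
  })
  expect_gt(mean(g5), 1.5)

  # diffuse clusters are statistically indistinguishable from Poisson
  set.seed(9)
  g10 <- replicate(20, {
    p <- simulate_thomas_pattern(0.01, 80, 1, wsq)
    unname(estimate_bivariate_pcf(p, p, r = 10))
  })
  expect_lt(abs(mean(g10) - 1), 0.1)
})

test_that("community simulator is deterministic and respects its contracts", {
  cfg <- scenario_config("neutral", n_species = 5, n_stems = 40, seed = 99)
  com1 <- simulate_community(cfg)
  com2 <- simulate_community(cfg)
  expect_identical(com1, com2)

  w <- cfg$window
  expect_true(all(com1$census$x >= w$x_min & com1$census$x <= w$x_max))
  expect_true(all(com1$census$y >= w$y_min & com1$census$y <= w$y_max))
  # no thinning under neutrality: abundances match the configuration
  expect_equal(nrow(com1$census), 5 * 40)
  # both life-stage classes populated
  expect_gt(sum(com1$census$dbh >= 1 & com1$census$dbh <= 3), 0)
  expect_gt(sum(com1$census$dbh > 10), 0)
  expect_true(all(com1$census$dbh > 0))
  # trait table: one positive row per species
  expect_equal(nrow(com1$traits), 5)
  expect_true(all(as.matrix(com1$traits[, -1]) > 0))
  expect_equal(com1$truth$scenario, "neutral")

  expect_error(scenario_config("no_such_mechanism"), "arg")
})

test_that("interaction scenarios only remove stems", {
  for (scn in c("filtering", "hierarchical", "limiting_similarity")) {
    com <- simulate_community(scenario_config(scn, n_species = 6,
                                              n_stems = 50, strength = 3,
                                              seed = 21))
    expect_lte(nrow(com$census), 6 * 50)
    expect_gt(nrow(com$census), 0)
    kept <- table(com$census$species_id)
    expect_true(all(kept <= 50))
  }
})

test_that("habitat covariate is smooth, bounded and periodic", {
  w <- pp_window(0, 250, 0, 250)
  x <- runif(100, 0, 250)
  y <- runif(100, 0, 250)
  e <- habitat_field(x, y, w, wavelength = 80, amplitude = 1)
  expect_true(all(abs(e) <= 1))
  expect_equal(habitat_field(x + 80, y, w, 80), habitat_field(x, y, w, 80),
               tolerance = 1e-9)
})
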