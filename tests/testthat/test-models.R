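# simulate data from the per-focal random-slope model
# z = a + a_i + (b + b_i) x + e
sim_eq_data <- function(n_focal, n_per, a = 0, b = -0.5, sd_a = 0.2,
                        sd_b = 0.2, sd_e = 1) {
  focal <- rep(sprintf("f%02d", seq_len(n_focal)), each = n_per)
  ai <- rnorm(n_focal, 0, sd_a)
  bi <- rnorm(n_focal, 0, sd_b)
  x <- rnorm(n_focal * n_per)
  idx <- rep(seq_len(n_focal), each = n_per)
  z <- a + ai[idx] + (b + bi[idx]) * x + rnorm(n_focal * n_per, 0, sd_e)
  data.frame(focal = focal, z = z, absolute = x)
}

test_that("mixed model agrees with OLS when random effects vanish", {
  set.seed(100)
  dat <- sim_eq_data(20, 40, a = 0.3, b = -0.5, sd_a = 0, sd_b = 0,
                     sd_e = 0.5)
  fit <- fit_mixed_model(dat, "absolute")
  ols <- lm(z ~ absolute, data = dat)
  expect_equal(unname(fit$fixed), unname(coef(ols)), tolerance = 0.02)
})

test_that("mixed model recovers generator parameters without gross bias", {
  set.seed(101)
  bhat <- replicate(10, {
    dat <- sim_eq_data(30, 30)
    fit_mixed_model(dat, "absolute")$fixed[["absolute"]]
  })
  expect_lt(abs(mean(bhat) + 0.5), 0.08)
})

test_that("degenerate model inputs raise errors", {
  set.seed(1)
  dat <- sim_eq_data(5, 10)
  dat$absolute <- 0
  expect_error(fit_mixed_model(dat, "absolute"), "degenerate predictor")
  one <- sim_eq_data(1, 10)
  expect_error(fit_mixed_model(one, "absolute"), "two focal species")
})

test_that("per-focal slopes are fixed plus predicted random deviations", {
  set.seed(102)
  dat <- sim_eq_data(25, 40, sd_b = 0.3)
  fit <- fit_mixed_model(dat, "absolute")
  sl <- focal_species_slopes(fit)
  expect_length(sl, 25)
  expect_equal(sort(names(sl)), sort(unique(dat$focal)))
  # balanced groups: the mean total slope stays close to the fixed slope
  expect_equal(mean(sl), unname(fit$fixed[["absolute"]]), tolerance = 0.05)

  # no random-slope variability: every species' slope collapses to b
  set.seed(103)
  flat <- sim_eq_data(20, 40, sd_b = 0, sd_e = 0.3)
  f2 <- fit_mixed_model(flat, "absolute")
  s2 <- focal_species_slopes(f2)
  expect_lt(max(abs(s2 - f2$fixed[["absolute"]])), 0.1)
})

test_that("conditional R-squared matches its variance-partition oracle", {
  set.seed(104)
  # known components: var_f = b^2, var_r = sd_a^2 + sd_b^2 (x ~ N(0,1)),
  # residual sd_e^2
  dat <- sim_eq_data(60, 60, b = -0.6, sd_a = 0.3, sd_b = 0.3, sd_e = 0.8)
  fit <- fit_mixed_model(dat, "absolute")
  theo <- (0.36 + 0.09 + 0.09) / (0.36 + 0.09 + 0.09 + 0.64)
  expect_equal(fit$r2c, theo, tolerance = 0.2)
  expect_gte(fit$r2c, 0)
  expect_lte(fit$r2c, 1)

  # near-zero residual noise drives R2c towards one
  set.seed(105)
  tight <- sim_eq_data(15, 30, sd_e = 0.01)
  expect_gt(fit_mixed_model(tight, "absolute")$r2c, 0.99)

  # null generator: nothing to explain
  set.seed(106)
  null <- sim_eq_data(15, 30, b = 0, sd_a = 0, sd_b = 0)
  expect_lt(fit_mixed_model(null, "absolute")$r2c, 0.1)
})

test_that("shuffled predictors are significant at roughly the nominal rate", {
  set.seed(107)
  dat <- sim_eq_data(20, 20, b = -0.5)
  rej <- replicate(40, {
    dat$absolute <- sample(dat$absolute)
    fit <- fit_mixed_model(dat, "absolute")
    fit$p[["absolute"]] < 0.05
  })
  expect_lte(mean(rej), 0.2)
})

mock_fit <- function(slopes, predictor = "absolute") {
  structure(list(fixed = setNames(0, predictor),
                 ranef = data.frame(row.names = names(slopes),
                                    x = unname(slopes),
                                    check.names = FALSE) |>
                   setNames(predictor),
                 predictors = predictor),
            class = "assoc_model_fit")
}

test_that("strength comparison handles ties, shifts and mismatches", {
  s <- c(f1 = 0.4, f2 = -0.2, f3 = 0.1, f4 = -0.5)
  same <- compare_strengths(mock_fit(s), mock_fit(s, "hierarchical"),
                            "absolute", "hierarchical")
  expect_equal(same$p, 1)
  expect_equal(same$flag, "identical_slopes")
  expect_equal(same$direction, "equal")

  shifted <- compare_strengths(mock_fit(s),
                               mock_fit(abs(s) + 0.3, "hierarchical"),
                               "absolute", "hierarchical")
  expect_equal(shifted$direction, "hierarchy")
  expect_lt(shifted$p, 1e-6)
  expect_equal(shifted$mean_hier - shifted$mean_abs, 0.3, tolerance = 1e-12)

  # swapping the inputs flips only the direction
  fwd <- compare_strengths(mock_fit(s), mock_fit(s * 2, "hierarchical"),
                           "absolute", "hierarchical")
  rev <- compare_strengths(mock_fit(s * 2), mock_fit(s, "hierarchical"),
                           "absolute", "hierarchical")
  expect_equal(fwd$p, rev$p)
  expect_equal(abs(fwd$t), abs(rev$t))
  expect_true(fwd$direction != rev$direction)

  other <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  expect_error(compare_strengths(mock_fit(s), mock_fit(other, "hierarchical"),
                                 "absolute", "hierarchical"),
               "identical focal-species set")
})

test_that("significance tiers follow the reporting convention", {
  expect_equal(significance_tier(0.0005), "***")
  expect_equal(significance_tier(0.005), "**")
  expect_equal(significance_tier(0.03), "*")
  expect_equal(significance_tier(0.07), ".")
  expect_equal(significance_tier(0.5), "ns")
  expect_equal(significance_tier(NA), "ns")
})

test_that("mechanism interpretation follows the decision tree", {
  hier_cmp <- structure(list(direction = "hierarchy", p = 0.001),
                        class = "strength_comparison")
  abs_cmp <- structure(list(direction = "absolute", p = 0.001),
                       class = "strength_comparison")
  tie_cmp <- structure(list(direction = "hierarchy", p = 0.5),
                       class = "strength_comparison")

  expect_equal(interpret_mechanism(0.2, 0.001), "limiting_similarity")
  expect_equal(interpret_mechanism(-0.2, 0.001, hier_cmp),
               "hierarchical_competition")
  expect_equal(interpret_mechanism(-0.2, 0.001, abs_cmp),
               "environmental_filtering")
  expect_equal(interpret_mechanism(-0.2, 0.001, tie_cmp),
               "environmental_filtering")
  expect_equal(interpret_mechanism(-0.2, 0.8), "none_detected")
  expect_error(interpret_mechanism(-0.2, 0.001), "comparison result required")
})
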