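test_that("pcf estimator equals the brute-force double loop exactly", {
  w <- pp_window(0, 80, 0, 60)
  set.seed(31)
  for (k in 1:10) {
    a <- random_pattern(sample(3:50, 1), w)
    b <- random_pattern(sample(3:50, 1), w)
    r <- sample(c(5, 10, 20), 1)
    bw <- runif(1, 0.5, r / 2)
    for (corr in c("translation", "none")) {
      expect_equal(unname(estimate_bivariate_pcf(a, b, r, bw, corr)),
                   bf_pcf(a, b, r, bw, corr), tolerance = 1e-10)
    }
  }
})

test_that("pcf estimator is order-free and validates its inputs", {
  w <- pp_window(0, 100, 0, 100)
  set.seed(5)
  a <- random_pattern(20, w)
  b <- random_pattern(25, w)
  perm <- sample(25)
  b2 <- pp_pattern(b$x[perm], b$y[perm], w)
  expect_equal(estimate_bivariate_pcf(a, b, c(5, 20)),
               estimate_bivariate_pcf(a, b2, c(5, 20)))

  empty <- pp_pattern(numeric(0), numeric(0), w)
  expect_error(estimate_bivariate_pcf(a, empty, 5), "empty pattern")
  expect_error(estimate_bivariate_pcf(a, b, 60), "half the shorter")
  other <- random_pattern(5, pp_window(0, 50, 0, 50))
  expect_error(estimate_bivariate_pcf(a, other, 5), "share")
})

test_that("pcf of independent Poisson patterns averages to one", {
  w <- pp_window(0, 300, 0, 300)
  set.seed(12)
  vals <- replicate(100, {
    a <- simulate_poisson_pattern(0.01, w)
    b <- simulate_poisson_pattern(0.01, w)
    unname(estimate_bivariate_pcf(a, b, 10))
  })
  expect_lt(abs(mean(vals) - 1), 0.05)
})

test_that("nearest-neighbour distribution matches hand values and the ecdf", {
  w <- pp_window(0, 100, 0, 100)
  fi <- pp_pattern(c(0, 10), c(0, 0), w)
  fj <- pp_pattern(c(1, 50), c(0, 0), w)
  expect_equal(unname(estimate_nn_distribution(fi, fj, 5)), 0.5)
  expect_equal(unname(estimate_nn_distribution(fi, fj, 45)), 1.0)

  set.seed(17)
  for (k in 1:6) {
    a <- random_pattern(sample(2:40, 1), w)
    b <- random_pattern(sample(2:40, 1), w)
    for (r in c(5, 30)) {
      expect_equal(unname(estimate_nn_distribution(a, b, r)),
                   bf_nn_fraction(a, b, r), tolerance = 1e-12)
    }
    # empirical CDF is monotone in r
    v <- estimate_nn_distribution(a, b, c(5, 30))
    expect_gte(v[[2]], v[[1]])
  }
})

test_that("null ensemble has the documented shape and determinism", {
  w <- pp_window(0, 120, 0, 120)
  set.seed(23)
  a <- random_pattern(30, w)
  b <- random_pattern(30, w)
  e1 <- null_ensemble(a, b, "pcf", c(5, 30), n_sim = 99, seed = 5)
  expect_equal(nrow(e1$replicates), 99)
  expect_equal(e1$mu, colMeans(e1$replicates))
  expect_equal(e1$sigma, apply(e1$replicates, 2, sd))
  e2 <- null_ensemble(a, b, "pcf", c(5, 30), n_sim = 99, seed = 5)
  expect_identical(e1$replicates, e2$replicates)
  expect_error(null_ensemble(a, b, "pcf", 5, n_sim = 1), "at least 2")
})

test_that("observed statistic ranks uniformly within its own null ensemble", {
  # under independence the observed pattern is exchangeable with the torus
  # shifts, so its rank among n_sim replicates is uniform
  w <- pp_window(0, 100, 0, 100)
  set.seed(41)
  ranks <- replicate(120, {
    a <- random_pattern(25, w)
    b <- random_pattern(25, w)
    e <- null_ensemble(a, b, "pcf", 10, n_sim = 19)
    obs <- estimate_bivariate_pcf(a, b, 10)
    sum(e$replicates[, 1] < obs) + 1
  })
  expect_gt(chisq.test(tabulate(ranks, nbins = 20))$p.value, 0.001)
})

test_that("standardized effect size follows its definition", {
  fake <- structure(list(statistic = "pcf", r = 5,
                         replicates = matrix(c(1, 2, 3)),
                         mu = c(`r=5` = 2), sigma = c(`r=5` = 1),
                         degenerate = c(`r=5` = FALSE), n_sim = 3),
                    class = "null_ensemble")
  expect_equal(as.numeric(ses(4, fake)), 2)
  expect_equal(as.numeric(ses(2, fake)), 0)
  expect_equal(as.numeric(ses(2 + 1.96, fake)), 1.96)

  degen <- fake
  degen$sigma <- c(`r=5` = 0)
  degen$degenerate <- c(`r=5` = TRUE)
  expect_equal(as.numeric(ses(2, degen)), 0)
  expect_equal(as.numeric(ses(5, degen)), Inf)
  expect_equal(as.numeric(ses(-1, degen)), -Inf)
  expect_true(attr(ses(5, degen), "degenerate"))
})

test_that("SES is invariant to shared affine rescaling a*S + b, a > 0", {
  w <- pp_window(0, 120, 0, 120)
  set.seed(6)
  a_pat <- random_pattern(30, w)
  b_pat <- random_pattern(35, w)
  e <- null_ensemble(a_pat, b_pat, "D", c(5, 30), n_sim = 49, seed = 2)
  obs <- estimate_nn_distribution(a_pat, b_pat, c(5, 30))
  z0 <- ses(obs, e)
  for (ab in list(c(2.5, 1), c(0.3, -4))) {
    e2 <- e
    e2$mu <- ab[1] * e$mu + ab[2]
    e2$sigma <- ab[1] * e$sigma
    z1 <- ses(ab[1] * obs + ab[2], e2)
    expect_equal(unname(z1), unname(z0), tolerance = 1e-10)
  }
})

test_that("classification uses strict two-sided critical values", {
  expect_equal(classify_association(2.5), "attraction")
  expect_equal(classify_association(-2.0), "repulsion")
  expect_equal(classify_association(qnorm(0.975)), "independence")
  expect_equal(classify_association(c(-5, 0, 5)),
               c("repulsion", "independence", "attraction"))
  expect_equal(classify_association(3, alpha = 0.01), "attraction")
  expect_equal(classify_association(2.5, alpha = 0.01), "independence")
})

test_that("pairwise analysis enumerates ordered pairs and is reproducible", {
  expect_equal(nrow(ordered_pairs(letters[1:4])), 12)
  expect_equal(nrow(ordered_pairs(paste0("s", 1:137))), 18632)

  com <- simulate_community(scenario_config("neutral", n_species = 4,
                                            n_stems = 40,
                                            window = pp_window(0, 150, 0, 150),
                                            seed = 3))
  w <- pp_window(0, 150, 0, 150)
  rec <- pairwise_association_analysis(com$census, w, radii = c(5, 30),
                                       statistics = c("pcf", "D"),
                                       n_sim = 39, seed = 7)
  expect_equal(nrow(rec), 12 * 2 * 2)
  expect_true(all(rec$focal_id != rec$other_id))
  expect_true(all(rec$class %in% c("attraction", "repulsion", "independence")))
  rec2 <- pairwise_association_analysis(com$census, w, radii = c(5, 30),
                                        statistics = c("pcf", "D"),
                                        n_sim = 39, seed = 7)
  expect_identical(rec, rec2)

  one_sp <- com$census[com$census$species_id == "sp01", ]
  expect_warning(out <- pairwise_association_analysis(one_sp, w, radii = 5,
                                                      n_sim = 39),
                 "fewer than two")
  expect_equal(nrow(out), 0)
})
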