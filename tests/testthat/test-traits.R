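test_that("absolute and hierarchical distances follow their definitions", {
  expect_equal(absolute_distance(3, 5), 2)
  expect_equal(absolute_distance(5, 3), 2)
  expect_equal(absolute_distance(4, 4), 0)
  expect_equal(hierarchical_distance(3, 5), -2)
  expect_equal(hierarchical_distance(5, 3), 2)
  expect_equal(hierarchical_distance(4, 4), 0)
})

test_that("H_max matches an independent quantile implementation", {
  expect_equal(max_height(rep(7, 10)), 7)
  expect_equal(max_height(12.5), 12.5)
  expect_equal(max_height(1:100), bf_quantile7(1:100, 0.99))
  set.seed(2)
  h <- rlnorm(57, 2, 0.4)
  expect_equal(max_height(h), bf_quantile7(h, 0.99))
  expect_equal(max_height(c(h, NA)), max_height(h))
  expect_error(max_height(numeric(0)), "no finite")
})

test_that("integrated trait axis reproduces an eigen-decomposition oracle", {
  set.seed(10)
  tab <- data.frame(species_id = paste0("s", 1:12),
                    matrix(rlnorm(12 * 4), 12, 4,
                           dimnames = list(NULL, c("LA", "SLA", "WD",
                                                   "H_max"))))
  res <- integrated_trait_scores(tab)

  m <- scale(as.matrix(tab[, -1]))
  eig <- eigen(cor(as.matrix(tab[, -1])))
  oracle_scores <- as.numeric(m %*% eig$vectors[, 1])
  agreement <- abs(cor(res$scores, oracle_scores))
  expect_equal(agreement, 1, tolerance = 1e-10)
  expect_equal(res$variance_share, eig$values[1] / sum(eig$values),
               tolerance = 1e-10)
  expect_equal(sum(res$variance_shares), 1, tolerance = 1e-10)
  expect_gt(res$loadings[["SLA"]], 0) # sign convention

  # row reordering leaves scores unchanged up to global sign
  perm <- sample(12)
  res2 <- integrated_trait_scores(tab[perm, ])
  expect_equal(abs(cor(res2$scores[names(res$scores)], res$scores)), 1,
               tolerance = 1e-10)
})

test_that("integrated trait axis handles degenerate inputs", {
  tab <- data.frame(species_id = c("a", "b", "c"),
                    t1 = c(1, 2, 3), t2 = c(2, 4, 6))
  res <- integrated_trait_scores(tab, sign_trait = "t1")
  expect_equal(res$variance_share, 1, tolerance = 1e-12)

  const <- data.frame(species_id = c("a", "b", "c"),
                      t1 = c(1, 2, 3), t2 = c(5, 5, 5))
  expect_error(integrated_trait_scores(const), "constant trait")
  expect_error(integrated_trait_scores(tab[1, ]), "two species")
})

test_that("pairwise distance table satisfies the symmetry invariants", {
  set.seed(14)
  tab <- data.frame(species_id = paste0("s", 1:8),
                    matrix(rlnorm(8 * 3), 8, 3,
                           dimnames = list(NULL, c("LA", "SLA", "WD"))))
  d <- trait_distance_table(tab)
  expect_equal(nrow(d), 8 * 7)
  for (tr in c("LA", "SLA", "WD", "PCA")) {
    ab <- d[[paste0(tr, "_abs")]]
    hi <- d[[paste0(tr, "_hier")]]
    expect_equal(ab, abs(hi))
    # antisymmetry of the hierarchical distance under pair reversal
    key <- paste(d$focal_id, d$other_id)
    rev_key <- paste(d$other_id, d$focal_id)
    expect_equal(hi, -hi[match(key, rev_key)])
  }
  expect_true(is.finite(attr(d, "pca_variance_share")))
})

test_that("standardization centers and scales each predictor", {
  two <- data.frame(focal_id = c("a", "b"), other_id = c("b", "a"),
                    v = c(1, 3))
  out <- standardize_distances(two, "v")
  expect_equal(out$v, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(3)
  d <- data.frame(focal_id = letters[1:10], other_id = letters[11:20],
                  a = rnorm(10, 5, 2), b = runif(10))
  s1 <- standardize_distances(d)
  expect_equal(mean(s1$a), 0, tolerance = 1e-12)
  expect_equal(sd(s1$a), 1, tolerance = 1e-12)
  expect_equal(sd(s1$b), 1, tolerance = 1e-12)
  # idempotence
  s2 <- standardize_distances(s1)
  expect_equal(s2$a, s1$a, tolerance = 1e-12)
  meta <- attr(s1, "standardization")
  expect_equal(meta$mean[meta$column == "a"], mean(d$a))

  d$c <- 1
  expect_error(standardize_distances(d), "zero or undefined variance")
})
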