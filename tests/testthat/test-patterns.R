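test_that("window and pattern constructors enforce their invariants", {
  expect_error(pp_window(10, 0, 0, 5), "invalid window")
  w <- pp_window(0, 1000, 0, 500)
  expect_equal(window_area(w), 5e5)
  expect_error(pp_pattern(c(1, 2000), c(1, 1), w), "outside")
  p <- pp_pattern(c(0, 1000), c(0, 500), w) # closed bounds: edges valid
  expect_equal(n_points(p), 2L)
  expect_equal(intensity_of(p), 2 / 5e5)
})

test_that("toroidal shift wraps coordinates and preserves structure", {
  w <- pp_window(0, 1000, 0, 500)
  p <- pp_pattern(999, 499, w)
  s <- toroidal_shift(p, 5, 5)
  expect_equal(c(s$x, s$y), c(4, 4))

  set.seed(11)
  q <- random_pattern(40, w)
  expect_equal(toroidal_shift(q, 0, 0), q)

  for (k in 1:5) {
    sh <- toroidal_shift(q, runif(1, -2000, 2000), runif(1, -900, 900))
    expect_equal(n_points(sh), n_points(q))
    expect_equal(sort(toroidal_pairdist(sh)), sort(toroidal_pairdist(q)),
                 tolerance = 1e-10)
  }
})

test_that("toroidal distances agree with a 9-image brute force", {
  w <- pp_window(0, 60, 0, 40)
  set.seed(4)
  p <- random_pattern(12, w)
  expect_equal(sort(toroidal_pairdist(p)), sort(bf_torus_dist(p)),
               tolerance = 1e-10)
})
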