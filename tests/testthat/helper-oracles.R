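# Independent brute-force oracles, kept deliberately naive: every estimator
# result is checked against a literal double loop over the defining formula.

# kernel pcf estimate by double loop (Epanechnikov, translation or no
# correction), one radius at a time
bf_pcf <- function(pat_i, pat_j, r, bw, correction = "translation") {
  w <- pat_i$window
  W <- w$x_max - w$x_min
  H <- w$y_max - w$y_min
  A <- W * H
  total <- 0
  for (p in seq_along(pat_i$x)) {
    for (q in seq_along(pat_j$x)) {
      dx <- pat_i$x[p] - pat_j$x[q]
      dy <- pat_i$y[p] - pat_j$y[q]
      d <- sqrt(dx^2 + dy^2)
      u <- (d - r) / bw
      k <- if (abs(u) < 1) 0.75 * (1 - u^2) / bw else 0
      wgt <- if (correction == "translation") {
        1 / ((W - abs(dx)) * (H - abs(dy)))
      } else {
        1 / A
      }
      total <- total + k * wgt
    }
  }
  lam_i <- length(pat_i$x) / A
  lam_j <- length(pat_j$x) / A
  total / (2 * base::pi * r * lam_i * lam_j)
}

# empirical nearest-neighbour CDF by brute force
bf_nn_fraction <- function(pat_i, pat_j, r) {
  nn <- vapply(seq_along(pat_i$x), function(p) {
    min(sqrt((pat_i$x[p] - pat_j$x)^2 + (pat_i$y[p] - pat_j$y)^2))
  }, numeric(1))
  mean(nn <= r)
}

# toroidal pairwise distances by explicit 9-image minimum
bf_torus_dist <- function(pat) {
  w <- pat$window
  W <- w$x_max - w$x_min
  H <- w$y_max - w$y_min
  n <- length(pat$x)
  out <- c()
  if (n < 2) return(numeric(0))
  for (p in 1:(n - 1)) {
    for (q in (p + 1):n) {
      best <- Inf
      for (ix in -1:1) {
        for (iy in -1:1) {
          d <- sqrt((pat$x[p] - pat$x[q] + ix * W)^2 +
                    (pat$y[p] - pat$y[q] + iy * H)^2)
          best <- min(best, d)
        }
      }
      out <- c(out, best)
    }
  }
  out
}

# order-statistic interpolation quantile (R type 7), written independently
bf_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# random toy pattern for oracle comparisons
random_pattern <- function(n, window) {
  pp_pattern(runif(n, window$x_min, window$x_max),
             runif(n, window$y_min, window$y_max), window)
}
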