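#' @title Bivariate pair correlation function
#'
#' @description
#' Kernel estimate of the bivariate pair correlation function `g_ij(r)`:
#' the density of species-j stems at distance `r` from a focal species-i
#' stem, relative to a homogeneous Poisson process of the same intensity.
#' `g = 1` indicates independence at that scale, `> 1` attraction, `< 1`
#' repulsion.
#'
#' The estimator sums an Epanechnikov kernel in `(distance - r)` over all
#' cross-species point pairs, divided by `2 pi r` and the intensity product
#' `lambda_i lambda_j`, with a translation edge-correction weight
#' `1 / ((W - |dx|)(H - |dy|))` per pair (or the uncorrected weight
#' `1 / area` when `correction = "none"`).
#'
#' The default bandwidth follows the common practice for kernel pcf
#' estimation, `0.15 / sqrt(lambda_j)`, clipped to `[0.5 m, r/2]` so the
#' kernel support never crosses zero distance.
#'
#' @param pattern_i Focal species pattern ([pp_pattern()]); non-empty.
#' @param pattern_j Second species pattern on the same window; non-empty.
#' @param r Radii in metres (each `> 0` and at most half the shorter
#'   window side).
#' @param bandwidth Kernel half-width in metres: a single value, a vector
#'   matching `r`, or `NULL` for the default rule.
#' @param correction `"translation"` (default) or `"none"`.
#' @return Numeric vector of `g_ij(r)` values named by radius.
#' @examples
#' w <- pp_window(0, 200, 0, 200)
#' a <- simulate_poisson_pattern(0.003, w, seed = 1)
#' b <- simulate_poisson_pattern(0.003, w, seed = 2)
#' estimate_bivariate_pcf(a, b, r = c(5, 30))
#' @export
estimate_bivariate_pcf <- function(pattern_i, pattern_j, r,
                                   bandwidth = NULL,
                                   correction = c("translation", "none")) {
  correction <- match.arg(correction)
  check_pair(pattern_i, pattern_j, r)
  bw <- pcf_bandwidth(bandwidth, r, intensity_of(pattern_j))
  w <- pattern_i$window
  sides <- window_sides(w)
  out <- cpp_cross_stats(pattern_i$x - w$x_min, pattern_i$y - w$y_min,
                         pattern_j$x - w$x_min, pattern_j$y - w$y_min,
                         sides[["width"]], sides[["height"]],
                         r, bw, correction == "translation")
  setNames(out$pcf, paste0("r=", r))
}

#' Bivariate nearest-neighbour distribution function
#'
#' `D_ij(r)`: the empirical probability that a focal species-i stem has its
#' nearest species-j neighbour within distance `r`. Estimated as the raw
#' empirical fraction with no edge correction — the identical estimator is
#' applied to the observed and every null pattern, so edge bias cancels in
#' the standardized effect size.
#'
#' @inheritParams estimate_bivariate_pcf
#' @return Numeric vector of probabilities in `[0, 1]` named by radius.
#' @examples
#' w <- pp_window(0, 100, 0, 100)
#' fi <- pp_pattern(c(0, 10), c(0, 0), w)
#' fj <- pp_pattern(c(1, 50), c(0, 0), w)
#' estimate_nn_distribution(fi, fj, r = 5) # NN distances 1 and 40 -> 0.5
#' @export
estimate_nn_distribution <- function(pattern_i, pattern_j, r) {
  check_pair(pattern_i, pattern_j, r, check_radius = FALSE)
  w <- pattern_i$window
  sides <- window_sides(w)
  out <- cpp_cross_stats(pattern_i$x - w$x_min, pattern_i$y - w$y_min,
                         pattern_j$x - w$x_min, pattern_j$y - w$y_min,
                         sides[["width"]], sides[["height"]],
                         r, rep(1, length(r)), FALSE)
  setNames(out$D, paste0("r=", r))
}

check_pair <- function(pattern_i, pattern_j, r, check_radius = TRUE) {
  stopifnot(inherits(pattern_i, "pp_pattern"), inherits(pattern_j, "pp_pattern"))
  if (!identical(unclass(pattern_i$window), unclass(pattern_j$window))) {
    stop("patterns must share one observation window")
  }
  if (n_points(pattern_i) == 0 || n_points(pattern_j) == 0) {
    stop("empty pattern: intensity undefined")
  }
  if (any(!is.finite(r)) || any(r <= 0)) stop("radii must be positive")
  if (check_radius) {
    half <- min(window_sides(pattern_i$window)) / 2
    if (any(r > half)) {
      stop(sprintf("radius exceeds half the shorter window side (%g m)", half))
    }
  }
  invisible(TRUE)
}

pcf_bandwidth <- function(bandwidth, r, lambda_j) {
  if (is.null(bandwidth)) {
    pmin(pmax(0.15 / sqrt(lambda_j), 0.5), pmax(0.5, r / 2))
  } else {
    if (any(bandwidth <= 0)) stop("bandwidth must be positive")
    rep_len(bandwidth, length(r))
  }
}

#' Toroidal-shift null ensemble for one ordered species pair
#'
#' Holds the focal pattern fixed and re-evaluates a summary statistic on
#' `n_sim` toroidal shifts of the second pattern, each shifted by an offset
#' drawn uniformly on the window. The shift destroys any cross-species
#' dependence while preserving each species' internal spatial structure, so
#' the ensemble is the reference distribution for interspecific
#' independence.
#'
#' @inheritParams estimate_bivariate_pcf
#' @param statistic `"pcf"` or `"D"`.
#' @param n_sim Number of null replicates (>= 2; 999 in the standard
#'   protocol).
#' @param seed Optional integer seed for the shift stream.
#' @return An object of class `null_ensemble`: list with `statistic`, `r`,
#'   `replicates` (matrix `n_sim` x `length(r)`), `mu` and `sigma` (sample
#'   mean and sample sd per radius), `degenerate` (TRUE where `sigma` is
#'   zero) and `n_sim`.
#' @export
null_ensemble <- function(pattern_i, pattern_j,
                          statistic = c("pcf", "D"), r, n_sim,
                          seed = NULL, bandwidth = NULL,
                          correction = c("translation", "none")) {
  statistic <- match.arg(statistic)
  correction <- match.arg(correction)
  check_pair(pattern_i, pattern_j, r, check_radius = statistic == "pcf")
  if (n_sim < 2) stop("n_sim must be at least 2")
  w <- pattern_i$window
  sides <- window_sides(w)
  bw <- pcf_bandwidth(bandwidth, r, intensity_of(pattern_j))
  reps <- with_seed(seed, {
    dx <- runif(n_sim, 0, sides[["width"]])
    dy <- runif(n_sim, 0, sides[["height"]])
    cpp_null_stats(pattern_i$x - w$x_min, pattern_i$y - w$y_min,
                   pattern_j$x - w$x_min, pattern_j$y - w$y_min,
                   sides[["width"]], sides[["height"]],
                   r, bw, correction == "translation", dx, dy)
  })
  m <- reps[[statistic]]
  colnames(m) <- paste0("r=", r)
  mu <- colMeans(m)
  sigma <- apply(m, 2, sd)
  structure(list(statistic = statistic, r = r, replicates = m,
                 mu = mu, sigma = sigma,
                 degenerate = sigma == 0, n_sim = n_sim),
            class = "null_ensemble")
}

#' Standardized effect size against a null ensemble
#'
#' `z(r) = (S0(r) - mu_null(r)) / sigma_null(r)`, where `S0` is the
#' observed summary statistic and `mu_null`, `sigma_null` are the mean and
#' sample standard deviation over the null replicates. When the null has
#' zero variance the result is 0 (if the observation equals the null mean)
#' or signed infinity, with the `degenerate` attribute set.
#'
#' @param observed Observed statistic values at the ensemble's radii (as
#'   returned by [estimate_bivariate_pcf()] or
#'   [estimate_nn_distribution()]).
#' @param ensemble A [null_ensemble()] for the same statistic and radii.
#' @return Numeric z values named by radius, with attribute `degenerate`.
#' @examples
#' # replicates {1, 2, 3}, observed 4: mean 2, sample sd 1 -> z = 2
#' @export
ses <- function(observed, ensemble) {
  if (!inherits(ensemble, "null_ensemble")) stop("ensemble must be a null_ensemble")
  if (length(observed) != length(ensemble$r)) {
    stop("observed values do not match the ensemble radii")
  }
  num <- unname(observed - ensemble$mu)
  sig <- unname(ensemble$sigma)
  z <- ifelse(sig > 0, num / sig, ifelse(num == 0, 0, sign(num) * Inf))
  structure(setNames(z, names(ensemble$mu)),
            degenerate = unname(ensemble$degenerate))
}

#' Classify a standardized effect size
#'
#' Attraction if `z > z_alpha`, repulsion if `z < -z_alpha`, independence
#' otherwise (strict inequalities, so `z` exactly at the critical value is
#' independence). `z_alpha` is the standard-normal two-sided critical value,
#' 1.96 at `alpha = 0.05`.
#'
#' @param z Standardized effect size(s); finite or signed infinite.
#' @param alpha Pointwise two-sided significance level in (0, 1).
#' @return Character vector in `{"attraction", "repulsion", "independence"}`.
#' @examples
#' classify_association(c(2.5, -2, 1.96)) # attraction, repulsion, independence
#' @export
classify_association <- function(z, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  z_alpha <- qnorm(1 - alpha / 2)
  ifelse(z > z_alpha, "attraction",
         ifelse(z < -z_alpha, "repulsion", "independence"))
}

#' All ordered species pairs
#'
#' @param species Character vector of species identifiers.
#' @return Data frame with columns `focal_id`, `other_id`, one row per
#'   ordered pair (`n * (n - 1)` rows): each pair is analysed twice, once
#'   with each species as focal, because spatial association is asymmetric.
#' @examples
#' nrow(ordered_pairs(letters[1:4])) # 12
#' @export
ordered_pairs <- function(species) {
  species <- unique(as.character(species))
  g <- expand.grid(other_id = species, focal_id = species,
                   stringsAsFactors = FALSE)[, c("focal_id", "other_id")]
  g <- g[g$focal_id != g$other_id, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Pairwise spatial association analysis
#'
#' Runs the full ordered-pair association protocol on a census: for every
#' ordered species pair (i, j), evaluates the chosen summary statistics at
#' each radius, builds a toroidal-shift null ensemble with the focal
#' pattern fixed, computes the standardized effect size, and classifies the
#' pair as attraction / repulsion / independence at pointwise `alpha` (no
#' multiple-testing correction across pairs — classification is pointwise
#' by design).
#'
#' @param census Census data frame with columns `species_id`, `x`, `y`
#'   (and `dbh` if `stage` is given).
#' @param window A [pp_window()] containing all stems.
#' @param radii Radii in metres (default the standard 5 / 30 / 50 m
#'   protocol scales).
#' @param statistics Subset of `c("pcf", "D")`.
#' @param n_sim Null replicates per pair.
#' @param alpha Pointwise significance level.
#' @param seed Optional integer seed governing all shift draws.
#' @param stage Optional [stage_filter()] applied to the census first.
#' @param bandwidth,correction Passed to the pcf estimator.
#' @return Data frame of association records: `focal_id`, `other_id`,
#'   `statistic`, `r`, `observed`, `null_mean`, `null_sd`, `z`, `class`,
#'   `degenerate`, `n_sim`. Empty (with a warning) if fewer than two
#'   species survive filtering.
#' @export
pairwise_association_analysis <- function(census, window,
                                          radii = c(5, 30, 50),
                                          statistics = c("pcf", "D"),
                                          n_sim = 999, alpha = 0.05,
                                          seed = NULL, stage = NULL,
                                          bandwidth = NULL,
                                          correction = "translation") {
  statistics <- match.arg(statistics, c("pcf", "D"), several.ok = TRUE)
  if ("pcf" %in% statistics && any(radii > min(window_sides(window)) / 2)) {
    stop("pcf radius exceeds half the shorter window side")
  }
  if (!is.null(stage)) census <- filter_census(census, stage)$census
  species <- sort(unique(census$species_id))
  empty <- data.frame(focal_id = character(), other_id = character(),
                      statistic = character(), r = numeric(),
                      observed = numeric(), null_mean = numeric(),
                      null_sd = numeric(), z = numeric(),
                      class = character(), degenerate = logical(),
                      n_sim = integer())
  if (length(species) < 2) {
    warning("fewer than two species after filtering; no pairs to analyse")
    return(empty)
  }
  patterns <- lapply(species, function(s) {
    rows <- census$species_id == s
    pp_pattern(census$x[rows], census$y[rows], window)
  })
  names(patterns) <- species
  pairs <- ordered_pairs(species)
  nr <- length(radii)
  sides <- window_sides(window)

  with_seed(seed, {
    res <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      pi_ <- patterns[[pairs$focal_id[k]]]
      pj_ <- patterns[[pairs$other_id[k]]]
      bw <- pcf_bandwidth(bandwidth, radii, intensity_of(pj_))
      dx <- runif(n_sim, 0, sides[["width"]])
      dy <- runif(n_sim, 0, sides[["height"]])
      obs <- cpp_cross_stats(pi_$x - window$x_min, pi_$y - window$y_min,
                             pj_$x - window$x_min, pj_$y - window$y_min,
                             sides[["width"]], sides[["height"]],
                             radii, bw, correction == "translation")
      nul <- cpp_null_stats(pi_$x - window$x_min, pi_$y - window$y_min,
                            pj_$x - window$x_min, pj_$y - window$y_min,
                            sides[["width"]], sides[["height"]],
                            radii, bw, correction == "translation", dx, dy)
      rows <- lapply(statistics, function(st) {
        mu <- colMeans(nul[[st]])
        sig <- apply(nul[[st]], 2, sd)
        num <- obs[[st]] - mu
        z <- ifelse(sig > 0, num / sig, ifelse(num == 0, 0, sign(num) * Inf))
        data.frame(focal_id = pairs$focal_id[k],
                   other_id = pairs$other_id[k],
                   statistic = st, r = radii,
                   observed = obs[[st]], null_mean = mu, null_sd = sig,
                   z = z, class = classify_association(z, alpha),
                   degenerate = sig == 0, n_sim = as.integer(n_sim))
      })
      res[[k]] <- do.call(rbind, rows)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}
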