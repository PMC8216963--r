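#' Null-model calibration experiment
#'
#' Generates independent species pairs (alternating homogeneous Poisson and
#' Thomas cluster patterns on a shared window), runs the toroidal-shift
#' null for each, and tabulates how often the standardized effect size
#' rejects independence at the two-sided threshold. Because both generators
#' are stationary on the window torus, the observed pattern is exchangeable
#' with its null replicates and the rejection rate should sit at the
#' nominal level for every statistic and radius. Degenerate records (zero
#' null variance, e.g. the nearest-neighbour statistic saturated at 1) are
#' excluded, as in the analysis pipeline.
#'
#' @param n_pairs Number of independent pairs (half Poisson, half Thomas).
#' @param n_sim Null replicates per pair.
#' @param radii Radii evaluated.
#' @param alpha Nominal two-sided level.
#' @param window Observation window.
#' @param intensity Poisson intensity; the Thomas generator matches its
#'   expected count (`kappa = intensity / mu_off`).
#' @param sigma,mu_off Thomas clustering parameters.
#' @param seed Integer seed.
#' @return Data frame with one row per statistic x radius: `n_eval`
#'   (non-degenerate pairs), `n_reject`, and the rejection `rate`.
#' @export
null_calibration <- function(n_pairs = 500, n_sim = 199,
                             radii = c(5, 30, 50), alpha = 0.05,
                             window = pp_window(0, 200, 0, 200),
                             intensity = 0.0025, sigma = 10, mu_off = 12.5,
                             seed = 1L) {
  z_alpha <- qnorm(1 - alpha / 2)
  stats <- c("pcf", "D")
  rej <- den <- matrix(0, 2, length(radii),
                       dimnames = list(stats, paste0("r=", radii)))
  with_seed(seed, {
    for (k in seq_len(n_pairs)) {
      gen <- if (k %% 2 == 0) {
        function() simulate_poisson_pattern(intensity, window)
      } else {
        function() simulate_thomas_pattern(intensity / mu_off, sigma,
                                           mu_off, window)
      }
      a <- gen()
      b <- gen()
      if (n_points(a) < 5 || n_points(b) < 5) next
      for (st in stats) {
        e <- null_ensemble(a, b, st, radii, n_sim = n_sim)
        obs <- if (st == "pcf") estimate_bivariate_pcf(a, b, radii)
               else estimate_nn_distribution(a, b, radii)
        z <- ses(obs, e)
        ok <- !e$degenerate
        den[st, ] <- den[st, ] + ok
        rej[st, ] <- rej[st, ] + (ok & abs(z) > z_alpha)
      }
    }
  })
  out <- expand.grid(statistic = stats, r = radii, stringsAsFactors = FALSE)
  out$n_eval <- as.integer(den[cbind(out$statistic, paste0("r=", out$r))])
  out$n_reject <- as.integer(rej[cbind(out$statistic, paste0("r=", out$r))])
  out$rate <- out$n_reject / out$n_eval
  out
}

#' Mixed-model parameter-recovery experiment
#'
#' Simulates data directly from the per-focal random-slope model
#' (`z = a + a_i + (b + b_i) x + e`), refits it, and reports how often the
#' Wald 95% confidence interval covers the generating fixed slope, along
#' with the mean estimation bias.
#'
#' @param n_rep Number of replicates.
#' @param n_focal,n_per Focal species and pairs per focal species.
#' @param a,b Generating fixed intercept and slope.
#' @param sd_re Random-effect standard deviation (intercepts and slopes).
#' @param sd_e Residual standard deviation.
#' @param seed Integer seed.
#' @return List with `coverage` (fraction of replicates whose 95% CI covers
#'   `b`), `mean_bias`, and the vector of `estimates`.
#' @export
slope_recovery <- function(n_rep = 100, n_focal = 50, n_per = 100,
                           a = 0, b = -0.5, sd_re = 0.2, sd_e = 1,
                           seed = 1L) {
  with_seed(seed, {
    est <- se <- numeric(n_rep)
    for (k in seq_len(n_rep)) {
      ai <- rnorm(n_focal, 0, sd_re)
      bi <- rnorm(n_focal, 0, sd_re)
      idx <- rep(seq_len(n_focal), each = n_per)
      x <- rnorm(n_focal * n_per)
      z <- a + ai[idx] + (b + bi[idx]) * x + rnorm(n_focal * n_per, 0, sd_e)
      dat <- data.frame(focal = sprintf("f%02d", idx), z = z, pred = x)
      fit <- fit_mixed_model(dat, "pred")
      est[k] <- fit$fixed[["pred"]]
      se[k] <- fit$se[["pred"]]
    }
    covered <- abs(est - b) <= 1.96 * se
    list(coverage = mean(covered), mean_bias = mean(est) - b,
         estimates = est)
  })
}

# frozen validation conditions: interaction strength and evaluation radius
# per scenario (competition mechanisms act within the 10-m interaction
# neighbourhood and are read at r = 5 m; habitat filtering aggregates
# stems over ~40-m patches and is read at r = 10 m)
scenario_validation_settings <- function(scenario) {
  switch(scenario,
         neutral = list(strength = 0, r = 5),
         filtering = list(strength = 6, r = 10),
         hierarchical = list(strength = 9, r = 5),
         limiting_similarity = list(strength = 3, r = 5),
         stop("unknown scenario: ", scenario))
}

#' Mechanism-recovery experiment
#'
#' Runs the full inference chain — community simulation under a known
#' assembly mechanism, pairwise toroidal-shift associations, integrated-
#' trait distances, the absolute-distance screening model, the
#' dissimilarity-vs-hierarchy comparison, and the mechanism label — for
#' several seeds of one scenario, under the package's frozen validation
#' conditions (20 species of 150 stems on a 250 x 250 m window, pcf
#' statistic, 199 null replicates, species with at least 20 surviving
#' stems).
#'
#' @param scenario Scenario name as in [scenario_config()].
#' @param seeds Integer vector of community seeds.
#' @param n_sim Null replicates per pair.
#' @param n_species,n_stems Community size.
#' @return Data frame, one row per seed: the screening slope `b_abs` and
#'   its p-value, mean per-focal `|slope|` under each predictor, the
#'   paired-t statistic/p-value and direction, and the `mechanism` label.
#' @export
mechanism_recovery <- function(scenario, seeds = 1:5, n_sim = 199,
                               n_species = 20, n_stems = 150) {
  set_ <- scenario_validation_settings(scenario)
  window <- pp_window(0, 250, 0, 250)
  rows <- lapply(seeds, function(s) {
    com <- simulate_community(scenario_config(scenario,
                                              n_species = n_species,
                                              n_stems = n_stems,
                                              window = window,
                                              strength = set_$strength,
                                              seed = s))
    fl <- filter_census(com$census, all_stems_filter(min_abundance = 20))
    assoc <- pairwise_association_analysis(fl$census, window, radii = set_$r,
                                           statistics = "pcf", n_sim = n_sim,
                                           seed = s + 1000L)
    dists <- trait_distance_table(com$traits, species = fl$species)
    dat <- build_model_data(assoc, dists, "PCA", "pcf", set_$r)
    fit_abs <- fit_mixed_model(dat, "absolute")
    fit_hier <- fit_mixed_model(dat, "hierarchical")
    cmp <- compare_strengths(fit_abs, fit_hier)
    mech <- interpret_mechanism(fit_abs$fixed[["absolute"]],
                                fit_abs$p[["absolute"]], cmp)
    data.frame(scenario = scenario, seed = s,
               b_abs = fit_abs$fixed[["absolute"]],
               p_abs = fit_abs$p[["absolute"]],
               mean_abs_slope = cmp$mean_abs,
               mean_hier_slope = cmp$mean_hier,
               t_paired = cmp$t, p_paired = cmp$p,
               direction = cmp$direction, mechanism = mech,
               n_species_retained = length(fl$species))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
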