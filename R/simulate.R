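#' Simulate a homogeneous Poisson point pattern
#'
#' Complete spatial randomness: the point count is Poisson with mean
#' `intensity * area` and locations are independent uniforms on the window.
#'
#' @param intensity Expected points per square metre (>= 0).
#' @param window A [pp_window()].
#' @param seed Optional integer seed; the global RNG stream is restored
#'   afterwards.
#' @return A [pp_pattern()].
#' @examples
#' simulate_poisson_pattern(0.001, pp_window(0, 100, 0, 100), seed = 1)
#' @export
simulate_poisson_pattern <- function(intensity, window, seed = NULL) {
  stopifnot(inherits(window, "pp_window"))
  if (!is.numeric(intensity) || length(intensity) != 1 || is.na(intensity) ||
      intensity < 0) {
    stop("intensity must be a single non-negative number")
  }
  with_seed(seed, {
    n <- rpois(1, intensity * window_area(window))
    pp_pattern(runif(n, window$x_min, window$x_max),
               runif(n, window$y_min, window$y_max), window)
  })
}

#' Simulate a Thomas cluster process
#'
#' Parents are Poisson with intensity `kappa`; each parent receives a
#' Poisson(`mu_off`) number of offspring displaced by an isotropic Gaussian
#' with standard deviation `sigma`. Offspring falling outside the window are
#' wrapped toroidally, which keeps the process exactly homogeneous on the
#' torus — consistent with the toroidal-shift null model used downstream.
#' The expected total count is `kappa * mu_off * area`.
#'
#' @param kappa Parent intensity per square metre (> 0).
#' @param sigma Offspring dispersion in metres (> 0).
#' @param mu_off Mean offspring per parent (> 0).
#' @inheritParams simulate_poisson_pattern
#' @return A [pp_pattern()].
#' @examples
#' simulate_thomas_pattern(5e-4, 10, 20, pp_window(0, 200, 0, 200), seed = 1)
#' @export
simulate_thomas_pattern <- function(kappa, sigma, mu_off, window, seed = NULL) {
  stopifnot(inherits(window, "pp_window"))
  if (!all(is.finite(c(kappa, sigma, mu_off))) ||
      kappa <= 0 || sigma <= 0 || mu_off <= 0) {
    stop("kappa, sigma and mu_off must all be positive")
  }
  with_seed(seed, {
    n_par <- rpois(1, kappa * window_area(window))
    px <- runif(n_par, window$x_min, window$x_max)
    py <- runif(n_par, window$y_min, window$y_max)
    n_off <- if (n_par > 0) rpois(n_par, mu_off) else integer(0)
    x <- rep(px, n_off) + rnorm(sum(n_off), 0, sigma)
    y <- rep(py, n_off) + rnorm(sum(n_off), 0, sigma)
    wrap_pattern(x, y, window)
  })
}

# wrap raw coordinates onto the window torus
wrap_pattern <- function(x, y, window) {
  sides <- window_sides(window)
  pp_pattern((x - window$x_min) %% sides[["width"]] + window$x_min,
             (y - window$y_min) %% sides[["height"]] + window$y_min,
             window)
}

#' Configuration for one synthetic assembly scenario
#'
#' Bundles the generative parameters for [simulate_community()]. Defaults
#' describe a 6.25-ha (250 x 250 m) stem-mapped subplot with 20 species of
#' 150 stems each (~480 stems/ha, a typical subtropical-forest density),
#' within-species Thomas clustering (8 stems per cluster, 8 m dispersion),
#' and six log-normal traits sharing a latent species axis so that the
#' first principal component carries roughly 45% of the trait variance, as
#' observed in subtropical tree communities.
#'
#' @param scenario One of `"neutral"`, `"filtering"`, `"hierarchical"`,
#'   `"limiting_similarity"`.
#' @param n_species Number of species (>= 1).
#' @param n_stems Stems generated per species before any thinning.
#' @param window A [pp_window()].
#' @param kappa Parent intensity per m^2, or `NULL` to derive it from
#'   `n_stems / (mu_off * area)`.
#' @param sigma Within-species cluster dispersion (m).
#' @param mu_off Mean stems per cluster.
#' @param trait_means Named positive vector of trait means on the natural
#'   scale (LA cm^2, SLA cm^2/g, LDMC g/g, WD g/cm^3, WDMC g/g, H_max m).
#' @param trait_log_sds Log-scale standard deviations, same names.
#' @param trait_cor Common inter-trait correlation on the log scale
#'   (controls the PCA axis-1 variance share, `(1 + 5 r) / 6`).
#' @param strength Dimensionless interaction strength (>= 0): the slope of
#'   the logistic thinning rule on standardized local pressure.
#' @param response_mix Hierarchical scenario only: weight of the
#'   directional shared-avoidance component of competitive pressure
#'   (crowding by high-ranked neighbours, felt by all stems) relative to
#'   the rank-gap component (each stem suffers in proportion to its
#'   neighbours' summed trait advantage).
#' @param interaction_radius Neighbourhood radius (m) over which competing
#'   stems exert pressure.
#' @param habitat_wavelength,habitat_amplitude Wavelength (m) and amplitude
#'   of the smooth sinusoidal habitat covariate used by the filtering
#'   scenario.
#' @param sapling_fraction Probability a stem's DBH falls in the 1-3 cm
#'   sapling class; the remainder are adults with DBH in (10, 60].
#' @param seed Integer seed; the configuration is fully deterministic.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("neutral", "filtering",
                                         "hierarchical",
                                         "limiting_similarity"),
                            n_species = 20, n_stems = 150,
                            window = pp_window(0, 250, 0, 250),
                            kappa = NULL, sigma = 8, mu_off = 8,
                            trait_means = c(LA = 30, SLA = 150, LDMC = 0.4,
                                            WD = 0.55, WDMC = 0.5,
                                            H_max = 15),
                            trait_log_sds = c(LA = 0.8, SLA = 0.35,
                                              LDMC = 0.25, WD = 0.2,
                                              WDMC = 0.2, H_max = 0.4),
                            trait_cor = 0.34,
                            strength = 1, response_mix = 0.35,
                            interaction_radius = 10,
                            habitat_wavelength = 80, habitat_amplitude = 1,
                            sapling_fraction = 0.65, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(window, "pp_window"),
            n_species >= 1, n_stems >= 1, sigma > 0, mu_off > 0,
            strength >= 0, response_mix >= 0, response_mix <= 1,
            interaction_radius > 0,
            habitat_wavelength > 0,
            trait_cor >= 0, trait_cor < 1,
            all(trait_means > 0), all(trait_log_sds > 0),
            identical(sort(names(trait_means)), sort(names(trait_log_sds))))
  if (is.null(kappa)) kappa <- n_stems / (mu_off * window_area(window))
  if (kappa <= 0) stop("kappa must be positive")
  structure(list(scenario = scenario, n_species = as.integer(n_species),
                 n_stems = as.integer(n_stems), window = window,
                 kappa = kappa, sigma = sigma, mu_off = mu_off,
                 trait_means = trait_means, trait_log_sds = trait_log_sds,
                 trait_cor = trait_cor, strength = strength,
                 response_mix = response_mix,
                 interaction_radius = interaction_radius,
                 habitat_wavelength = habitat_wavelength,
                 habitat_amplitude = habitat_amplitude,
                 sapling_fraction = sapling_fraction,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Smooth sinusoidal habitat covariate
#'
#' `amplitude * sin(2 pi x / wavelength) * sin(2 pi y / wavelength)`,
#' evaluated relative to the window origin. A parameter-sparse stand-in for
#' topographic/edaphic gradients: it is smooth, bounded in
#' `[-amplitude, amplitude]`, and periodic.
#'
#' @param x,y Coordinates in metres.
#' @param window A [pp_window()].
#' @param wavelength Spatial period in metres.
#' @param amplitude Field amplitude.
#' @return Numeric vector of covariate values.
#' @export
habitat_field <- function(x, y, window, wavelength, amplitude = 1) {
  amplitude * sin(2 * pi * (x - window$x_min) / wavelength) *
    sin(2 * pi * (y - window$y_min) / wavelength)
}

# species trait table driven by a shared latent axis `u`:
# log t_ks = log(mean_k) + sd_k * (l * u_s + sqrt(1 - l^2) * e_ks),
# with loading l = sqrt(trait_cor), so every log-trait pair correlates at
# trait_cor and the correlation-matrix leading eigenvalue is 1 + 5 * trait_cor.
simulate_trait_table <- function(config, latent) {
  nm <- names(config$trait_means)
  l <- sqrt(config$trait_cor)
  n <- config$n_species
  vals <- sapply(nm, function(k) {
    eps <- rnorm(n)
    exp(log(config$trait_means[[k]]) +
          config$trait_log_sds[[k]] * (l * latent + sqrt(1 - l^2) * eps))
  })
  df <- data.frame(species_id = sprintf("sp%02d", seq_len(n)), vals,
                   row.names = NULL, check.names = FALSE)
  df[, c("species_id", "LA", "SLA", "LDMC", "WD", "WDMC", "H_max")]
}

# exact-abundance Thomas placement: cluster count Poisson, each stem
# assigned to a uniformly chosen cluster, Gaussian displacement, toroidal
# wrap (keeps the per-species candidate abundance exactly n_stems)
place_species <- function(config) {
  w <- config$window
  n_par <- max(1L, rpois(1, config$kappa * window_area(w)))
  px <- runif(n_par, w$x_min, w$x_max)
  py <- runif(n_par, w$y_min, w$y_max)
  idx <- sample.int(n_par, config$n_stems, replace = TRUE)
  x <- px[idx] + rnorm(config$n_stems, 0, config$sigma)
  y <- py[idx] + rnorm(config$n_stems, 0, config$sigma)
  p <- wrap_pattern(x, y, w)
  data.frame(x = p$x, y = p$y)
}

#' Simulate a mapped community under a known assembly mechanism
#'
#' Generates a stem-mapped census and a species trait table under one of
#' four generative scenarios, providing ground truth for the downstream
#' association/trait/model chain:
#'
#' * `neutral` — every species is an independent Thomas cluster process;
#'   traits are independent of location. Spatial associations should be
#'   classified non-independent at roughly the nominal rate only.
#' * `filtering` — each stem survives with probability decreasing in the
#'   squared mismatch between the local habitat covariate and its species'
#'   trait-ranked habitat optimum, so similar-trait species co-locate.
#' * `hierarchical` — each stem's pressure is the count of neighbours
#'   (within `interaction_radius`) carrying a higher latent trait value;
#'   thinning removes stems under directional competitive disadvantage, so
#'   association tracks the signed trait difference.
#' * `limiting_similarity` — pressure is a Gaussian trait-similarity kernel
#'   summed over neighbours, so functionally similar stems repel.
#'
#' All interaction scenarios use the same thinning rule: survival
#' probability `plogis(-strength * z)`, where `z` is the community-wide
#' standardized local pressure. `strength = 0` disables thinning; larger
#' values sharpen selection without collapsing abundances (mean survival
#' stays near one half).
#'
#' DBH values are drawn from a sapling/adult mixture so both census stages
#' are populated; per-stem heights are proportional to the species' maximum
#' height.
#'
#' @param config A [scenario_config()].
#' @return A list with `census` (data.frame: stem_id, species_id, x, y,
#'   dbh, height), `traits` (data.frame: species_id plus six trait
#'   columns), and `truth` (scenario name, per-species latent trait values
#'   and ranks, interaction strength, stems retained per species).
#' @examples
#' com <- simulate_community(scenario_config("neutral", n_species = 4,
#'                                           n_stems = 30, seed = 42))
#' head(com$census)
#' @export
simulate_community <- function(config) {
  if (!inherits(config, "scenario_config")) {
    stop("config must be created by scenario_config()")
  }
  with_seed(config$seed, {
    latent <- rnorm(config$n_species)
    traits <- simulate_trait_table(config, latent)

    placed <- do.call(rbind, lapply(seq_len(config$n_species), function(s) {
      d <- place_species(config)
      d$species_id <- traits$species_id[s]
      d$latent <- latent[s]
      d
    }))

    keep <- rep(TRUE, nrow(placed))
    # pressure fields use gaussianized species ranks, so one extreme trait
    # draw cannot dominate the interaction structure
    grank <- qnorm((rank(latent) - 0.5) / config$n_species)
    placed$ulevel <- grank[match(placed$species_id, traits$species_id)]
    if (config$scenario != "neutral" && config$strength > 0) {
      pressure <- switch(
        config$scenario,
        filtering = {
          # species are matched to equal-area quantile bands of the
          # habitat field: species s prefers locations where the field's
          # spatial CDF is near q_s = (rank_s - 0.5) / S. Quantile
          # matching keeps habitat area (hence abundance and clustering)
          # identical across ranks, so only trait similarity structures
          # co-occurrence.
          w <- config$window
          gx <- seq(w$x_min, w$x_max, length.out = 101)
          gy <- seq(w$y_min, w$y_max, length.out = 101)
          fld <- habitat_field(rep(gx, each = 101), rep(gy, 101), w,
                               config$habitat_wavelength,
                               config$habitat_amplitude)
          cdf <- stats::ecdf(fld)
          q_s <- (rank(latent) - 0.5) / config$n_species
          env_q <- cdf(habitat_field(placed$x, placed$y, w,
                                     config$habitat_wavelength,
                                     config$habitat_amplitude))
          (env_q - q_s[match(placed$species_id, traits$species_id)])^2
        },
        hierarchical = {
          # two faces of competitive hierarchy, combined after
          # standardization: a rank-gap disadvantage (each stem suffers in
          # proportion to its neighbours' summed trait advantage, so
          # rank-distant pairs segregate) and shared avoidance of strong
          # competitive effects (every stem suffers under crowding by
          # high-ranked neighbours, effect Phi(2 u_q), so subordinate
          # species co-occur in refugia). response_mix weights the second,
          # directional component.
          sp_idx <- match(placed$species_id, traits$species_id)
          gap <- cpp_neighbor_pressure(placed$x, placed$y, placed$ulevel,
                                       sp_idx, config$interaction_radius,
                                       3L, 1)
          dir <- cpp_neighbor_pressure(placed$x, placed$y, placed$ulevel,
                                       sp_idx, config$interaction_radius,
                                       1L, 0.5)
          zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
          (1 - config$response_mix) * zs(gap) + config$response_mix * zs(dir)
        },
        limiting_similarity = cpp_neighbor_pressure(
          placed$x, placed$y, placed$ulevel,
          match(placed$species_id, traits$species_id),
          config$interaction_radius, 2L, 1)
      )
      s_p <- sd(pressure)
      if (s_p > 0) {
        z <- (pressure - mean(pressure)) / s_p
        keep <- runif(nrow(placed)) < stats::plogis(-config$strength * z)
      }
    }
    census <- placed[keep, c("species_id", "x", "y"), drop = FALSE]

    n <- nrow(census)
    sap <- runif(n) < config$sapling_fraction
    census$dbh <- ifelse(sap, runif(n, 1, 3), runif(n, 10, 60))
    hmax <- traits$H_max[match(census$species_id, traits$species_id)]
    census$height <- hmax * runif(n)^(1 / 3)
    census$stem_id <- sprintf("t%05d", seq_len(n))
    census <- census[, c("stem_id", "species_id", "x", "y", "dbh", "height")]
    rownames(census) <- NULL

    truth <- list(scenario = config$scenario,
                  latent = setNames(latent, traits$species_id),
                  trait_rank = setNames(rank(latent), traits$species_id),
                  strength = config$strength,
                  stems_retained = table(census$species_id))
    list(census = census, traits = traits, truth = truth)
  })
}
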