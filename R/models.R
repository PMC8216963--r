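#' Assemble model data for one trait, statistic and radius
#'
#' Joins association records 1:1 with the ordered-pair trait distances,
#' producing the data frame fitted by [fit_mixed_model()]: one row per
#' ordered pair with the standardized effect size `z`, the focal species,
#' and the standardized `absolute` and `hierarchical` predictors for the
#' chosen trait. Degenerate records (zero null variance) and pairs with a
#' missing trait value are dropped, with counts reported in attributes
#' `n_degenerate_dropped` and `n_missing_dropped`.
#'
#' @param assoc Association records from [pairwise_association_analysis()].
#' @param distances Raw pairwise distances from [trait_distance_table()].
#' @param trait Trait name (a column prefix in `distances`, e.g. `"SLA"`
#'   or `"PCA"`).
#' @param statistic,r The summary statistic and radius to select.
#' @param standardize Standardize the predictors over the included pairs
#'   (default TRUE, the protocol's centering/scaling step).
#' @return Data frame with columns `focal`, `other`, `z`, `absolute`,
#'   `hierarchical`.
#' @export
build_model_data <- function(assoc, distances, trait, statistic, r,
                             standardize = TRUE) {
  sel <- assoc[assoc$statistic == statistic & assoc$r == r, , drop = FALSE]
  if (nrow(sel) == 0) stop("no association records for that statistic/radius")
  cols <- paste0(trait, c("_abs", "_hier"))
  if (!all(cols %in% names(distances))) {
    stop("trait not present in distance table: ", trait)
  }
  key_a <- paste(sel$focal_id, sel$other_id)
  key_d <- paste(distances$focal_id, distances$other_id)
  idx <- match(key_a, key_d)
  if (anyNA(idx)) stop("association records missing from the distance table")
  df <- data.frame(focal = sel$focal_id, other = sel$other_id, z = sel$z,
                   absolute = distances[[cols[1]]][idx],
                   hierarchical = distances[[cols[2]]][idx])
  n0 <- nrow(df)
  keep <- !sel$degenerate & is.finite(df$z)
  n_degen <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  miss <- !stats::complete.cases(df[, c("absolute", "hierarchical")])
  df <- df[!miss, , drop = FALSE]
  if (nrow(df) < 4) stop("too few usable pairs after exclusions")
  if (standardize) {
    df <- standardize_distances(df, columns = c("absolute", "hierarchical"))
  }
  rownames(df) <- NULL
  attr(df, "n_degenerate_dropped") <- n_degen
  attr(df, "n_missing_dropped") <- sum(miss)
  attr(df, "meta") <- list(trait = trait, statistic = statistic, r = r)
  df
}

#' Per-focal-species random-slope mixed model of spatial association
#'
#' Fits, by restricted maximum likelihood via [lme4::lmer()],
#'
#' \deqn{z_{ij} = a + a_i + (b + b_i)\,\mathrm{pred}_{ij} + \varepsilon_{ij}}
#'
#' where `z_ij` is the standardized effect size of the ordered pair with
#' focal species i, `pred_ij` a standardized trait-distance predictor, `a`
#' and `b` fixed effects, and `a_i`, `b_i` a random intercept and random
#' slope per focal species. With two predictors (the joint
#' absolute + hierarchical comparison model) each gets its own fixed and
#' random slope. Random effects are allowed to covary (unstructured
#' covariance); if that fit is singular the model is refitted with
#' independent random effects and flagged.
#'
#' Fixed-effect p-values use the large-sample normal approximation on the
#' t statistic (pair counts are large in this design).
#'
#' @param data Data frame from [build_model_data()] (or any frame with the
#'   response, group and predictor columns).
#' @param predictors Character vector of predictor column names, e.g.
#'   `"absolute"` for the screening model or
#'   `c("absolute", "hierarchical")` for the joint comparison model.
#' @param response,group Column names of the response and the focal-species
#'   grouping factor.
#' @param reml Fit by REML (default) or ML.
#' @return Object of class `assoc_model_fit`: the `lme4` model plus fixed
#'   effects (`fixed`, `se`, `t`, `p`), per-focal random effects
#'   (`ranef`), random-effect covariance (`vcov_re`), residual variance
#'   `sigma2`, `r2c` (conditional R-squared), flags `singular` and
#'   `converged`, and metadata.
#' @export
fit_mixed_model <- function(data, predictors, response = "z",
                            group = "focal", reml = TRUE) {
  stopifnot(is.data.frame(data), length(predictors) >= 1,
            all(c(response, group, predictors) %in% names(data)))
  for (p in predictors) {
    if (sd(data[[p]]) == 0) stop("degenerate predictor (zero variance): ", p)
  }
  if (length(unique(data[[group]])) < 2) stop("need at least two focal species")
  pterm <- paste(predictors, collapse = " + ")
  form <- stats::as.formula(sprintf("%s ~ %s + (1 + %s | %s)",
                                    response, pterm, pterm, group))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(lme4::lmer(form, data = data, REML = reml,
                                     control = ctrl))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  structure_used <- "unstructured"
  if (singular && length(predictors) >= 1) {
    form2 <- stats::as.formula(sprintf("%s ~ %s + (1 + %s || %s)",
                                       response, pterm, pterm, group))
    fit2 <- suppressMessages(lme4::lmer(form2, data = data, REML = reml,
                                        control = ctrl))
    if (!lme4::isSingular(fit2, tol = 1e-4)) {
      fit <- fit2
      structure_used <- "independent"
      singular <- FALSE
    }
  }
  cf <- summary(fit)$coefficients
  fixed <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  tval <- cf[, "t value"]
  pval <- 2 * pnorm(-abs(tval))
  re <- lme4::ranef(fit)[[group]]
  vc <- re_covariance(fit, group)
  out <- structure(list(model = fit, predictors = predictors,
                        response = response, group = group,
                        fixed = fixed, se = se, t = tval, p = pval,
                        ranef = re, vcov_re = vc,
                        sigma2 = stats::sigma(fit)^2,
                        singular = singular,
                        re_structure = structure_used,
                        converged = length(fit@optinfo$conv$lme4$messages) == 0,
                        n_focal = length(unique(data[[group]])),
                        n_pairs = nrow(data),
                        meta = attr(data, "meta")),
                   class = "assoc_model_fit")
  out$r2c <- conditional_r_squared(out)
  out
}

# combined random-effect covariance matrix over (Intercept) + predictors,
# summing the diagonal blocks of a double-bar (independent) fit
re_covariance <- function(fit, group) {
  vc <- lme4::VarCorr(fit)
  terms <- which(names(vc) == group | startsWith(names(vc), paste0(group, ".")))
  all_names <- unique(unlist(lapply(vc[terms], rownames)))
  m <- matrix(0, length(all_names), length(all_names),
              dimnames = list(all_names, all_names))
  for (k in terms) {
    blk <- vc[[k]]
    m[rownames(blk), colnames(blk)] <-
      m[rownames(blk), colnames(blk)] + blk[, , drop = FALSE]
  }
  m
}

#' @export
print.assoc_model_fit <- function(x, ...) {
  cat("mixed model of spatial association (Eq. z = a + a_i + (b + b_i) pred)\n")
  cat(sprintf("  %d pairs, %d focal species; predictors: %s\n",
              x$n_pairs, x$n_focal, paste(x$predictors, collapse = ", ")))
  est <- cbind(estimate = x$fixed, se = x$se, t = x$t, p = x$p)
  print(round(est, 4))
  cat(sprintf("  conditional R^2 = %.3f; residual var = %.3f%s\n", x$r2c,
              x$sigma2, if (x$singular) " [singular RE covariance]" else ""))
  invisible(x)
}

#' Per-focal-species total slopes
#'
#' The per-focal-species coefficient of a predictor is the fixed slope plus
#' the predicted (shrunken, BLUP) random deviation, `b + b_i` — the only
#' scale on which per-species effects are comparable across models.
#'
#' @param fit An [fit_mixed_model()] result.
#' @param predictor Which predictor's slopes to extract (default the
#'   first).
#' @return Named numeric vector, one total slope per focal species.
#' @export
focal_species_slopes <- function(fit, predictor = fit$predictors[1]) {
  stopifnot(inherits(fit, "assoc_model_fit"),
            predictor %in% fit$predictors)
  b <- fit$fixed[[predictor]]
  bi <- if (predictor %in% names(fit$ranef)) fit$ranef[[predictor]] else
    rep(0, nrow(fit$ranef))
  setNames(b + bi, rownames(fit$ranef))
}

#' Conditional R-squared of a random-slope mixed model
#'
#' The proportion of variance explained jointly by fixed and random
#' effects (Nakagawa-Schielzeth, with the random-slope extension):
#' `R2c = (var_fixed + var_random) / (var_fixed + var_random + var_resid)`,
#' where `var_fixed` is the variance of the fixed-effect linear predictor
#' and `var_random` the mean over observations of the quadratic form of the
#' random-effect design in the random-effect covariance (i.e. the slope
#' variance enters through the predictor's second moment).
#'
#' @param fit An [fit_mixed_model()] result.
#' @return `R2c` in `[0, 1]`.
#' @export
conditional_r_squared <- function(fit) {
  stopifnot(inherits(fit, "assoc_model_fit"))
  X <- stats::model.matrix(fit$model)
  beta <- lme4::fixef(fit$model)
  var_f <- var(as.numeric(X %*% beta))
  re_cols <- rownames(fit$vcov_re)
  Xr <- X[, re_cols, drop = FALSE]
  var_r <- mean(rowSums((Xr %*% fit$vcov_re) * Xr))
  tot <- var_f + var_r + fit$sigma2
  if (tot <= 0) stop("zero total variance")
  (var_f + var_r) / tot
}

#' Significance tier label
#'
#' `***` p < .001, `**` p < .01, `*` p < .05, `.` p < .1, `ns` otherwise.
#'
#' @param p A p-value.
#' @return Character tier.
#' @export
significance_tier <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p < 0.1) "." else "ns"
}

#' Compare the strengths of trait dissimilarity and trait hierarchy
#'
#' For each focal species, takes the absolute value of its total slope
#' (`|b + b_i|`) under the absolute-distance predictor and under the
#' hierarchical-distance predictor, and compares the two paired
#' distributions with a paired t-test. The direction says which
#' trait-distance measure structures the pairwise associations more
#' strongly — the key contrast separating environmental filtering
#' (dissimilarity stronger) from hierarchical competition (hierarchy
#' stronger).
#'
#' Both slopes may come from one joint two-predictor fit (the default
#' comparison model) or from two separate single-predictor fits covering
#' the identical focal-species set.
#'
#' @param fit_abs Fit providing the absolute-distance slopes.
#' @param fit_hier Fit providing the hierarchical-distance slopes; defaults
#'   to `fit_abs` (joint model).
#' @param predictor_abs,predictor_hier Predictor names in the respective
#'   fits.
#' @return Object of class `strength_comparison`: `t`, `p`, `tier`,
#'   `mean_abs`, `mean_hier`, `direction` (`"hierarchy"`, `"absolute"` or
#'   `"equal"`), `slopes` (per-focal data frame), and `flag` for
#'   zero-variance differences.
#' @export
compare_strengths <- function(fit_abs, fit_hier = fit_abs,
                              predictor_abs = "absolute",
                              predictor_hier = "hierarchical") {
  sa <- abs(focal_species_slopes(fit_abs, predictor_abs))
  sh <- abs(focal_species_slopes(fit_hier, predictor_hier))
  if (!identical(sort(names(sa)), sort(names(sh)))) {
    stop("fits do not cover the identical focal-species set")
  }
  sh <- sh[names(sa)]
  d <- sh - sa
  flag <- "none"
  # guard the degenerate cases t.test refuses: identical vectors and
  # (numerically) constant nonzero differences
  if (sd(d) <= 1e-10 * (abs(mean(d)) + 1e-10)) {
    if (isTRUE(all.equal(max(abs(d)), 0))) {
      tstat <- 0
      p <- 1
      flag <- "identical_slopes"
    } else {
      tstat <- sign(mean(d)) * Inf
      p <- 0
      flag <- "constant_difference"
    }
  } else {
    tt <- t.test(sh, sa, paired = TRUE)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  direction <- if (mean(sh) > mean(sa)) "hierarchy"
  else if (mean(sh) < mean(sa)) "absolute" else "equal"
  structure(list(t = tstat, p = p, tier = significance_tier(p),
                 mean_abs = mean(sa), mean_hier = mean(sh),
                 direction = direction,
                 slopes = data.frame(focal = names(sa), absolute = unname(sa),
                                     hierarchical = unname(sh)),
                 flag = flag),
            class = "strength_comparison")
}

#' @export
print.strength_comparison <- function(x, ...) {
  cat(sprintf(
    "strength comparison: mean |b_abs| = %.3f, mean |b_hier| = %.3f\n",
    x$mean_abs, x$mean_hier))
  cat(sprintf("  paired t = %.3f, p = %.3g (%s); stronger: %s\n",
              x$t, x$p, x$tier, x$direction))
  invisible(x)
}

#' Map model results to an assembly-mechanism label
#'
#' The decision tree linking the sign of the absolute-distance effect and
#' the dissimilarity-vs-hierarchy comparison to a mechanism:
#'
#' * significant positive `b_abs` — functionally similar species segregate:
#'   limiting similarity;
#' * significant negative `b_abs` — similar species co-occur; then if
#'   hierarchy is significantly the stronger measure the label is
#'   hierarchical competition, otherwise environmental filtering;
#' * non-significant `b_abs` — no signal, `none_detected`.
#'
#' @param b_abs Fixed absolute-distance slope from the screening model.
#' @param p_abs Its p-value.
#' @param comparison A [compare_strengths()] result (needed only when
#'   `b_abs` is significantly negative).
#' @param alpha Significance level for the screening decision.
#' @param comparison_alpha Threshold below which the paired test counts as
#'   evidence that hierarchy is the stronger measure. Defaults to 0.1,
#'   the boundary of the "ns" tier in the reporting convention (see
#'   [significance_tier()]): a comparison at or above it reads as "no
#'   significant difference", and ties go to environmental filtering.
#' @return One of `"limiting_similarity"`, `"environmental_filtering"`,
#'   `"hierarchical_competition"`, `"none_detected"`.
#' @export
interpret_mechanism <- function(b_abs, p_abs, comparison = NULL,
                                alpha = 0.05, comparison_alpha = 0.1) {
  if (is.na(p_abs) || p_abs >= alpha) return("none_detected")
  if (b_abs > 0) return("limiting_similarity")
  if (is.null(comparison)) {
    stop("comparison result required to separate filtering from ",
         "hierarchical competition")
  }
  stopifnot(inherits(comparison, "strength_comparison"))
  if (comparison$direction == "hierarchy" && comparison$p < comparison_alpha) {
    "hierarchical_competition"
  } else {
    "environmental_filtering"
  }
}
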