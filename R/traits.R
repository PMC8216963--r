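#' Absolute and hierarchical trait distances
#'
#' For focal species i and neighbour species j with trait values `t_i`,
#' `t_j`: the absolute trait distance `|t_i - t_j|` measures trait
#' dissimilarity (a proxy for niche difference); the hierarchical trait
#' distance `t_i - t_j` keeps the sign, measuring trait hierarchy (a proxy
#' for competitive-rank difference). The focal species always comes first,
#' matching the focal species of the corresponding spatial analysis.
#'
#' @param t_i,t_j Finite trait values (focal first).
#' @return `absolute_distance()`: non-negative value; missing inputs give
#'   `NA` (pairs with missing traits are excluded downstream, with a
#'   logged count).
#' @examples
#' absolute_distance(3, 5)     # 2
#' hierarchical_distance(3, 5) # -2
#' @export
absolute_distance <- function(t_i, t_j) abs(t_i - t_j)

#' @rdname absolute_distance
#' @export
hierarchical_distance <- function(t_i, t_j) t_i - t_j

#' Species maximum height
#'
#' The 99% quantile of a species' per-stem height measurements, the
#' conventional plot-level operationalization of maximum attainable height
#' (robust to single outlier stems). Uses linear interpolation between
#' order statistics (R quantile type 7) by default.
#'
#' @param heights Numeric vector of stem heights in metres (NAs dropped).
#' @param prob Quantile level (default 0.99).
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return `H_max` in metres.
#' @examples
#' max_height(rep(7, 10)) # 7
#' @export
max_height <- function(heights, prob = 0.99, type = 7) {
  heights <- heights[is.finite(heights)]
  if (length(heights) == 0) stop("no finite height measurements")
  unname(quantile(heights, probs = prob, type = type))
}

#' Integrated trait axis: first principal component
#'
#' PCA of the species x trait matrix with columns centered and scaled to
#' unit variance (the correlation-matrix PCA — traits carry heterogeneous
#' units). The axis-1 score is the integrated, multi-trait measure of each
#' species' functional strategy, and is used exactly like a single trait
#' when building distances.
#'
#' The sign of a principal axis is arbitrary; it is fixed here so that the
#' `sign_trait` loading (SLA by default) is positive. Note that
#' hierarchical distances on the integrated axis flip sign with the axis
#' orientation, so results must always be read relative to this
#' convention.
#'
#' @param trait_table Data frame with `species_id` plus numeric trait
#'   columns; at least two species and two traits, no missing values.
#' @param traits Which trait columns to use (default: all numeric columns).
#' @param sign_trait Trait whose axis-1 loading is forced positive.
#' @return List with `scores` (named per species), `variance_share` of
#'   axis 1, `loadings`, and `variance_shares` for all axes (summing to 1).
#' @export
integrated_trait_scores <- function(trait_table, traits = NULL,
                                    sign_trait = "SLA") {
  stopifnot(is.data.frame(trait_table), "species_id" %in% names(trait_table))
  if (anyDuplicated(trait_table$species_id)) stop("duplicated species_id")
  if (is.null(traits)) {
    traits <- setdiff(names(trait_table)[vapply(trait_table, is.numeric,
                                                logical(1))], "species_id")
  }
  m <- as.matrix(trait_table[, traits, drop = FALSE])
  if (nrow(m) < 2) stop("need at least two species")
  if (ncol(m) < 2) stop("need at least two traits")
  if (anyNA(m)) stop("missing trait values; drop incomplete species first")
  if (any(apply(m, 2, sd) == 0)) stop("constant trait column cannot be scaled")
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  flip <- 1
  if (sign_trait %in% traits && p$rotation[sign_trait, 1] < 0) flip <- -1
  shares <- p$sdev^2 / sum(p$sdev^2)
  list(scores = setNames(flip * p$x[, 1], trait_table$species_id),
       variance_share = shares[1],
       loadings = flip * p$rotation[, 1],
       variance_shares = shares)
}

#' Pairwise trait distance table
#'
#' Builds, for every ordered species pair, the absolute and hierarchical
#' distance for each trait and (optionally) the integrated PCA axis. Pairs
#' involving a species with a missing value for some trait get `NA` for
#' that trait only and are excluded from that trait's model downstream.
#'
#' @param trait_table Data frame with `species_id` and trait columns.
#' @param species Optional subset of species to include (e.g. the species
#'   retained for one life stage); default all.
#' @param traits Trait columns to use; default all numeric columns.
#' @param include_pca Add the integrated axis (computed on the included
#'   species with complete trait data) as pseudo-trait `"PCA"`.
#' @return Data frame with `focal_id`, `other_id`, then
#'   `<trait>_abs` and `<trait>_hier` columns (raw, unstandardized). The
#'   PCA variance share is attached as attribute `pca_variance_share`.
#' @export
trait_distance_table <- function(trait_table, species = NULL, traits = NULL,
                                 include_pca = TRUE) {
  stopifnot(is.data.frame(trait_table), "species_id" %in% names(trait_table))
  if (is.null(traits)) {
    traits <- setdiff(names(trait_table)[vapply(trait_table, is.numeric,
                                                logical(1))], "species_id")
  }
  tab <- trait_table
  if (!is.null(species)) {
    missing_sp <- setdiff(species, tab$species_id)
    if (length(missing_sp)) {
      stop("species absent from trait table: ",
           paste(missing_sp, collapse = ", "))
    }
    tab <- tab[tab$species_id %in% species, , drop = FALSE]
  }
  vals <- lapply(traits, function(tr) setNames(tab[[tr]], tab$species_id))
  names(vals) <- traits
  share <- NA_real_
  if (include_pca) {
    complete <- tab[stats::complete.cases(tab[, traits, drop = FALSE]), ,
                    drop = FALSE]
    pca <- integrated_trait_scores(complete, traits = traits)
    sc <- rep(NA_real_, nrow(tab))
    names(sc) <- tab$species_id
    sc[names(pca$scores)] <- pca$scores
    vals$PCA <- sc
    share <- pca$variance_share
  }
  pairs <- ordered_pairs(tab$species_id)
  out <- pairs
  for (tr in names(vals)) {
    ti <- vals[[tr]][pairs$focal_id]
    tj <- vals[[tr]][pairs$other_id]
    out[[paste0(tr, "_abs")]] <- absolute_distance(ti, tj)
    out[[paste0(tr, "_hier")]] <- hierarchical_distance(ti, tj)
  }
  attr(out, "pca_variance_share") <- unname(share)
  out
}

#' Center and standardize distance predictors
#'
#' Transforms each predictor column to mean 0 and sample sd 1 over the
#' pairs in the analysis set, so coefficient magnitudes are comparable
#' across traits and between the absolute and hierarchical measures. The
#' transformation parameters are stored in the `standardization` attribute.
#'
#' @param distance_table Output of [trait_distance_table()] (or any data
#'   frame whose non-id numeric columns are predictors).
#' @param columns Columns to standardize; default every numeric column
#'   except the id columns.
#' @return The table with standardized columns and attribute
#'   `standardization` (data frame of column, mean, sd).
#' @export
standardize_distances <- function(distance_table, columns = NULL) {
  if (is.null(columns)) {
    columns <- setdiff(names(distance_table)[vapply(distance_table,
                                                    is.numeric, logical(1))],
                       c("focal_id", "other_id"))
  }
  if (nrow(distance_table) < 2) stop("need at least two pairs")
  meta <- data.frame(column = columns, mean = NA_real_, sd = NA_real_)
  for (k in seq_along(columns)) {
    v <- distance_table[[columns[k]]]
    mu <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("zero or undefined variance in predictor: ", columns[k])
    }
    distance_table[[columns[k]]] <- (v - mu) / s
    meta$mean[k] <- mu
    meta$sd[k] <- s
  }
  attr(distance_table, "standardization") <- meta
  distance_table
}
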