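#' Life-stage census filter
#'
#' Defines a DBH interval and a minimum per-species abundance. The standard
#' protocol analyses two stages: saplings with DBH in the closed interval
#' 1-3 cm, and adults with DBH strictly greater than 10 cm; species with
#' fewer than 50 in-stage individuals are dropped so every pattern is large
#' enough for point-pattern analysis.
#'
#' @param name Stage label.
#' @param dbh_min,dbh_max DBH bounds in cm (`dbh_max` may be `Inf`).
#' @param lower_strict,upper_strict Whether the bounds exclude the endpoint
#'   (default: closed bounds).
#' @param min_abundance Minimum in-stage individuals per retained species.
#' @return A `stage_filter` object.
#' @examples
#' sapling_filter()
#' adult_filter()
#' @export
stage_filter <- function(name, dbh_min, dbh_max = Inf,
                         lower_strict = FALSE, upper_strict = FALSE,
                         min_abundance = 1) {
  stopifnot(dbh_min > 0, dbh_max > dbh_min, min_abundance >= 1)
  structure(list(name = name, dbh_min = dbh_min, dbh_max = dbh_max,
                 lower_strict = lower_strict, upper_strict = upper_strict,
                 min_abundance = as.integer(min_abundance)),
            class = "stage_filter")
}

#' @rdname stage_filter
#' @export
sapling_filter <- function(min_abundance = 50) {
  stage_filter("sapling", 1, 3, min_abundance = min_abundance)
}

#' @rdname stage_filter
#' @export
adult_filter <- function(min_abundance = 50) {
  stage_filter("adult", 10, Inf, lower_strict = TRUE,
               min_abundance = min_abundance)
}

#' @rdname stage_filter
#' @param min_dbh Lower DBH bound for the all-stems filter.
#' @export
all_stems_filter <- function(min_abundance = 1, min_dbh = 1) {
  stage_filter("all", min_dbh, Inf, min_abundance = min_abundance)
}

#' Filter a census to one life stage
#'
#' Keeps stems whose DBH lies in the stage interval, then drops every
#' species whose in-stage abundance falls below the stage's
#' `min_abundance` (the remaining stems of that species are removed
#' entirely for this stage).
#'
#' @param census Census data frame with columns `species_id` and `dbh`.
#' @param stage A [stage_filter()].
#' @return List with `census` (filtered rows), `species` (retained
#'   species, sorted), and `counts` (named in-stage abundances of retained
#'   species).
#' @export
filter_census <- function(census, stage) {
  stopifnot(inherits(stage, "stage_filter"),
            all(c("species_id", "dbh") %in% names(census)))
  lo <- if (stage$lower_strict) census$dbh > stage$dbh_min
        else census$dbh >= stage$dbh_min
  hi <- if (stage$upper_strict) census$dbh < stage$dbh_max
        else census$dbh <= stage$dbh_max
  kept <- census[lo & hi, , drop = FALSE]
  counts <- table(kept$species_id)
  species <- sort(names(counts)[counts >= stage$min_abundance])
  kept <- kept[kept$species_id %in% species, , drop = FALSE]
  if (nrow(kept) == 0) warning("stage filter removed every stem")
  rownames(kept) <- NULL
  list(census = kept, species = species,
       counts = counts[species])
}

#' Proportions of association classes
#'
#' Summarizes association records into the fractions of attraction,
#' repulsion and independence per statistic and radius. Degenerate records
#' (zero null variance) are excluded from the denominator, with their
#' count reported in the `n_degenerate` column.
#'
#' @param records Association records from
#'   [pairwise_association_analysis()].
#' @return Data frame with one row per statistic x radius: `statistic`,
#'   `r`, `attraction`, `repulsion`, `independence` (summing to 1),
#'   `n_pairs`, `n_degenerate`.
#' @export
association_proportions <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no association records")
  cells <- unique(records[, c("statistic", "r")])
  cells <- cells[order(cells$statistic, cells$r), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    sel <- records$statistic == cells$statistic[k] & records$r == cells$r[k]
    rec <- records[sel, , drop = FALSE]
    degen <- rec$degenerate
    rec <- rec[!degen, , drop = FALSE]
    n <- nrow(rec)
    data.frame(statistic = cells$statistic[k], r = cells$r[k],
               attraction = sum(rec$class == "attraction") / n,
               repulsion = sum(rec$class == "repulsion") / n,
               independence = sum(rec$class == "independence") / n,
               n_pairs = n, n_degenerate = sum(degen))
  }))
  rownames(out) <- NULL
  out
}

#' Read and write census/trait tables
#'
#' Plain-CSV interchange with documented headers: the census carries
#' `stem_id, species_id, x, y, dbh[, height]`, the trait table
#' `species_id, LA, SLA, LDMC, WD, WDMC, H_max`. The observation window is
#' written to a small JSON sidecar next to the census. A `column_map`
#' (named vector `standard = foreign`) adapts foreign headers on read.
#'
#' @param path File path.
#' @param column_map Optional named character vector renaming foreign
#'   columns, e.g. `c(species_id = "sp", dbh = "dbh_cm")`.
#' @return `read_census_csv()` and `read_traits_csv()` return data frames;
#'   writers return the path invisibly.
#' @name community_io
NULL

#' @rdname community_io
#' @export
read_census_csv <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      names(df)[names(df) == column_map[[std]]] <- std
    }
  }
  need <- c("species_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("census must provide columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname community_io
#' @export
read_traits_csv <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      names(df)[names(df) == column_map[[std]]] <- std
    }
  }
  if (!"species_id" %in% names(df)) stop("trait table needs species_id")
  df
}

#' @rdname community_io
#' @param census,traits Data frames to write.
#' @param window A [pp_window()] written to `<census>.window.json`.
#' @export
write_community_csv <- function(census, traits, window, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  census_path <- paste0(path, "_census.csv")
  traits_path <- paste0(path, "_traits.csv")
  write.csv(census, census_path, row.names = FALSE)
  write.csv(traits, traits_path, row.names = FALSE)
  jsonlite::write_json(unclass(window), paste0(path, "_window.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(census = census_path, traits = traits_path))
}

#' @rdname community_io
#' @export
read_window_json <- function(path) {
  w <- jsonlite::read_json(path, simplifyVector = TRUE)
  pp_window(w$x_min, w$x_max, w$y_min, w$y_max)
}

#' Run configuration
#'
#' Bundles every knob of [run_full_analysis()]. `standard_protocol_config()`
#' pins the standard protocol: radii 5/30/50 m, both summary statistics,
#' 999 null replicates, pointwise alpha 0.05, sapling and adult stages at
#' minimum abundance 50.
#'
#' @param census Census data frame or path to a census CSV.
#' @param traits Trait data frame or path to a trait CSV.
#' @param window A [pp_window()] or path to a window JSON sidecar.
#' @param stages List of [stage_filter()]s.
#' @param radii Radii in metres.
#' @param statistics Subset of `c("pcf", "D")`.
#' @param n_sim Null replicates per pair.
#' @param alpha Pointwise significance level.
#' @param traits_used Trait names modelled (column prefixes of the
#'   distance table; `"PCA"` is the integrated axis).
#' @param model_mode `"separate"` (two single-predictor fits, the
#'   default: within a focal species the absolute and hierarchical
#'   distances are nearly collinear, which leaves a joint random-slope
#'   model ill-identified) or `"joint"` (one two-predictor model).
#' @param seed Integer seed for the null-model shift streams.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(census, traits, window,
                       stages = list(all_stems_filter(min_abundance = 30)),
                       radii = c(5, 30, 50), statistics = c("pcf", "D"),
                       n_sim = 199, alpha = 0.05,
                       traits_used = c("LA", "SLA", "LDMC", "WD", "WDMC",
                                       "H_max", "PCA"),
                       model_mode = c("separate", "joint"),
                       seed = 1L, out_dir = NULL) {
  model_mode <- match.arg(model_mode)
  stopifnot(n_sim >= 2, all(radii > 0), alpha > 0, alpha < 1)
  if (is.character(census)) census <- read_census_csv(census)
  if (is.character(traits)) traits <- read_traits_csv(traits)
  if (is.character(window)) window <- read_window_json(window)
  structure(list(census = census, traits = traits, window = window,
                 stages = stages, radii = radii, statistics = statistics,
                 n_sim = n_sim, alpha = alpha, traits_used = traits_used,
                 model_mode = model_mode, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param ... Overrides passed on to [run_config()].
#' @export
standard_protocol_config <- function(census, traits, window, ...) {
  args <- list(census = census, traits = traits, window = window,
               stages = list(sapling_filter(), adult_filter()),
               radii = c(5, 30, 50), statistics = c("pcf", "D"),
               n_sim = 999, alpha = 0.05)
  args[names(list(...))] <- list(...)
  do.call(run_config, args)
}

#' Load a run configuration from YAML or JSON
#'
#' The document mirrors [run_config()]: paths `census`, `traits`,
#' `window`, scalar options, and a `stages` list of
#' `{name, dbh_min, dbh_max, lower_strict, upper_strict, min_abundance}`
#' entries. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p)))
      file.path(base, p) else p
  }
  stages <- lapply(doc$stages, function(s) {
    do.call(stage_filter, s[intersect(names(s),
                                      names(formals(stage_filter)))])
  })
  args <- list(census = resolve(doc$census), traits = resolve(doc$traits),
               window = resolve(doc$window))
  if (length(stages)) args$stages <- stages
  for (k in c("radii", "statistics", "n_sim", "alpha", "traits_used",
              "model_mode", "seed", "out_dir")) {
    if (!is.null(doc[[k]])) args[[k]] <- doc[[k]]
  }
  do.call(run_config, args)
}

#' Run the full assembly-inference pipeline
#'
#' Executes, for every stage x statistic x radius x trait cell:
#' census filtering, pairwise association analysis, trait-distance
#' construction (with a stage-specific integrated PCA axis and
#' stage-specific standardization), the absolute-distance screening model,
#' the joint (or separate) dissimilarity-vs-hierarchy comparison model,
#' and the mechanism label. Deterministic for a fixed configuration.
#'
#' @param config A [run_config()].
#' @return List with `associations` (all records), `proportions` (per
#'   stage), `models` (summary data frame: fixed effects, R2c, comparison
#'   t/p, mechanism label), `distances` (per stage), `manifest` (config
#'   echo, seed, timings, and — when `out_dir` is set — output files with
#'   MD5 hashes). All tables are also written as CSV/JSON under `out_dir`
#'   if given.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  all_assoc <- list()
  all_prop <- list()
  all_dist <- list()
  model_rows <- list()

  for (stage in config$stages) {
    fl <- filter_census(config$census, stage)
    if (length(fl$species) < 2) {
      warning(sprintf("stage '%s': fewer than two species; skipped",
                      stage$name))
      next
    }
    assoc <- pairwise_association_analysis(
      fl$census, config$window, radii = config$radii,
      statistics = config$statistics, n_sim = config$n_sim,
      alpha = config$alpha, seed = config$seed)
    assoc$stage <- stage$name
    all_assoc[[stage$name]] <- assoc
    prop <- association_proportions(assoc)
    prop$stage <- stage$name
    all_prop[[stage$name]] <- prop

    dist_raw <- trait_distance_table(config$traits, species = fl$species)
    dist_raw$stage <- stage$name
    all_dist[[stage$name]] <- dist_raw

    for (st in config$statistics) {
      for (r in config$radii) {
        for (tr in config$traits_used) {
          row <- tryCatch(
            analyse_cell(assoc, dist_raw, tr, st, r, config),
            error = function(e) {
              data.frame(stage = stage$name, statistic = st, r = r,
                         trait = tr, error = conditionMessage(e),
                         stringsAsFactors = FALSE)
            })
          row$stage <- stage$name
          model_rows[[length(model_rows) + 1]] <- row
        }
      }
    }
  }

  models <- if (length(model_rows)) {
    do.call(rbind, lapply(model_rows, pad_row,
                          cols = unique(unlist(lapply(model_rows, names)))))
  } else NULL
  out <- list(associations = do.call(rbind, all_assoc),
              proportions = do.call(rbind, all_prop),
              distances = do.call(rbind, all_dist),
              models = models)
  manifest <- list(seed = config$seed, radii = config$radii,
                   statistics = config$statistics, n_sim = config$n_sim,
                   alpha = config$alpha, model_mode = config$model_mode,
                   stages = vapply(config$stages, `[[`, "", "name"),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (nm in c("associations", "proportions", "distances", "models")) {
      if (!is.null(out[[nm]])) {
        f <- file.path(config$out_dir, paste0(nm, ".csv"))
        write.csv(out[[nm]], f, row.names = FALSE)
        files[nm] <- f
      }
    }
    manifest$files <- lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out$manifest <- manifest
  out
}

pad_row <- function(row, cols) {
  for (c in setdiff(cols, names(row))) row[[c]] <- NA
  row[, cols, drop = FALSE]
}

# one stage x statistic x radius x trait cell: screening fit, comparison
# fit, mechanism label
analyse_cell <- function(assoc, dist_raw, trait, statistic, r, config) {
  dat <- build_model_data(assoc, dist_raw, trait, statistic, r)
  screen <- fit_mixed_model(dat, predictors = "absolute")
  if (config$model_mode == "joint") {
    joint <- fit_mixed_model(dat, predictors = c("absolute", "hierarchical"))
    cmp <- compare_strengths(joint)
    r2c_cmp <- joint$r2c
  } else {
    fa <- fit_mixed_model(dat, predictors = "absolute")
    fh <- fit_mixed_model(dat, predictors = "hierarchical")
    cmp <- compare_strengths(fa, fh)
    r2c_cmp <- fh$r2c
  }
  mech <- interpret_mechanism(screen$fixed[["absolute"]],
                              screen$p[["absolute"]], cmp,
                              alpha = config$alpha)
  data.frame(statistic = statistic, r = r, trait = trait,
             b_abs = screen$fixed[["absolute"]],
             se_abs = screen$se[["absolute"]],
             p_abs = screen$p[["absolute"]],
             r2c_screen = screen$r2c, r2c_comparison = r2c_cmp,
             mean_abs_slope = cmp$mean_abs,
             mean_hier_slope = cmp$mean_hier,
             t_paired = cmp$t, p_paired = cmp$p, tier = cmp$tier,
             direction = cmp$direction, mechanism = mech,
             n_pairs = screen$n_pairs, n_focal = screen$n_focal,
             singular = screen$singular, error = NA_character_,
             stringsAsFactors = FALSE)
}
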