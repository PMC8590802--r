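#' Study-design defaults
#'
#' The single source of truth for every design constant of the analysis:
#' the 4:1 availability ratio, the 5,600 m pseudo-absence buffer (radius of
#' a 99.7 km2 circle, rounded to 100 m), the 7/15/30/50 km2 moving-window
#' scales, the |r| > 0.7 collinearity screen, the 2-AICc model-averaging
#' window, the 95% KDE isopleth and >30-fix residency filter, the
#' linear/c=2/c=8 resistance transforms, the 5-km disperser buffer with 3
#' available points per location, and the 10-bin quantile classification.
#'
#' @return named list of defaults (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    mean_home_range_km2 = 99.7,
    pseudo_absence_ratio = 4,
    pseudo_absence_buffer_m = 5600,
    window_scales_km2 = c(7, 15, 30, 50),
    correlation_threshold = 0.7,
    delta_cutoff = 2,
    kfold_train_frac = 0.95,
    kfold_reps = 1000,
    min_fixes = 30,
    kde_isopleth = 0.95,
    resistance_transforms = list(linear = resistance_transform("linear"),
                                 c2 = resistance_transform("exponential", 2),
                                 c8 = resistance_transform("exponential", 8)),
    n_node_regions = 5,
    n_dispersers = 46,
    disperser_n_avail = 3,
    disperser_buffer_m = 5000,
    quantile_bins = 10,
    stages = c(synth = TRUE, covars = TRUE, poprsf = TRUE, indrsf = TRUE,
               connect = TRUE, validate = TRUE)
  ), class = "run_config")
}

#' Default synthetic-run configuration
#'
#' The study-design defaults of [default_run_config] plus the synthetic
#' landscape and ground truth, with the extent-dependent distances
#' (pseudo-absence exclusion, disperser buffer) rescaled to the synthetic
#' 200 x 200-cell extent so the geometry stays proportionate to the
#' original 30 m / state-wide design.
#'
#' @param nrow,ncol synthetic extent in cells (default 200 x 200).
#' @param cellsize cell size in meters (default 30).
#' @return a `run_config` list with `landscape`, `truth` and synthetic
#'   sampling sizes filled in.
#' @export
synthetic_run_config <- function(nrow = 200, ncol = 200, cellsize = 30) {
  cfg <- default_run_config()
  cfg$landscape <- landscape_config(nrow = nrow, ncol = ncol,
                                    cellsize = cellsize)
  cfg$truth <- truth_model(
    beta = c(forest_50km2 = 1.2, pasture_50km2 = 0.6, dist_main_roads = 0.4),
    ind_beta = c(forest_7km2 = 1.0, road_density = -1.0),
    hr_sigma = 20 * cellsize)
  cfg$n_presences <- 400
  cfg$n_individuals <- 12
  cfg$fixes_per_individual <- c(40, 60, 80, 100, 55, 45, 70, 90, 65, 50,
                                75, 85)
  extent_m <- min(nrow, ncol) * cellsize
  cfg$pseudo_absence_buffer_m <- round(extent_m / 40)
  cfg$disperser_buffer_m <- round(extent_m / 8)
  cfg$window_scales_km2 <- cfg$window_scales_km2 *
    (extent_m / (500 * 30))^2  # keep windows a constant fraction of extent
  cfg$candidate_models <- list(
    c("dist_main_roads", "forest_50km2", "pasture_50km2"),
    c("dist_main_roads", "forest_50km2", "pasture_50km2",
      "herbaceous_30km2"),
    c("dist_main_roads", "forest_50km2"),
    c("dist_main_roads", "forest_15km2", "pasture_15km2"),
    c("dist_main_roads"),
    character(0))
  cfg$kfold_reps <- 100
  cfg
}

# square node regions placed in the four quadrants and the center
default_node_regions <- function(grid_geom, n = 5) {
  nr <- nrow(grid_geom$values); nc <- ncol(grid_geom$values)
  half <- max(2L, round(min(nr, nc) * 0.05))
  centers <- list(c(0.15, 0.15), c(0.15, 0.85), c(0.85, 0.15),
                  c(0.85, 0.85), c(0.5, 0.5))[seq_len(n)]
  regions <- list()
  for (i in seq_along(centers)) {
    m <- matrix(0, nr, nc)
    r0 <- round(centers[[i]][1] * nr); c0 <- round(centers[[i]][2] * nc)
    m[max(1, r0 - half):min(nr, r0 + half),
      max(1, c0 - half):min(nc, c0 + half)] <- 1
    regions[[paste0("region", i)]] <- grid_like(grid_geom, m)
  }
  regions
}

write_artifact <- function(obj, path) {
  if (is.scape_grid(obj)) write_grid(obj, path)
  else if (inherits(obj, "scape_lines")) write_lines(obj, path)
  else if (is.data.frame(obj)) utils::write.csv(obj, path, row.names = FALSE)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order (synthesize landscape ->
#' covariates -> population RSF and suitability -> individual RSF ->
#' connectivity -> disperser validation), writes every artifact to `outdir`
#' and returns a manifest with an md5 hash per artifact plus the config
#' snapshot. Identical `(config, seed)` give a byte-identical set of
#' artifacts. A master seed deterministically spawns per-stage seeds.
#'
#' @param config a `run_config` from [synthetic_run_config].
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param quiet suppress stage messages.
#' @return manifest list: `artifacts` (name -> path), `hashes`, `config`,
#'   `results` (key in-memory results per stage).
#' @export
run_pipeline <- function(config, outdir, seed = 1, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[selscape] ", ...)
  on_stage <- function(s) isTRUE(config$stages[[s]])
  art <- list()
  res <- list()
  sseed <- function(k) (seed * 13L + k * 101L) %% .Machine$integer.max

  need <- function(stage, dep) {
    if (!on_stage(dep))
      stop("stage '", stage, "' requires stage '", dep,
           "' which is toggled off")
  }

  if (on_stage("synth")) {
    say("stage synth")
    lc <- generate_landcover(config$landscape, seed = sseed(1))
    ln <- generate_lines(config$landscape, seed = sseed(1))
    art$landcover <- write_artifact(lc, file.path(outdir, "landcover.asc"))
    art$lines <- write_artifact(ln, file.path(outdir, "lines.geojson"))
    res$landcover <- lc; res$lines <- ln
  }

  if (on_stage("covars")) {
    need("covars", "synth")
    say("stage covars")
    stack <- build_covariates(res$landcover, res$lines,
                              scales_km2 = config$window_scales_km2,
                              density_window_km2 =
                                config$window_scales_km2[1])
    # label scales by their design names (7/15/30/50) regardless of any
    # synthetic rescaling of the window areas
    design <- c(7, 15, 30, 50)
    for (i in seq_along(config$window_scales_km2)) {
      names(stack$layers) <- sub(
        sprintf("_%gkm2", config$window_scales_km2[i]),
        sprintf("_%dkm2", design[i]), names(stack$layers), fixed = TRUE)
    }
    stack <- scale_covariates(stack)
    res$stack <- stack
    res$screen <- correlation_screen(stack, config$correlation_threshold)
    art$covariate_manifest <- write_artifact(
      stack$scaling, file.path(outdir, "covariate_manifest.csv"))
  }

  if (on_stage("poprsf")) {
    need("poprsf", "covars")
    say("stage poprsf")
    pres <- generate_presences(res$stack, config$truth, config$n_presences,
                               seed = sseed(2))
    abs <- generate_pseudo_absences(pres, res$landcover,
                                    ratio = config$pseudo_absence_ratio,
                                    buffer_m = config$pseudo_absence_buffer_m,
                                    seed = sseed(2))
    ua <- use_availability_data(pres, abs, res$stack)
    fits <- lapply(config$candidate_models,
                   function(tm) fit_logistic(ua, tm))
    avg <- model_average_predict(fits, res$stack,
                                 delta_cutoff = config$delta_cutoff)
    top_terms <- config$candidate_models[[
      which.min(vapply(fits, function(f) f$AICc, 0))]]
    top <- fits[[which.min(vapply(fits, function(f) f$AICc, 0))]]
    p_all <- stats::fitted(top$fit)
    res$auc <- auc_roc(p_all, ua$use)
    res$cv <- kfold_accuracy(ua, top_terms, config$kfold_train_frac,
                             reps = config$kfold_reps, seed = sseed(2))
    res$presences <- pres; res$model_table <- avg$table
    res$suitability <- avg$suitability
    art$presences <- write_artifact(as.data.frame(pres),
                                    file.path(outdir, "presences.csv"))
    art$model_table <- write_artifact(avg$table,
                                      file.path(outdir, "model_table.csv"))
    art$suitability <- write_artifact(avg$suitability,
                                      file.path(outdir, "suitability.asc"))
    art$fit_report <- write_artifact(
      list(auc = res$auc, cv_mean_accuracy = res$cv$mean_accuracy),
      file.path(outdir, "fit_report.json"))
  }

  if (on_stage("indrsf")) {
    need("indrsf", "covars")
    say("stage indrsf")
    tel <- generate_telemetry(res$stack, config$truth, config$n_individuals,
                              config$fixes_per_individual, seed = sseed(3))
    tel <- filter_individuals(tel, min_fixes = config$min_fixes)
    ids <- unique(tel$individual_id)
    hr_rows <- list(); used <- list(); avail <- list()
    for (k in seq_along(ids)) {
      fx <- tel[tel$individual_id == ids[k], ]
      hr <- kde_home_range(fx, isopleth = config$kde_isopleth)
      hr_rows[[k]] <- data.frame(individual_id = ids[k], sex = fx$sex[1],
                                 study_area = fx$study_area[1],
                                 n_fixes = nrow(fx),
                                 area_km2 = hr$area_km2)
      av <- sample_availability(hr, nrow(fx), seed = sseed(3) + k)
      av$individual_id <- ids[k]
      used[[k]] <- fx; avail[[k]] <- av
    }
    hr_tab <- do.call(rbind, hr_rows)
    used <- do.call(rbind, used); avail <- do.call(rbind, avail)
    avail$id <- paste0(avail$id, "_", avail$individual_id)
    ind_terms <- names(config$truth$ind_beta)
    rsf <- fit_weighted_rsf(used, avail, res$stack, terms = ind_terms,
                            form = "exponential_RSF",
                            weighting = "distribution")
    res$homeranges <- hr_tab
    res$kw_sex <- kruskal_wallis(hr_tab$area_km2, hr_tab$sex)
    res$ind_rsf <- rsf
    coefs <- data.frame(term = names(rsf$coef), beta = unname(rsf$coef),
                        se = unname(rsf$se))
    art$homerange_table <- write_artifact(
      hr_tab, file.path(outdir, "homerange_table.csv"))
    art$telemetry <- write_artifact(as.data.frame(tel),
                                    file.path(outdir, "telemetry.csv"))
    art$rsf_coefficients <- write_artifact(
      coefs, file.path(outdir, "rsf_coefficients.csv"))
  }

  if (on_stage("connect")) {
    need("connect", "poprsf")
    say("stage connect")
    regions <- default_node_regions(res$suitability, config$n_node_regions)
    res$currents <- list()
    pair_tabs <- list()
    for (nm in names(config$resistance_transforms)) {
      R <- suitability_to_resistance(res$suitability,
                                     config$resistance_transforms[[nm]])
      gr <- grid_to_graph(R)
      cm <- cumulative_current(gr, regions)
      res$currents[[nm]] <- cm
      pair_tabs[[nm]] <- cbind(transform = nm, cm$pairs)
      art[[paste0("current_", nm)]] <- write_artifact(
        cm$current, file.path(outdir, paste0("current_", nm, ".asc")))
    }
    res$deciles <- lapply(res$currents, function(cm)
      quantile_classify(cm, config$quantile_bins))
    for (nm in names(res$deciles))
      art[[paste0("decile_", nm)]] <- write_artifact(
        res$deciles[[nm]], file.path(outdir, paste0("decile_", nm, ".asc")))
    art$pair_resistance <- write_artifact(
      do.call(rbind, pair_tabs), file.path(outdir, "pair_resistance.csv"))
  }

  if (on_stage("validate")) {
    need("validate", "connect")
    say("stage validate")
    disp <- generate_dispersers(res$currents$c2$current,
                                config$n_dispersers,
                                config$truth$disperser_preference,
                                seed = sseed(5))
    matched <- build_matched_sets(disp, res$deciles,
                                  buffer_m = config$disperser_buffer_m,
                                  n_avail = config$disperser_n_avail,
                                  seed = sseed(5))
    nms <- names(res$deciles)
    fits <- lapply(stats::setNames(nms, nms),
                   function(nm) fit_mixed_logistic(matched, nm))
    avg <- rank_and_average_maps(
      fits, lapply(res$currents, function(cm) cm$current))
    res$map_weights <- avg$weights
    res$validation_table <- avg$table
    art$matched_sets <- write_artifact(
      matched, file.path(outdir, "matched_sets.csv"))
    art$validation_table <- write_artifact(
      avg$table, file.path(outdir, "validation_table.csv"))
    art$averaged_current <- write_artifact(
      avg$averaged, file.path(outdir, "averaged_current.asc"))
  }

  cfg_snapshot <- config
  cfg_snapshot$resistance_transforms <-
    lapply(config$resistance_transforms, unclass)
  cfg_snapshot$truth <- if (!is.null(config$truth)) unclass(config$truth)
  cfg_snapshot$landscape <- if (!is.null(config$landscape))
    unclass(config$landscape)
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(list(seed = seed, config = unclass(cfg_snapshot)),
                       cfg_path, auto_unbox = TRUE, digits = NA, force = TRUE)
  art$config <- cfg_path
  hashes <- vapply(art, function(p) unname(tools::md5sum(p)), "")
  manifest <- list(artifacts = art, hashes = hashes, seed = seed)
  jsonlite::write_json(list(seed = seed, hashes = as.list(hashes)),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- res
  invisible(manifest)
}
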