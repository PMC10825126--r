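# Pipeline stages tying the modules into the survey workflow. Each stage
# reads/writes plain files, logs what it did, and drops a JSON sidecar
# carrying the seed and configuration so any output can be reproduced. The
# `exec/camcooccur` script exposes these as shell subcommands.

#' @keywords internal
pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' @keywords internal
write_sidecar <- function(path, stage, seed, config) {
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         config = config,
         package = "camcooccur",
         version = as.character(utils::packageVersion("camcooccur"))),
    path, auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
}

#' @keywords internal
format_records <- function(records) {
  data.frame(site_id = records$site_id,
             species = records$species,
             timestamp = format(records$timestamp, "%Y-%m-%dT%H:%M:%S",
                                tz = "UTC"),
             count = records$count,
             stringsAsFactors = FALSE)
}

#' Load a pipeline run configuration from YAML
#'
#' Reads a YAML file with optional blocks `survey`
#' (`occasion_days`, `independence_minutes`), `model` (`psi_covariates`,
#' `p_covariates`, `prior_sd`), `mcmc` (`chains`, `adapt`, `burn`,
#' `iterations`), `overlap` (`reps`, `gridsize`, `adjust`, `min_n`), `idw`
#' (`cell_size`, `n_cells`, `power`) and `seed`, merged over the package
#' defaults.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return named list of settings.
#' @export
load_run_config <- function(path = NULL) {
  defaults <- list(
    survey = list(occasion_days = 7, deployment_days = 21,
                  independence_minutes = 30),
    model = list(psi_covariates = c("canopycover", "predators", "livestock",
                                    "human", "othercat"),
                 p_covariates = c("dist_water", "dist_road",
                                  "dist_settlement"),
                 prior_mean = 0, prior_sd = 3.16,
                 collinearity_threshold = 0.7),
    mcmc = list(chains = 3, adapt = 1000, burn = 1000, iterations = 15000),
    overlap = list(reps = 999, gridsize = 128, adjust = 0.8, min_n = 10,
                   level = 0.95),
    idw = list(cell_size = NULL, n_cells = 100, power = 2),
    seed = 1)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  for (block in names(user)) {
    if (is.list(user[[block]]) && block %in% names(defaults))
      defaults[[block]][names(user[[block]])] <- user[[block]]
    else defaults[[block]] <- user[[block]]
  }
  defaults
}

#' Pipeline stage: simulate a synthetic study
#'
#' Writes `records.csv`, `covariates.csv`, a ground-truth `truth.json` and a
#' sidecar into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param seed optional override of the config seed.
#' @return invisibly, the [simulate_study()] result.
#' @export
pipeline_simulate <- function(out_dir, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (config$n_sites < 1) stop("'n_sites' must be positive")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config)
  utils::write.csv(format_records(study$records),
                   file.path(out_dir, "records.csv"), row.names = FALSE)
  utils::write.csv(study$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg <- config
  cfg$diel <- lapply(cfg$diel, unclass)
  cfg$deploy_start <- as.character(cfg$deploy_start)
  write_sidecar(file.path(out_dir, "simulate.sidecar.json"), "simulate",
                config$seed, cfg)
  pipeline_log("simulate", "%d sites, %d records, seed %d",
               config$n_sites, nrow(study$records), config$seed)
  invisible(study)
}

# Derive the other-cat presence covariate when the table lacks it: naive
# detection (>= 1 record) of the other species at each site.
#' @keywords internal
add_othercat <- function(covariates, records, other_species, design) {
  if ("othercat" %in% names(covariates)) return(covariates)
  h <- build_detection_history(records, design, other_species)
  covariates$othercat <- as.integer(h$y_total > 0)[
    match(covariates$site_id, h$sites)]
  covariates
}

#' Pipeline stage: fit the two-species occupancy workflow
#'
#' Ingests records and covariates, collapses dependent photo events, builds
#' weekly detection histories, screens collinearity, fits the Bayesian
#' occupancy model per species, and writes per-species coefficient summary
#' CSVs, per-site psi/p CSVs and a species-comparison CSV.
#'
#' @param records_file,covariates_file input CSV paths.
#' @param out_dir output directory.
#' @param species length-2 character vector of species labels to fit.
#' @param deploy_start deployment start date for the survey design.
#' @param run_config list from [load_run_config()].
#' @param seed MCMC seed (overrides the run config seed).
#' @param allow_collinear proceed despite a failed collinearity screen.
#' @param allow_nonconverged do not error when any Rhat >= 1.1.
#' @return invisibly, list of per-species fits, summaries and comparisons.
#' @export
pipeline_occupancy <- function(records_file, covariates_file, out_dir,
                               species = c("junglecat", "leopardcat"),
                               deploy_start = "2022-12-15",
                               run_config = load_run_config(),
                               seed = NULL,
                               allow_collinear = FALSE,
                               allow_nonconverged = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% run_config$seed)
  records <- read_detection_records(records_file)
  records <- collapse_independent_events(
    records, run_config$survey$independence_minutes)
  covariates <- read_site_covariates(covariates_file)
  design <- survey_design(covariates$site_id, deploy_start,
                          run_config$survey$deployment_days,
                          run_config$survey$occasion_days)
  spec <- occu_spec(run_config$model$psi_covariates,
                    run_config$model$p_covariates,
                    run_config$model$prior_mean, run_config$model$prior_sd)
  settings <- mcmc_settings(run_config$mcmc$chains, run_config$mcmc$adapt,
                            run_config$mcmc$burn, run_config$mcmc$iterations,
                            seed = seed)
  fits <- list(); summaries <- list(); site_probs <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    other <- species[-si][1]
    cov_sp <- add_othercat(covariates, records, other, design)
    std <- standardize_covariates(
      cov_sp, union(spec$psi_covariates, spec$p_covariates))
    screen <- screen_collinearity(std,
                                  run_config$model$collinearity_threshold)
    if (!screen$passed) {
      print(screen)
      if (!allow_collinear)
        stop("collinearity screen failed; drop a covariate or set ",
             "allow_collinear = TRUE")
    }
    history <- build_detection_history(records, design, sp)
    pipeline_log("occupancy", "%s: %d detections at %d sites", sp,
                 sum(history$y_total), sum(history$y_total > 0))
    fit <- fit_occupancy(history, std, spec,
                         mcmc_settings(settings$chains, settings$adapt,
                                       settings$burn, settings$iterations,
                                       seed = seed + 100L * si))
    summ <- summarize_posterior(fit)
    bad <- !is.na(summ$rhat) & summ$rhat >= 1.1
    if (any(bad)) {
      msg <- sprintf("%s: %d parameter(s) with Rhat >= 1.1", sp, sum(bad))
      if (allow_nonconverged) warning(msg) else stop(msg)
    }
    utils::write.csv(summ,
                     file.path(out_dir, sprintf("occupancy_summary_%s.csv",
                                                sp)),
                     row.names = FALSE)
    probs <- derive_site_probabilities(fit)
    utils::write.csv(probs,
                     file.path(out_dir, sprintf("site_probabilities_%s.csv",
                                                sp)),
                     row.names = FALSE)
    fits[[sp]] <- fit; summaries[[sp]] <- summ; site_probs[[sp]] <- probs
  }
  cmp_psi <- compare_species(site_probs[[1]]$psi_mean,
                             site_probs[[2]]$psi_mean)
  cmp_p <- compare_species(site_probs[[1]]$p_mean, site_probs[[2]]$p_mean)
  comparison <- data.frame(
    quantity = c("psi", "p"),
    species_a = species[1], species_b = species[2],
    mean_a = c(cmp_psi$mean_a, cmp_p$mean_a),
    sd_a = c(cmp_psi$sd_a, cmp_p$sd_a),
    mean_b = c(cmp_psi$mean_b, cmp_p$mean_b),
    sd_b = c(cmp_psi$sd_b, cmp_p$sd_b),
    t_statistic = c(cmp_psi$t_statistic, cmp_p$t_statistic),
    p_value = c(cmp_psi$p_value, cmp_p$p_value),
    stringsAsFactors = FALSE)
  utils::write.csv(comparison, file.path(out_dir, "species_comparison.csv"),
                   row.names = FALSE)
  write_sidecar(file.path(out_dir, "occupancy.sidecar.json"), "occupancy",
                seed, run_config[c("survey", "model", "mcmc")])
  invisible(list(fits = fits, summaries = summaries,
                 site_probabilities = site_probs, comparison = comparison))
}

#' Pipeline stage: diel activity overlap
#'
#' Computes the overall Dhat1 with its bootstrap CI between two species,
#' plus stratified results for every 0/1 stratum column supplied (e.g.
#' `predators`, `protected`), and writes `overlap_results.csv` (and a
#' density plot when `plot_file` is given).
#'
#' @inheritParams pipeline_occupancy
#' @param strata_columns covariate columns (0/1) to stratify by; present
#'   columns only (default `c("protected", "predators")`).
#' @param plot_file optional image path (`.png`) for the overlaid densities.
#' @param sunrise,sunset clock hours for the plot's reference lines.
#' @return invisibly, the results data.frame.
#' @export
pipeline_overlap <- function(records_file, covariates_file, out_dir,
                             species = c("junglecat", "leopardcat"),
                             strata_columns = c("protected", "predators"),
                             run_config = load_run_config(), seed = NULL,
                             plot_file = NULL, sunrise = 6.5,
                             sunset = 17.75) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% run_config$seed)
  oc <- run_config$overlap
  records <- read_detection_records(records_file)
  records <- collapse_independent_events(
    records, run_config$survey$independence_minutes)
  covariates <- read_site_covariates(covariates_file)
  ta <- to_radians(records$timestamp[records$species == species[1]])
  tb <- to_radians(records$timestamp[records$species == species[2]])
  if (length(ta) < oc$min_n || length(tb) < oc$min_n)
    stop("fewer than ", oc$min_n, " detections for a species")
  overall <- bootstrap_ci(ta, tb, reps = oc$reps, level = oc$level,
                          gridsize = oc$gridsize, adjust = oc$adjust,
                          seed = seed)
  rows <- data.frame(stratum = "overall", n_a = overall$n_a,
                     n_b = overall$n_b, dhat1 = overall$dhat1,
                     ci_low = overall$ci_low, ci_high = overall$ci_high,
                     skipped = FALSE, stringsAsFactors = FALSE)
  for (colnm in intersect(strata_columns, names(covariates))) {
    strata <- stats::setNames(
      ifelse(covariates[[colnm]] > 0, paste0(colnm, "_present"),
             paste0(colnm, "_absent")),
      covariates$site_id)
    res <- stratified_overlap(records, strata, species[1], species[2],
                              min_n = oc$min_n, reps = oc$reps,
                              level = oc$level, gridsize = oc$gridsize,
                              adjust = oc$adjust,
                              seed = seed + 7L * match(colnm, strata_columns))
    rows <- rbind(rows, res)
  }
  rows$species_a <- species[1]
  rows$species_b <- species[2]
  rows$reps <- oc$reps
  rows$seed <- seed
  utils::write.csv(rows, file.path(out_dir, "overlap_results.csv"),
                   row.names = FALSE)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 900, height = 600)
    overlap_plot(ta, tb, gridsize = oc$gridsize, adjust = oc$adjust,
                 labels = species, sunrise = sunrise, sunset = sunset,
                 main = sprintf("Dhat1 = %.3f", overall$dhat1))
    grDevices::dev.off()
  }
  write_sidecar(file.path(out_dir, "overlap.sidecar.json"), "overlap",
                seed, run_config["overlap"])
  pipeline_log("overlap", "Dhat1 = %.3f (%.3f-%.3f), n = %d/%d",
               overall$dhat1, overall$ci_low, overall$ci_high,
               overall$n_a, overall$n_b)
  invisible(rows)
}

#' Pipeline stage: IDW detection-frequency maps
#'
#' Builds the per-site detection frequencies for each species and
#' interpolates them onto a raster, written as an ESRI ASCII grid plus a
#' long-format CSV per species.
#'
#' @inheritParams pipeline_occupancy
#' @return invisibly, named list of interpolated [raster_grid()]s.
#' @export
pipeline_idw <- function(records_file, covariates_file, out_dir,
                         species = c("junglecat", "leopardcat"),
                         deploy_start = "2022-12-15",
                         run_config = load_run_config(), seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% run_config$seed)
  records <- read_detection_records(records_file)
  records <- collapse_independent_events(
    records, run_config$survey$independence_minutes)
  covariates <- read_site_covariates(covariates_file)
  if (nrow(covariates) < 1) stop("empty site list")
  design <- survey_design(covariates$site_id, deploy_start,
                          run_config$survey$deployment_days,
                          run_config$survey$occasion_days)
  out <- list()
  for (sp in species) {
    history <- build_detection_history(records, design, sp)
    pts <- site_detection_frequency(history, covariates)
    grid <- grid_over_points(pts, cell_size = run_config$idw$cell_size,
                             n_cells = run_config$idw$n_cells)
    grid <- idw_interpolate(pts, grid, power = run_config$idw$power)
    write_esri_ascii(grid, file.path(out_dir, sprintf("idw_%s.asc", sp)))
    utils::write.csv(raster_to_df(grid),
                     file.path(out_dir, sprintf("idw_%s.csv", sp)),
                     row.names = FALSE)
    out[[sp]] <- grid
    pipeline_log("idw", "%s: %d x %d cells, values in [%.3f, %.3f]", sp,
                 grid$n_rows, grid$n_cols, min(grid$values),
                 max(grid$values))
  }
  write_sidecar(file.path(out_dir, "idw.sidecar.json"), "idw", seed,
                run_config["idw"])
  invisible(out)
}
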