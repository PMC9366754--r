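# Configuration and end-to-end orchestration: home ranges -> design tables
# -> RSF fits -> cross-validation -> trade-offs -> NCE models, with a
# manifest of seeds and input checksums for reproducibility.

#' Pipeline configuration
#'
#' Defaults equal the analysis constants used throughout the package:
#' summer season July 1 - August 31, rest window 11:00-18:00, 500 used /
#' 1000 available second-order points, a 10:1 third-order availability
#' ratio, available-row weight 1000, 99 percent isopleths, fivefold CV with
#' 5 bins.
#'
#' @param telemetry,de,lion,wolf,demography input paths (telemetry and
#'   demography CSV; rasters as ESRI ASCII grids). Leave `NULL` when the
#'   inputs are passed in memory to [run_pipeline()].
#' @param ... overrides of the default settings (unknown names error).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(telemetry = NULL, de = NULL, lion = NULL,
                            wolf = NULL, demography = NULL, ...) {
  cfg <- list(
    telemetry = telemetry, de = de, lion = lion, wolf = wolf,
    demography = demography,
    season = c("07-01", "08-31"), rest_window = c("11:00", "18:00"),
    isopleth_level = 0.99, grid_resolution = 250,
    n_used_second = 500, n_avail_second = 1000, ratio_third = 10,
    weight_available = 1000,
    k_folds = 5, n_bins = 5,
    prior_sd_fixed = 2, sigma_upper = 2, intercept_re_sd = 100,
    method = "map", chains = 4, iter = 1000, warmup = 1000,
    seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config setting(s): ", paste(unknown, collapse = ", "))
  structure(utils::modifyList(cfg, dots), class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Estimate individual and population summer home ranges
#'
#' Daily-subsampled fixes per animal-year feed fixed-kernel UDs; the
#' population range pools the daily fixes of all individuals.
#'
#' @param telemetry telemetry `data.frame`.
#' @param isopleth_level isopleth mass fraction (default 0.99).
#' @param grid_resolution UD grid cell size (m).
#' @param bandwidth optional fixed bandwidth (default: per-axis reference
#'   rule on each point set).
#' @param clip_extent optional `c(xmin, xmax, ymin, ymax)`; isopleths are
#'   clipped to it (normally the covariate raster extent) so availability
#'   sampling stays on the mapped landscape.
#' @return list with `individual` (named list of [home_range()]) and
#'   `population`.
#' @export
estimate_home_ranges <- function(telemetry, isopleth_level = 0.99,
                                 grid_resolution = 250, bandwidth = NULL,
                                 clip_extent = NULL) {
  daily <- subsample_daily(telemetry)
  ids <- unique(daily$animal_id)
  clip <- function(hr) if (is.null(clip_extent)) hr
                       else hr_clip(hr, clip_extent)
  individual <- lapply(ids, function(id) {
    ud <- estimate_kde_ud(daily[daily$animal_id == id, , drop = FALSE],
                          bandwidth = bandwidth,
                          grid_resolution = grid_resolution, owner = id)
    clip(extract_isopleth(ud, isopleth_level))
  })
  names(individual) <- ids
  pop_ud <- estimate_kde_ud(daily, bandwidth = bandwidth,
                            grid_resolution = grid_resolution,
                            owner = "population")
  list(individual = individual,
       population = clip(extract_isopleth(pop_ud, isopleth_level)))
}

#' Run the full analysis pipeline
#'
#' Chains every stage and writes tables, posterior summaries, the CV report,
#' trade-off and NCE summaries, a log and a manifest into `outdir`. Stages
#' are deterministic given the config seed; partial outputs are preserved
#' with a status file if a stage fails.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created).
#' @param inputs optional in-memory inputs overriding config paths: a list
#'   with `telemetry`, `rasters` (`de`, `lion`, `wolf`) and `demography`.
#' @return (invisibly) list of in-memory stage results.
#' @export
run_pipeline <- function(config, outdir, inputs = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  status <- file.path(outdir, "status.json")
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  done <- character(0)
  fail <- function(stage, e) {
    jsonlite::write_json(list(completed = done, failed = stage,
                              error = conditionMessage(e)),
                         status, auto_unbox = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  }
  checksums <- list()
  if (is.null(inputs)) {
    for (nm in c("telemetry", "de", "lion", "wolf", "demography")) {
      p <- config[[nm]]
      if (is.null(p) || !file.exists(p))
        stop("missing input for '", nm, "': ",
             if (is.null(p)) "no path configured" else p)
      checksums[[nm]] <- unname(tools::md5sum(p))
    }
    inputs <- list(
      telemetry = read_telemetry(config$telemetry),
      rasters = list(de = read_esri_ascii(config$de),
                     lion = read_esri_ascii(config$lion),
                     wolf = read_esri_ascii(config$wolf)),
      demography = utils::read.csv(config$demography,
                                   colClasses = c(individual_id = "character")))
  }
  seeds <- derive_seeds(config$seed, 6, salt = 23L)
  res <- list()

  stage <- "homerange"
  res$hr <- tryCatch({
    say("estimating home ranges (%.0f%% isopleths)",
        100 * config$isopleth_level)
    estimate_home_ranges(inputs$telemetry, config$isopleth_level,
                         config$grid_resolution,
                         clip_extent = raster_extent(inputs$rasters$de))
  }, error = function(e) fail(stage, e))
  writeLines(c(hr_to_wkt(res$hr$population),
               vapply(res$hr$individual, hr_to_wkt, "")),
             file.path(outdir, "home_ranges.wkt"))
  done <- c(done, stage)

  stage <- "design"
  res$tables <- tryCatch({
    say("building second- and third-order used-available tables")
    second <- build_second_order_table(
      res$hr$individual, res$hr$population, inputs$rasters,
      n_used = config$n_used_second, n_avail = config$n_avail_second,
      weight_available = config$weight_available, seed = seeds[[1]])
    used <- filter_foraging_locations(inputs$telemetry, config$season,
                                      config$rest_window)
    third <- build_third_order_table(
      used, res$hr$individual, inputs$rasters, ratio = config$ratio_third,
      weight_available = config$weight_available, seed = seeds[[2]])
    list(second = standardize_covariates(second),
         third = standardize_covariates(third))
  }, error = function(e) fail(stage, e))
  write_ua_table(res$tables$second, file.path(outdir, "second_order.csv"))
  write_ua_table(res$tables$third, file.path(outdir, "third_order.csv"))
  done <- c(done, stage)

  stage <- "fit"
  spec <- rsf_model_spec(prior_sd_fixed = config$prior_sd_fixed,
                         sigma_upper = config$sigma_upper,
                         intercept_re_sd = config$intercept_re_sd,
                         weight_available = config$weight_available)
  res$fits <- tryCatch({
    say("fitting hierarchical RSFs (%s)", config$method)
    lapply(res$tables, fit_hierarchical_rsf, spec = spec,
           method = config$method, chains = config$chains,
           iter = config$iter, warmup = config$warmup, seed = seeds[[3]])
  }, error = function(e) fail(stage, e))
  for (ord in names(res$fits)) {
    f <- res$fits[[ord]]
    s <- split(f$summary[c("mean", "lo90", "hi90", "rhat", "ess")],
               f$summary$parameter)
    jsonlite::write_json(lapply(s, as.list),
                         file.path(outdir, paste0("rsf_", ord, ".json")),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(individual_id = rownames(f$gamma), f$gamma,
                                check.names = FALSE),
                     file.path(outdir, paste0("gamma_", ord, ".csv")),
                     row.names = FALSE)
    if (!is.null(f$draws))
      utils::write.csv(f$draws,
                       file.path(outdir, paste0("draws_", ord, ".csv")),
                       row.names = FALSE)
  }
  done <- c(done, stage)

  stage <- "validate"
  res$cv <- tryCatch({
    say("fivefold cross-validation")
    lapply(res$tables, function(tb)
      boyce_cross_validate(tb, spec, n_bins = config$n_bins,
                           method = "map", seed = seeds[[4]]))
  }, error = function(e) fail(stage, e))
  for (ord in names(res$cv))
    write_cv_report(res$cv[[ord]], file.path(outdir,
                                             paste0("cv_", ord, ".json")))
  done <- c(done, stage)

  stage <- "tradeoff"
  res$tradeoff <- tryCatch({
    say("computing per-individual trade-off metrics")
    tradeoff_demography_table(
      compute_tradeoff(res$fits$third, res$tables$third, "ml"),
      compute_tradeoff(res$fits$third, res$tables$third, "wf"),
      inputs$demography)
  }, error = function(e) fail(stage, e))
  utils::write.csv(res$tradeoff, file.path(outdir, "tradeoff_demography.csv"),
                   row.names = FALSE)
  done <- c(done, stage)

  stage <- "nce"
  res$nce <- tryCatch({
    say("fitting body-fat and pregnancy models")
    list(bodyfat_ml = fit_bodyfat_model(res$tradeoff, "ml", seed = seeds[[5]]),
         bodyfat_wf = fit_bodyfat_model(res$tradeoff, "wf", seed = seeds[[5]]),
         pregnancy_ml = fit_pregnancy_model(res$tradeoff, "ml",
                                            seed = seeds[[6]]),
         pregnancy_wf = fit_pregnancy_model(res$tradeoff, "wf",
                                            seed = seeds[[6]]))
  }, error = function(e) fail(stage, e))
  write_nce_report(res$nce, file.path(outdir, "nce.json"))
  done <- c(done, stage)

  manifest <- list(
    package_version = as.character(utils::packageVersion("elkrsf")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed, stage_seeds = unlist(seeds),
    input_checksums = checksums,
    settings = unclass(config)[setdiff(names(config),
                                       c("telemetry", "de", "lion", "wolf",
                                         "demography"))],
    n_individuals = length(res$hr$individual),
    mean_rs = lapply(res$cv, `[[`, "mean_rs"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(completed = done, failed = NULL), status,
                       auto_unbox = TRUE, null = "null")
  say("pipeline complete")
  invisible(res)
}
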