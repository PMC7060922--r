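# Allowed keys per config block; schema violations name the offending key.
pipeline_schema <- function() list(
  top = c("stages", "seed", "output_dir", "simulate", "preprocess",
          "dynamics", "kinetics", "quantify"),
  simulate = c(names(formals(sim_config)), "geometry"),
  geometry = names(formals(acquisition_geometry)),
  preprocess = c(names(formals(preprocess_params)), "input"),
  dynamics = setdiff(names(formals(dynamics_params)), "rois"),
  kinetics = c("frames_per_timepoint", "background"),
  quantify = c("n_fields", "surface_fraction_basal", "fold", "noise",
               "treatment"))

check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible())
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("unknown config key \"%s\" in %s", bad[1], where))
  invisible()
}

# Counter-based child seeds so each stage is reproducible independently
# of stage order; kept below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483647L + 1)
}

#' Run the pipeline from a single configuration
#'
#' Executes the requested stages (`simulate`, `preprocess`, `dynamics`,
#' `kinetics`, `quantify`) in dependency order from one YAML or list
#' configuration, with one master seed fanned out to per-stage child
#' seeds.  Writes standard-format outputs (TIFF movies, CSV tables, JSON
#' fits) and a run manifest with parameters, seeds and MD5 checksums of
#' every output; re-running an identical configuration reproduces
#' identical files.
#'
#' @param config Path to a YAML file or a named list.  Top-level keys:
#'   `stages` (character vector), `seed`, `output_dir`, plus per-stage
#'   parameter blocks matching [sim_config()], [preprocess_params()],
#'   [dynamics_params()], [intensity_series()] and
#'   [simulate_translocation_fields()] arguments.
#' @param output_dir Overrides `config$output_dir`.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  schema <- pipeline_schema()
  check_keys(config, schema$top, "top level")
  for (blk in c("simulate", "preprocess", "dynamics", "kinetics",
                "quantify"))
    check_keys(config[[blk]], schema[[blk]], blk)
  check_keys(config$simulate$geometry, schema$geometry,
             "simulate$geometry")
  stages <- config$stages %||% c("simulate", "preprocess", "dynamics",
                                 "kinetics")
  bad <- setdiff(stages, c("simulate", "preprocess", "dynamics",
                           "kinetics", "quantify"))
  if (length(bad)) stop(sprintf("unknown stage \"%s\"", bad[1]))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- output_dir %||% config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$preprocess$input) &&
      !file.exists(config$preprocess$input))
    stop(sprintf("preprocess input \"%s\" does not exist",
                 config$preprocess$input))

  outputs <- character(0)
  params_used <- list(seed = seed)
  raw <- NULL; clean <- NULL

  fail <- function(stage, e)
    stop(sprintf("stage \"%s\" failed: %s", stage, conditionMessage(e)),
         call. = FALSE)

  if ("simulate" %in% stages) {
    res <- tryCatch({
      geo_args <- config$simulate$geometry %||% list()
      geometry <- do.call(acquisition_geometry, geo_args)
      sim_args <- config$simulate
      sim_args$geometry <- NULL
      sim_args$seed <- sim_args$seed %||% child_seed(seed, 1)
      cfg <- do.call(sim_config, sim_args)
      simulate_tirf_movie(cfg, geometry)
    }, error = function(e) fail("simulate", e))
    raw <- res$movie
    p <- file.path(out_dir, "movie.tif")
    write_movie(raw, p, extra = list(seed = res$config$seed))
    write_truth(res$truth, file.path(out_dir, "truth.csv"))
    outputs <- c(outputs, p, paste0(p, ".json"),
                 file.path(out_dir, "truth.csv"))
    params_used$simulate <- unclass(res$config)
  }

  if ("preprocess" %in% stages) {
    clean <- tryCatch({
      if (is.null(raw)) {
        if (is.null(config$preprocess$input))
          stop("no movie available: run simulate or give preprocess$input")
        raw <- read_movie(config$preprocess$input)
      }
      pp_args <- config$preprocess
      pp_args$input <- NULL
      preprocess_stack(raw, do.call(preprocess_params, pp_args))
    }, error = function(e) fail("preprocess", e))
    p <- file.path(out_dir, "clean.tif")
    write_movie(clean, p)
    outputs <- c(outputs, p, paste0(p, ".json"))
    params_used$preprocess <- config$preprocess %||% list()
  }

  if ("dynamics" %in% stages) {
    counts <- tryCatch({
      if (is.null(clean)) stop("dynamics requires a preprocessed movie")
      run_dynamics(clean, do.call(dynamics_params,
                                  config$dynamics %||% list()))
    }, error = function(e) fail("dynamics", e))
    p <- file.path(out_dir, "counts.csv")
    utils::write.csv(counts, p, row.names = FALSE)
    outputs <- c(outputs, p)
    params_used$dynamics <- config$dynamics %||% list()
  }

  if ("kinetics" %in% stages) {
    fitj <- tryCatch({
      if (is.null(raw) || is.null(clean))
        stop("kinetics requires the raw and preprocessed movies")
      pre_idx <- seq_len(max(raw$insulin_frame, 1L))
      ref <- proj_mean(raw$frames[, , pre_idx, drop = FALSE])
      mask <- footprint_mask(ref, raw$geometry)
      fpt <- config$kinetics$frames_per_timepoint %||% 10
      ser <- intensity_series(clean, mask, fpt,
                              background = config$kinetics$background %||%
                                "outside")
      fit <- fit_translocation(ser)
      list(t_min = ser$t_min, intensity = ser$intensity,
           normalized_intensity = fit$normalized_intensity,
           A = fit$A, t_half = fit$t_half, rss = fit$rss,
           fold_final = fit$fold_final, converged = fit$converged,
           mask_area_um2 = mask$area_um2)
    }, error = function(e) fail("kinetics", e))
    p <- file.path(out_dir, "fit.json")
    jsonlite::write_json(fitj, p, auto_unbox = TRUE, digits = NA,
                         na = "null")
    outputs <- c(outputs, p)
    params_used$kinetics <- config$kinetics %||% list()
  }

  if ("quantify" %in% stages) {
    q <- tryCatch({
      qa <- config$quantify %||% list()
      qa$seed <- child_seed(seed, 5)
      fields <- do.call(simulate_translocation_fields, qa)
      meas <- measure_fields(fields)
      rat <- ha_gfp_ratio(meas)
      stats_df <- compare_groups(split(rat$norm_ratio, rat$stimulation))
      list(measurements = rat, stats = stats_df)
    }, error = function(e) fail("quantify", e))
    p1 <- file.path(out_dir, "fields.csv")
    utils::write.csv(q$measurements, p1, row.names = FALSE)
    p2 <- file.path(out_dir, "group_stats.json")
    jsonlite::write_json(q$stats, p2, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, p1, p2)
    params_used$quantify <- config$quantify %||% list()
  }

  manifest <- list(stages = stages, seed = seed,
                   parameters = params_used,
                   outputs = lapply(stats::setNames(outputs, basename(outputs)),
                                    function(p) list(
                                      path = p,
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}
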