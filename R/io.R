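# Readers and writers for the pipeline's tabular products.  Everything is
# plain CSV (UTC ISO-8601 timestamps); schemas are checked on read and
# violations are reported with the offending column and file.

check_schema <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema violation in '", path, "': missing required column(s) ",
         paste0("'", missing, "'", collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

read_product_csv <- function(path, required, time_cols = character()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_schema(df, required, path)
  for (tc in intersect(time_cols, names(df))) {
    if (!inherits(df[[tc]], "POSIXct")) {
      df[[tc]] <- as.POSIXct(df[[tc]], tz = "UTC")
    }
    attr(df[[tc]], "tzone") <- "UTC"
  }
  df
}

#' Read and write pipeline CSV products
#'
#' Thin, schema-checked wrappers around [readr::read_csv()] /
#' [readr::write_csv()].  `read_ctd_csv()` expects one row per (station,
#' depth) sample; `read_sv_csv()` a long Sv grid (half-open depth bins);
#' `read_sed_csv()` one row per single-echo detection.  All timestamps are
#' UTC ISO-8601.  `write_product_csv()` writes any product tibble;
#' round-tripping a product through write/read preserves its values.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return The tibble (readers), or `path` invisibly (writer).
#' @export
read_ctd_csv <- function(path) {
  read_product_csv(path,
                   c("station", "time", "lat", "lon", "depth",
                     "temperature", "salinity"),
                   time_cols = "time")
}

#' @rdname read_ctd_csv
#' @export
read_sv_csv <- function(path) {
  read_product_csv(path,
                   c("frequency", "time", "lat", "lon",
                     "depth_top", "depth_bottom", "sv_db"),
                   time_cols = "time")
}

#' @rdname read_ctd_csv
#' @export
read_sed_csv <- function(path) {
  read_product_csv(path,
                   c("ping_time", "platform_depth", "range", "ts",
                     "echo_length", "phase_dev", "gain_comp"),
                   time_cols = "ping_time")
}

#' @rdname read_ctd_csv
#' @export
write_product_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

# ---- pipeline configuration ------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the scene, acoustic-processing, echo-counting and modelling
#' settings for [run_pipeline()].  Defaults are the package's standard
#' processing choices: -85 dB Sv threshold, 15 m surface exclusion,
#' 5 m x 600 s integration cells, daylight restriction to 1 h inside
#' sunrise/sunset for NASC (and sun above 50 degrees for DSL widths),
#' 40 m echo-count bins, VIF cutoff 3 and concurvity cutoff 0.8, NASC
#' model hours 7-18 UTC.
#'
#' @param scene A [scene_config()].
#' @param acoustics List of echo-integration settings (see defaults).
#' @param counting List: `criteria` ([sed_criteria()]), `bin_height` (m).
#' @param models List: `vif_cutoff`, `concurvity_cutoff`, `nasc_hours`,
#'   `k_echo` (basis dimension for the sparse echo-count models).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scene = scene_config(),
                            acoustics = list(),
                            counting = list(),
                            models = list()) {
  acoustics <- utils::modifyList(
    list(threshold_db = -85, surface_cutoff = 15,
         cell_dz = 5, cell_dt = 600,
         alpha_nominal = 0, alpha_true = 0,
         daylight_mode = "sunrise_sunset_1h",
         dsl_daylight_mode = "elevation_50deg",
         dsl_window = c(200, 1200), dsl_smooth_bins = 3,
         dsl_prominence_db = 3), acoustics)
  counting <- utils::modifyList(
    list(criteria = sed_criteria(), bin_height = 40), counting)
  models <- utils::modifyList(
    list(vif_cutoff = 3, concurvity_cutoff = 0.8,
         nasc_hours = 7:18, k_echo = 5), models)
  structure(list(scene = scene, acoustics = acoustics, counting = counting,
                 models = models),
            class = "pipeline_config")
}

#' A small demonstration configuration
#'
#' The full transect structure at reduced grid sizes (8 h of echogram at
#' 600 s columns, 8 stations), so a complete pipeline run stays light.
#'
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(scene = scene_config(seed = seed, n_stations = 8,
                                       echogram_hours = 8, time_step = 600))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns the reconstructed
#'   `pipeline_config`; the writer returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$scene
  plain <- list(
    scene = list(
      latitude_range = sc$latitude_range, n_stations = sc$n_stations,
      depth_max = sc$depth_max, depth_step = sc$depth_step,
      time_step = sc$time_step, echogram_hours = sc$echogram_hours,
      start_time = format(sc$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      seed = sc$seed,
      endmembers = as.list(as.data.frame(sc$endmembers)),
      grouping = list(sigma_upper = sc$grouping$sigma_upper,
                      sigma_lower = sc$grouping$sigma_lower,
                      triples = sc$grouping$triples),
      ctd_noise_sd = as.list(sc$ctd_noise_sd),
      dsl_specs = sc$dsl_specs,
      noise_floor_sv = sc$noise_floor_sv,
      echogram_noise_db = sc$echogram_noise_db,
      frequency = sc$frequency, transducer_depth = sc$transducer_depth,
      omz_spec = sc$omz_spec, fluor_lat_min = sc$fluor_lat_min,
      sed_spec = sc$sed_spec,
      beam = unclass(sc$beam)),
    acoustics = config$acoustics,
    counting = list(criteria = unclass(config$counting$criteria),
                    bin_height = config$counting$bin_height),
    models = config$models)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- y$scene
  scene <- scene_config(
    latitude_range = as.numeric(sc$latitude_range),
    n_stations = sc$n_stations,
    depth_max = sc$depth_max, depth_step = sc$depth_step,
    time_step = sc$time_step, echogram_hours = sc$echogram_hours,
    start_time = as.POSIXct(sc$start_time, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%SZ"),
    seed = sc$seed,
    endmembers = endmember_registry(sc$endmembers$name,
                                    sc$endmembers$temperature,
                                    sc$endmembers$salinity),
    grouping = layer_grouping(sc$grouping$sigma_upper,
                              sc$grouping$sigma_lower,
                              lapply(sc$grouping$triples, unlist)),
    ctd_noise_sd = unlist(sc$ctd_noise_sd),
    dsl_specs = lapply(sc$dsl_specs, function(s) {
      s$lat_range <- as.numeric(s$lat_range)
      s$depth_knots_lat <- as.numeric(s$depth_knots_lat)
      s$depth_knots_m <- as.numeric(s$depth_knots_m)
      s
    }),
    noise_floor_sv = sc$noise_floor_sv,
    echogram_noise_db = sc$echogram_noise_db,
    frequency = sc$frequency, transducer_depth = sc$transducer_depth,
    omz_spec = list(lat_range = as.numeric(sc$omz_spec$lat_range),
                    depth_range = as.numeric(sc$omz_spec$depth_range),
                    o2_min = sc$omz_spec$o2_min),
    fluor_lat_min = sc$fluor_lat_min,
    sed_spec = sc$sed_spec,
    beam = beam_config(frequency = sc$beam$frequency,
                       eba_db = sc$beam$eba_db,
                       pulse_us = sc$beam$pulse_us,
                       range_gate = as.numeric(sc$beam$range_gate),
                       orientation = sc$beam$orientation,
                       ping_interval = sc$beam$ping_interval))
  acoustics <- y$acoustics
  acoustics$dsl_window <- as.numeric(acoustics$dsl_window)
  pipeline_config(
    scene = scene,
    acoustics = acoustics,
    counting = list(criteria = sed_criteria(
      min_ts = y$counting$criteria$min_ts,
      echo_length = as.numeric(y$counting$criteria$echo_length),
      max_phase = y$counting$criteria$max_phase,
      max_gain = y$counting$criteria$max_gain),
      bin_height = y$counting$bin_height),
    models = utils::modifyList(y$models,
                               list(nasc_hours = as.integer(y$models$nasc_hours))))
}
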