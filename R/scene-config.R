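#' Synthetic survey scene configuration
#'
#' Bundles every parameter of the synthetic transect scene: a latitudinal
#' CTD section mixed from the water-type endmembers, a depth x time Sv
#' echogram containing Gaussian deep scattering layers (DSLs) with
#' latitudinal drift, and a stream of single-echo detections (SEDs) drawn
#' from a known density / target-strength field.  Defaults emulate a May
#' North-East Atlantic transect from 17 to 48 degN: 20 CTD stations, casts
#' to 1200 m, an oxygen-minimum feature at 200-600 m in the south, two
#' mesopelagic DSLs in the south (around 400 and 650 m) that deepen
#' northwards with the lower one vanishing north of 30 degN, a surface
#' scattering layer absent between 37 and 45 degN, and a mesopelagic echo
#' density peak of 0.15 m\eqn{^{-3}} near 400 m.
#'
#' All randomness flows from `seed` through one fixed sub-stream per
#' product: `seed + 101` for CTD casts, `seed + 202` for the echogram,
#' `seed + 303` for the SED stream, so the three simulators are
#' independently reproducible.
#'
#' @param latitude_range Transect extent, degrees N.
#' @param n_stations Number of CTD stations (>= 2), equally spaced in
#'   latitude.
#' @param depth_max Maximum depth, m (> 0).
#' @param depth_step Vertical sample / bin size, m (> 0).
#' @param time_step Echogram ping-grid spacing, s.
#' @param echogram_hours Echogram duration, h (columns sweep the latitude
#'   range linearly over this window).
#' @param start_time Survey start (UTC).
#' @param seed Master integer seed.
#' @param endmembers Water-type endmember registry, see
#'   [endmember_registry()].
#' @param grouping Density-layer grouping, see [layer_grouping()].
#' @param ctd_noise_sd Named numeric: Gaussian measurement noise sd for
#'   `temperature` (degC) and `salinity` (psu).
#' @param dsl_specs List of scattering-layer specs; each a list with
#'   `name`, `lat_range` (degN), `depth_knots_lat` / `depth_knots_m`
#'   (piecewise-linear peak depth vs latitude), `sigma` (Gaussian depth sd,
#'   m, > 0) and `peak_sv` (dB re 1 m\eqn{^{-1}}).
#' @param noise_floor_sv Echogram background level, dB re 1 m\eqn{^{-1}}.
#' @param echogram_noise_db Optional Gaussian noise sd added to Sv in dB
#'   (0 = noise-free).
#' @param frequency Echosounder frequency tag for the simulated grid, kHz.
#' @param transducer_depth Transducer depth below surface, m.
#' @param omz_spec Oxygen-minimum-zone feature: list with `lat_range`,
#'   `depth_range` (m) and `o2_min` (ml l\eqn{^{-1}}).
#' @param fluor_lat_min Latitude north of which the near-surface
#'   fluorescence maximum appears, degN.
#' @param sed_spec Single-echo stream spec: list with `ts_mean`, `ts_sd`
#'   (dB re 1 m\eqn{^{2}}), `contamination` (fraction of records given one
#'   violated SED criterion each, in \eqn{[0,1]}), `descent_rate` (m
#'   s\eqn{^{-1}}), `max_depth` (m) and `density` (either
#'   `list(constant = rho)` in m\eqn{^{-3}} or a surface-exponential +
#'   mesopelagic-Gaussian profile `list(surface_density, surface_scale,
#'   peak_density, peak_depth, peak_sd)`).
#' @param beam Trawl-mounted beam geometry, see [beam_config()].
#' @return A `scene_config` list.
#' @export
scene_config <- function(latitude_range = c(17, 48),
                         n_stations = 20,
                         depth_max = 1200,
                         depth_step = 5,
                         time_step = 120,
                         echogram_hours = 48,
                         start_time = as.POSIXct("2019-05-03 12:00:00", tz = "UTC"),
                         seed = 1L,
                         endmembers = endmember_registry(),
                         grouping = layer_grouping(),
                         ctd_noise_sd = c(temperature = 0.005, salinity = 0.002),
                         dsl_specs = default_dsl_specs(),
                         noise_floor_sv = -90,
                         echogram_noise_db = 0,
                         frequency = 38,
                         transducer_depth = 11.6,
                         omz_spec = list(lat_range = c(17, 21),
                                         depth_range = c(200, 600),
                                         o2_min = 1.5),
                         fluor_lat_min = 37,
                         sed_spec = default_sed_spec(),
                         beam = beam_config()) {
  if (depth_max <= 0) stop("`depth_max` must be positive", call. = FALSE)
  if (depth_step <= 0) stop("`depth_step` must be positive", call. = FALSE)
  if (n_stations < 2) stop("`n_stations` must be >= 2", call. = FALSE)
  if (sed_spec$contamination < 0 || sed_spec$contamination > 1) {
    stop("`sed_spec$contamination` must be in [0, 1]", call. = FALSE)
  }
  for (spec in dsl_specs) {
    if (spec$sigma <= 0) {
      stop("scattering-layer `sigma` must be positive (layer '",
           spec$name, "')", call. = FALSE)
    }
  }
  structure(
    list(latitude_range = latitude_range, n_stations = as.integer(n_stations),
         depth_max = depth_max, depth_step = depth_step,
         time_step = time_step, echogram_hours = echogram_hours,
         start_time = start_time, seed = as.integer(seed),
         endmembers = endmembers, grouping = grouping,
         ctd_noise_sd = ctd_noise_sd, dsl_specs = dsl_specs,
         noise_floor_sv = noise_floor_sv,
         echogram_noise_db = echogram_noise_db,
         frequency = frequency, transducer_depth = transducer_depth,
         omz_spec = omz_spec, fluor_lat_min = fluor_lat_min,
         sed_spec = sed_spec, beam = beam),
    class = "scene_config")
}

#' @rdname scene_config
#' @export
default_dsl_specs <- function() {
  list(
    list(name = "dsl_upper", lat_range = c(17, 48),
         depth_knots_lat = c(17, 30, 48), depth_knots_m = c(400, 550, 550),
         sigma = 50, peak_sv = -72),
    list(name = "dsl_lower", lat_range = c(17, 30),
         depth_knots_lat = c(17, 30), depth_knots_m = c(650, 850),
         sigma = 60, peak_sv = -75),
    list(name = "surface_south", lat_range = c(17, 37),
         depth_knots_lat = c(17, 37), depth_knots_m = c(50, 50),
         sigma = 25, peak_sv = -70),
    list(name = "surface_north", lat_range = c(45, 48),
         depth_knots_lat = c(45, 48), depth_knots_m = c(50, 50),
         sigma = 25, peak_sv = -70))
}

#' @rdname scene_config
#' @export
default_sed_spec <- function() {
  list(ts_mean = -65, ts_sd = 4, contamination = 0.05,
       descent_rate = 0.5, max_depth = 1200,
       density = list(surface_density = 0.12, surface_scale = 80,
                      peak_density = 0.15, peak_depth = 400, peak_sd = 80))
}

# Piecewise-linear peak depth of a layer spec at given latitudes.
dsl_peak_depth <- function(spec, lat) {
  if (length(spec$depth_knots_lat) == 1L) {
    return(rep(spec$depth_knots_m, length(lat)))
  }
  stats::approx(spec$depth_knots_lat, spec$depth_knots_m, xout = lat,
                rule = 2)$y
}

# True volumetric density (m^-3) at depth z from the SED spec.
sed_density_fun <- function(sed_spec) {
  d <- sed_spec$density
  if (!is.null(d$constant)) {
    function(z) rep(d$constant, length(z))
  } else {
    function(z) {
      d$surface_density * exp(-z / d$surface_scale) +
        d$peak_density * exp(-(z - d$peak_depth)^2 / (2 * d$peak_sd^2))
    }
  }
}

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_stream <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
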