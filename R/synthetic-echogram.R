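#' Simulate a gridded Sv echogram with known scattering layers
#'
#' Builds a depth x time volume-backscattering grid.  Each configured layer
#' contributes a Gaussian-in-depth profile whose peak depth follows its
#' piecewise-linear latitudinal trend; layer intensities and the noise floor
#' are summed in the *linear* sv domain and then converted to dB, since
#' scattered intensities add while decibels do not.  The per-column ground
#' truth records the analytic peak depth and full width at half maximum,
#' FWHM \eqn{= 2\sqrt{2\ln 2}\,\sigma}.
#'
#' @param config A [scene_config()]; `dsl_specs` must be non-empty.
#' @return A list with
#'   * `sv`: long tibble, one row per (time, depth bin): `frequency`,
#'     `time`, `lat`, `lon`, `depth_top`, `depth_bottom`, `sv_db`;
#'   * `truth`: one row per (column, layer active at that latitude):
#'     `time`, `lat`, `layer`, `peak_depth`, `sigma`, `fwhm`, `peak_sv`.
#' @export
simulate_echogram <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  if (length(config$dsl_specs) == 0) {
    stop("`dsl_specs` must be non-empty", call. = FALSE)
  }
  for (spec in config$dsl_specs) {
    if (spec$sigma <= 0) stop("layer sigma must be positive", call. = FALSE)
  }
  with_stream(config$seed + 202L, {
    n_cols <- max(2L, round(config$echogram_hours * 3600 / config$time_step))
    times <- config$start_time + (seq_len(n_cols) - 1) * config$time_step
    frac <- (seq_len(n_cols) - 1) / (n_cols - 1)
    lats <- config$latitude_range[1] +
      frac * diff(config$latitude_range)
    lons <- -24 + (lats - 17) * (16 / 31)
    edges <- seq(0, config$depth_max, by = config$depth_step)
    z_top <- edges[-length(edges)]
    z_mid <- z_top + config$depth_step / 2

    sv_lin <- matrix(10^(config$noise_floor_sv / 10),
                     nrow = length(z_mid), ncol = n_cols)
    truth <- list()
    for (spec in config$dsl_specs) {
      active <- lats >= spec$lat_range[1] & lats <= spec$lat_range[2]
      if (!any(active)) next
      mu <- dsl_peak_depth(spec, lats[active])
      gauss <- exp(-outer(z_mid, mu, function(z, m) (z - m)^2) /
                     (2 * spec$sigma^2))
      sv_lin[, active] <- sv_lin[, active] + 10^(spec$peak_sv / 10) * gauss
      truth[[spec$name]] <- tibble::tibble(
        time = times[active], lat = lats[active], layer = spec$name,
        peak_depth = mu, sigma = spec$sigma,
        fwhm = 2 * sqrt(2 * log(2)) * spec$sigma, peak_sv = spec$peak_sv)
    }
    sv_db <- 10 * log10(sv_lin)
    if (config$echogram_noise_db > 0) {
      sv_db <- sv_db + stats::rnorm(length(sv_db), 0, config$echogram_noise_db)
    }
    sv <- tibble::tibble(
      frequency = config$frequency,
      time = rep(times, each = length(z_mid)),
      lat = rep(lats, each = length(z_mid)),
      lon = rep(lons, each = length(z_mid)),
      depth_top = rep(z_top, n_cols),
      depth_bottom = rep(z_top + config$depth_step, n_cols),
      sv_db = as.numeric(sv_db))
    list(sv = sv, truth = dplyr::bind_rows(truth))
  })
}
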