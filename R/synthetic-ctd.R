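# Smooth logistic ramp in depth.
ramp <- function(z, z0, w) stats::plogis((z - z0) / w)

# True endmember weights at depth z (m) and latitude (degN).  Weights are
# built by top-down stick breaking so that, at every depth, the set of
# active endmembers is a subset of the triple the sample's density layer
# selects: near-surface STUW/u-NACW (plus l-NACW) mixes stay within the
# upper triple, the u-NACW -> l-NACW and l-NACW -> AAIW transitions are
# valid in the layers on both sides of the 27 and 27.25 kg m^-3
# boundaries, and MOW only enters once AAIW dominance guarantees
# sigma-theta > 27.25.  Weights below 2e-3 are truncated to exactly zero
# and renormalised, so each sample is an exact convex combination of at
# most three endmembers of one triple; the ramp centres/widths are spaced
# so that each endmember's truncation depth clears the density boundary
# where its triple membership would lapse (u-NACW gone by ~535 m, well
# above the 27.25 crossing near 570 m; AAIW absent above ~390 m, just
# below the 27.0 crossing near 386 m).
watermass_weights <- function(z, lat) {
  r1 <- ramp(z, 150, 30)   # leaves the surface STUW/u-NACW pair
  r2 <- ramp(z, 380, 25)   # u-NACW -> l-NACW
  r3 <- ramp(z, 600, 35)   # l-NACW -> AAIW
  r4 <- ramp(z, 950, 60)   # AAIW -> AAIW/MOW
  q_stuw <- 0.75 * stats::plogis((34 - lat) / 2.5)  # STUW only in the south
  m_mow <- 0.55 * stats::plogis((lat - 30) / 3)     # MOW only in the north
  l_deep <- 0.15                                    # residual l-NACW at depth
  w <- cbind(
    `STUW`   = (1 - r1) * q_stuw,
    `u-NACW` = (1 - r1) * (1 - q_stuw) + r1 * (1 - r2),
    `l-NACW` = r1 * r2 * (1 - r3) + r1 * r2 * r3 * l_deep,
    `AAIW`   = r1 * r2 * r3 * (1 - l_deep) * (1 - m_mow * r4),
    `MOW`    = r1 * r2 * r3 * (1 - l_deep) * m_mow * r4)
  w[w < 2e-3] <- 0
  w / rowSums(w)
}

# Background oxygen (ml l^-1) and the OMZ drawdown feature.
oxygen_field <- function(z, lat, omz) {
  bg <- 6 - 1.8 * stats::plogis((z - 150) / 80) +
    0.5 * stats::plogis((z - 800) / 150)
  win <- function(x, rng) {
    u <- (x - rng[1]) / (rng[2] - rng[1])
    ifelse(u > 0 & u < 1, sin(pi * u)^2, 0)
  }
  bump <- win(lat, omz$lat_range) * win(z, omz$depth_range)
  bg - (bg - omz$o2_min) * bump
}

# Relative fluorescence (mg m^-3): near-surface maximum, strong north of
# `fluor_lat_min` (spring-bloom analogue).
fluorescence_field <- function(z, lat, fluor_lat_min) {
  amp <- 0.1 + 1.1 * stats::plogis((lat - fluor_lat_min) / 1.5)
  0.05 + amp * exp(-(z - 30)^2 / (2 * 25^2))
}

#' Simulate a CTD transect with known water-mass composition
#'
#' Generates one cast per station along the latitude range.  At every depth
#' the noise-free (temperature, salinity) pair is an *exact* convex
#' combination of at most three endmembers belonging to a single
#' density-layer triple, so the mixing inversion of [classify_profile()] can
#' recover the stored fractions exactly; configurable Gaussian measurement
#' noise is then added.  Oxygen contains the configured oxygen-minimum-zone
#' feature; fluorescence peaks in the upper 100 m north of
#' `config$fluor_lat_min`.
#'
#' @param config A [scene_config()].
#' @return A tibble, one row per (station, depth): columns `station`,
#'   `time`, `lat`, `lon`, `depth`, `temperature`, `salinity`, `oxygen`,
#'   `fluorescence`, plus ground truth `true_x_<endmember>` (all five
#'   fractions, zeros outside the active triple), `true_layer` and
#'   `true_dominant`.
#' @export
simulate_ctd_transect <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  if (nrow(config$endmembers) < 3) {
    stop("endmember registry must hold at least 3 endmembers", call. = FALSE)
  }
  if (config$depth_max <= 0) stop("`depth_max` must be positive", call. = FALSE)
  with_stream(config$seed + 101L, {
    lats <- seq(config$latitude_range[1], config$latitude_range[2],
                length.out = config$n_stations)
    lons <- -24 + (lats - 17) * (16 / 31)   # SW-NE track, 24W -> 8W
    depths <- seq(0, config$depth_max, by = config$depth_step)
    grid <- tidyr::expand_grid(station = seq_len(config$n_stations),
                               depth = depths)
    grid$lat <- lats[grid$station]
    grid$lon <- lons[grid$station]
    grid$time <- config$start_time + (grid$station - 1) * 86400
    w <- watermass_weights(grid$depth, grid$lat)
    reg <- config$endmembers[match(colnames(w), config$endmembers$name), ]
    t0 <- as.numeric(w %*% reg$temperature)
    s0 <- as.numeric(w %*% reg$salinity)
    noise_t <- stats::rnorm(nrow(grid), 0, config$ctd_noise_sd[["temperature"]])
    noise_s <- stats::rnorm(nrow(grid), 0, config$ctd_noise_sd[["salinity"]])
    sigma0 <- potential_density(t0, s0)
    dominant <- colnames(w)[max.col(w, ties.method = "first")]
    out <- tibble::as_tibble(grid[c("station", "time", "lat", "lon", "depth")])
    out$temperature <- t0 + noise_t
    out$salinity <- s0 + noise_s
    out$oxygen <- oxygen_field(grid$depth, grid$lat, config$omz_spec)
    out$fluorescence <- fluorescence_field(grid$depth, grid$lat,
                                           config$fluor_lat_min)
    for (j in seq_len(ncol(w))) {
      out[[paste0("true_x_", colnames(w)[j])]] <- w[, j]
    }
    out$true_layer <- assign_layer(as.numeric(sigma0), config$grouping)
    out$true_dominant <- dominant
    out
  })
}
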