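# Independent oracles used across the suite.

# Astronomical-Almanac low-precision solar position (Michalsky-style
# ecliptic elements + sidereal-time hour angle) — an independent
# formulation from the package's NOAA/Meeus implementation.
oracle_solar_elevation <- function(time, lat, lon) {
  jd <- as.numeric(time) / 86400 + 2440587.5
  n <- jd - 2451545.0
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180
  lam <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  eps <- (23.439 - 4e-7 * n) * pi / 180
  dec <- asin(sin(eps) * sin(lam))
  ra <- atan2(cos(eps) * sin(lam), cos(lam))
  lt <- as.POSIXlt(time, tz = "UTC")
  hours <- lt$hour + lt$min / 60 + lt$sec / 3600
  n0 <- floor(jd - 0.5) + 0.5 - 2451545.0
  gmst <- (6.697375 + 0.0657098242 * n0 + 1.00273790935 * hours) %% 24
  ha <- (gmst * 15 + lon) * pi / 180 - ra
  asin(sin(lat * pi / 180) * sin(dec) +
         cos(lat * pi / 180) * cos(dec) * cos(ha)) * 180 / pi
}

# Brute-force search over the unit simplex (grid step `step`) minimising
# squared T/S reconstruction error for one observation.
simplex_grid <- local({
  cache <- NULL
  function(step = 1e-3) {
    if (is.null(cache)) {
      g <- seq(0, 1, by = step)
      grid <- expand.grid(x1 = g, x2 = g)
      cache <<- grid[grid$x1 + grid$x2 <= 1 + 1e-12, ]
    }
    cache
  }
})

oracle_simplex_fractions <- function(t_obs, s_obs, triple, step = 1e-3) {
  grid <- simplex_grid(step)
  x3 <- 1 - grid$x1 - grid$x2
  err <- (grid$x1 * triple$temperature[1] + grid$x2 * triple$temperature[2] +
            x3 * triple$temperature[3] - t_obs)^2 +
    (grid$x1 * triple$salinity[1] + grid$x2 * triple$salinity[2] +
       x3 * triple$salinity[3] - s_obs)^2
  k <- which.min(err)
  c(grid$x1[k], grid$x2[k], x3[k])
}

# Monte-Carlo volume of the conical beam sector between the range gates:
# rejection sampling in a bounding box around the cone axis.
oracle_frustum_volume <- function(beam, n = 1e6) {
  omega <- 10^(beam$eba_db / 10)
  cos_th <- 1 - omega / (2 * pi)
  th <- acos(cos_th)
  rmax <- beam$range_gate[2]
  s <- rmax * sin(th)
  x <- stats::runif(n, -s, s)
  y <- stats::runif(n, -s, s)
  z <- stats::runif(n, 0, rmax)
  r <- sqrt(x^2 + y^2 + z^2)
  inside <- r > beam$range_gate[1] & r < rmax & z / r >= cos_th
  (2 * s)^2 * rmax * mean(inside)
}

# Fine-grid echo-integration oracle: brute-force column total NASC from a
# continuous sv(z) function sampled at dz_fine.
oracle_column_nasc <- function(sv_fun_db, z_min, z_max, dz_fine = 0.01) {
  z <- seq(z_min + dz_fine / 2, z_max - dz_fine / 2, by = dz_fine)
  4 * pi * 1852^2 * sum(10^(sv_fun_db(z) / 10) * dz_fine)
}

# A small noise-free scene for fast round-trip tests.
quiet_scene <- function(...) {
  scene_config(ctd_noise_sd = c(temperature = 0, salinity = 0), ...)
}

# One-column Sv grid from a numeric profile (depth bins of `dz` m).
profile_grid <- function(sv_db, dz = 5, frequency = 38,
                         time = as.POSIXct("2019-05-03 12:00:00", tz = "UTC"),
                         lat = 20, lon = -20) {
  n <- length(sv_db)
  tibble::tibble(frequency = frequency, time = time, lat = lat, lon = lon,
                 depth_top = (seq_len(n) - 1) * dz,
                 depth_bottom = seq_len(n) * dz,
                 sv_db = sv_db)
}

# Gaussian-layer Sv profile in dB over bin centres.
gaussian_profile_db <- function(peak_db, mu, sigma, floor_db = -999,
                                depth_max = 1200, dz = 5) {
  zc <- seq(dz / 2, depth_max - dz / 2, by = dz)
  10 * log10(10^(floor_db / 10) +
               10^(peak_db / 10) * exp(-(zc - mu)^2 / (2 * sigma^2)))
}
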