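# Solar geometry for daylight filtering of survey data.
#
# Implements the NOAA solar-position algorithm (Meeus-style ecliptic
# elements: equation of centre, apparent longitude, corrected obliquity,
# equation of time), then the hour-angle / zenith relation.  Accuracy is
# about 0.01 degree, ample for daylight masks whose thresholds are
# crossed at >~ 0.1 deg min^-1.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Apparent solar elevation angle
#'
#' @param time POSIXct (UTC) vector.
#' @param lat,lon Degrees north / east (west negative). Recycled against
#'   `time`.
#' @return Solar elevation above the geometric horizon, degrees.
#' @examples
#' solar_elevation(as.POSIXct("2019-03-21 12:00", tz = "UTC"), 0, 0)
#' @export
solar_elevation <- function(time, lat, lon) {
  if (any(abs(lat) > 90) || any(abs(lon) > 360)) {
    stop("invalid lat/lon", call. = FALSE)
  }
  n <- max(length(time), length(lat), length(lon))
  time <- rep_len(time, n); lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  lt <- as.POSIXlt(time, tz = "UTC")
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525                  # Julian centuries from J2000
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M <- deg2rad(357.52911 + jc * (35999.05029 - 0.0001537 * jc))
  ecc <- 0.016708634 - jc * (0.000042037 + 1.267e-7 * jc)
  C <- sin(M) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * M) * (0.019993 - 0.000101 * jc) + sin(3 * M) * 0.000289
  omega <- deg2rad(125.04 - 1934.136 * jc)
  lambda_app <- deg2rad(L0 + C - 0.00569 - 0.00478 * sin(omega))
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  eps <- deg2rad(eps0 + 0.00256 * cos(omega))
  decl <- asin(sin(eps) * sin(lambda_app))
  y <- tan(eps / 2)^2
  L0r <- deg2rad(L0)
  eqtime <- 4 * rad2deg(y * sin(2 * L0r) - 2 * ecc * sin(M) +
                          4 * ecc * y * sin(M) * cos(2 * L0r) -
                          0.5 * y^2 * sin(4 * L0r) -
                          1.25 * ecc^2 * sin(2 * M))    # minutes
  tst <- hour * 60 + eqtime + 4 * lon           # true solar time, minutes
  ha <- deg2rad(tst / 4 - 180)                  # hour angle
  cos_zen <- sin(deg2rad(lat)) * sin(decl) +
    cos(deg2rad(lat)) * cos(decl) * cos(ha)
  90 - rad2deg(acos(pmin(1, pmax(-1, cos_zen))))
}

#' Daylight mask for acoustic columns
#'
#' Computes, per (time, position), whether a solar daylight condition
#' holds.  Three modes:
#' * `"above_horizon"`: apparent sun above the horizon (elevation >
#'   -0.833 deg, the standard sunrise/sunset depression accounting for
#'   refraction and solar radius);
#' * `"sunrise_sunset_1h"`: later than 1 h after sunrise and earlier than
#'   1 h before sunset, evaluated as "apparent sun above the horizon at
#'   both `t - 1 h` and `t + 1 h`" (equivalent for days with a single
#'   daylight period, since elevation is unimodal about solar noon);
#' * `"elevation_50deg"`: sun more than 50 degrees above the horizon.
#'
#' The three masks are nested: `elevation_50deg` implies
#' `sunrise_sunset_1h` implies `above_horizon`.
#'
#' @param time POSIXct (UTC) vector.
#' @param lat,lon Degrees north / east.
#' @param mode One of `"above_horizon"`, `"sunrise_sunset_1h"`,
#'   `"elevation_50deg"`.
#' @return Logical vector.
#' @export
daylight_mask <- function(time, lat, lon,
                          mode = c("above_horizon", "sunrise_sunset_1h",
                                   "elevation_50deg")) {
  mode <- match.arg(mode)
  horizon <- -0.833
  switch(mode,
         above_horizon = solar_elevation(time, lat, lon) > horizon,
         sunrise_sunset_1h =
           solar_elevation(time - 3600, lat, lon) > horizon &
           solar_elevation(time + 3600, lat, lon) > horizon,
         elevation_50deg = solar_elevation(time, lat, lon) > 50)
}

#' Restrict an Sv grid to daylight columns
#'
#' Drops grid columns (time, lat, lon combinations) whose daylight
#' condition fails.
#'
#' @param grid Long Sv tibble with `time`, `lat`, `lon` columns.
#' @param mode See [daylight_mask()].
#' @return The filtered tibble.
#' @export
filter_daylight <- function(grid, mode = "sunrise_sunset_1h") {
  cols <- dplyr::distinct(grid, .data$time, .data$lat, .data$lon)
  cols$.keep <- daylight_mask(cols$time, cols$lat, cols$lon, mode)
  out <- dplyr::inner_join(grid, cols[cols$.keep, c("time", "lat", "lon")],
                           by = c("time", "lat", "lon"))
  out
}
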