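# Echo integration: from calibrated Sv grids to NASC cells.
#
# A grid is a long tibble with columns frequency, time, lat, lon,
# depth_top, depth_bottom (half-open [top, bottom), metres below surface,
# positive down) and sv_db (dB re 1 m^-1).  Two distinguished values:
# -Inf marks "no echo" (below threshold; integrates as zero in the linear
# domain) and NA marks "missing" (excluded data; never integrates as
# zero).  Keeping the two apart prevents absence of data masquerading as
# absence of scatterers.

#' Apply an Sv threshold
#'
#' Samples below the threshold are set to the no-echo value (`-Inf` dB,
#' i.e. zero in the linear domain); samples at or above it, and missing
#' samples, are unchanged.
#'
#' @param grid Long Sv tibble (see [simulate_echogram()] for the layout).
#' @param threshold_db Threshold, dB re 1 m\eqn{^{-1}}.
#' @return The thresholded tibble.
#' @export
apply_threshold <- function(grid, threshold_db = -85) {
  if (!is.finite(threshold_db)) stop("threshold must be finite", call. = FALSE)
  dplyr::mutate(grid, sv_db = dplyr::if_else(
    !is.na(.data$sv_db) & .data$sv_db < threshold_db, -Inf, .data$sv_db))
}

#' Exclude the near-surface blind zone
#'
#' Marks as missing every depth bin lying wholly above the cutoff
#' (`depth_bottom <= cutoff`, per the half-open bin convention), emulating
#' the unusable zone above the transducer face plus its near field.
#'
#' @param grid Long Sv tibble.
#' @param cutoff Exclusion depth, m (default 15).
#' @return The tibble with excluded bins set to `NA`.
#' @export
exclude_surface <- function(grid, cutoff = 15) {
  dplyr::mutate(grid, sv_db = dplyr::if_else(
    .data$depth_bottom <= cutoff, NA_real_, .data$sv_db))
}

#' Correct Sv for a revised absorption coefficient and sound speed
#'
#' Backscatter logged with a nominal absorption coefficient
#' \eqn{\alpha_{nom}} is re-referenced to the true coefficient by
#' \eqn{S_v' (r) = S_v(r) + 2(\alpha_{true} - \alpha_{nom}) r}, with
#' \eqn{r} the range from the transducer.  Optionally the depth axis is
#' rescaled by \eqn{c_{true}/c_{nom}} about the transducer depth (a static
#' sound-speed profile correction).
#'
#' @param grid Long Sv tibble.
#' @param alpha_nominal,alpha_true Absorption coefficients, dB m\eqn{^{-1}}
#'   (both >= 0).
#' @param transducer_depth Transducer depth below surface, m.
#' @param c_nominal,c_true Optional sound speeds, m s\eqn{^{-1}}; if both
#'   given, depth bins are stretched by their ratio.
#' @return The corrected tibble.
#' @export
correct_absorption <- function(grid, alpha_nominal, alpha_true,
                               transducer_depth = 11.6,
                               c_nominal = NULL, c_true = NULL) {
  if (alpha_nominal < 0 || alpha_true < 0) {
    stop("absorption coefficients must be nonnegative", call. = FALSE)
  }
  out <- grid
  if (!is.null(c_nominal) && !is.null(c_true)) {
    k <- c_true / c_nominal
    out$depth_top <- transducer_depth + (out$depth_top - transducer_depth) * k
    out$depth_bottom <- transducer_depth +
      (out$depth_bottom - transducer_depth) * k
  }
  r <- pmax(0, (out$depth_top + out$depth_bottom) / 2 - transducer_depth)
  dplyr::mutate(out, sv_db = .data$sv_db +
                  2 * (alpha_true - alpha_nominal) * r)
}

#' Integrate an Sv grid into NASC cells
#'
#' Partitions the grid into cells of `dz` metres by `dt` seconds and
#' computes, per cell, the Nautical Area Scattering Coefficient
#' \deqn{NASC = 4\pi\,1852^2\ \overline{s_v}\ dz \quad [m^2\,nmi^{-2}]}
#' with \eqn{\overline{s_v}} the mean *linear* volume backscattering
#' coefficient over the cell's non-missing samples.  No-echo samples
#' (`-Inf` dB) contribute zero; cells whose samples are all missing get
#' `NA`, not zero.
#'
#' @param grid Long Sv tibble, already thresholded and surface-excluded.
#' @param dz Cell height, m (default 5).
#' @param dt Cell duration, s (default 600).
#' @return Tibble of cells: `frequency`, `time_start`, `depth_top`,
#'   `depth_bottom`, `lat`, `lon` (cell means), `nasc`, `n_samples`
#'   (non-missing source samples).
#' @export
integrate_cells <- function(grid, dz = 5, dt = 600) {
  if (dz <= 0 || dt <= 0) stop("`dz` and `dt` must be positive", call. = FALSE)
  g <- dplyr::mutate(grid,
    sv_lin = ifelse(is.na(.data$sv_db), NA_real_, 10^(.data$sv_db / 10)),
    cell_depth = floor((.data$depth_top + .data$depth_bottom) / 2 / dz) * dz,
    cell_time = as.POSIXct(floor(as.numeric(.data$time) / dt) * dt,
                           origin = "1970-01-01", tz = "UTC"))
  cells <- dplyr::summarise(
    dplyr::group_by(g, .data$frequency, .data$cell_time, .data$cell_depth),
    lat = mean(.data$lat), lon = mean(.data$lon),
    mean_sv = mean(.data$sv_lin, na.rm = TRUE),
    n_samples = sum(!is.na(.data$sv_lin)),
    .groups = "drop")
  dplyr::transmute(cells,
    frequency = .data$frequency,
    time_start = .data$cell_time,
    depth_top = .data$cell_depth,
    depth_bottom = .data$cell_depth + dz,
    lat = .data$lat, lon = .data$lon,
    nasc = ifelse(.data$n_samples == 0, NA_real_,
                  4 * pi * 1852^2 * .data$mean_sv * dz),
    n_samples = .data$n_samples)
}

#' Label NASC cells with water masses from a classified CTD section
#'
#' Each cell inherits the dominant water-type label of the *nearest
#' station* (great-circle distance from the cell's mean position), taken
#' at the station depth nearest the cell's mid-depth.
#'
#' @param cells NASC cell tibble from [integrate_cells()].
#' @param section Classified section from [classify_profile()] (columns
#'   `station`, `lat`, `lon`, `depth`, `dominant`).
#' @return `cells` plus `station` and `water_mass` columns.
#' @export
label_cells_by_watermass <- function(cells, section) {
  stations <- dplyr::distinct(section, .data$station, .data$lat, .data$lon)
  if (nrow(stations) == 0) stop("no classified stations", call. = FALSE)
  dmat <- vapply(seq_len(nrow(stations)), function(i) {
    geosphere::distHaversine(cbind(cells$lon, cells$lat),
                             c(stations$lon[i], stations$lat[i]))
  }, numeric(nrow(cells)))
  dmat <- matrix(dmat, nrow = nrow(cells))
  nearest <- stations$station[max.col(-dmat, ties.method = "first")]
  out <- dplyr::mutate(cells, station = nearest,
                       .mid = (.data$depth_top + .data$depth_bottom) / 2)
  lookup <- split(section[c("depth", "dominant")], section$station)
  out$water_mass <- vapply(seq_len(nrow(out)), function(i) {
    prof <- lookup[[as.character(out$station[i])]]
    prof$dominant[which.min(abs(prof$depth - out$.mid[i]))]
  }, character(1))
  out$.mid <- NULL
  out
}

#' Summarise NASC by water mass
#'
#' Per water-mass label and frequency: arithmetic mean, standard
#' deviation, maximum NASC and the number of integration cells (the
#' layout of a per-oceanographic-zone backscatter table).
#'
#' @param cells Labelled cell tibble from [label_cells_by_watermass()].
#' @return Tibble with `frequency`, `water_mass`, `mean_nasc`, `sd_nasc`
#'   (`NA` for a single cell), `max_nasc`, `n`.
#' @export
summarize_by_watermass <- function(cells) {
  ok <- dplyr::filter(cells, !is.na(.data$nasc))
  if (nrow(ok) == 0) stop("no labelled cells with NASC values", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(ok, .data$frequency, .data$water_mass),
    mean_nasc = mean(.data$nasc),
    sd_nasc = stats::sd(.data$nasc),
    max_nasc = max(.data$nasc),
    n = dplyr::n(),
    .groups = "drop")
}
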