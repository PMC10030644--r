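# Echo counting: single-echo detections -> volumetric densities.

#' Beam configuration for a trawl-mounted or towed echosounder
#'
#' @param frequency Operating frequency, kHz.
#' @param eba_db Equivalent beam angle, dB re 1 sr (< 0).  The effective
#'   beam solid angle is \eqn{\Omega = 10^{EBA/10}} sr.  The default
#'   -20.7 dB is the nominal value for a 7-degree split-beam transducer.
#' @param pulse_us Pulse duration, microseconds.
#' @param range_gate Open interval `(r_min, r_max)` of counted ranges, m.
#' @param orientation `"horizontal_forward"` (headrope-mounted, beam along
#'   the tow direction) or `"vertical_down"`.
#' @param ping_interval Ping spacing, s.
#' @return A `beam_config` list.
#' @export
beam_config <- function(frequency = 200, eba_db = -20.7, pulse_us = 256,
                        range_gate = c(3, 15),
                        orientation = c("horizontal_forward", "vertical_down"),
                        ping_interval = 2) {
  orientation <- match.arg(orientation)
  if (range_gate[1] > range_gate[2]) {
    stop("invalid range gate: r_min must be <= r_max", call. = FALSE)
  }
  if (eba_db >= 0) stop("`eba_db` must be negative", call. = FALSE)
  structure(list(frequency = frequency, eba_db = eba_db, pulse_us = pulse_us,
                 range_gate = range_gate, orientation = orientation,
                 ping_interval = ping_interval),
            class = "beam_config")
}

#' Single-echo-detection acceptance criteria
#'
#' An echo is accepted iff its compensated target strength is at least
#' `min_ts`, its echo length (relative to the pulse length) lies in
#' `echo_length`, its phase deviation is at most `max_phase` and its gain
#' compensation is at most `max_gain`.
#'
#' @param min_ts Minimum TS, dB re 1 m\eqn{^{2}} (default -80).
#' @param echo_length Min/max echo length relative to pulse (default
#'   0.6-1.4).
#' @param max_phase Maximum phase deviation, phase steps (default 10).
#' @param max_gain Maximum gain compensation, dB (default 3).
#' @return A `sed_criteria` list.
#' @export
sed_criteria <- function(min_ts = -80, echo_length = c(0.6, 1.4),
                         max_phase = 10, max_gain = 3) {
  stopifnot(echo_length[1] < echo_length[2],
            all(is.finite(c(min_ts, echo_length, max_phase, max_gain))))
  structure(list(min_ts = min_ts, echo_length = echo_length,
                 max_phase = max_phase, max_gain = max_gain),
            class = "sed_criteria")
}

#' Filter single-echo detections
#'
#' Applies the four SED acceptance criteria.  Rejections carry the *first*
#' violated criterion in the fixed evaluation order TS, echo length,
#' phase deviation, gain compensation, so rejection reasons are
#' deterministic.
#'
#' @param echoes Tibble with columns `ts`, `echo_length`, `phase_dev`,
#'   `gain_comp` (other columns carried through).
#' @param criteria A [sed_criteria()].
#' @return `echoes` plus `accepted` (logical) and `rejection` (criterion
#'   name, `NA` when accepted).
#' @export
sed_filter <- function(echoes, criteria = sed_criteria()) {
  ok_ts <- echoes$ts >= criteria$min_ts
  ok_len <- echoes$echo_length >= criteria$echo_length[1] &
    echoes$echo_length <= criteria$echo_length[2]
  ok_phase <- echoes$phase_dev <= criteria$max_phase
  ok_gain <- echoes$gain_comp <= criteria$max_gain
  rejection <- rep(NA_character_, nrow(echoes))
  rejection[!ok_gain] <- "gain_comp"
  rejection[!ok_phase] <- "phase_dev"
  rejection[!ok_len] <- "echo_length"
  rejection[!ok_ts] <- "ts"
  dplyr::mutate(echoes,
                accepted = ok_ts & ok_len & ok_phase & ok_gain,
                rejection = rejection)
}

#' Gate echoes by range
#'
#' Keeps echoes strictly inside the beam's open range gate
#' `(r_min, r_max)`; everything else is excluded from both counting and
#' volume.
#'
#' @param echoes Tibble with a `range` column, m.
#' @param beam A [beam_config()].
#' @return The gated tibble.
#' @export
gate_by_range <- function(echoes, beam) {
  dplyr::filter(echoes, .data$range > beam$range_gate[1],
                .data$range < beam$range_gate[2])
}

#' Acoustically sampled volume of a conical beam sector
#'
#' The volume insonified between the range gates by `n_pings` pings:
#' \deqn{V = n\ \frac{\Omega}{3}\left(r_{max}^3 - r_{min}^3\right), \qquad
#'   \Omega = 10^{EBA/10}\ \mathrm{sr}.}
#'
#' @param beam A [beam_config()].
#' @param n_pings Number of pings (>= 0).
#' @return Volume, m\eqn{^{3}}.
#' @examples
#' sampled_volume(beam_config(eba_db = -20.7, range_gate = c(3, 15)), 1)
#' @export
sampled_volume <- function(beam, n_pings) {
  if (n_pings < 0) stop("`n_pings` must be >= 0", call. = FALSE)
  if (beam$range_gate[1] > beam$range_gate[2]) {
    stop("invalid range gate", call. = FALSE)
  }
  omega <- 10^(beam$eba_db / 10)
  n_pings * omega / 3 * (beam$range_gate[2]^3 - beam$range_gate[1]^3)
}

#' Depth assignment of single echoes
#'
#' A horizontally forward-pointing beam assigns every echo the platform
#' depth (over a short range gate the vertical spread of a narrow beam is
#' far below the depth-bin height); a downward beam adds the range.
#'
#' @param echoes Tibble with `platform_depth` (m) and `range` (m).
#' @param beam A [beam_config()].
#' @return Numeric vector of echo depths, m.
#' @export
echo_depth <- function(echoes, beam) {
  if (any(is.na(echoes$platform_depth))) {
    stop("missing platform depth", call. = FALSE)
  }
  switch(beam$orientation,
         horizontal_forward = echoes$platform_depth,
         vertical_down = echoes$platform_depth + echoes$range)
}

#' Volumetric density profile from accepted echoes
#'
#' Per depth bin: the count of accepted, in-gate echoes whose depth falls
#' in the bin, divided by the summed sampled volume of the pings whose
#' platform depth lay in the bin.  Bins insonified by no ping (zero
#' volume) are flagged missing, not zero.
#'
#' @param echoes SED tibble; if an `accepted` column is present only
#'   accepted echoes are counted.  Rows are range-gated internally.
#' @param pings Ping tibble with `platform_depth` (m); an optional `phase`
#'   column (e.g. downcast/upcast) partitions the profile.
#' @param beam A [beam_config()].
#' @param bin_height Depth bin height, m (default 40).
#' @param by_phase Split by the `phase` column when present.
#' @return Tibble: (`phase`,) `depth_top`, `depth_bottom`, `n_echoes`,
#'   `n_pings`, `volume_m3`, `density_m3` (m\eqn{^{-3}}, `NA` where
#'   volume is zero).
#' @export
density_profile <- function(echoes, pings, beam, bin_height = 40,
                            by_phase = FALSE) {
  if (nrow(pings) == 0) stop("no pings", call. = FALSE)
  if ("accepted" %in% names(echoes)) {
    echoes <- dplyr::filter(echoes, .data$accepted)
  }
  echoes <- gate_by_range(echoes, beam)
  echoes$.depth <- if (nrow(echoes)) echo_depth(echoes, beam) else numeric()
  edges_max <- ceiling(max(pings$platform_depth, 1) / bin_height) * bin_height
  bin_of <- function(z) pmin(floor(z / bin_height) * bin_height,
                             edges_max - bin_height)
  use_phase <- by_phase && "phase" %in% names(pings)
  pings$.phase <- if (use_phase) pings$phase else "all"
  echoes$.phase <- if (use_phase) echoes$phase else "all"
  v_ping <- sampled_volume(beam, 1)
  pc <- dplyr::count(pings, .phase = .data$.phase,
                     depth_top = bin_of(.data$platform_depth),
                     name = "n_pings")
  full <- tidyr::expand_grid(
    .phase = unique(pings$.phase),
    depth_top = seq(0, edges_max - bin_height, by = bin_height))
  pc <- dplyr::left_join(full, pc, by = c(".phase", "depth_top"))
  pc$n_pings[is.na(pc$n_pings)] <- 0L
  ec <- dplyr::count(echoes, .phase = .data$.phase,
                     depth_top = bin_of(.data$.depth), name = "n_echoes")
  out <- dplyr::left_join(pc, ec, by = c(".phase", "depth_top"))
  out$n_echoes[is.na(out$n_echoes)] <- 0L
  out <- dplyr::mutate(out,
    depth_bottom = .data$depth_top + bin_height,
    volume_m3 = .data$n_pings * v_ping,
    density_m3 = ifelse(.data$volume_m3 > 0,
                        .data$n_echoes / .data$volume_m3, NA_real_))
  out <- dplyr::rename(out, phase = ".phase")
  if (!use_phase) out$phase <- NULL
  dplyr::select(out, dplyr::any_of(c("phase")), "depth_top", "depth_bottom",
                "n_echoes", "n_pings", "volume_m3", "density_m3")
}

#' Target-strength histograms by depth bin
#'
#' Counts accepted echoes in (depth bin, TS bin) classes, optionally split
#' into descending and ascending platform phases.
#'
#' @param echoes SED tibble with depth already implied by
#'   `platform_depth`/`range`; if an `accepted` column is present only
#'   accepted echoes are used.
#' @param beam A [beam_config()] (for depth assignment).
#' @param bin_height Depth bin height, m (default 40).
#' @param ts_bin_db TS class width, dB (default 2).
#' @param by_phase Split by the `phase` column when present.
#' @return Tibble: (`phase`,) `depth_top`, `depth_bottom`, `ts_low`,
#'   `ts_high`, `n`.
#' @export
ts_depth_profile <- function(echoes, beam, bin_height = 40, ts_bin_db = 2,
                             by_phase = TRUE) {
  if ("accepted" %in% names(echoes)) {
    echoes <- dplyr::filter(echoes, .data$accepted)
  }
  if (nrow(echoes) == 0) {
    return(tibble::tibble(phase = character(), depth_top = numeric(),
                          depth_bottom = numeric(), ts_low = numeric(),
                          ts_high = numeric(), n = integer()))
  }
  echoes$.depth <- echo_depth(echoes, beam)
  use_phase <- by_phase && "phase" %in% names(echoes)
  echoes$.phase <- if (use_phase) echoes$phase else "all"
  out <- dplyr::count(echoes,
                      phase = .data$.phase,
                      depth_top = floor(.data$.depth / bin_height) * bin_height,
                      ts_low = floor(.data$ts / ts_bin_db) * ts_bin_db,
                      name = "n")
  dplyr::mutate(out, depth_bottom = .data$depth_top + bin_height,
                ts_high = .data$ts_low + ts_bin_db,
                .after = "depth_top")
}

#' Compare paired-frequency density profiles
#'
#' Ordinary least-squares regression of profile B's densities on profile
#' A's over their paired, non-missing depth bins, plus the overall density
#' ratio \eqn{\sum B / \sum A} — the form in which closely agreeing
#' frequencies are reported (e.g. "3% higher, R^2 = 0.93").
#'
#' @param profile_a,profile_b Density profiles from [density_profile()] on
#'   matching depth bins.
#' @return One-row tibble: `n_pairs`, `slope`, `intercept`, `r_squared`,
#'   `ratio`.
#' @export
paired_frequency_comparison <- function(profile_a, profile_b) {
  paired <- dplyr::inner_join(
    dplyr::select(profile_a, "depth_top", a = "density_m3"),
    dplyr::select(profile_b, "depth_top", b = "density_m3"),
    by = "depth_top")
  paired <- dplyr::filter(paired, !is.na(.data$a), !is.na(.data$b))
  if (nrow(paired) < 3) {
    stop("need at least 3 paired non-missing bins", call. = FALSE)
  }
  fit <- stats::lm(b ~ a, data = paired)
  tibble::tibble(
    n_pairs = nrow(paired),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    ratio = sum(paired$b) / sum(paired$a))
}
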