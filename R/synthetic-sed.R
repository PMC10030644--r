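#' Simulate a single-echo-detection stream from a known density field
#'
#' Emulates a trawl-mounted echosounder lowered to `max_depth` and hauled
#' back (downcast then upcast) while pinging at the beam's ping interval.
#' Per ping, the number of detected echoes is Poisson with mean
#' \eqn{\rho(z)\,V_{\mathrm{ping}}}, where \eqn{V_{\mathrm{ping}}} is the
#' conical-sector sampled volume of one ping (see [sampled_volume()]).
#' Ranges are drawn inside the gate with probability density proportional
#' to \eqn{r^2}, mirroring the growth of the insonified volume with range;
#' target strength is Gaussian.  A `contamination` fraction of records is
#' given attribute values violating *exactly one* SED acceptance criterion
#' each (chosen uniformly among the four), to exercise the filter; the
#' planted violation is recorded in the truth column.
#'
#' @param config A [scene_config()]; the relevant parts are `sed_spec` and
#'   `beam`.
#' @return A list with
#'   * `echoes`: tibble of SED records: `ping_time`, `platform_depth`,
#'     `phase` (`"down"`/`"up"`), `range`, `ts`, `echo_length`,
#'     `phase_dev`, `gain_comp`, and ground truth `planted_violation`
#'     (`NA` for clean records);
#'   * `pings`: tibble with `ping_time`, `platform_depth`, `phase`;
#'   * `truth`: 40-m-binned true density profile: `depth_top`,
#'     `depth_bottom`, `rho_true` (m\eqn{^{-3}}, bin-centre value).
#' @export
simulate_sed <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  beam <- config$beam
  spec <- config$sed_spec
  if (beam$range_gate[1] >= beam$range_gate[2]) {
    stop("range gates inverted: r_min must be < r_max", call. = FALSE)
  }
  rho_fun <- sed_density_fun(spec)
  if (any(rho_fun(seq(0, spec$max_depth, by = 10)) < 0)) {
    stop("true density profile must be nonnegative", call. = FALSE)
  }
  with_stream(config$seed + 303L, {
    leg_s <- spec$max_depth / spec$descent_rate
    t_rel <- seq(0, 2 * leg_s, by = beam$ping_interval)
    depth_p <- ifelse(t_rel <= leg_s,
                      t_rel * spec$descent_rate,
                      (2 * leg_s - t_rel) * spec$descent_rate)
    pings <- tibble::tibble(
      ping_time = config$start_time + t_rel,
      platform_depth = depth_p,
      phase = ifelse(t_rel <= leg_s, "down", "up"))

    v_ping <- sampled_volume(beam, 1)
    n_echo <- stats::rpois(nrow(pings), rho_fun(pings$platform_depth) * v_ping)
    idx <- rep.int(seq_len(nrow(pings)), n_echo)
    n <- length(idx)
    r3 <- beam$range_gate^3
    echoes <- tibble::tibble(
      ping_time = pings$ping_time[idx],
      platform_depth = pings$platform_depth[idx],
      phase = pings$phase[idx],
      range = (r3[1] + stats::runif(n) * (r3[2] - r3[1]))^(1 / 3),
      ts = stats::rnorm(n, spec$ts_mean, spec$ts_sd),
      echo_length = stats::runif(n, 0.7, 1.3),
      phase_dev = stats::runif(n, 0, 8),
      gain_comp = stats::runif(n, 0, 2.5),
      planted_violation = NA_character_)

    if (n > 0 && spec$contamination > 0) {
      hit <- stats::runif(n) < spec$contamination
      crit <- sample(c("ts", "echo_length", "phase_dev", "gain_comp"),
                     n, replace = TRUE)
      crit[!hit] <- NA_character_
      k <- which(crit == "ts")
      echoes$ts[k] <- stats::runif(length(k), -95, -80.5)
      k <- which(crit == "echo_length")
      echoes$echo_length[k] <- ifelse(stats::runif(length(k)) < 0.5,
                                      stats::runif(length(k), 0.2, 0.55),
                                      stats::runif(length(k), 1.45, 1.8))
      k <- which(crit == "phase_dev")
      echoes$phase_dev[k] <- stats::runif(length(k), 10.5, 20)
      k <- which(crit == "gain_comp")
      echoes$gain_comp[k] <- stats::runif(length(k), 3.2, 6)
      echoes$planted_violation <- crit
    }

    edges <- seq(0, ceiling(spec$max_depth / 40) * 40, by = 40)
    truth <- tibble::tibble(
      depth_top = edges[-length(edges)],
      depth_bottom = edges[-1],
      rho_true = rho_fun(edges[-length(edges)] + 20))
    list(echoes = echoes, pings = pings, truth = truth)
  })
}
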