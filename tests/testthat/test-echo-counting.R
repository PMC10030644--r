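one_echo <- function(ts = -70, len = 1.0, phase = 5, gain = 2, range = 10,
                     platform_depth = 500) {
  tibble::tibble(ping_time = as.POSIXct("2019-05-03 12:00", tz = "UTC"),
                 platform_depth = platform_depth, range = range, ts = ts,
                 echo_length = len, phase_dev = phase, gain_comp = gain)
}

test_that("the SED filter applies all four criteria with fixed reasons", {
  e <- dplyr::bind_rows(
    one_echo(ts = -79),                      # all pass
    one_echo(ts = -81),                      # TS fail
    one_echo(ts = -70, len = 1.5),           # length fail
    one_echo(phase = 12),                    # phase fail
    one_echo(gain = 3.5),                    # gain fail
    one_echo(ts = -85, len = 0.2, phase = 15, gain = 5))  # all fail
  f <- sed_filter(e)
  expect_identical(f$accepted, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(f$rejection,
                   c(NA, "ts", "echo_length", "phase_dev", "gain_comp", "ts"))
  # boundary values are accepted (criteria are inclusive)
  b <- sed_filter(one_echo(ts = -80, len = 0.6, phase = 10, gain = 3))
  expect_true(b$accepted)
})

test_that("acceptance equals the conjunction of single-criterion filters", {
  cfg <- scene_config(seed = 9, sed_spec = list(
    ts_mean = -65, ts_sd = 4, contamination = 0.3, descent_rate = 0.5,
    max_depth = 1200, density = list(constant = 0.1)))
  sed <- simulate_sed(cfg)
  f <- sed_filter(sed$echoes)
  crit <- sed_criteria()
  conj <- sed$echoes$ts >= crit$min_ts &
    sed$echoes$echo_length >= crit$echo_length[1] &
    sed$echoes$echo_length <= crit$echo_length[2] &
    sed$echoes$phase_dev <= crit$max_phase &
    sed$echoes$gain_comp <= crit$max_gain
  expect_identical(f$accepted, conj)
})

test_that("range gating keeps the open interval only", {
  beam <- beam_config(range_gate = c(4, 15))
  e <- dplyr::bind_rows(one_echo(range = 10), one_echo(range = 2),
                        one_echo(range = 17))
  expect_identical(nrow(gate_by_range(e, beam)), 1L)
  degenerate <- beam_config(range_gate = c(10, 10))
  expect_identical(nrow(gate_by_range(e, degenerate)), 0L)
  expect_identical(sampled_volume(degenerate, 5), 0)
})

test_that("sampled volume matches the closed form and is linear in pings", {
  beam <- beam_config(eba_db = -20.7, range_gate = c(3, 15))
  v1 <- sampled_volume(beam, 1)
  expect_equal(v1, 10^(-2.07) / 3 * (15^3 - 3^3), tolerance = 1e-12)
  expect_equal(v1, 9.499, tolerance = 1e-4)
  expect_equal(sampled_volume(beam, 8), 8 * v1, tolerance = 1e-12)
  expect_error(sampled_volume(beam, -1), ">= 0")
})

test_that("sampled volume matches Monte-Carlo integration of the cone", {
  set.seed(61)
  beam <- beam_config(eba_db = -20.7, range_gate = c(3, 15))
  mc <- oracle_frustum_volume(beam, n = 1e6)
  expect_equal(sampled_volume(beam, 1), mc, tolerance = 5e-3)
})

test_that("echo depth follows beam orientation", {
  h <- beam_config(orientation = "horizontal_forward")
  v <- beam_config(orientation = "vertical_down")
  e <- dplyr::bind_rows(one_echo(range = 10, platform_depth = 500),
                        one_echo(range = 100, platform_depth = 2))
  expect_identical(echo_depth(e, h), c(500, 2))
  expect_identical(echo_depth(e, v), c(510, 102))
  # horizontal depth independent of range
  e2 <- one_echo(range = 19, platform_depth = 500)
  expect_identical(echo_depth(e2, h), 500)
  expect_error(echo_depth(dplyr::mutate(e, platform_depth = NA), h),
               "platform depth")
})

test_that("density is count over summed ping volume per 40-m bin", {
  beam <- beam_config(eba_db = -20.7, range_gate = c(3, 15))
  v1 <- sampled_volume(beam, 1)
  pings <- tibble::tibble(
    ping_time = as.POSIXct("2019-05-03 12:00", tz = "UTC") + 0:1,
    platform_depth = c(500, 510))
  echoes <- dplyr::bind_rows(lapply(1:19, function(i)
    one_echo(range = 10, platform_depth = 505)))
  prof <- density_profile(echoes, pings, beam)
  bin <- prof[prof$depth_top == 480, ]
  expect_equal(bin$volume_m3, 2 * v1, tolerance = 1e-12)
  expect_equal(bin$density_m3, 19 / (2 * v1), tolerance = 1e-12)
  expect_equal(bin$density_m3, 1.0, tolerance = 1e-3)
  # positive-volume empty bins are zero; ping-free bins are missing
  empty <- prof[prof$depth_top == 440, ]
  expect_true(is.na(empty$density_m3))
  expect_error(density_profile(echoes, pings[0, ], beam), "no pings")
})

test_that("merging ping sets is additive and volume-weights the density", {
  beam <- beam_config(range_gate = c(3, 15))
  mk <- function(n_ping, n_echo, depth) {
    pings <- tibble::tibble(
      ping_time = as.POSIXct("2019-05-03 12:00", tz = "UTC") +
        seq_len(n_ping),
      platform_depth = depth)
    echoes <- dplyr::bind_rows(lapply(seq_len(n_echo), function(i)
      one_echo(range = 10, platform_depth = depth)))
    list(pings = pings, echoes = echoes)
  }
  a <- mk(10, 7, 100); b <- mk(30, 9, 100)
  pa <- density_profile(a$echoes, a$pings, beam)
  pb <- density_profile(b$echoes, b$pings, beam)
  pm <- density_profile(dplyr::bind_rows(a$echoes, b$echoes),
                        dplyr::bind_rows(a$pings, b$pings), beam)
  i <- pm$depth_top == 80
  expect_equal(pm$n_echoes[i], pa$n_echoes[pa$depth_top == 80] +
                 pb$n_echoes[pb$depth_top == 80])
  expect_equal(pm$volume_m3[i], pa$volume_m3[pa$depth_top == 80] +
                 pb$volume_m3[pb$depth_top == 80], tolerance = 1e-12)
  wmean <- (pa$density_m3[pa$depth_top == 80] * pa$volume_m3[pa$depth_top == 80] +
              pb$density_m3[pb$depth_top == 80] * pb$volume_m3[pb$depth_top == 80]) /
    pm$volume_m3[i]
  expect_equal(pm$density_m3[i], wmean, tolerance = 1e-12)
})

test_that("constant-density scenes are recovered within sampling error", {
  cfg <- scene_config(seed = 13, sed_spec = list(
    ts_mean = -65, ts_sd = 4, contamination = 0, descent_rate = 0.5,
    max_depth = 1200, density = list(constant = 0.1)))
  sed <- simulate_sed(cfg)
  f <- sed_filter(sed$echoes)
  prof <- density_profile(f, sed$pings, cfg$beam)
  est <- sum(prof$n_echoes) / sum(prof$volume_m3)
  se <- sqrt(sum(prof$n_echoes)) / sum(prof$volume_m3)
  expect_lte(abs(est - 0.1), 3 * se)
})

test_that("TS histograms are per-bin and phases partition the pings", {
  beam <- beam_config()
  echoes <- dplyr::bind_rows(
    dplyr::mutate(one_echo(ts = -75, platform_depth = 100), phase = "down"),
    dplyr::mutate(one_echo(ts = -75, platform_depth = 100), phase = "down"),
    dplyr::mutate(one_echo(ts = -75, platform_depth = 100), phase = "up"))
  h <- ts_depth_profile(echoes, beam)
  expect_identical(sort(unique(h$phase)), c("down", "up"))
  expect_identical(sum(h$n), 3L)
  expect_identical(unique(h$ts_low), -76)   # single 2-dB class
  # bimodal TS resolves into two classes
  set.seed(62)
  bi <- dplyr::bind_rows(lapply(1:200, function(i)
    one_echo(ts = sample(c(-80, -65), 1) + stats::rnorm(1, 0, 0.3),
             platform_depth = 100)))
  hb <- ts_depth_profile(bi, beam, ts_bin_db = 2)
  modes <- hb$ts_low[order(-hb$n)][1:2]
  expect_lte(min(modes), -78)   # one mode near -80 dB
  expect_gte(max(modes), -68)   # one mode near -65 dB
})

test_that("paired-frequency comparison recovers ratio, slope and R2", {
  a <- tibble::tibble(depth_top = seq(0, 360, 40),
                      density_m3 = c(0.01, 0.05, 0.1, 0.15, 0.12, 0.08,
                                     0.05, 0.03, 0.02, 0.01))
  same <- paired_frequency_comparison(a, a)
  expect_equal(same$slope, 1, tolerance = 1e-12)
  expect_equal(same$ratio, 1, tolerance = 1e-12)
  expect_equal(same$r_squared, 1, tolerance = 1e-12)
  b <- dplyr::mutate(a, density_m3 = 1.03 * density_m3)
  scaled <- paired_frequency_comparison(a, b)
  expect_equal(scaled$ratio, 1.03, tolerance = 1e-12)
  expect_equal(scaled$r_squared, 1, tolerance = 1e-12)
  expect_error(paired_frequency_comparison(a[1:2, ], a[1:2, ]), "3 paired")
})

test_that("R2 of the paired comparison degrades monotonically with noise", {
  a <- tibble::tibble(depth_top = seq(0, 760, 40),
                      density_m3 = 0.05 + 0.1 * exp(-(seq(0, 760, 40) - 400)^2 /
                                                      (2 * 150^2)))
  mean_r2 <- vapply(c(0.002, 0.01, 0.05), function(s) {
    mean(vapply(1:20, function(i) {
      set.seed(1000 + i)
      b <- dplyr::mutate(a, density_m3 = pmax(
        density_m3 + stats::rnorm(dplyr::n(), 0, s * (1 + density_m3 * 5)), 0))
      paired_frequency_comparison(a, b)$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})
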