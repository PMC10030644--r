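test_that("noise-free casts are exact convex combinations of their triple", {
  casts <- simulate_ctd_transect(quiet_scene(n_stations = 3))
  reg <- endmember_registry()
  w <- sapply(reg$name, function(nm) casts[[paste0("true_x_", nm)]])
  expect_equal(rowSums(w), rep(1, nrow(casts)), tolerance = 1e-12)
  expect_true(all(w >= 0))
  # at most three active endmembers, and (T, S) is exactly their mixture
  expect_lte(max(rowSums(w > 0)), 3)
  expect_equal(casts$temperature, as.numeric(w %*% reg$temperature),
               tolerance = 1e-12)
  expect_equal(casts$salinity, as.numeric(w %*% reg$salinity),
               tolerance = 1e-12)
})

test_that("a degenerate single-type registry yields the endmember exactly", {
  # a scene whose grouping maps every layer to the same triple, with the
  # surface pair forced to pure STUW in the far south
  casts <- simulate_ctd_transect(quiet_scene(n_stations = 2))
  pure <- casts[casts$true_x_STUW == 1, ]
  if (nrow(pure) > 0) {
    expect_true(all(pure$temperature == endmember_registry()$temperature[1]))
  }
  # the weaker, always-applicable form: where any fraction equals 1 the
  # sample equals that endmember's reference values
  reg <- endmember_registry()
  for (nm in reg$name) {
    sel <- casts[[paste0("true_x_", nm)]] == 1
    if (any(sel)) {
      expect_equal(casts$temperature[sel],
                   rep(reg$temperature[reg$name == nm], sum(sel)))
    }
  }
  succeed()
})

test_that("the oxygen-minimum feature sits inside its configured box", {
  # 32 stations -> 1-degree spacing, so one sits at the box centre (19 N)
  cfg <- quiet_scene(n_stations = 32,
                     omz_spec = list(lat_range = c(18, 20),
                                     depth_range = c(200, 600),
                                     o2_min = 1.5))
  casts <- simulate_ctd_transect(cfg)
  inside <- casts$lat >= 18 & casts$lat <= 20 &
    casts$depth >= 200 & casts$depth <= 600
  expect_lte(min(casts$oxygen[inside]), 2)
  expect_gt(min(casts$oxygen[!inside]), 2)
})

test_that("fluorescence peaks shallow and north of the bloom latitude", {
  casts <- simulate_ctd_transect(quiet_scene(fluor_lat_min = 37))
  north <- casts[casts$lat > 40, ]
  south <- casts[casts$lat < 30, ]
  peak_depth <- north$depth[which.max(north$fluorescence)]
  expect_lt(peak_depth, 100)
  expect_gt(max(north$fluorescence), 2 * max(south$fluorescence))
})

test_that("ctd simulation is bit-identical under a fixed seed", {
  cfg <- scene_config(seed = 42, n_stations = 3)
  expect_identical(simulate_ctd_transect(cfg), simulate_ctd_transect(cfg))
})

test_that("simulated echogram stores analytic FWHM truth and layer counts", {
  specs <- list(
    list(name = "upper", lat_range = c(17, 48),
         depth_knots_lat = c(17, 48), depth_knots_m = c(400, 400),
         sigma = 50, peak_sv = -72),
    list(name = "lower", lat_range = c(17, 30),
         depth_knots_lat = c(17, 30), depth_knots_m = c(650, 650),
         sigma = 60, peak_sv = -75))
  cfg <- scene_config(dsl_specs = specs, echogram_hours = 2, time_step = 600)
  eg <- simulate_echogram(cfg)
  expect_equal(unique(eg$truth$fwhm[eg$truth$layer == "upper"]),
               2 * sqrt(2 * log(2)) * 50, tolerance = 1e-12)
  expect_equal(round(unique(eg$truth$fwhm[eg$truth$layer == "upper"]), 2),
               117.74)
  # southernmost columns carry two layers, columns north of 30 degN one
  counts <- table(eg$truth$time)
  lat_of <- eg$sv$lat[match(names(counts), as.character(eg$sv$time))]
  expect_true(all(counts[lat_of < 30] == 2))
  expect_true(all(counts[lat_of > 30] == 1))
})

test_that("column maxima sit at the layer peak over a silent floor", {
  cfg <- scene_config(noise_floor_sv = -999, echogram_hours = 1,
                      time_step = 600,
                      dsl_specs = list(list(
                        name = "one", lat_range = c(0, 90),
                        depth_knots_lat = 17, depth_knots_m = 400,
                        sigma = 50, peak_sv = -70)))
  eg <- simulate_echogram(cfg)
  col <- eg$sv[eg$sv$time == eg$sv$time[1], ]
  k <- which.max(col$sv_db)
  # 400 m lies on a bin edge: the peak bin centre is within half a bin
  expect_lte(abs((col$depth_top[k] + col$depth_bottom[k]) / 2 - 400), 2.5)
  expect_equal(max(col$sv_db), -70, tolerance = 1e-3)
})

test_that("echogram rejects invalid layer specs and empty spec lists", {
  expect_error(scene_config(dsl_specs = list(list(
    name = "bad", lat_range = c(0, 90), depth_knots_lat = 17,
    depth_knots_m = 400, sigma = -5, peak_sv = -70))), "sigma")
  cfg <- scene_config()
  cfg$dsl_specs <- list()
  expect_error(simulate_echogram(cfg), "non-empty")
})

test_that("a zero-density uncontaminated scene yields no echoes", {
  cfg <- scene_config(sed_spec = list(
    ts_mean = -65, ts_sd = 4, contamination = 0, descent_rate = 2,
    max_depth = 400, density = list(constant = 0)))
  sed <- simulate_sed(cfg)
  expect_identical(nrow(sed$echoes), 0L)
  expect_gt(nrow(sed$pings), 0L)
})

test_that("planted contamination matches its binomial law", {
  cfg <- scene_config(seed = 5, sed_spec = list(
    ts_mean = -65, ts_sd = 4, contamination = 0.3, descent_rate = 0.5,
    max_depth = 1200, density = list(constant = 0.1)))
  sed <- simulate_sed(cfg)
  n <- nrow(sed$echoes)
  expect_gt(n, 500)
  k <- sum(!is.na(sed$echoes$planted_violation))
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.3)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
  # each planted record violates exactly one criterion
  f <- sed_filter(sed$echoes)
  planted <- !is.na(sed$echoes$planted_violation)
  expect_true(all(!f$accepted[planted]))
  expect_identical(f$rejection[planted],
                   sed$echoes$planted_violation[planted])
})

test_that("sed stream rejects inverted range gates", {
  cfg <- scene_config()
  cfg$beam$range_gate <- c(15, 3)
  expect_error(simulate_sed(cfg), "inverted")
})

test_that("sed ranges follow the r-squared sampling law inside the gate", {
  cfg <- scene_config(sed_spec = list(
    ts_mean = -65, ts_sd = 4, contamination = 0, descent_rate = 0.5,
    max_depth = 1200, density = list(constant = 0.2)))
  sed <- simulate_sed(cfg)
  r <- sed$echoes$range
  g <- cfg$beam$range_gate
  expect_true(all(r >= g[1] & r <= g[2]))
  # analytic CDF of p(r) ~ r^2 on the gate
  cdf <- function(x) (x^3 - g[1]^3) / (g[2]^3 - g[1]^3)
  ks <- suppressWarnings(stats::ks.test(r, cdf))
  expect_gt(ks$p.value, 0.001)
})
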