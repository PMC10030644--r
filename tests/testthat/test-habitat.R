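# Synthetic model dataset with a dome-shaped temperature effect peaking
# at `peak` degC, an hour factor, and tweedie noise of power `p`.
make_habitat_data <- function(n, seed, peak = 11, p = 1.5, phi = 1.2) {
  set.seed(seed)
  d <- tibble::tibble(
    temperature = stats::runif(n, 5, 22),
    depth = stats::runif(n, 0, 200),
    oxygen = stats::runif(n, 2, 6),
    salinity = stats::runif(n, 34.8, 36.5),
    hour = factor(sample(7:18, n, TRUE), levels = 7:18))
  hour_eff <- seq(-0.5, 0.5, length.out = 12)[as.integer(d$hour)]
  mu <- exp(1 + 2 * exp(-(d$temperature - peak)^2 / (2 * 2^2)) -
              0.003 * d$depth + hour_eff)
  d$response <- mgcv::rTweedie(mu, p = p, phi = phi)
  d
}

test_that("dataset assembly interpolates covariates and splits strata", {
  casts <- simulate_ctd_transect(quiet_scene(n_stations = 3))
  section <- classify_profile(casts)
  cells <- tibble::tibble(
    frequency = 38,
    time_start = as.POSIXct("2019-05-03 13:00", tz = "UTC"),
    depth_top = c(97.5, 197.5, 500), depth_bottom = c(102.5, 202.5, 505),
    lat = casts$lat[1], lon = casts$lon[1],
    nasc = c(1, 2, 3))
  surf <- assemble_dataset(cells, section, "surface", "nasc")
  deep <- assemble_dataset(cells, section, "deep", "nasc")
  # 100 m row is surface; the 200 m boundary row belongs to deep
  expect_identical(nrow(surf), 1L)
  expect_identical(nrow(deep), 2L)
  expect_setequal(deep$depth, c(200, 502.5))
  # covariates at an exact station depth match the cast exactly
  expect_equal(surf$temperature,
               casts$temperature[casts$station == 1 & casts$depth == 100])
  expect_equal(surf$oxygen,
               casts$oxygen[casts$station == 1 & casts$depth == 100])
  expect_identical(as.character(surf$hour), "13")
})

test_that("strata are disjoint and cover the sampled depth range", {
  casts <- simulate_ctd_transect(quiet_scene(n_stations = 2))
  section <- classify_profile(casts)
  set.seed(71)
  cells <- tibble::tibble(
    frequency = 38,
    time_start = as.POSIXct("2019-05-03 13:00", tz = "UTC"),
    depth_top = stats::runif(200, 0, 1195),
    lat = casts$lat[1], lon = casts$lon[1],
    nasc = stats::rexp(200))
  cells$depth_bottom <- cells$depth_top + 5
  surf <- assemble_dataset(cells, section, "surface", "nasc")
  deep <- assemble_dataset(cells, section, "deep", "nasc")
  expect_identical(nrow(surf) + nrow(deep), nrow(cells))
  expect_lt(max(surf$depth), 200)
  expect_gte(min(deep$depth), 200)
})

test_that("NASC datasets respect the 7-18 hour restriction", {
  casts <- simulate_ctd_transect(quiet_scene(n_stations = 2))
  section <- classify_profile(casts)
  cells <- tibble::tibble(
    frequency = 38,
    time_start = as.POSIXct("2019-05-03 00:00", tz = "UTC") +
      3600 * c(3, 7, 12, 18, 21),
    depth_top = 100, depth_bottom = 105,
    lat = casts$lat[1], lon = casts$lon[1], nasc = 1)
  d <- assemble_dataset(cells, section, "surface", "nasc", hours = 7:18)
  expect_setequal(as.integer(as.character(d$hour)), c(7, 12, 18))
})

test_that("two-covariate VIF equals the closed form 1/(1-R2)", {
  set.seed(72)
  x1 <- stats::rnorm(500)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * stats::rnorm(500)
  d <- tibble::tibble(a = x1, b = x2, c = stats::rnorm(500))
  vs <- vif_screen(d, c("a", "b"), cutoff = 3)
  r2 <- summary(stats::lm(a ~ b, d))$r.squared
  expect_equal(vs$steps$vif[vs$steps$covariate == "a"][1], 1 / (1 - r2),
               tolerance = 1e-9)
  expect_identical(length(vs$dropped), 1L)
  # orthogonal covariates are both kept with VIF near 1
  vs2 <- vif_screen(d, c("a", "c"), cutoff = 3)
  expect_identical(vs2$dropped, character(0))
  expect_lt(max(vs2$steps$vif), 1.05)
  # exact duplicates give infinite VIF and one is dropped
  d$dup <- d$a
  vs3 <- vif_screen(d, c("a", "dup", "c"), cutoff = 3)
  expect_true(any(is.infinite(vs3$steps$vif)))
  expect_identical(length(vs3$dropped), 1L)
  expect_error(vif_screen(dplyr::mutate(d, k = 1), c("a", "k")),
               "constant")
})

test_that("the fitted temperature smooth peaks within 1 degC of truth", {
  d <- make_habitat_data(2000, seed = 73, peak = 11)
  fit <- fit_tweedie_gam(d, "nasc_surface")
  expect_true(fit$converged)
  curve <- smooth_curves(fit, n = 400)
  tcurve <- curve[curve$covariate == "temperature", ]
  expect_lte(abs(tcurve$value[which.max(tcurve$estimate)] - 11), 1)
  expect_gt(fit$deviance_explained, 20)
  expect_gt(fit$tweedie_power, 1)
  expect_lt(fit$tweedie_power, 2)
})

test_that("a null dataset shrinks the smooths and explains ~nothing", {
  set.seed(74)
  d <- make_habitat_data(800, seed = 74)
  d$response <- mgcv::rTweedie(rep(2, 800), p = 1.5, phi = 1.2)
  fit <- fit_tweedie_gam(d, "nasc_surface")
  edf <- tidy(fit)
  expect_lt(max(edf$edf[edf$type == "smooth"]), 2.5)
  expect_lt(fit$deviance_explained, 5)
})

test_that("concurvity screening flags duplicated smooth information", {
  d <- make_habitat_data(800, seed = 75)
  fit <- fit_tweedie_gam(d, "nasc_surface")
  cs <- concurvity_screen(fit)
  # independent covariates: indices near zero, nothing flagged
  expect_lt(max(cs$concurvity$worst), 0.3)
  expect_identical(cs$flagged, character(0))
  expect_identical(cs$model$smooths, fit$smooths)
  # near-duplicate covariate: flagged and refit without it
  d$oxygen <- d$temperature + stats::rnorm(800, 0, 1e-3)
  fit2 <- fit_tweedie_gam(d, "nasc_surface")
  cs2 <- concurvity_screen(fit2)
  expect_true(length(cs2$flagged) >= 1)
  expect_lt(length(cs2$model$smooths), length(fit2$smooths))
})

test_that("AIC selection prefers the true model over an overfit one", {
  wins <- vapply(1:5, function(s) {
    d <- make_habitat_data(800, seed = 600 + s)
    d$depth <- stats::runif(800, 0, 200)     # decouple irrelevant covariates
    d$oxygen <- stats::runif(800, 2, 6)
    mu_only_t <- exp(1 + 2 * exp(-(d$temperature - 11)^2 / 8))
    set.seed(600 + s)
    d$response <- mgcv::rTweedie(mu_only_t, p = 1.5, phi = 1.2)
    m_true <- fit_tweedie_gam(d, smooths = "temperature",
                              formula_id = "true")
    m_over <- fit_tweedie_gam(d, smooths = c("temperature", "depth", "oxygen"),
                              formula_id = "overfit")
    sel <- select_model(m_true, m_over)
    sel$best$formula_id == "true"
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("model selection tie-breaks to the first candidate", {
  d <- make_habitat_data(500, seed = 76)
  fit <- fit_tweedie_gam(d, "echo_surface")
  sel <- select_model(fit, fit)
  expect_identical(sel$best$formula_id, fit$formula_id)
  expect_identical(nrow(sel$comparison), 2L)
  expect_true(all(sel$comparison$delta_aic == 0))
  # single candidate returns itself; mismatched datasets error
  expect_identical(select_model(fit)$best$formula_id, "echo_surface")
  d2 <- make_habitat_data(400, seed = 77)
  fit2 <- fit_tweedie_gam(d2, "echo_surface")
  expect_error(select_model(fit, fit2), "different size")
})

test_that("tidiers and autoplot expose the fit in standard shapes", {
  d <- make_habitat_data(600, seed = 78)
  fit <- fit_tweedie_gam(d, "nasc_deep")
  td <- tidy(fit)
  expect_true(all(c("s(temperature)", "s(oxygen)") %in% td$term))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$tweedie_power > 1 && gl$tweedie_power < 2)
  expect_true(gl$deviance_explained >= 0 && gl$deviance_explained <= 100)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  sel <- select_model(fit)
  expect_s3_class(tidy(sel), "tbl_df")
  expect_s3_class(ggplot2::autoplot(sel), "ggplot")
})

test_that("fitted smooths track the true effect curve", {
  d <- make_habitat_data(3000, seed = 79)
  fit <- fit_tweedie_gam(d, "nasc_surface")
  tc <- smooth_curves(fit, n = 100)
  tc <- tc[tc$covariate == "temperature", ]
  true_eff <- 2 * exp(-(tc$value - 11)^2 / (2 * 2^2))
  expect_gte(stats::cor(tc$estimate, true_eff), 0.9)
})
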