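# Tweedie GAM habitat models linking acoustic abundance to hydrography.

#' Canonical habitat-model formulas
#'
#' The four model structures fitted by the pipeline, one per
#' response/stratum combination.  Abundance is modelled with time of day
#' as a factor and thin-plate regression-spline smooths of the remaining
#' covariates:
#' * `nasc_surface`:  `response ~ hour + s(temperature) + s(depth) + s(oxygen)`
#' * `nasc_deep`:     `response ~ hour + s(temperature) + s(oxygen)`
#' * `echo_surface`:  `response ~ hour + s(temperature) + s(depth)`
#' * `echo_deep`:     `response ~ hour + s(temperature) + s(salinity) + s(oxygen)`
#'
#' @param formula_id One of the four ids above.
#' @return A formula.
#' @export
gam_formula <- function(formula_id = c("nasc_surface", "nasc_deep",
                                       "echo_surface", "echo_deep")) {
  formula_id <- match.arg(formula_id)
  smooths <- switch(formula_id,
                    nasc_surface = c("temperature", "depth", "oxygen"),
                    nasc_deep = c("temperature", "oxygen"),
                    echo_surface = c("temperature", "depth"),
                    echo_deep = c("temperature", "salinity", "oxygen"))
  build_gam_formula(smooths)
}

# response ~ hour + s(x1) + ... ; `hour` optional.
build_gam_formula <- function(smooths, include_hour = TRUE) {
  rhs <- paste0("s(", smooths, ")", collapse = " + ")
  if (include_hour) rhs <- paste("hour", rhs, sep = " + ")
  stats::as.formula(paste("response ~", rhs), env = globalenv())
}

#' Assemble a model dataset for one depth stratum
#'
#' Joins acoustic responses (NASC cells or echo densities) to hydrographic
#' covariates: each response row receives temperature, salinity and oxygen
#' from the *nearest station's* profile, linearly interpolated to the
#' row's mid-depth, plus `depth` itself and the UTC `hour` factor taken
#' from the row's time (interval midpoint).  Rows are then restricted to
#' one stratum: `surface` = depths in \eqn{[0, 200)} m, `deep` =
#' \eqn{[200, 1200]} m (200 m belongs to the deep stratum).
#'
#' @param data Response tibble with columns `time`, `lat`, `lon`,
#'   `depth_top`, `depth_bottom` (or a `depth` column), the response
#'   column, and optionally `frequency`.  For NASC cells use `time_start`
#'   or `time`.
#' @param section Classified CTD section from [classify_profile()]
#'   (station positions and covariate profiles).
#' @param stratum `"surface"` or `"deep"`.
#' @param response Name of the response column (e.g. `"nasc"`,
#'   `"density_m3"`).
#' @param hours Optional integer vector of UTC hours to keep (the NASC
#'   models use 7-18); `NULL` keeps all.
#' @return A tibble: `response`, `depth`, `temperature`, `salinity`,
#'   `oxygen`, `hour` (factor), `lat`, `lon`, `stratum`, `frequency` (if
#'   present), `station`.  Rows with missing response are dropped.
#' @export
assemble_dataset <- function(data, section, stratum = c("surface", "deep"),
                             response = "nasc", hours = NULL) {
  stratum <- match.arg(stratum)
  d <- tibble::as_tibble(data)
  if (!"time" %in% names(d) && "time_start" %in% names(d)) {
    d$time <- d$time_start
  }
  if (!"depth" %in% names(d)) {
    d$depth <- (d$depth_top + d$depth_bottom) / 2
  }
  if (!response %in% names(d)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  d$response <- d[[response]]
  d <- dplyr::filter(d, !is.na(.data$response))
  stations <- dplyr::distinct(section, .data$station, .data$lat, .data$lon)
  if (nrow(stations) == 0) stop("no overlapping stations", call. = FALSE)
  dmat <- vapply(seq_len(nrow(stations)), function(i) {
    geosphere::distHaversine(cbind(d$lon, d$lat),
                             c(stations$lon[i], stations$lat[i]))
  }, numeric(nrow(d)))
  dmat <- matrix(dmat, nrow = nrow(d))
  d$station <- stations$station[max.col(-dmat, ties.method = "first")]
  prof <- split(section, section$station)
  interp <- function(var) {
    vapply(seq_len(nrow(d)), function(i) {
      p <- prof[[as.character(d$station[i])]]
      stats::approx(p$depth, p[[var]], xout = d$depth[i], rule = 2)$y
    }, numeric(1))
  }
  d$temperature <- interp("temperature")
  d$salinity <- interp("salinity")
  d$oxygen <- interp("oxygen")
  d$hour <- factor(as.POSIXlt(d$time, tz = "UTC")$hour)
  if (!is.null(hours)) {
    d <- dplyr::filter(d, as.integer(as.character(.data$hour)) %in% hours)
    d$hour <- droplevels(d$hour)
  }
  d <- if (stratum == "surface") {
    dplyr::filter(d, .data$depth >= 0, .data$depth < 200)
  } else {
    dplyr::filter(d, .data$depth >= 200, .data$depth <= 1200)
  }
  d$stratum <- stratum
  dplyr::select(d, "response", "depth", "temperature", "salinity", "oxygen",
                "hour", "lat", "lon", "stratum",
                dplyr::any_of(c("frequency", "station")))
}

#' Screen covariates by variance inflation factor
#'
#' Computes each covariate's VIF \eqn{= 1/(1 - R^2)} from the ordinary
#' regression of that covariate on all the others, then iteratively drops
#' the highest-VIF covariate until all remaining VIFs are at or below the
#' cutoff.
#'
#' @param data Data frame holding the covariates.
#' @param covariates Character vector of covariate column names (>= 2).
#' @param cutoff VIF cutoff (default 3).
#' @return A list: `retained`, `dropped` (in drop order) and `steps`, a
#'   tibble of per-iteration VIFs (`step`, `covariate`, `vif`,
#'   `dropped`).  Exact linear duplicates yield infinite VIF and are
#'   dropped first.
#' @export
vif_screen <- function(data, covariates, cutoff = 3) {
  stopifnot(length(covariates) >= 2,
            all(covariates %in% names(data)),
            nrow(data) >= length(covariates) + 1)
  X <- as.data.frame(data[covariates])
  if (any(vapply(X, function(x) stats::var(x) == 0, logical(1)))) {
    stop("degenerate (constant) covariate: ",
         paste(covariates[vapply(X, function(x) stats::var(x) == 0,
                                 logical(1))], collapse = ", "),
         call. = FALSE)
  }
  vif_of <- function(vars) {
    vapply(vars, function(v) {
      r2 <- suppressWarnings(summary(stats::lm(
        stats::reformulate(setdiff(vars, v), response = v),
        data = X))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  retained <- covariates
  dropped <- character()
  steps <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    vifs <- if (length(retained) >= 2) vif_of(retained) else
      stats::setNames(1, retained)
    worst <- names(vifs)[which.max(vifs)]
    drop_now <- max(vifs) > cutoff && length(retained) > 1
    steps[[step]] <- tibble::tibble(step = step, covariate = names(vifs),
                                    vif = unname(vifs),
                                    dropped = names(vifs) == worst & drop_now)
    if (!drop_now) break
    dropped <- c(dropped, worst)
    retained <- setdiff(retained, worst)
  }
  list(retained = retained, dropped = dropped,
       steps = dplyr::bind_rows(steps))
}

#' Fit a Tweedie GAM habitat model
#'
#' Fits the requested formula by [mgcv::gam()] with a Tweedie family whose
#' power parameter is estimated alongside the smoothing parameters by
#' restricted maximum likelihood (REML); smooths are thin-plate regression
#' splines (the mgcv default basis).
#'
#' @param data A model dataset from [assemble_dataset()] (or any tibble
#'   with a nonnegative `response` and the covariates the formula needs).
#' @param formula_id One of the ids of [gam_formula()]; ignored if
#'   `smooths` is given.
#' @param smooths Optional character vector of covariates to smooth
#'   (overrides `formula_id`), e.g. the retained set of a screening step.
#' @param k Optional basis dimension passed to every smooth.
#' @return An `echomix_gam` object: the mgcv fit plus `formula_id`,
#'   `aic`, `deviance_explained` (percent), `tweedie_power` and `n`.
#'   Non-convergence raises a warning with diagnostics.  Use
#'   [generics::tidy()] / [generics::glance()] / [smooth_curves()] to
#'   inspect it.
#' @export
fit_tweedie_gam <- function(data, formula_id = "nasc_surface",
                            smooths = NULL, k = NULL) {
  if (any(data$response < 0, na.rm = TRUE)) {
    stop("response must be nonnegative", call. = FALSE)
  }
  include_hour <- "hour" %in% names(data) && nlevels(factor(data$hour)) >= 2
  if (is.null(smooths)) {
    smooths <- switch(formula_id,
                      nasc_surface = c("temperature", "depth", "oxygen"),
                      nasc_deep = c("temperature", "oxygen"),
                      echo_surface = c("temperature", "depth"),
                      echo_deep = c("temperature", "salinity", "oxygen"),
                      stop("unknown formula id: ", formula_id, call. = FALSE))
  }
  rhs <- if (is.null(k)) paste0("s(", smooths, ")") else
    paste0("s(", smooths, ", k = ", k, ")")
  rhs <- paste(rhs, collapse = " + ")
  if (include_hour) rhs <- paste("hour", rhs, sep = " + ")
  form <- stats::as.formula(paste("response ~", rhs))
  environment(form) <- environment()
  fit <- mgcv::gam(form, family = mgcv::tw(), method = "REML",
                   data = data)
  if (!fit$converged) {
    warning("tweedie GAM did not converge (formula '", formula_id,
            "'): outer iterations exhausted; inspect gcv/REML gradient ",
            "and smoothing parameters ",
            paste(signif(fit$sp, 3), collapse = ", "), call. = FALSE)
  }
  power <- fit$family$getTheta(TRUE)
  structure(list(fit = fit, formula_id = formula_id, smooths = smooths,
                 include_hour = include_hour,
                 aic = stats::AIC(fit),
                 deviance_explained = 100 * summary(fit)$dev.expl,
                 tweedie_power = power, n = stats::nobs(fit),
                 converged = fit$converged),
            class = "echomix_gam")
}

#' @export
print.echomix_gam <- function(x, ...) {
  cat("Tweedie GAM habitat model (", x$formula_id, ")\n", sep = "")
  cat("  n =", x$n, " AIC =", round(x$aic, 1),
      " deviance explained =", round(x$deviance_explained, 1), "%",
      " tweedie power =", round(x$tweedie_power, 3), "\n")
  invisible(x)
}

#' Screen fitted smooths for concurvity
#'
#' Reports mgcv's worst-case concurvity index per smooth term and, when
#' any index exceeds the cutoff, refits the model without the flagged
#' smooths (the GAM analogue of dropping collinear covariates).
#'
#' @param model An `echomix_gam` from [fit_tweedie_gam()].
#' @param cutoff Concurvity cutoff (default 0.8).
#' @return A list: `concurvity` (tibble of `term`, `worst`, `flagged`),
#'   `flagged` (covariate names), and `model` (the refit without flagged
#'   smooths, or the input when nothing was flagged).
#' @export
concurvity_screen <- function(model, cutoff = 0.8) {
  stopifnot(inherits(model, "echomix_gam"))
  cc <- mgcv::concurvity(model$fit, full = TRUE)
  terms <- setdiff(colnames(cc), "para")
  worst <- cc["worst", terms]
  tab <- tibble::tibble(term = terms, worst = unname(worst),
                        flagged = unname(worst) > cutoff)
  flagged_vars <- gsub("^s\\(|\\)$", "", tab$term[tab$flagged])
  out_model <- model
  if (length(flagged_vars) > 0) {
    keep <- setdiff(model$smooths, flagged_vars)
    if (length(keep) == 0) {
      stop("all smooth terms flagged for concurvity; no model left",
           call. = FALSE)
    }
    out_model <- fit_tweedie_gam(model$fit$model,
                                 formula_id = model$formula_id,
                                 smooths = keep)
  }
  list(concurvity = tab, flagged = flagged_vars, model = out_model)
}

#' Select among candidate habitat models by AIC
#'
#' Returns the minimum-AIC candidate (ties break to the first listed)
#' together with a comparison table and residual diagnostics of the
#' winner.
#'
#' @param ... `echomix_gam` candidates fitted on the same dataset, or a
#'   single list of them.
#' @return A `model_selection` list: `best`, `comparison` (tibble with
#'   `formula_id`, `aic`, `delta_aic`, `deviance_explained`,
#'   `tweedie_power`), `residuals` (deviance-residual summary and QQ
#'   data of the best model).
#' @export
select_model <- function(...) {
  cands <- list(...)
  if (length(cands) == 1 && !inherits(cands[[1]], "echomix_gam")) {
    cands <- cands[[1]]
  }
  stopifnot(length(cands) >= 1,
            all(vapply(cands, inherits, logical(1), "echomix_gam")))
  ns <- vapply(cands, function(m) m$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("candidates were fitted on datasets of different size; AIC is ",
         "not comparable", call. = FALSE)
  }
  aics <- vapply(cands, function(m) m$aic, numeric(1))
  best <- cands[[which.min(aics)]]
  comparison <- tibble::tibble(
    formula_id = vapply(cands, function(m) m$formula_id, character(1)),
    aic = aics, delta_aic = aics - min(aics),
    deviance_explained = vapply(cands, function(m) m$deviance_explained,
                                numeric(1)),
    tweedie_power = vapply(cands, function(m) m$tweedie_power, numeric(1)))
  res <- stats::residuals(best$fit, type = "deviance")
  qq <- stats::qqnorm(res, plot.it = FALSE)
  structure(list(best = best, comparison = comparison,
                 residuals = list(
                   summary = stats::quantile(res, c(0, .25, .5, .75, 1)),
                   qq = tibble::tibble(theoretical = qq$x, sample = qq$y),
                   fitted = stats::fitted(best$fit))),
            class = "model_selection")
}

#' Tidy evaluation of fitted smooth curves
#'
#' Evaluates each smooth term of a fitted habitat model over a grid of its
#' covariate (other covariates held at their medians, hour at its first
#' level) and returns the centred smooth with pointwise 95% intervals —
#' the data behind partial-effect plots.
#'
#' @param model An `echomix_gam`.
#' @param n Grid points per smooth.
#' @return Tibble: `term`, `covariate`, `value`, `estimate`, `lower`,
#'   `upper` (link scale, centred smooth contribution).
#' @export
smooth_curves <- function(model, n = 200) {
  stopifnot(inherits(model, "echomix_gam"))
  fit <- model$fit
  mf <- fit$model
  out <- lapply(model$smooths, function(v) {
    grid <- mf[rep(1, n), , drop = FALSE]
    for (u in model$smooths) grid[[u]] <- stats::median(mf[[u]])
    if (model$include_hour) grid$hour <- factor(levels(mf$hour)[1],
                                                levels = levels(mf$hour))
    grid[[v]] <- seq(min(mf[[v]]), max(mf[[v]]), length.out = n)
    pr <- stats::predict(fit, newdata = grid, type = "terms", se.fit = TRUE)
    col <- grep(paste0("^s\\(", v, "\\)$"), colnames(pr$fit))
    tibble::tibble(term = paste0("s(", v, ")"), covariate = v,
                   value = grid[[v]],
                   estimate = pr$fit[, col],
                   lower = pr$fit[, col] - 1.96 * pr$se.fit[, col],
                   upper = pr$fit[, col] + 1.96 * pr$se.fit[, col])
  })
  dplyr::bind_rows(out)
}
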