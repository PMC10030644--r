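#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted habitat model
#'
#' One row per model term: smooth terms with effective degrees of freedom
#' and the test statistic/p-value of the significance test, parametric
#' (hour factor) terms with coefficient estimates.
#'
#' @param x An `echomix_gam` from [fit_tweedie_gam()].
#' @param ... Unused.
#' @return A tibble with `term`, `type`, `edf`, `ref_df`, `statistic`,
#'   `p_value`, `estimate`, `std_error`.
#' @export
tidy.echomix_gam <- function(x, ...) {
  s <- summary(x$fit)
  smooth <- if (nrow(s$s.table) > 0) {
    tibble::tibble(term = rownames(s$s.table), type = "smooth",
                   edf = s$s.table[, "edf"], ref_df = s$s.table[, "Ref.df"],
                   statistic = s$s.table[, "F"],
                   p_value = s$s.table[, "p-value"],
                   estimate = NA_real_, std_error = NA_real_)
  } else NULL
  para <- if (nrow(s$p.table) > 0) {
    tibble::tibble(term = rownames(s$p.table), type = "parametric",
                   edf = NA_real_, ref_df = NA_real_,
                   statistic = s$p.table[, "t value"],
                   p_value = s$p.table[, "Pr(>|t|)"],
                   estimate = s$p.table[, "Estimate"],
                   std_error = s$p.table[, "Std. Error"])
  } else NULL
  dplyr::bind_rows(para, smooth)
}

#' Glance at a fitted habitat model
#'
#' @param x An `echomix_gam`.
#' @param ... Unused.
#' @return One-row tibble: `formula_id`, `n`, `aic`,
#'   `deviance_explained` (percent), `tweedie_power`, `reml`,
#'   `converged`.
#' @export
glance.echomix_gam <- function(x, ...) {
  tibble::tibble(formula_id = x$formula_id, n = x$n, aic = x$aic,
                 deviance_explained = x$deviance_explained,
                 tweedie_power = x$tweedie_power,
                 reml = as.numeric(x$fit$gcv.ubre),
                 converged = x$converged)
}

#' @rdname tidy.echomix_gam
#' @export
tidy.model_selection <- function(x, ...) x$comparison
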