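# International one-atmosphere equation of state of seawater (EOS-80,
# UNESCO Technical Papers in Marine Science 44).  Valid for S in [0, 42]
# psu and T in [-2, 40] degC.  Check values: rho(0, 5) = 999.96675,
# rho(35, 5) = 1027.67547, rho(35, 25) = 1023.34306 kg m^-3.

eos80_rho_smow <- function(temperature) {
  999.842594 +
    6.793952e-2 * temperature -
    9.095290e-3 * temperature^2 +
    1.001685e-4 * temperature^3 -
    1.120083e-6 * temperature^4 +
    6.536332e-9 * temperature^5
}

eos80_rho <- function(salinity, temperature) {
  A <- 8.24493e-1 - 4.0899e-3 * temperature + 7.6438e-5 * temperature^2 -
    8.2467e-7 * temperature^3 + 5.3875e-9 * temperature^4
  B <- -5.72466e-3 + 1.0227e-4 * temperature - 1.6546e-6 * temperature^2
  C <- 4.8314e-4
  eos80_rho_smow(temperature) + A * salinity + B * salinity^1.5 + C * salinity^2
}

#' Potential density anomaly of seawater
#'
#' Computes the potential density anomaly \eqn{\sigma_\theta} (kg m\eqn{^{-3}})
#' referenced to surface pressure, used to separate the water column into the
#' density layers within which the three-endmember mixing system is solved.
#' Temperature is taken as potential temperature referenced to the surface, so
#' the surface-pressure density can be evaluated directly from the practical
#' salinity / potential temperature pair.
#'
#' @param temperature Potential temperature, degrees Celsius.
#' @param salinity Practical salinity, psu. Must be positive.
#' @param formulation Equation-of-state formulation. Only `"EOS-80"` (the
#'   UNESCO 1983 one-atmosphere International Equation of State) is provided;
#'   the argument exists so the formulation used is always recorded
#'   explicitly in outputs.
#' @return Numeric vector of \eqn{\sigma_\theta} values (kg m\eqn{^{-3}}),
#'   with the formulation name attached as attribute `"formulation"`.
#' @examples
#' potential_density(5, 35)   # 27.67547 kg m^-3
#' @export
potential_density <- function(temperature, salinity, formulation = "EOS-80") {
  formulation <- match.arg(formulation)
  if (any(!is.finite(temperature)) || any(!is.finite(salinity))) {
    stop("`temperature` and `salinity` must be finite", call. = FALSE)
  }
  if (any(salinity <= 0)) {
    stop("`salinity` must be positive", call. = FALSE)
  }
  sigma <- eos80_rho(salinity, temperature) - 1000
  attr(sigma, "formulation") <- formulation
  sigma
}
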