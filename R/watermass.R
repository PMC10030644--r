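#' Water-type endmember registry
#'
#' A water *type* is a reference point in temperature/salinity space; the
#' mixed water *mass* observed at a CTD sample is described as fractions of
#' three such endmembers.  The default registry holds the five North-East
#' Atlantic types used along a 17-48 degN transect: upper and lower North
#' Atlantic Central Water (u-NACW, l-NACW), Subtropical Underwater (STUW),
#' Antarctic Intermediate Water (AAIW) and Mediterranean Overflow Water (MOW).
#'
#' The shipped reference values are illustrative, chosen so the five types
#' have realistic and well-separated densities (\eqn{\sigma_\theta} 25.60,
#' 26.55, 27.15, 27.55 and 27.78 kg m\eqn{^{-3}}); they are configuration,
#' not survey-calibrated constants, and should be replaced with
#' regionally characterised values for real applications.
#'
#' @param name,temperature,salinity Equal-length vectors: endmember label,
#'   reference temperature (degC) and reference practical salinity (psu).
#' @return A tibble with columns `name`, `temperature`, `salinity`.
#' @examples
#' endmember_registry()
#' @export
endmember_registry <- function(name = c("STUW", "u-NACW", "l-NACW", "AAIW", "MOW"),
                               temperature = c(20.0, 14.0, 10.0, 6.0, 11.5),
                               salinity = c(36.097, 35.469, 35.253, 34.996, 36.408)) {
  if (anyDuplicated(name)) stop("endmember names must be unique", call. = FALSE)
  if (!all(is.finite(temperature)) || !all(is.finite(salinity))) {
    stop("endmember reference values must be finite", call. = FALSE)
  }
  tibble::tibble(name = as.character(name),
                 temperature = as.numeric(temperature),
                 salinity = as.numeric(salinity))
}

#' Density-layer grouping of endmember triples
#'
#' The water column is split by potential density anomaly into three layers,
#' each associated with an ordered triple of endmembers among which linear
#' mixing is solved: the lower layer (\eqn{\sigma_\theta >} 27.25 kg
#' m\eqn{^{-3}}) mixes AAIW, MOW and l-NACW; the middle layer (27 <
#' \eqn{\sigma_\theta \le} 27.25) mixes AAIW, l-NACW and u-NACW; the upper
#' layer (\eqn{\sigma_\theta \le} 27) mixes STUW, l-NACW and u-NACW.  Triple
#' order is meaningful: it is the tie-break order for dominant-type
#' classification.
#'
#' @param sigma_upper,sigma_lower Layer boundaries in kg m\eqn{^{-3}}
#'   (`sigma_upper < sigma_lower`). Boundary values are assigned to the
#'   less-dense side (a sample exactly at 27.25 is "middle").
#' @param triples Named list of three character triples, names `lower`,
#'   `middle`, `upper`.
#' @return A `layer_grouping` list.
#' @export
layer_grouping <- function(sigma_upper = 27.0, sigma_lower = 27.25,
                           triples = list(
                             lower  = c("AAIW", "MOW", "l-NACW"),
                             middle = c("AAIW", "l-NACW", "u-NACW"),
                             upper  = c("STUW", "l-NACW", "u-NACW"))) {
  stopifnot(sigma_upper < sigma_lower,
            identical(sort(names(triples)), c("lower", "middle", "upper")))
  if (any(vapply(triples, function(x) length(unique(x)) != 3L, logical(1)))) {
    stop("each layer triple must list exactly 3 distinct endmember names",
         call. = FALSE)
  }
  structure(list(sigma_upper = sigma_upper, sigma_lower = sigma_lower,
                 triples = triples),
            class = "layer_grouping")
}

#' Assign a density layer from sigma-theta
#'
#' @param sigma_theta Potential density anomaly, kg m\eqn{^{-3}} (vectorised).
#' @param grouping A [layer_grouping()].
#' @return Character vector: `"lower"`, `"middle"` or `"upper"`.
#' @examples
#' assign_layer(c(26.5, 27.1, 27.5))
#' @export
assign_layer <- function(sigma_theta, grouping = layer_grouping()) {
  dplyr::case_when(
    sigma_theta > grouping$sigma_lower ~ "lower",
    sigma_theta > grouping$sigma_upper ~ "middle",
    .default = "upper"
  )
}

#' Solve the three-endmember linear mixing system
#'
#' At each sample the observed temperature and salinity are modelled as a
#' linear mixture of three water types:
#' \deqn{x_1 T_1 + x_2 T_2 + x_3 T_3 = T}
#' \deqn{x_1 S_1 + x_2 S_2 + x_3 S_3 = S}
#' \deqn{x_1 + x_2 + x_3 = 1}
#' an exactly determined 3x3 system.  Fractions are *not* constrained to
#' \eqn{[0,1]}: an observation outside the endmember triangle yields negative
#' fractions, which are flagged via `in_triangle` rather than clipped.
#'
#' @param observations A data frame with columns `temperature` and `salinity`
#'   (one row per sample); other columns are carried through.
#' @param endmembers A three-row endmember table (subset of
#'   [endmember_registry()]) giving the triple, in tie-break order.
#' @return The input tibble plus columns `em1`, `em2`, `em3` (endmember
#'   names), `x1`, `x2`, `x3` (mixing fractions), `dominant` (name of the
#'   largest raw fraction, ties to the first-listed), `residual` (max
#'   absolute T/S reconstruction error) and `in_triangle` (all fractions in
#'   \eqn{[0,1]}).
#' @examples
#' reg <- endmember_registry()
#' solve_mixing(data.frame(temperature = 12, salinity = 35.36),
#'              reg[reg$name %in% c("AAIW", "l-NACW", "u-NACW"), ])
#' @export
solve_mixing <- function(observations, endmembers) {
  stopifnot(is.data.frame(observations),
            all(c("temperature", "salinity") %in% names(observations)))
  if (nrow(endmembers) != 3L) {
    stop("`endmembers` must have exactly 3 rows", call. = FALSE)
  }
  M <- rbind(endmembers$temperature, endmembers$salinity, rep(1, 3))
  if (abs(det(M)) < 1e-10) {
    stop("degenerate endmember geometry: the three endmembers are collinear ",
         "in (T, S) space, the mixing system is singular", call. = FALSE)
  }
  obs <- tibble::as_tibble(observations)
  if (nrow(obs) == 0L) {
    return(dplyr::mutate(obs, em1 = character(), em2 = character(),
                         em3 = character(), x1 = numeric(), x2 = numeric(),
                         x3 = numeric(), dominant = character(),
                         residual = numeric(), in_triangle = logical()))
  }
  rhs <- rbind(obs$temperature, obs$salinity, rep(1, nrow(obs)))
  x <- solve(M, rhs)                       # 3 x n fractions
  recon <- M %*% x
  residual <- apply(abs(recon[1:2, , drop = FALSE] -
                          rhs[1:2, , drop = FALSE]), 2, max)
  dominant <- endmembers$name[apply(x, 2, which.max)]
  dplyr::mutate(obs,
                em1 = endmembers$name[1], em2 = endmembers$name[2],
                em3 = endmembers$name[3],
                x1 = x[1, ], x2 = x[2, ], x3 = x[3, ],
                dominant = dominant,
                residual = residual,
                # tolerance absorbs roundoff at vertices/edges
                in_triangle = apply(x >= -1e-9 & x <= 1 + 1e-9, 2, all))
}

#' Dominant water type of mixing solutions
#'
#' The dominant type is the endmember with the highest raw mixing fraction
#' (negative fractions included as-is); ties break to the first-listed
#' endmember of the triple.
#'
#' @param solution A data frame as returned by [solve_mixing()] (columns
#'   `em1..em3`, `x1..x3`).
#' @return Character vector of water-type labels.
#' @export
classify_dominant <- function(solution) {
  stopifnot(all(c("em1", "em2", "em3", "x1", "x2", "x3") %in% names(solution)))
  if (any(!is.finite(as.matrix(solution[, c("x1", "x2", "x3")])))) {
    stop("mixing fractions must be finite", call. = FALSE)
  }
  idx <- max.col(as.matrix(solution[, c("x1", "x2", "x3")]),
                 ties.method = "first")
  ems <- as.matrix(solution[, c("em1", "em2", "em3")])
  ems[cbind(seq_len(nrow(solution)), idx)]
}

#' Classify a hydrographic section into water masses
#'
#' Runs the full per-sample chain: \eqn{\sigma_\theta} from T/S, density
#' layer from \eqn{\sigma_\theta}, the layer's endmember triple, the exact
#' three-endmember mixing solve, and the dominant-type label.  The result is
#' a long section table (station x depth) of fractions and labels.
#'
#' @param casts A data frame of CTD samples with columns `station`, `depth`,
#'   `temperature`, `salinity` (plus any of `time`, `lat`, `lon`, `oxygen`,
#'   `fluorescence`, carried through).  Casts should be depth-sorted within
#'   station.
#' @param registry Endmember table, see [endmember_registry()].
#' @param grouping Layer grouping, see [layer_grouping()].
#' @return A tibble: the input columns plus `sigma_theta`, `layer`, `em1..3`,
#'   `x1..3`, `dominant`, `residual`, `in_triangle`.  The equation-of-state
#'   formulation used is attached as attribute `"eos_formulation"`.
#' @export
classify_profile <- function(casts, registry = endmember_registry(),
                             grouping = layer_grouping()) {
  stopifnot(is.data.frame(casts),
            all(c("station", "depth", "temperature", "salinity") %in% names(casts)))
  missing_ems <- setdiff(unique(unlist(grouping$triples)), registry$name)
  if (length(missing_ems)) {
    stop("endmembers missing from registry: ",
         paste(missing_ems, collapse = ", "), call. = FALSE)
  }
  sigma <- potential_density(casts$temperature, casts$salinity)
  out <- tibble::as_tibble(casts)
  out$sigma_theta <- as.numeric(sigma)
  out$layer <- assign_layer(out$sigma_theta, grouping)
  out$.row <- seq_len(nrow(out))
  solved <- dplyr::bind_rows(lapply(names(grouping$triples), function(lab) {
    rows <- out[out$layer == lab, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    triple <- registry[match(grouping$triples[[lab]], registry$name), ]
    tryCatch(
      solve_mixing(rows, triple),
      error = function(e) {
        stop("layer '", lab, "' (stations ",
             paste(unique(rows$station), collapse = ","), "): ",
             conditionMessage(e), call. = FALSE)
      })
  }))
  solved <- dplyr::arrange(solved, .data$.row)
  solved$.row <- NULL
  attr(solved, "eos_formulation") <- attr(sigma, "formulation")
  solved
}
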