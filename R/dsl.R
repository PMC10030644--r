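# Deep-scattering-layer detection by full-width-at-half-maximum.

# Moving-average smoothing of a linear-domain profile; width in bins
# (odd; 1 = no smoothing).  NAs are preserved.
smooth_linear <- function(x, width) {
  if (width <= 1) return(x)
  if (width %% 2 == 0) width <- width + 1
  half <- (width - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

# Topographic prominence (dB) of a local maximum at index i of linear
# profile v: height above the higher of the two key saddles separating it
# from higher terrain (profile minimum if none).
peak_prominence_db <- function(v, i) {
  saddle <- function(side) {
    idx <- if (side == "left") rev(seq_len(i - 1)) else
      seq(i + 1, length.out = length(v) - i)
    lo <- v[i]
    for (j in idx) {
      if (is.na(v[j])) break
      if (v[j] > v[i]) return(lo)
      lo <- min(lo, v[j])
    }
    lo
  }
  key <- max(saddle("left"), saddle("right"))
  if (key <= 0) Inf else 10 * log10(v[i] / key)
}

# Depth of the half-maximum crossing walking outward from peak i.
# Returns list(depth, truncated).
half_crossing <- function(v, z, i, half, dir) {
  n <- length(v)
  j <- i
  repeat {
    k <- j + dir
    if (k < 1 || k > n || is.na(v[k])) {
      return(list(depth = z[j], truncated = TRUE))
    }
    if (v[k] < half) {
      f <- (v[j] - half) / (v[j] - v[k])
      return(list(depth = z[j] + f * (z[k] - z[j]), truncated = FALSE))
    }
    if (v[k] > v[j] && v[k] > half * 2) {
      # rising into a neighbouring, unresolved layer
      return(list(depth = z[j], truncated = TRUE))
    }
    j <- k
  }
}

#' Detect deep scattering layers and their FWHM widths
#'
#' Per grid column (time), finds local maxima of the (optionally smoothed)
#' linear-domain Sv profile inside the depth window, retains peaks with
#' topographic prominence of at least `prominence_db`, and locates the
#' half-maximum crossings on either side by linear interpolation between
#' depth bins.  The layer width is the separation of the two crossings
#' (full width at half maximum).  Peaks whose half-max region reaches the
#' window edge (or an unresolved neighbouring layer) are flagged
#' `truncated`.
#'
#' @param grid Long Sv tibble.
#' @param depth_window Two-element depth range, m, searched for layers.
#' @param smooth_bins Moving-average width (bins) applied to the linear
#'   profile before peak finding; 1 disables smoothing.
#' @param prominence_db Minimum peak prominence, dB (default 3).
#' @return Tibble of bands: `frequency`, `time`, `lat`, `peak_depth`,
#'   `peak_sv`, `upper_hm`, `lower_hm` (half-max depths), `width`,
#'   `truncated`.
#' @export
detect_dsl <- function(grid, depth_window = c(200, 1200), smooth_bins = 1,
                       prominence_db = 3) {
  if (depth_window[1] >= depth_window[2]) {
    stop("empty depth window", call. = FALSE)
  }
  g <- dplyr::filter(grid,
                     (.data$depth_top + .data$depth_bottom) / 2 >= depth_window[1],
                     (.data$depth_top + .data$depth_bottom) / 2 <= depth_window[2])
  cols <- split(g, g$time)
  bands <- lapply(cols, function(col) {
    col <- col[order(col$depth_top), ]
    z <- (col$depth_top + col$depth_bottom) / 2
    v_raw <- ifelse(is.na(col$sv_db), NA_real_, 10^(col$sv_db / 10))
    if (sum(!is.na(v_raw)) < 3) return(NULL)
    v <- smooth_linear(v_raw, smooth_bins)
    n <- length(v)
    is_peak <- c(FALSE, vapply(2:(n - 1), function(i) {
      !is.na(v[i]) && !is.na(v[i - 1]) && !is.na(v[i + 1]) &&
        v[i] > v[i - 1] && v[i] >= v[i + 1]
    }, logical(1)), FALSE)
    peaks <- which(is_peak)
    peaks <- peaks[vapply(peaks, function(i)
      peak_prominence_db(v, i) >= prominence_db, logical(1))]
    if (length(peaks) == 0) return(NULL)
    rows <- lapply(peaks, function(i) {
      up <- half_crossing(v, z, i, v[i] / 2, -1L)
      lo <- half_crossing(v, z, i, v[i] / 2, +1L)
      tibble::tibble(frequency = col$frequency[1], time = col$time[1],
                     lat = col$lat[1], peak_depth = z[i],
                     peak_sv = 10 * log10(v[i]),
                     upper_hm = up$depth, lower_hm = lo$depth,
                     width = lo$depth - up$depth,
                     truncated = up$truncated || lo$truncated)
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(bands)
  if (nrow(out) == 0) {
    out <- tibble::tibble(frequency = numeric(), time = as.POSIXct(character()),
                          lat = numeric(), peak_depth = numeric(),
                          peak_sv = numeric(), upper_hm = numeric(),
                          lower_hm = numeric(), width = numeric(),
                          truncated = logical())
  }
  out
}
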