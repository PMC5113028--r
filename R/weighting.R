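# ISO 5349-1 hand-arm frequency weighting (Wh) and band-domain RMS summaries.

# Tabulated Wh factors of ISO 5349-1 at one-third octave band centers,
# 6.3-1250 Hz (dimensionless). Keys are band indices n (center = 10^(n/10) Hz).
WH_TABLE <- c(
  `8` = 0.727, `9` = 0.873, `10` = 0.951, `11` = 0.958, `12` = 0.896,
  `13` = 0.782, `14` = 0.647, `15` = 0.519, `16` = 0.411, `17` = 0.324,
  `18` = 0.256, `19` = 0.202, `20` = 0.160, `21` = 0.127, `22` = 0.101,
  `23` = 0.0799, `24` = 0.0634, `25` = 0.0503, `26` = 0.0398, `27` = 0.0314,
  `28` = 0.0245, `29` = 0.0186, `30` = 0.0135, `31` = 0.00894
)

#' Hand-arm weighting filter magnitude
#'
#' Analog-filter realization of the Wh weighting: the product of the
#' band-limiting filters (two-pole Butterworth high-pass at `10^0.8` ~ 6.31 Hz
#' and low-pass at `10^3.1` ~ 1258.9 Hz) and the acceleration-to-velocity
#' transition filter (corner `f3 = f4 = 15.915` Hz, `Q = 0.64`), evaluated at
#' frequency `f`.
#'
#' @param f Frequencies in Hz (vectorized).
#' @return Dimensionless weighting magnitudes.
#' @export
wh_filter_magnitude <- function(f) {
  stopifnot(is.numeric(f), all(f > 0))
  f1 <- 10^0.8
  f2 <- 10^3.1
  f3 <- 15.915
  f4 <- 15.915
  q2 <- 0.64
  hp <- 1 / sqrt(1 + (f1 / f)^4)
  lp <- 1 / sqrt(1 + (f / f2)^4)
  tr <- f4^2 * sqrt(f^2 + f3^2) /
    (f3 * sqrt((f4^2 - f^2)^2 + (f4 * f / q2)^2))
  hp * lp * tr
}

#' Frequency-weighting vector on a band grid
#'
#' Evaluates the hand-arm frequency weighting Wh of ISO 5349-1 at the exact
#' midband frequencies of a one-third octave grid. Three modes are available:
#' `"iso_wh"` evaluates the analog-filter magnitude product (see
#' [wh_filter_magnitude()]); `"table"` uses the per-band factors tabulated in
#' the standard (defined for 6.3--1250 Hz only); `"unity"` returns 1.0 in every
#' band, giving unweighted ("unit weighting") summaries.
#'
#' @param grid A [band_grid()].
#' @param mode One of `"iso_wh"`, `"unity"`, `"table"`.
#' @return A `wh_weighting` object: tibble with columns `index`, `center_hz`,
#'   `wh`, plus attribute `mode`.
#' @examples
#' g <- band_grid(6.3, 1250)
#' w <- wh_weights(g, "table")
#' max(w$wh[w$center_hz > 500])   # <= 0.0314
#' @export
wh_weights <- function(grid, mode = c("iso_wh", "unity", "table")) {
  stopifnot(is_band_grid(grid))
  mode <- match.arg(mode)
  wh <- switch(mode,
    unity = rep(1.0, nrow(grid)),
    iso_wh = wh_filter_magnitude(grid$center_hz),
    table = {
      key <- as.character(grid$index)
      miss <- setdiff(key, names(WH_TABLE))
      if (length(miss) > 0) {
        stop(sprintf(
          "tabulated Wh factors cover 6.3-1250 Hz only; no entry for band index %s",
          paste(miss, collapse = ", ")
        ), call. = FALSE)
      }
      unname(WH_TABLE[key])
    }
  )
  out <- tibble::tibble(index = grid$index, center_hz = grid$center_hz, wh = wh)
  class(out) <- c("wh_weighting", class(out))
  attr(out, "mode") <- mode
  out
}

#' @export
print.wh_weighting <- function(x, ...) {
  cat(sprintf("<wh_weighting> mode = %s, %d bands\n", attr(x, "mode"), nrow(x)))
  NextMethod()
}

weighting_mode <- function(weights) attr(weights, "mode")

# Summary label used in results tables: unity weighting -> "unweighted".
summary_mode_label <- function(weights) {
  if (identical(weighting_mode(weights), "unity")) "unweighted" else "weighted"
}

check_weights_on_grid <- function(values, weights, grid = NULL) {
  if (!inherits(weights, "wh_weighting")) {
    stop("`weights` must be created with wh_weights()", call. = FALSE)
  }
  if (length(values) != nrow(weights)) {
    stop("band values and weighting vector are on different grids", call. = FALSE)
  }
  if (!is.null(grid) && !all(grid$index == weights$index)) {
    stop("weighting vector does not match the band grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Frequency-weighted RMS of per-band accelerations
#'
#' Band-domain realization of the ISO 5349-1 weighted overall value: each band
#' holds an RMS acceleration, so the weighted overall RMS is
#' `sqrt(sum((wh_i * a_i)^2))`.
#'
#' @param values Non-negative per-band RMS accelerations (m/s^2).
#' @param weights A `wh_weighting` on the same grid.
#' @return Scalar weighted RMS acceleration (m/s^2).
#' @export
weighted_band_rms <- function(values, weights) {
  stopifnot(is.numeric(values))
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("band values must be finite and >= 0", call. = FALSE)
  }
  check_weights_on_grid(values, weights)
  sqrt(sum((weights$wh * values)^2))
}

#' Vector total (root-sum-of-squares) of component accelerations
#'
#' Total vibration as defined in ISO 5349-1: the vector sum of the orthogonal
#' component magnitudes, `sqrt(sum(a_i^2))`.
#'
#' @param components Non-negative scalar accelerations (m/s^2).
#' @return Scalar total acceleration (m/s^2).
#' @examples
#' vector_total(c(10.35, 23.02))  # 25.24
#' @export
vector_total <- function(components) {
  stopifnot(is.numeric(components), length(components) >= 1)
  if (any(!is.finite(components)) || any(components < 0)) {
    stop("components must be finite and >= 0", call. = FALSE)
  }
  sqrt(sum(components^2))
}
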