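# One-third octave band grid (base-10 convention, IEC 61260 preferred labels).

# R10 preferred numbers: nominal midband labels within one decade.
R10_NOMINAL <- c(1, 1.25, 1.6, 2, 2.5, 3.15, 4, 5, 6.3, 8)

# Supported band-index range: n = 0 (1 Hz) .. 41 (12.5 kHz); exact center 10^(n/10).
BAND_INDEX_RANGE <- c(0L, 41L)

band_nominal_for_index <- function(n) {
  R10_NOMINAL[(n %% 10L) + 1L] * 10^(n %/% 10L)
}

band_exact_for_index <- function(n) 10^(n / 10)

#' Find the one-third octave band index for a nominal center frequency
#'
#' @param f Nominal midband frequency in Hz (e.g. 6.3, 100, 1250).
#' @return Integer band index `n` such that the exact midband is `10^(n/10)` Hz.
#' @keywords internal
band_index_for_nominal <- function(f) {
  stopifnot(is.numeric(f), length(f) == 1, is.finite(f), f > 0)
  n_all <- seq(BAND_INDEX_RANGE[1], BAND_INDEX_RANGE[2])
  noms <- band_nominal_for_index(n_all)
  hit <- which(abs(noms - f) / noms < 1e-6)
  if (length(hit) != 1) {
    below <- max(noms[noms < f], -Inf)
    above <- min(noms[noms > f], Inf)
    stop(sprintf(
      "%g Hz is not a standard one-third octave nominal center; nearest valid centers are %g and %g Hz",
      f, below, above
    ), call. = FALSE)
  }
  n_all[hit]
}

#' Construct a one-third octave band grid
#'
#' Builds the spectral axis used throughout the package: all one-third octave
#' bands whose nominal midband labels lie in `[fmin_nominal, fmax_nominal]`.
#' Exact (base-10) midband frequencies `10^(n/10)` are used for every
#' computation; the rounded nominal labels are kept for I/O only. Band edges
#' are a factor `10^(1/20)` below/above the exact center, so the edge ratio per
#' band is `10^(1/10)` and consecutive bands tile the frequency axis.
#'
#' The hand-arm vibration assessment range is 6.3--1250 Hz (24 bands); glove
#' transmissibility work uses the 6.3--500 Hz subset (20 bands).
#'
#' @param fmin_nominal,fmax_nominal Nominal midband frequencies (Hz) of the
#'   first and last band. Must be standard nominal centers (6.3, 8, 10, 12.5,
#'   16, 20, 25, 31.5, ...), `fmin_nominal <= fmax_nominal`.
#' @return A `band_grid` object: a tibble with columns `index`, `nominal_hz`,
#'   `center_hz`, `lower_hz`, `upper_hz`.
#' @examples
#' band_grid(6.3, 1250)   # 24 bands
#' band_grid(6.3, 500)    # 20 bands
#' @export
band_grid <- function(fmin_nominal = 6.3, fmax_nominal = 1250) {
  n1 <- band_index_for_nominal(fmin_nominal)
  n2 <- band_index_for_nominal(fmax_nominal)
  if (n1 > n2) stop("fmin_nominal must not exceed fmax_nominal", call. = FALSE)
  n <- seq(n1, n2)
  g <- tibble::tibble(
    index = as.integer(n),
    nominal_hz = band_nominal_for_index(n),
    center_hz = band_exact_for_index(n),
    lower_hz = 10^(n / 10 - 1 / 20),
    upper_hz = 10^(n / 10 + 1 / 20)
  )
  class(g) <- c("band_grid", class(g))
  g
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf(
    "<band_grid> %d one-third octave bands, %g-%g Hz (nominal)\n",
    nrow(x), min(x$nominal_hz), max(x$nominal_hz)
  ))
  NextMethod()
}

#' Test whether two band grids are identical
#'
#' @param a,b `band_grid` objects.
#' @keywords internal
same_grid <- function(a, b) {
  is_band_grid(a) && is_band_grid(b) &&
    nrow(a) == nrow(b) && all(a$index == b$index)
}

#' @rdname same_grid
#' @keywords internal
is_band_grid <- function(a) inherits(a, "band_grid")

#' Restrict a band grid to a nominal frequency range
#'
#' @param grid A `band_grid`.
#' @param fmin,fmax Nominal range to keep (inclusive).
#' @return A `band_grid` covering the intersection.
#' @export
restrict_grid <- function(grid, fmin = 6.3, fmax = 500) {
  n1 <- band_index_for_nominal(fmin)
  n2 <- band_index_for_nominal(fmax)
  out <- grid[grid$index >= n1 & grid$index <= n2, ]
  if (nrow(out) == 0) stop("requested band range lies outside the grid", call. = FALSE)
  class(out) <- class(grid)
  out
}
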