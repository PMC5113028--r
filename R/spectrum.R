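# Glove/finger transmissibility spectra: class, per-band algebra, averaging,
# low-frequency extension, and serialization.

GLOVE_LOCATIONS <- c("fingertip", "proximal", "full")
GLOVE_DIRECTIONS <- c("x", "y", "z", "xz", "xyz")

#' Bare-hand sentinel glove identifier
#'
#' Point-measurement pools contain bare-hand records under this glove id; the
#' glove transmissibility of the sentinel is all-unity by construction.
#' @export
BARE_HAND <- "bare"

#' Construct a transmissibility spectrum
#'
#' A per-band dimensionless transmissibility (output/input acceleration ratio)
#' tagged by glove, finger location and direction. Transmissibility spectra
#' are defined at most over 6.3--500 Hz, the range in which glove-finger
#' transfer functions can be measured or extended.
#'
#' @param glove Glove identifier ([BARE_HAND] is the bare-hand sentinel).
#' @param location `"fingertip"`, `"proximal"` or `"full"`.
#' @param direction `"x"`, `"y"`, `"z"` (single axes), `"xz"` (combined
#'   compression) or `"xyz"` (total).
#' @param grid A [band_grid()] spanning at most 6.3--500 Hz.
#' @param values Positive per-band transmissibilities.
#' @param provenance Free-text data origin tag (`"measured-synthesized"`,
#'   `"generated"`, `"fixture"`).
#' @return A `trans_spectrum` object.
#' @export
trans_spectrum <- function(glove, location, direction, grid, values,
                           provenance = "generated") {
  stopifnot(is.character(glove), length(glove) == 1)
  location <- match.arg(location, GLOVE_LOCATIONS)
  direction <- match.arg(direction, GLOVE_DIRECTIONS)
  stopifnot(is_band_grid(grid), is.numeric(values))
  if (length(values) != nrow(grid)) {
    stop("values and grid have different numbers of bands", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("transmissibility values must be finite and > 0", call. = FALSE)
  }
  if (max(grid$nominal_hz) > 500) {
    stop("transmissibility spectra are limited to bands at or below 500 Hz", call. = FALSE)
  }
  structure(
    list(
      glove = glove, location = location, direction = direction,
      grid = grid, values = as.numeric(values), provenance = provenance
    ),
    class = "trans_spectrum"
  )
}

#' @export
print.trans_spectrum <- function(x, ...) {
  cat(sprintf(
    "<trans_spectrum> glove = %s, location = %s, direction = %s, %d bands (%g-%g Hz), provenance = %s\n",
    x$glove, x$location, x$direction, nrow(x$grid),
    min(x$grid$nominal_hz), max(x$grid$nominal_hz), x$provenance
  ))
  invisible(x)
}

#' @export
as.data.frame.trans_spectrum <- function(x, ...) {
  data.frame(
    glove = x$glove, location = x$location, direction = x$direction,
    freq_hz = x$grid$nominal_hz, value = x$values
  )
}

check_same_tags <- function(a, b, what = c("glove", "location"), grid = TRUE) {
  for (field in what) {
    if (!identical(a[[field]], b[[field]])) {
      stop(sprintf("spectra disagree on %s (%s vs %s)", field, a[[field]], b[[field]]),
        call. = FALSE
      )
    }
  }
  if (grid && !same_grid(a$grid, b$grid)) {
    stop("spectra are defined on different band grids", call. = FALSE)
  }
  invisible(TRUE)
}

#' Finger transmissibility from a point measurement
#'
#' Per-band ratio of the acceleration measured on the finger surface to the
#' excitation acceleration measured on the handle, for one measurement point
#' in one direction (the first step of the transfer-function method).
#'
#' @param m A point measurement: a data frame with one row per band, columns
#'   `freq_hz` (nominal band centers), `response_ms2`, `excitation_ms2`, plus
#'   metadata columns `glove`, `area` (1 = fingertip, 2 = proximal) and
#'   `direction` (constant within `m`).
#' @return A `trans_spectrum` for the measurement's glove condition.
#' @export
finger_transmissibility <- function(m) {
  req <- c("glove", "area", "direction", "freq_hz", "response_ms2", "excitation_ms2")
  miss <- setdiff(req, names(m))
  if (length(miss) > 0) {
    stop("point measurement lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  stopifnot(length(unique(m$direction)) == 1, length(unique(m$glove)) == 1)
  m <- m[order(m$freq_hz), ]
  bad <- m$excitation_ms2 <= 0 | !is.finite(m$excitation_ms2)
  if (any(bad)) {
    stop(sprintf(
      "excitation is zero or invalid in band(s) %s Hz",
      paste(m$freq_hz[bad], collapse = ", ")
    ), call. = FALSE)
  }
  grid <- band_grid(min(m$freq_hz), max(m$freq_hz))
  if (nrow(grid) != nrow(m)) {
    stop("point measurement bands are not a contiguous one-third octave run", call. = FALSE)
  }
  loc <- if (unique(m$area) == 1) "fingertip" else "proximal"
  trans_spectrum(
    glove = as.character(unique(m$glove)), location = loc,
    direction = as.character(unique(m$direction)),
    grid = grid, values = m$response_ms2 / m$excitation_ms2,
    provenance = "measured-synthesized"
  )
}

#' Glove transmissibility from gloved and bare finger transmissibilities
#'
#' The transfer function attributable to the glove alone: the per-band ratio
#' of the gloved-finger transmissibility to the bare-finger transmissibility
#' measured under the same conditions.
#'
#' @param gloved,bare `trans_spectrum` objects sharing location, direction and
#'   grid; `bare` must come from the bare-hand condition.
#' @return A `trans_spectrum` tagged with the glove of `gloved`.
#' @export
glove_transmissibility <- function(gloved, bare) {
  stopifnot(inherits(gloved, "trans_spectrum"), inherits(bare, "trans_spectrum"))
  check_same_tags(gloved, bare, what = c("location", "direction"))
  trans_spectrum(
    glove = gloved$glove, location = gloved$location, direction = gloved$direction,
    grid = gloved$grid, values = gloved$values / bare$values,
    provenance = gloved$provenance
  )
}

#' Combined compression-direction transmissibility
#'
#' Combines the x and z (compression) direction spectra into a single
#' orientation-independent compression transmissibility,
#' `sqrt((Tx^2 + Tz^2) / 2)` per band. Finger orientation on a handle is hard
#' to pin down in the x--z plane, but this quadratic mean is invariant to it.
#'
#' @param tx,tz `trans_spectrum` objects with directions `"x"` and `"z"`.
#' @return A `trans_spectrum` with direction `"xz"`.
#' @export
combine_xz <- function(tx, tz) {
  stopifnot(inherits(tx, "trans_spectrum"), inherits(tz, "trans_spectrum"))
  if (tx$direction != "x" || tz$direction != "z") {
    stop("combine_xz() needs an x-direction and a z-direction spectrum", call. = FALSE)
  }
  check_same_tags(tx, tz, what = c("glove", "location"))
  trans_spectrum(
    glove = tx$glove, location = tx$location, direction = "xz",
    grid = tx$grid, values = sqrt((tx$values^2 + tz$values^2) / 2),
    provenance = tx$provenance
  )
}

#' Total (three-direction) transmissibility
#'
#' Quadratic mean of the three single-axis spectra,
#' `sqrt((Tx^2 + Ty^2 + Tz^2) / 3)` per band: the transmissibility of the
#' vector-sum (total) vibration when the input energy is split evenly.
#'
#' @param tx,ty,tz `trans_spectrum` objects with directions `"x"`, `"y"`, `"z"`.
#' @return A `trans_spectrum` with direction `"xyz"`.
#' @export
combine_xyz <- function(tx, ty, tz) {
  stopifnot(
    inherits(tx, "trans_spectrum"), inherits(ty, "trans_spectrum"),
    inherits(tz, "trans_spectrum")
  )
  if (tx$direction != "x" || ty$direction != "y" || tz$direction != "z") {
    stop("combine_xyz() needs x, y and z direction spectra in that order", call. = FALSE)
  }
  check_same_tags(tx, ty, what = c("glove", "location"))
  check_same_tags(tx, tz, what = c("glove", "location"))
  trans_spectrum(
    glove = tx$glove, location = tx$location, direction = "xyz",
    grid = tx$grid,
    values = sqrt((tx$values^2 + ty$values^2 + tz$values^2) / 3),
    provenance = tx$provenance
  )
}

#' Average transmissibility spectra
#'
#' Per-band arithmetic mean of transmissibility magnitudes, used at the three
#' aggregation levels of the synthesis chain: across measurement points within
#' an area (`level = "points"`), across the fingertip and proximal area
#' spectra to form the full-finger spectrum (`level = "areas"`), and across
#' subjects (`level = "subjects"`).
#'
#' @param spectra A non-empty list of `trans_spectrum` objects sharing glove,
#'   direction and grid. For `level = "areas"` the list must hold exactly one
#'   fingertip and one proximal spectrum; other levels also require a common
#'   location.
#' @param level `"points"`, `"areas"` or `"subjects"`.
#' @return The mean `trans_spectrum` (location `"full"` for `level = "areas"`).
#' @export
average_spectra <- function(spectra, level = c("points", "areas", "subjects")) {
  level <- match.arg(level)
  if (!is.list(spectra) || length(spectra) == 0) {
    stop("`spectra` must be a non-empty list of trans_spectrum objects", call. = FALSE)
  }
  ok <- vapply(spectra, inherits, logical(1), what = "trans_spectrum")
  if (!all(ok)) stop("all elements must be trans_spectrum objects", call. = FALSE)
  first <- spectra[[1]]
  for (s in spectra[-1]) {
    check_same_tags(first, s, what = c("glove", "direction"))
  }
  if (level == "areas") {
    locs <- sort(vapply(spectra, function(s) s$location, character(1)))
    if (!identical(locs, c("fingertip", "proximal"))) {
      stop("level = \"areas\" needs exactly one fingertip and one proximal spectrum",
        call. = FALSE
      )
    }
    location <- "full"
  } else {
    locs <- unique(vapply(spectra, function(s) s$location, character(1)))
    if (length(locs) != 1) {
      stop("spectra to be averaged must share one location", call. = FALSE)
    }
    location <- locs
  }
  vals <- rowMeans(vapply(spectra, function(s) s$values, numeric(nrow(first$grid))))
  trans_spectrum(
    glove = first$glove, location = location, direction = first$direction,
    grid = first$grid, values = vals, provenance = first$provenance
  )
}

#' Extend a transmissibility spectrum down to 6.3 Hz
#'
#' Glove-finger transfer functions can only be measured from 16 Hz up, but
#' assessment needs the bands down to 6.3 Hz, where glove transmissibility is
#' very close to unity. The missing 6.3--12.5 Hz bands are filled by linear
#' interpolation between 1.0 at the 6.3 Hz band and the measured value at the
#' 16 Hz band. By default the interpolation is linear in log-frequency
#' (equivalently, equal increments per band index), which is grid-independent
#' on the log-uniform one-third octave axis; `abscissa = "linear"` interpolates
#' in Hz instead.
#'
#' @param t A `trans_spectrum` whose lowest band is 16 Hz.
#' @param abscissa `"log"` (default) or `"linear"`.
#' @return The spectrum extended to start at the 6.3 Hz band; bands at or
#'   above 16 Hz are unchanged and the 6.3 Hz band is exactly 1.0.
#' @export
extend_low_frequency <- function(t, abscissa = c("log", "linear")) {
  stopifnot(inherits(t, "trans_spectrum"))
  abscissa <- match.arg(abscissa)
  n16 <- band_index_for_nominal(16)
  n63 <- band_index_for_nominal(6.3)
  if (min(t$grid$index) < n16) {
    stop("spectrum already contains bands below 16 Hz", call. = FALSE)
  }
  if (min(t$grid$index) > n16) {
    stop("spectrum must include the 16 Hz band to anchor the extension", call. = FALSE)
  }
  ext <- band_grid(6.3, 12.5)
  t16 <- t$values[t$grid$index == n16]
  frac <- switch(abscissa,
    log = (ext$index - n63) / (n16 - n63),
    linear = (ext$center_hz - band_exact_for_index(n63)) /
      (band_exact_for_index(n16) - band_exact_for_index(n63))
  )
  ext_vals <- 1.0 + frac * (t16 - 1.0)
  new_grid <- band_grid(6.3, max(t$grid$nominal_hz))
  trans_spectrum(
    glove = t$glove, location = t$location, direction = t$direction,
    grid = new_grid, values = c(ext_vals, t$values), provenance = t$provenance
  )
}

#' Filter point measurements to one hand-force condition
#'
#' Glove transmissibility varies with the applied hand force; the reference
#' condition used for assessment is the 30 N grip combined with 50 N push.
#'
#' @param pool Point-measurement tibble with `grip_n` and `push_n` columns.
#' @param grip_n,push_n Required force condition (N).
#' @return The matching subset of `pool`.
#' @export
select_force_condition <- function(pool, grip_n = 30, push_n = 50) {
  stopifnot(all(c("grip_n", "push_n") %in% names(pool)))
  out <- pool[pool$grip_n == grip_n & pool$push_n == push_n, ]
  if (nrow(out) == 0) {
    avail <- unique(paste0("grip ", pool$grip_n, " N / push ", pool$push_n, " N"))
    stop(sprintf(
      "no measurements under grip %g N / push %g N; available conditions: %s",
      grip_n, push_n, paste(avail, collapse = "; ")
    ), call. = FALSE)
  }
  out
}

#' Truncate a transmissibility spectrum to an upper band limit
#'
#' @param t A `trans_spectrum`.
#' @param fmax Nominal upper band (default 500 Hz).
#' @return The truncated spectrum.
#' @export
truncate_spectrum <- function(t, fmax = 500) {
  stopifnot(inherits(t, "trans_spectrum"))
  keep <- t$grid$nominal_hz <= fmax * (1 + 1e-9)
  if (!any(keep)) stop("truncation removes every band", call. = FALSE)
  grid <- band_grid(min(t$grid$nominal_hz), max(t$grid$nominal_hz[keep]))
  trans_spectrum(
    glove = t$glove, location = t$location, direction = t$direction,
    grid = grid, values = t$values[keep], provenance = t$provenance
  )
}
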