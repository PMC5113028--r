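# Seeded synthetic-data generator: single-resonance base-excitation glove
# transmissibility curves with multiplicative lognormal measurement noise, and
# peaked tri-axial tool spectra. Lets the whole assessment pipeline run, and
# parameter recovery be demonstrated, without laboratory data.

#' Base-excitation single-resonance transmissibility magnitude
#'
#' Magnitude response of a damped single-degree-of-freedom system driven
#' through its support:
#' `T(f) = sqrt((1 + (2 zeta r)^2) / ((1 - r^2)^2 + (2 zeta r)^2))` with
#' `r = f / fn`. Tends to 1 as `f -> 0`; peaks near `fn` for light damping.
#'
#' @param f Frequencies (Hz), vectorized.
#' @param fn Resonance (natural) frequency, Hz.
#' @param zeta Damping ratio, > 0.
#' @return Dimensionless transmissibility magnitudes.
#' @export
sdof_transmissibility <- function(f, fn, zeta) {
  stopifnot(fn > 0, zeta > 0)
  r <- f / fn
  sqrt((1 + (2 * zeta * r)^2) / ((1 - r^2)^2 + (2 * zeta * r)^2))
}

#' Glove preset for the synthetic generator
#'
#' Parameterizes one glove archetype: a resonance-frequency/damping/plateau
#' triple per direction (x, y, z) and finger location (fingertip, proximal),
#' an optional second resonance, multiplicative measurement-noise level, and
#' the experiment's panel size. The modeled curve is
#' `T(f) = sdof(f; fn, zeta) * [sdof(f; fn2, zeta2)] + plateau * r^2/(1+r^2)`
#' (`r = f/fn`): a base-excitation resonance with a residual high-frequency
#' transmission plateau, times an optional second mode.
#'
#' @param glove_id Identifier.
#' @param modes Tibble with columns `direction` (`x`/`y`/`z`), `location`
#'   (`fingertip`/`proximal`), `resonance_hz` (16--500), `damping` ((0, 2]),
#'   `plateau` (>= 0), and optionally `resonance2_hz`, `damping2` (NA = single
#'   mode). All six direction x location rows must be present.
#' @param noise_sigma Standard deviation of the lognormal measurement noise on
#'   the log scale (>= 0).
#' @param n_subjects Number of synthetic subjects.
#' @param n_points Named integer vector: measurement points per area, e.g.
#'   `c(fingertip = 4, proximal = 6)`.
#' @return A `glove_preset` object.
#' @export
glove_preset <- function(glove_id, modes, noise_sigma = 0.05, n_subjects = 6,
                         n_points = c(fingertip = 4, proximal = 6)) {
  stopifnot(is.character(glove_id), length(glove_id) == 1, is.data.frame(modes))
  req <- c("direction", "location", "resonance_hz", "damping", "plateau")
  miss <- setdiff(req, names(modes))
  if (length(miss) > 0) {
    stop("modes table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"resonance2_hz" %in% names(modes)) modes$resonance2_hz <- NA_real_
  if (!"damping2" %in% names(modes)) modes$damping2 <- NA_real_
  want <- tidyr::expand_grid(
    direction = c("x", "y", "z"), location = c("fingertip", "proximal")
  )
  got <- unique(paste(modes$direction, modes$location))
  if (!setequal(got, paste(want$direction, want$location)) ||
    nrow(modes) != nrow(want)) {
    stop("modes must hold exactly one row per direction x location", call. = FALSE)
  }
  fns <- c(modes$resonance_hz, modes$resonance2_hz[!is.na(modes$resonance2_hz)])
  if (any(fns < 16 | fns > 500)) {
    stop("resonance frequencies must lie within 16-500 Hz", call. = FALSE)
  }
  zs <- c(modes$damping, modes$damping2[!is.na(modes$damping2)])
  if (any(zs <= 0 | zs > 2)) stop("damping ratios must lie in (0, 2]", call. = FALSE)
  if (any(modes$plateau < 0)) stop("plateau levels must be >= 0", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  stopifnot(
    all(c("fingertip", "proximal") %in% names(n_points)),
    all(n_points >= 1), n_subjects >= 1
  )
  structure(
    list(
      glove_id = glove_id, modes = tibble::as_tibble(modes),
      noise_sigma = noise_sigma, n_subjects = as.integer(n_subjects),
      n_points = n_points
    ),
    class = "glove_preset"
  )
}

#' Uniform-mode glove preset
#'
#' Convenience constructor: the same resonance/damping/plateau in every
#' direction and location (useful for parameter-recovery studies).
#'
#' @inheritParams glove_preset
#' @param resonance_hz,damping,plateau Shared curve parameters.
#' @return A `glove_preset`.
#' @export
uniform_glove_preset <- function(glove_id, resonance_hz, damping, plateau = 0.2,
                                 noise_sigma = 0.05, n_subjects = 6,
                                 n_points = c(fingertip = 4, proximal = 6)) {
  modes <- tidyr::expand_grid(
    direction = c("x", "y", "z"), location = c("fingertip", "proximal")
  )
  modes$resonance_hz <- resonance_hz
  modes$damping <- damping
  modes$plateau <- plateau
  glove_preset(glove_id, modes,
    noise_sigma = noise_sigma,
    n_subjects = n_subjects, n_points = n_points
  )
}

#' Noiseless glove transmissibility curve of a preset
#'
#' @param preset A `glove_preset`.
#' @param direction `"x"`, `"y"` or `"z"`.
#' @param location `"fingertip"` or `"proximal"`.
#' @param f Frequencies (Hz).
#' @return Transmissibility magnitudes.
#' @export
preset_curve <- function(preset, direction, location, f) {
  stopifnot(inherits(preset, "glove_preset"))
  row <- preset$modes[preset$modes$direction == direction &
    preset$modes$location == location, ]
  stopifnot(nrow(row) == 1)
  t <- sdof_transmissibility(f, row$resonance_hz, row$damping)
  if (!is.na(row$resonance2_hz)) {
    t <- t * sdof_transmissibility(f, row$resonance2_hz, row$damping2)
  }
  r <- f / row$resonance_hz
  t + row$plateau * r^2 / (1 + r^2)
}

#' Generate synthetic point measurements for a glove preset
#'
#' Emulates the laser-vibrometer experiment: for every subject, area,
#' measurement point and direction, the excitation spectrum is flat (overall
#' RMS `excitation_rms` per direction, split evenly across bands) and the
#' response equals excitation times the preset's transmissibility curve times
#' multiplicative lognormal noise `exp(N(0, noise_sigma))`. Bare-hand sentinel
#' records (unit transmissibility times noise) are generated alongside so the
#' synthesis chain can form the gloved/bare ratio. Deterministic given `seed`.
#'
#' @param preset A [glove_preset()].
#' @param seed Integer seed.
#' @param grid Measurement [band_grid()] (default 16--500 Hz, the measurable
#'   range).
#' @param excitation_rms Overall per-direction excitation RMS (m/s^2),
#'   default 19.6.
#' @param grip_n,push_n Force-condition metadata attached to every record.
#' @param areas Areas to measure (default both).
#' @return Point-measurement tibble in the package's delimited format.
#' @export
generate_glove_measurements <- function(preset, seed, grid = band_grid(16, 500),
                                        excitation_rms = 19.6,
                                        grip_n = 30, push_n = 50,
                                        areas = c("fingertip", "proximal")) {
  stopifnot(inherits(preset, "glove_preset"), is_band_grid(grid))
  areas <- match.arg(areas, c("fingertip", "proximal"), several.ok = TRUE)
  area_code <- c(fingertip = 1L, proximal = 2L)
  excitation_band <- excitation_rms / sqrt(nrow(grid))

  design <- dplyr::bind_rows(lapply(areas, function(loc) {
    tidyr::expand_grid(
      subject = seq_len(preset$n_subjects),
      area = area_code[[loc]],
      point = seq_len(preset$n_points[[loc]]),
      direction = c("x", "y", "z"),
      glove = c(BARE_HAND, preset$glove_id)
    )
  }))
  # index/middle fingers alternate across points within an area
  design$finger <- ifelse(design$point %% 2 == 1, "index", "middle")
  rows <- tidyr::expand_grid(design, freq_hz = grid$nominal_hz)

  curves <- rows |>
    dplyr::distinct(.data$area, .data$direction, .data$freq_hz) |>
    dplyr::mutate(
      t_true = purrr::pmap_dbl(
        list(.data$area, .data$direction, .data$freq_hz),
        function(area, direction, freq_hz) {
          loc <- names(area_code)[match(area, area_code)]
          preset_curve(preset, direction, loc, band_exact_for_index(
            band_index_for_nominal(freq_hz)
          ))
        }
      )
    )
  rows <- dplyr::left_join(rows, curves, by = c("area", "direction", "freq_hz"))
  rows$t_true[rows$glove == BARE_HAND] <- 1.0

  noise <- withr::with_seed(
    seed,
    exp(stats::rnorm(nrow(rows), mean = 0, sd = preset$noise_sigma))
  )
  rows$excitation_ms2 <- excitation_band
  rows$response_ms2 <- excitation_band * rows$t_true * noise
  rows$grip_n <- grip_n
  rows$push_n <- push_n
  tibble::as_tibble(rows[, POINT_COLUMNS])
}

#' Tool preset for the synthetic generator
#'
#' A unimodal tool spectrum archetype: a triangular envelope in log-frequency
#' around a dominant band, an overall unweighted magnitude, a shear/compression
#' energy split, and optional harmonic side-peaks at half the main amplitude.
#'
#' @param tool_id Identifier.
#' @param dominant_hz Nominal one-third octave center of the dominant band.
#' @param bandwidth Envelope half-width in bands (>= 1; amplitude falls
#'   linearly in band index and reaches zero `bandwidth` bands away).
#' @param total_ms2 Target unweighted total acceleration over 6.3--500 Hz.
#' @param shear_fraction Fraction of band energy in the shear (y) axis, in
#'   `[0, 1]`; the rest is split evenly between x and z.
#' @param harmonics Optional numeric vector of nominal centers (Hz) receiving
#'   secondary envelopes at half the dominant amplitude.
#' @return A `tool_preset` object.
#' @export
tool_preset <- function(tool_id, dominant_hz, bandwidth = 2, total_ms2 = 10,
                        shear_fraction = 1 / 3, harmonics = NULL) {
  stopifnot(
    is.character(tool_id), length(tool_id) == 1,
    bandwidth >= 1, total_ms2 >= 0,
    shear_fraction >= 0, shear_fraction <= 1
  )
  band_index_for_nominal(dominant_hz) # validates the label
  if (!is.null(harmonics)) vapply(harmonics, band_index_for_nominal, integer(1))
  structure(
    list(
      tool_id = tool_id, dominant_hz = dominant_hz, bandwidth = bandwidth,
      total_ms2 = total_ms2, shear_fraction = shear_fraction,
      harmonics = harmonics
    ),
    class = "tool_preset"
  )
}

#' Generate a synthetic tool spectrum from a preset
#'
#' Builds the triangular log-frequency envelope of the preset on the grid,
#' splits band energy between the shear and compression axes per
#' `shear_fraction`, and scales the spectrum so its unweighted total
#' acceleration over 6.3--500 Hz equals `total_ms2` exactly. The construction
#' is deterministic; `seed` is accepted for interface symmetry with the glove
#' generator.
#'
#' @param preset A [tool_preset()].
#' @param seed Integer seed (unused; the generator is deterministic).
#' @param grid Target [band_grid()] (default 6.3--1250 Hz).
#' @return A `tool_spectrum`.
#' @export
generate_tool_spectrum <- function(preset, seed = 0L, grid = band_grid(6.3, 1250)) {
  stopifnot(inherits(preset, "tool_preset"), is_band_grid(grid))
  i0 <- band_index_for_nominal(preset$dominant_hz)
  if (!i0 %in% grid$index) {
    stop("dominant band lies outside the target grid", call. = FALSE)
  }
  envelope <- function(center_index, amp) {
    pmax(0, 1 - abs(grid$index - center_index) / preset$bandwidth) * amp
  }
  amp <- envelope(i0, 1)
  for (h in preset$harmonics) {
    amp <- amp + envelope(band_index_for_nominal(h), 0.5)
  }
  in_range <- grid$nominal_hz >= 6.3 & grid$nominal_hz <= 500
  energy <- sum(amp[in_range]^2)
  if (energy == 0) {
    stop("preset places no energy in the 6.3-500 Hz normalization range", call. = FALSE)
  }
  scale <- preset$total_ms2 / sqrt(energy)
  a_band <- amp * scale
  ay <- a_band * sqrt(preset$shear_fraction)
  axz <- a_band * sqrt((1 - preset$shear_fraction) / 2)
  tool_spectrum(
    preset$tool_id, grid,
    ax = axz, ay = ay, az = axz,
    source_citation = "synthetic preset"
  )
}

#' Named suite of glove and tool scenario presets
#'
#' Four glove archetypes loosely mimicking common VR glove mechanisms (gel,
#' air bladder, air bubble, dipped neoprene) and four tool archetypes
#' (low-frequency tamper-like, mid-frequency impact, high-frequency grinder,
#' and a shear-dominant 80 Hz scaler-like source). The glove curves are
#' qualitative archetypes chosen to respect near-unity transmissibility below
#' 25 Hz; their peak magnitudes are illustrative, not calibrated to any
#' measured glove.
#'
#' @param noise_sigma Measurement-noise level shared by the glove presets.
#' @return List with elements `gloves` and `tools`, each a named list of
#'   presets.
#' @export
scenario_suite <- function(noise_sigma = 0.05) {
  mode_row <- function(direction, location, fn, zeta, plateau,
                       fn2 = NA_real_, z2 = NA_real_) {
    tibble::tibble(
      direction = direction, location = location, resonance_hz = fn,
      damping = zeta, plateau = plateau, resonance2_hz = fn2, damping2 = z2
    )
  }
  gel <- glove_preset("gel_like", dplyr::bind_rows(
    mode_row("x", "fingertip", 100, 0.60, 0.9),
    mode_row("z", "fingertip", 100, 0.60, 0.9),
    mode_row("y", "fingertip", 100, 0.30, 0.5, fn2 = 400, z2 = 0.30),
    mode_row("x", "proximal", 125, 0.50, 0.8),
    mode_row("z", "proximal", 125, 0.50, 0.8),
    mode_row("y", "proximal", 100, 0.50, 1.0)
  ), noise_sigma = noise_sigma)
  bladder <- glove_preset("bladder_like", dplyr::bind_rows(
    mode_row("x", "fingertip", 400, 0.60, 0.7),
    mode_row("z", "fingertip", 400, 0.60, 0.7),
    mode_row("y", "fingertip", 400, 0.28, 0.4), # peak ~2x input in shear
    mode_row("x", "proximal", 125, 0.40, 0.6),
    mode_row("z", "proximal", 125, 0.40, 0.6),
    mode_row("y", "proximal", 125, 0.50, 0.6)
  ), noise_sigma = noise_sigma)
  bubble <- glove_preset("bubble_like", dplyr::bind_rows(
    mode_row("x", "fingertip", 125, 0.35, 0.6),
    mode_row("z", "fingertip", 125, 0.35, 0.6),
    mode_row("y", "fingertip", 125, 0.35, 0.5, fn2 = 400, z2 = 0.40),
    mode_row("x", "proximal", 160, 0.50, 0.9),
    mode_row("z", "proximal", 160, 0.50, 0.9),
    mode_row("y", "proximal", 160, 0.60, 0.8)
  ), noise_sigma = noise_sigma)
  neoprene <- glove_preset("neoprene_like", dplyr::bind_rows(
    mode_row("x", "fingertip", 100, 0.20, 0.3), # sharp resonance, attenuates above
    mode_row("z", "fingertip", 100, 0.20, 0.3),
    mode_row("y", "fingertip", 100, 0.35, 0.4),
    mode_row("x", "proximal", 160, 0.40, 0.9),
    mode_row("z", "proximal", 160, 0.40, 0.9),
    mode_row("y", "proximal", 125, 0.50, 0.8)
  ), noise_sigma = noise_sigma)
  tools <- list(
    lowfreq_tamper = tool_preset("lowfreq_tamper",
      dominant_hz = 12.5,
      bandwidth = 2, total_ms2 = 30, shear_fraction = 0.2
    ),
    impact_mid = tool_preset("impact_mid",
      dominant_hz = 31.5, bandwidth = 4,
      total_ms2 = 70, shear_fraction = 0.15, harmonics = 63
    ),
    highfreq_grinder = tool_preset("highfreq_grinder",
      dominant_hz = 315,
      bandwidth = 3, total_ms2 = 90, shear_fraction = 0.1
    ),
    shear80_scaler = tool_preset("shear80_scaler",
      dominant_hz = 80,
      bandwidth = 2, total_ms2 = 80, shear_fraction = 0.8
    )
  )
  list(
    gloves = list(
      gel_like = gel, bladder_like = bladder,
      bubble_like = bubble, neoprene_like = neoprene
    ),
    tools = tools
  )
}
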