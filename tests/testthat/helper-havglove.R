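# Shared fixtures: random spectra builders and independent brute-force oracles
# (explicit per-band loops, kept deliberately naive).

rand_spectrum <- function(direction, glove = "g1", location = "fingertip",
                          grid = band_grid(6.3, 500), lo = 0.5, hi = 1.8) {
  trans_spectrum(
    glove = glove, location = location, direction = direction,
    grid = grid, values = stats::runif(nrow(grid), lo, hi)
  )
}

const_spectrum <- function(value, direction, glove = "g1",
                           location = "fingertip", grid = band_grid(6.3, 500)) {
  trans_spectrum(glove, location, direction, grid, rep(value, nrow(grid)))
}

rand_tool <- function(grid = band_grid(6.3, 1250), id = "t1", lo = 0, hi = 5) {
  n <- nrow(grid)
  tool_spectrum(
    id, grid,
    ax = stats::runif(n, lo, hi), ay = stats::runif(n, lo, hi),
    az = stats::runif(n, lo, hi)
  )
}

# per-band loop oracles for the directional combinations
oracle_combine_xz <- function(tx, tz) {
  out <- numeric(length(tx))
  for (i in seq_along(tx)) out[i] <- sqrt((tx[i]^2 + tz[i]^2) / 2)
  out
}

oracle_combine_xyz <- function(tx, ty, tz) {
  out <- numeric(length(tx))
  for (i in seq_along(tx)) out[i] <- sqrt((tx[i]^2 + ty[i]^2 + tz[i]^2) / 3)
  out
}

# naive per-band summation oracle for the tool-specific values (weighted or
# unweighted through the wh vector)
oracle_tool_values <- function(ty, txz, ax, ay, az, wh) {
  num_y <- den_y <- num_xz <- den_xz <- 0
  for (i in seq_along(ty)) {
    num_y <- num_y + (ty[i] * ay[i] * wh[i])^2
    den_y <- den_y + (ay[i] * wh[i])^2
    num_xz <- num_xz + txz[i]^2 * (ax[i]^2 + az[i]^2) * wh[i]^2
    den_xz <- den_xz + (ax[i]^2 + az[i]^2) * wh[i]^2
  }
  list(
    T_y = sqrt(num_y / den_y),
    T_xz = sqrt(num_xz / den_xz),
    T_xzy = sqrt((num_y + num_xz) / (den_y + den_xz))
  )
}

# minimal noiseless measurement pool for one glove + bare sentinel
tiny_points <- function(glove = "gA", t_curve = function(f) rep(1.2, length(f)),
                        grid = band_grid(16, 500), subjects = 1,
                        grip_n = 30, push_n = 50) {
  base <- tidyr::expand_grid(
    subject = seq_len(subjects), finger = "index", area = c(1L, 2L),
    point = 1L, direction = c("x", "y", "z"), freq_hz = grid$nominal_hz
  )
  exc <- 19.6 / sqrt(nrow(grid))
  gloved <- dplyr::mutate(base,
    glove = glove, grip_n = grip_n, push_n = push_n,
    excitation_ms2 = exc, response_ms2 = exc * t_curve(.data$freq_hz)
  )
  bare <- dplyr::mutate(base,
    glove = BARE_HAND, grip_n = grip_n, push_n = push_n,
    excitation_ms2 = exc, response_ms2 = exc
  )
  dplyr::bind_rows(gloved, bare)
}
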