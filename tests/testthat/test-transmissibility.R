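make_point <- function(response, excitation, glove = "gA", area = 1L,
                       direction = "x", grid = band_grid(16, 500)) {
  tibble::tibble(
    glove = glove, area = area, direction = direction,
    freq_hz = grid$nominal_hz,
    response_ms2 = response, excitation_ms2 = excitation
  )
}

test_that("finger transmissibility is the per-band response/excitation ratio", {
  grid <- band_grid(16, 500)
  exc <- rep(2.5, nrow(grid))
  expect_equal(finger_transmissibility(make_point(exc, exc))$values,
    rep(1, nrow(grid)))
  expect_equal(finger_transmissibility(make_point(2 * exc, exc))$values,
    rep(2, nrow(grid)))
  withr::with_seed(21, {
    resp <- runif(nrow(grid), 0.5, 40)
    exc2 <- runif(nrow(grid), 1, 30)
    spec <- finger_transmissibility(make_point(resp, exc2))
    expect_equal(spec$values, resp / exc2)
    expect_identical(spec$location, "fingertip")
  })
  bad <- make_point(exc, exc)
  bad$excitation_ms2[3] <- 0
  expect_error(finger_transmissibility(bad), as.character(bad$freq_hz[3]))
})

test_that("glove transmissibility divides out the bare-finger response", {
  grid <- band_grid(16, 500)
  withr::with_seed(22, {
    exc <- runif(nrow(grid), 1, 30)
    g_resp <- runif(nrow(grid), 0.5, 40)
    b_resp <- runif(nrow(grid), 0.5, 40)
  })
  gloved <- finger_transmissibility(make_point(g_resp, exc))
  bare <- finger_transmissibility(make_point(b_resp, exc, glove = BARE_HAND))
  out <- glove_transmissibility(gloved, bare)
  # shared excitation cancels algebraically
  expect_equal(out$values, g_resp / b_resp, tolerance = 1e-12)
  expect_equal(glove_transmissibility(gloved, gloved)$values,
    rep(1, nrow(grid)))
  half <- gloved
  half$values <- gloved$values / 2
  expect_equal(glove_transmissibility(half, gloved)$values,
    rep(0.5, nrow(grid)))
  other_dir <- finger_transmissibility(make_point(b_resp, exc, direction = "y"))
  expect_error(glove_transmissibility(gloved, other_dir), "direction")
})

test_that("direction combinations match their closed forms and oracles", {
  grid <- band_grid(6.3, 500)
  t_any <- rand_spectrum("x", grid = grid)
  t_same_z <- trans_spectrum("g1", "fingertip", "z", grid, t_any$values)
  expect_equal(combine_xz(t_any, t_same_z)$values, t_any$values)

  ones <- const_spectrum(1, "x", grid = grid)
  tiny <- const_spectrum(1e-9, "z", grid = grid)
  expect_equal(combine_xz(ones, tiny)$values, rep(sqrt(1 / 2), nrow(grid)),
    tolerance = 1e-9
  )

  withr::with_seed(23, {
    tx <- rand_spectrum("x", grid = grid)
    ty <- rand_spectrum("y", grid = grid)
    tz <- rand_spectrum("z", grid = grid)
  })
  expect_equal(combine_xz(tx, tz)$values, oracle_combine_xz(tx$values, tz$values),
    tolerance = 1e-14
  )
  expect_equal(combine_xyz(tx, ty, tz)$values,
    oracle_combine_xyz(tx$values, ty$values, tz$values),
    tolerance = 1e-14
  )
  expect_identical(combine_xz(tx, tz)$direction, "xz")
  expect_identical(combine_xyz(tx, ty, tz)$direction, "xyz")

  # unity preservation and per-band bounds
  u <- lapply(c("x", "y", "z"), const_spectrum, value = 1, grid = grid)
  expect_equal(combine_xyz(u[[1]], u[[2]], u[[3]])$values, rep(1, nrow(grid)))
  comb <- combine_xyz(tx, ty, tz)$values
  expect_true(all(comb >= pmin(tx$values, ty$values, tz$values) - 1e-12))
  expect_true(all(comb <= pmax(tx$values, ty$values, tz$values) + 1e-12))

  expect_error(combine_xz(tx, ty), "z-direction")
  off_glove <- rand_spectrum("z", glove = "g2", grid = grid)
  expect_error(combine_xz(tx, off_glove), "glove")
})

test_that("total combination reduces to the compression combination when
           Ty^2 equals the mean of Tx^2 and Tz^2", {
  grid <- band_grid(6.3, 500)
  withr::with_seed(24, {
    tx <- rand_spectrum("x", grid = grid)
    tz <- rand_spectrum("z", grid = grid)
  })
  ty <- trans_spectrum("g1", "fingertip", "y", grid,
    sqrt((tx$values^2 + tz$values^2) / 2))
  expect_equal(combine_xyz(tx, ty, tz)$values, combine_xz(tx, tz)$values,
    tolerance = 1e-12
  )
})

test_that("spectrum averaging is the per-band arithmetic mean with tag rules", {
  grid <- band_grid(6.3, 500)
  s1 <- rand_spectrum("y", grid = grid)
  expect_equal(average_spectra(list(s1), level = "points")$values, s1$values)

  lo <- const_spectrum(0.8, "y", grid = grid)
  hi <- const_spectrum(1.2, "y", grid = grid)
  expect_equal(average_spectra(list(lo, hi), level = "points")$values,
    rep(1, nrow(grid)))

  withr::with_seed(25, specs <- replicate(7, rand_spectrum("y", grid = grid),
    simplify = FALSE
  ))
  acc <- Reduce(`+`, lapply(specs, function(s) s$values)) / length(specs)
  expect_equal(average_spectra(specs, level = "subjects")$values, acc,
    tolerance = 1e-14
  )

  tip <- rand_spectrum("y", location = "fingertip", grid = grid)
  prox <- rand_spectrum("y", location = "proximal", grid = grid)
  full <- average_spectra(list(tip, prox), level = "areas")
  expect_identical(full$location, "full")
  expect_equal(full$values, (tip$values + prox$values) / 2)
  expect_error(average_spectra(list(tip, tip), level = "areas"), "proximal")
  expect_error(average_spectra(list(), level = "points"), "non-empty")
  expect_error(
    average_spectra(list(tip, rand_spectrum("x", location = "fingertip", grid = grid)),
      level = "points"
    ),
    "direction"
  )
})

test_that("low-frequency extension interpolates to unity at 6.3 Hz", {
  grid <- band_grid(16, 500)
  flat <- const_spectrum(1, "y", grid = grid)
  ext <- extend_low_frequency(flat)
  expect_equal(min(ext$grid$nominal_hz), 6.3)
  expect_equal(ext$values[ext$grid$nominal_hz <= 16], rep(1, 5))

  ramp <- const_spectrum(1.4, "y", grid = grid)
  ext2 <- extend_low_frequency(ramp, abscissa = "log")
  expect_equal(ext2$values[1:5], c(1.0, 1.1, 1.2, 1.3, 1.4), tolerance = 1e-12)
  # bands at or above 16 Hz are untouched
  expect_equal(ext2$values[-(1:4)], ramp$values)

  lin <- extend_low_frequency(ramp, abscissa = "linear")
  expect_equal(lin$values[1], 1.0)
  expect_equal(lin$values[5], 1.4)
  expect_false(isTRUE(all.equal(lin$values[2:4], ext2$values[2:4])))
  # interpolants stay between 1.0 and the 16 Hz anchor
  expect_true(all(lin$values[1:5] >= 1 & lin$values[1:5] <= 1.4))

  down <- const_spectrum(0.7, "y", grid = grid)
  ext3 <- extend_low_frequency(down)
  expect_true(all(ext3$values[1:5] >= 0.7 & ext3$values[1:5] <= 1))

  expect_error(extend_low_frequency(ext2), "below 16 Hz")
  no16 <- const_spectrum(1, "y", grid = band_grid(20, 500))
  expect_error(extend_low_frequency(no16), "16 Hz band")
})

test_that("force-condition selection filters and reports availability", {
  pool <- tidyr::expand_grid(
    grip_n = c(15, 30, 50, 30), push_n = c(0, 0, 0, 50), id = 1:3
  )
  sel <- select_force_condition(pool, 30, 50)
  expect_true(all(sel$grip_n == 30 & sel$push_n == 50))
  expect_equal(nrow(sel), sum(pool$grip_n == 30 & pool$push_n == 50))
  expect_error(select_force_condition(pool, 40, 40), "available conditions")
})

test_that("the synthesis pipeline preserves unity and ignores row order", {
  pts <- tiny_points(t_curve = function(f) rep(1, length(f)), subjects = 3)
  sp <- synthesize_glove_spectra(pts)
  expect_true(all(abs(sp$value - 1) < 1e-12))

  withr::with_seed(26, {
    curve <- function(f) 1 + 0.5 * exp(-((log(f) - log(100))^2))
    pts2 <- tiny_points(t_curve = curve, subjects = 2)
    shuffled <- pts2[sample.int(nrow(pts2)), ]
  })
  a <- synthesize_glove_spectra(pts2) |> dplyr::arrange(glove, location, direction, freq_hz)
  b <- synthesize_glove_spectra(shuffled) |> dplyr::arrange(glove, location, direction, freq_hz)
  expect_equal(a, b, tolerance = 1e-12)
})
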