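grid500 <- band_grid(6.3, 500)

pair_and_tool <- function(seed, lo = 0.5, hi = 1.8) {
  withr::with_seed(seed, list(
    t_y = rand_spectrum("y", grid = grid500, lo = lo, hi = hi),
    t_xz = rand_spectrum("xz", grid = grid500, lo = lo, hi = hi),
    tool = rand_tool(band_grid(6.3, 1250), lo = 0)
  ))
}

test_that("tool-specific values collapse to the band value for single-band tools", {
  withr::with_seed(41, {
    t_y <- rand_spectrum("y", grid = grid500)
    t_xz <- rand_spectrum("xz", grid = grid500)
  })
  grid <- band_grid(6.3, 1250)
  pick <- which(grid$nominal_hz == 100)
  a <- numeric(nrow(grid))
  ax <- a; ax[pick] <- 2
  ay <- a; ay[pick] <- 3
  az <- a; az[pick] <- 1.5
  tool <- tool_spectrum("oneband", grid, ax, ay, az)
  for (mode in c("unity", "iso_wh")) {
    w <- wh_weights(grid500, mode)
    res <- tool_specific_values(t_y, t_xz, tool, w)
    i <- which(grid500$nominal_hz == 100)
    expect_equal(res$T_y, t_y$values[i], tolerance = 1e-12)
    expect_equal(res$T_xz, t_xz$values[i], tolerance = 1e-12)
    expected_total <- sqrt(
      (t_xz$values[i]^2 * (2^2 + 1.5^2) + t_y$values[i]^2 * 3^2) /
        (2^2 + 3^2 + 1.5^2)
    )
    expect_equal(res$T_xzy, expected_total, tolerance = 1e-12)
  }
})

test_that("unit transmissibility spectra give unit values for any tool", {
  ones_y <- const_spectrum(1, "y", grid = grid500)
  ones_xz <- const_spectrum(1, "xz", grid = grid500)
  withr::with_seed(42, tool <- rand_tool(band_grid(6.3, 1250)))
  for (mode in c("unity", "table")) {
    res <- tool_specific_values(ones_y, ones_xz, tool, wh_weights(grid500, mode))
    expect_equal(c(res$T_y, res$T_xz, res$T_xzy), c(1, 1, 1), tolerance = 1e-12)
    expect_equal(res$R, 0, tolerance = 1e-10)
  }
})

test_that("production implementation equals the naive per-band oracle", {
  for (seed in 43:52) {
    inp <- pair_and_tool(seed)
    for (mode in c("unity", "iso_wh")) {
      w <- wh_weights(grid500, mode)
      res <- tool_specific_values(inp$t_y, inp$t_xz, inp$tool, w)
      keep <- inp$tool$grid$index %in% grid500$index
      orc <- oracle_tool_values(
        inp$t_y$values, inp$t_xz$values,
        inp$tool$ax[keep], inp$tool$ay[keep], inp$tool$az[keep], w$wh
      )
      expect_equal(res$T_y, orc$T_y, tolerance = 1e-12)
      expect_equal(res$T_xz, orc$T_xz, tolerance = 1e-12)
      expect_equal(res$T_xzy, orc$T_xzy, tolerance = 1e-12)
      # values lie between the directional values
      expect_gte(res$T_xzy, min(res$T_y, res$T_xz) - 1e-12)
      expect_lte(res$T_xzy, max(res$T_y, res$T_xz) + 1e-12)
    }
  }
})

test_that("values are invariant to uniform scaling of the tool spectrum", {
  inp <- pair_and_tool(53)
  scaled <- tool_spectrum(
    "scaled", inp$tool$grid, 7 * inp$tool$ax, 7 * inp$tool$ay, 7 * inp$tool$az
  )
  w <- wh_weights(grid500, "iso_wh")
  a <- tool_specific_values(inp$t_y, inp$t_xz, inp$tool, w)
  b <- tool_specific_values(inp$t_y, inp$t_xz, scaled, w)
  expect_equal(a$T_xzy, b$T_xzy, tolerance = 1e-12)
})

test_that("the total value satisfies the energy identity against tool summaries", {
  inp <- pair_and_tool(54)
  for (mode in c("unity", "iso_wh")) {
    w <- wh_weights(grid500, mode)
    res <- tool_specific_values(inp$t_y, inp$t_xz, inp$tool, w)
    s <- tool_summary(inp$tool, w)
    lhs <- res$T_xzy^2 * s$At^2
    rhs <- res$T_xz^2 * s$Axz^2 + res$T_y^2 * s$Ay^2
    expect_equal(lhs, rhs, tolerance = 1e-9)
    expect_equal(
      res$T_xzy,
      total_transmissibility_value(res$T_y, res$T_xz, s$Ay, s$Axz),
      tolerance = 1e-12
    )
  }
})

test_that("a zero-energy direction yields NA there but a defined total", {
  withr::with_seed(55, {
    t_y <- rand_spectrum("y", grid = grid500)
    t_xz <- rand_spectrum("xz", grid = grid500)
  })
  grid <- band_grid(6.3, 1250)
  a <- runif(nrow(grid), 0.1, 2)
  pure_xz <- tool_spectrum("noshear", grid, a, numeric(nrow(grid)), a)
  res <- tool_specific_values(t_y, t_xz, pure_xz, wh_weights(grid500, "unity"))
  expect_true(is.na(res$T_y))
  expect_false(is.na(res$T_xzy))
  expect_equal(res$T_xzy, res$T_xz, tolerance = 1e-12)

  hf <- numeric(nrow(grid))
  hf[grid$nominal_hz > 500] <- 1
  out_of_range <- tool_spectrum("hf", grid, hf, hf, hf)
  expect_error(
    tool_specific_values(t_y, t_xz, out_of_range, wh_weights(grid500, "unity")),
    "no energy"
  )
})

test_that("percent reduction follows the sign convention", {
  expect_equal(percent_reduction(1.0), 0)
  expect_equal(percent_reduction(0.9), 10)
  expect_equal(percent_reduction(1.25), -25)
  inp <- pair_and_tool(56)
  res <- tool_specific_values(inp$t_y, inp$t_xz, inp$tool, wh_weights(grid500, "unity"))
  expect_equal(percent_reduction(res), res$R)
  expect_equal(res$R, (1 - res$T_xzy) * 100, tolerance = 1e-12)
})

test_that("full-finger aggregation strategies agree on identical inputs and
           bracket heterogeneous ones", {
  withr::with_seed(57, {
    tip <- list(
      t_y = rand_spectrum("y", location = "fingertip", grid = grid500),
      t_xz = rand_spectrum("xz", location = "fingertip", grid = grid500)
    )
    tool <- rand_tool(band_grid(6.3, 1250), lo = 0.05)
  })
  w <- wh_weights(grid500, "unity")
  same_prox <- list(
    t_y = trans_spectrum("g1", "proximal", "y", grid500, tip$t_y$values),
    t_xz = trans_spectrum("g1", "proximal", "xz", grid500, tip$t_xz$values)
  )
  a <- full_finger_result(tip, same_prox, tool, w, strategy = "spectrum_mean")
  b <- full_finger_result(tip, same_prox, tool, w, strategy = "value_mean")
  expect_equal(a$T_xzy, b$T_xzy, tolerance = 1e-12)
  expect_identical(a$location, "full")

  # constant 0.8 / 1.2 spectra act as a constant 1.0 spectrum
  c_tip <- list(
    t_y = const_spectrum(0.8, "y", location = "fingertip", grid = grid500),
    t_xz = const_spectrum(0.8, "xz", location = "fingertip", grid = grid500)
  )
  c_prox <- list(
    t_y = const_spectrum(1.2, "y", location = "proximal", grid = grid500),
    t_xz = const_spectrum(1.2, "xz", location = "proximal", grid = grid500)
  )
  res <- full_finger_result(c_tip, c_prox, tool, w)
  expect_equal(res$T_xzy, 1, tolerance = 1e-12)

  withr::with_seed(58, prox <- list(
    t_y = rand_spectrum("y", location = "proximal", grid = grid500),
    t_xz = rand_spectrum("xz", location = "proximal", grid = grid500)
  ))
  sm <- full_finger_result(tip, prox, tool, w, strategy = "spectrum_mean")
  vm <- full_finger_result(tip, prox, tool, w, strategy = "value_mean")
  expect_false(isTRUE(all.equal(sm$T_xzy, vm$T_xzy, tolerance = 1e-12)))
  r_tip <- tool_specific_values(tip$t_y, tip$t_xz, tool, w)
  r_prox <- tool_specific_values(prox$t_y, prox$t_xz, tool, w)
  expect_gte(vm$T_xzy, min(r_tip$T_xzy, r_prox$T_xzy) - 1e-12)
  expect_lte(vm$T_xzy, max(r_tip$T_xzy, r_prox$T_xzy) + 1e-12)
  band_lo <- min(pmin(tip$t_y$values, prox$t_y$values),
    pmin(tip$t_xz$values, prox$t_xz$values))
  band_hi <- max(pmax(tip$t_y$values, prox$t_y$values),
    pmax(tip$t_xz$values, prox$t_xz$values))
  expect_gte(sm$T_xzy, band_lo - 1e-12)
  expect_lte(sm$T_xzy, band_hi + 1e-12)

  expect_error(full_finger_result(tip, list(t_y = 1), tool, w), "t_xz")
})

test_that("match classification rounds to integer percent and honors the
           comparison flag", {
  results <- tibble::tibble(
    glove = "g", tool = paste0("t", 1:5),
    R_percent = c(9.4, 9.5, 10.0, -10.4, -10.6)
  )
  incl <- classify_matches(results, threshold = 10, comparison = "inclusive")
  expect_equal(incl$counts$reduced, 2) # 9.5 rounds half away to 10
  expect_equal(incl$counts$amplified, 2) # -10.4 rounds to -10 (inclusive)
  expect_equal(incl$counts$neutral, 1)
  expect_equal(sum(incl$counts[, c("reduced", "amplified", "neutral")]), 5)

  strict <- classify_matches(results, threshold = 10, comparison = "strict")
  expect_equal(strict$counts$reduced, 0)
  expect_equal(strict$counts$amplified, 1)

  zero <- classify_matches(dplyr::mutate(results, R_percent = 0))
  expect_equal(zero$counts$neutral, 5)
})

test_that("rendered reports use table precision and summarize per glove", {
  withr::with_seed(59, results <- tibble::tibble(
    glove = rep(c("gA", "gB"), each = 3),
    tool = rep(paste0("t", 1:3), 2),
    mode = "unweighted",
    T_y = runif(6, 0.8, 1.2), T_xz = runif(6, 0.8, 1.2),
    T_xzy = runif(6, 0.8, 1.2),
    R_percent = runif(6, -20, 20)
  ))
  rep_obj <- classify_matches(results)
  out <- render_report(rep_obj, format = "tibble")
  expect_named(out, c("per_tool", "per_glove"))
  expect_equal(nrow(out$per_tool), 6)
  expect_equal(out$per_tool$T_y, round(out$per_tool$T_y, 2)) # 2-decimal precision
  expect_equal(out$per_tool$R_percent, round(out$per_tool$R_percent, 0))
  expect_equal(nrow(out$per_glove), 2)
  txt <- render_report(rep_obj, format = "text")
  expect_true(any(grepl("match report", txt)))
  empty <- rep_obj
  empty$r_table <- empty$r_table[0, ]
  expect_error(render_report(empty), "no results")
})
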