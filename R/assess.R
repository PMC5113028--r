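# Batch assessment: every glove x tool x mode x location in one results table.

#' Assess gloves against tools
#'
#' Computes tool-specific transmissibility values and percent reductions for
#' every combination of glove (from a spectra table), tool, weighting mode and
#' finger location.
#'
#' @param spectra Spectra table (columns `glove, location, direction, freq_hz,
#'   value`) as produced by [synthesize_glove_spectra()]; must contain `y` and
#'   `xz` direction rows for the requested locations. If `"full"` is requested
#'   but absent from the table, it is derived by per-band averaging of the
#'   fingertip and proximal spectra.
#' @param tools Named list of `tool_spectrum` objects (zero-filled grids are
#'   handled internally).
#' @param modes Subset of `c("unweighted", "weighted")`.
#' @param locations Subset of `c("fingertip", "proximal", "full")`.
#' @param wh_mode Weighting realization for the weighted mode: `"iso_wh"`
#'   (filter magnitudes) or `"table"` (tabulated factors).
#' @param fmin,fmax Assessment band range (nominal Hz), default 6.3--500.
#' @return Tibble with columns `tool, glove, location, mode, T_y, T_xz,
#'   T_xzy, R_percent`.
#' @export
assess_gloves <- function(spectra, tools,
                          modes = c("unweighted", "weighted"),
                          locations = c("fingertip", "proximal", "full"),
                          wh_mode = c("iso_wh", "table"),
                          fmin = 6.3, fmax = 500) {
  modes <- match.arg(modes, several.ok = TRUE)
  locations <- match.arg(locations, several.ok = TRUE)
  wh_mode <- match.arg(wh_mode)
  if (inherits(tools, "tool_spectrum")) tools <- list(tools)
  if (is.null(names(tools)) || any(names(tools) == "")) {
    names(tools) <- vapply(tools, function(t) t$tool_id, character(1))
  }
  gloves <- setdiff(unique(spectra$glove), BARE_HAND)
  if (length(gloves) == 0) stop("spectra table holds no gloves", call. = FALSE)

  grid <- band_grid(fmin, fmax)
  full_grid <- band_grid(fmin, 1250)
  weights_of <- function(mode) {
    wh_weights(grid, if (mode == "unweighted") "unity" else wh_mode)
  }

  get_pair <- function(gl, loc) {
    have_full <- any(spectra$glove == gl & spectra$location == "full")
    if (loc != "full" || have_full) {
      list(
        t_y = truncate_spectrum(spectrum_from_table(spectra, gl, loc, "y"), fmax),
        t_xz = truncate_spectrum(spectrum_from_table(spectra, gl, loc, "xz"), fmax)
      )
    } else {
      tip <- get_pair(gl, "fingertip")
      prox <- get_pair(gl, "proximal")
      list(
        t_y = average_spectra(list(tip$t_y, prox$t_y), level = "areas"),
        t_xz = average_spectra(list(tip$t_xz, prox$t_xz), level = "areas")
      )
    }
  }

  rows <- list()
  for (gl in gloves) {
    for (loc in locations) {
      pair <- get_pair(gl, loc)
      if (!same_grid(pair$t_y$grid, grid)) {
        stop(sprintf(
          "spectra for glove %s do not cover the %g-%g Hz assessment grid", gl, fmin, fmax
        ), call. = FALSE)
      }
      for (tl in names(tools)) {
        filled <- zero_fill(tools[[tl]], full_grid)
        for (mode in modes) {
          res <- tool_specific_values(pair$t_y, pair$t_xz, filled, weights_of(mode))
          rows <- c(rows, list(tibble::as_tibble(as.data.frame(res))))
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
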