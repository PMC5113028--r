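# End-to-end synthesis of representative glove-finger transmissibility spectra
# from point-level measurements, and the delimited-text formats for both.

POINT_COLUMNS <- c(
  "subject", "glove", "finger", "area", "point", "grip_n", "push_n",
  "direction", "freq_hz", "response_ms2", "excitation_ms2"
)

check_point_columns <- function(points) {
  miss <- setdiff(POINT_COLUMNS, names(points))
  if (length(miss) > 0) {
    stop("point-measurement table lacks columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Synthesize representative glove transmissibility spectra
#'
#' Runs the full synthesis chain on a pool of point-level measurements:
#'
#' 1. select the reference hand-force condition (30 N grip + 50 N push);
#' 2. per point and direction, form the finger transmissibility
#'    (response/excitation) and divide the gloved by the bare-hand spectrum to
#'    obtain the glove transmissibility;
#' 3. average the measurement points within each area (fingertip: Area 1,
#'    proximal: Area 2), pooling index/middle fingers and hands;
#' 4. per subject, combine directions into the compression (`xz`) and total
#'    (`xyz`) transmissibilities and average the two areas into the
#'    full-finger spectrum;
#' 5. average across subjects;
#' 6. truncate to 500 Hz and extend down to 6.3 Hz with the near-unity
#'    low-frequency interpolation (see [extend_low_frequency()]).
#'
#' @param points Point-measurement tibble with the columns listed in the
#'   package's delimited format: `subject, glove, finger, area, point, grip_n,
#'   push_n, direction, freq_hz, response_ms2, excitation_ms2`.
#' @param grip_n,push_n Hand-force condition to select.
#' @param bare_id Glove id of the bare-hand sentinel records.
#' @param extend If `TRUE` (default) apply the 6.3--16 Hz extension.
#' @param abscissa Interpolation abscissa for the extension, `"log"` or
#'   `"linear"`.
#' @return A tibble with columns `glove, location, direction, freq_hz, value`,
#'   one row per band, holding the subject-mean spectra for every glove,
#'   location (`fingertip`, `proximal`, `full`) and direction
#'   (`x`, `y`, `z`, `xz`, `xyz`).
#' @export
synthesize_glove_spectra <- function(points, grip_n = 30, push_n = 50,
                                     bare_id = BARE_HAND, extend = TRUE,
                                     abscissa = c("log", "linear")) {
  check_point_columns(points)
  abscissa <- match.arg(abscissa)
  cond <- select_force_condition(points, grip_n = grip_n, push_n = push_n)
  if (any(cond$excitation_ms2 <= 0)) {
    stop("excitation must be strictly positive in every band", call. = FALSE)
  }
  cond$t_finger <- cond$response_ms2 / cond$excitation_ms2

  bare <- dplyr::filter(cond, .data$glove == bare_id)
  gloved <- dplyr::filter(cond, .data$glove != bare_id)
  if (nrow(bare) == 0) stop("no bare-hand records in the pool", call. = FALSE)
  if (nrow(gloved) == 0) stop("no gloved records in the pool", call. = FALSE)

  keys <- c("subject", "finger", "area", "point", "direction", "freq_hz")
  joined <- dplyr::inner_join(
    gloved,
    dplyr::select(bare, dplyr::all_of(keys), t_bare = "t_finger"),
    by = keys
  )
  if (nrow(joined) < nrow(gloved)) {
    stop("some gloved measurements have no matching bare-hand record", call. = FALSE)
  }
  joined$t_glove <- joined$t_finger / joined$t_bare

  # Point -> area means (pooling fingers/points), per subject and direction.
  area_means <- joined |>
    dplyr::summarise(
      value = mean(.data$t_glove),
      .by = c("glove", "subject", "area", "direction", "freq_hz")
    ) |>
    dplyr::mutate(
      location = ifelse(.data$area == 1, "fingertip", "proximal")
    )

  finalize <- function(spec) {
    spec <- truncate_spectrum(spec, 500)
    if (extend) spec <- extend_low_frequency(spec, abscissa = abscissa)
    spec
  }

  out <- list()
  for (gl in unique(area_means$glove)) {
    gdat <- area_means[area_means$glove == gl, ]
    subj_spectra <- list() # [[location]][[direction]] -> list over subjects
    for (sb in unique(gdat$subject)) {
      sdat <- gdat[gdat$subject == sb, ]
      per_loc <- list()
      for (loc in intersect(c("fingertip", "proximal"), unique(sdat$location))) {
        ld <- sdat[sdat$location == loc, ]
        dir_spec <- list()
        for (dir in c("x", "y", "z")) {
          dd <- ld[ld$direction == dir, ]
          dd <- dd[order(dd$freq_hz), ]
          if (nrow(dd) == 0) {
            stop(sprintf("direction %s missing for glove %s", dir, gl), call. = FALSE)
          }
          grid <- band_grid(min(dd$freq_hz), max(dd$freq_hz))
          dir_spec[[dir]] <- trans_spectrum(
            glove = gl, location = loc, direction = dir, grid = grid,
            values = dd$value, provenance = "measured-synthesized"
          )
        }
        dir_spec$xz <- combine_xz(dir_spec$x, dir_spec$z)
        dir_spec$xyz <- combine_xyz(dir_spec$x, dir_spec$y, dir_spec$z)
        per_loc[[loc]] <- dir_spec
      }
      if (length(per_loc) == 2) {
        per_loc$full <- lapply(GLOVE_DIRECTIONS, function(dir) {
          average_spectra(
            list(per_loc$fingertip[[dir]], per_loc$proximal[[dir]]),
            level = "areas"
          )
        })
        names(per_loc$full) <- GLOVE_DIRECTIONS
      }
      for (loc in names(per_loc)) {
        for (dir in names(per_loc[[loc]])) {
          subj_spectra[[loc]][[dir]] <- c(
            subj_spectra[[loc]][[dir]], list(per_loc[[loc]][[dir]])
          )
        }
      }
    }
    for (loc in names(subj_spectra)) {
      for (dir in names(subj_spectra[[loc]])) {
        spec <- finalize(average_spectra(subj_spectra[[loc]][[dir]], level = "subjects"))
        out <- c(out, list(tibble::as_tibble(as.data.frame(spec))))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Extract one spectrum from a spectra table
#'
#' @param tbl A spectra table as produced by [synthesize_glove_spectra()] or
#'   [read_trans_spectra()] (columns `glove, location, direction, freq_hz,
#'   value`).
#' @param glove,location,direction Tags selecting the spectrum.
#' @param provenance Provenance tag for the returned object.
#' @return A `trans_spectrum`.
#' @export
spectrum_from_table <- function(tbl, glove, location, direction,
                                provenance = "fixture") {
  sel <- tbl[tbl$glove == glove & tbl$location == location &
    tbl$direction == direction, ]
  if (nrow(sel) == 0) {
    stop(sprintf(
      "no spectrum for glove %s / %s / %s in the table", glove, location, direction
    ), call. = FALSE)
  }
  sel <- sel[order(sel$freq_hz), ]
  grid <- band_grid(min(sel$freq_hz), max(sel$freq_hz))
  trans_spectrum(glove, location, direction, grid, sel$value, provenance)
}

#' Read and write point-measurement tables
#'
#' Comma-separated UTF-8 with a header row; columns `subject, glove, finger,
#' area, point, grip_n, push_n, direction, freq_hz, response_ms2,
#' excitation_ms2`, one row per measurement point, direction and band.
#'
#' @param path File path.
#' @return `read_point_measurements()` returns the validated tibble.
#' @export
read_point_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  points <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_point_columns(points)
  points
}

#' @rdname read_point_measurements
#' @param points Point-measurement tibble.
#' @export
write_point_measurements <- function(points, path) {
  check_point_columns(points)
  readr::write_csv(points[, POINT_COLUMNS], path)
  invisible(path)
}

#' Read and write transmissibility spectra tables
#'
#' Comma-separated UTF-8 with columns `glove, location, direction, freq_hz,
#' value`.
#'
#' @param path File path.
#' @return `read_trans_spectra()` returns the spectra tibble.
#' @export
read_trans_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("glove", "location", "direction", "freq_hz", "value")
  miss <- setdiff(req, names(tbl))
  if (length(miss) > 0) {
    stop("spectra table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' @rdname read_trans_spectra
#' @param spectra Spectra tibble (or list of `trans_spectrum` objects).
#' @export
write_trans_spectra <- function(spectra, path) {
  if (is.list(spectra) && !is.data.frame(spectra)) {
    spectra <- dplyr::bind_rows(lapply(spectra, function(s) {
      tibble::as_tibble(as.data.frame(s))
    }))
  }
  readr::write_csv(spectra, path)
  invisible(path)
}
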