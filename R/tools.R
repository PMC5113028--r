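# Tri-axial tool vibration spectra: container, CSV ingest with validation,
# zero-fill of missing bands, and weighted/unweighted summaries.

#' Construct a tool vibration spectrum
#'
#' Tri-axial RMS accelerations per one-third octave band for one tool or
#' process. Axis convention (fixed at ingest): `y` is the shear direction
#' along the handle/finger axis; `x` and `z` are the compression directions
#' pressing into the fingers.
#'
#' @param tool_id Identifier.
#' @param grid A [band_grid()] (at most 6.3--1250 Hz).
#' @param ax,ay,az Per-band RMS accelerations (m/s^2), one value per band,
#'   all `>= 0`, with at least one band strictly positive across the axes.
#' @param display_name Human-readable name (defaults to `tool_id`).
#' @param shear_axis_note Free text documenting the shear (y) axis choice.
#' @param source_citation Free text data origin.
#' @return A `tool_spectrum` object.
#' @export
tool_spectrum <- function(tool_id, grid, ax, ay, az,
                          display_name = tool_id,
                          shear_axis_note = "y = shear along the handle/finger axis",
                          source_citation = "") {
  stopifnot(is.character(tool_id), length(tool_id) == 1, is_band_grid(grid))
  n <- nrow(grid)
  for (v in list(ax, ay, az)) {
    if (length(v) != n) stop("axis vectors must match the grid", call. = FALSE)
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("band accelerations must be finite and >= 0", call. = FALSE)
    }
  }
  if (all(c(ax, ay, az) == 0)) {
    stop("tool spectrum has no energy in any band", call. = FALSE)
  }
  structure(
    list(
      tool_id = tool_id, display_name = display_name, grid = grid,
      ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
      shear_axis_note = shear_axis_note, source_citation = source_citation
    ),
    class = "tool_spectrum"
  )
}

#' @export
print.tool_spectrum <- function(x, ...) {
  cat(sprintf(
    "<tool_spectrum> %s: %d bands (%g-%g Hz), unweighted At (6.3-500 Hz) = %.2f m/s^2\n",
    x$tool_id, nrow(x$grid), min(x$grid$nominal_hz), max(x$grid$nominal_hz),
    tryCatch(tool_summary(x, wh_weights(restrict_grid(x$grid, 6.3, 500), "unity"))$At,
      error = function(e) NA_real_
    )
  ))
  invisible(x)
}

#' @export
as.data.frame.tool_spectrum <- function(x, ...) {
  data.frame(
    tool = x$tool_id, freq_hz = x$grid$nominal_hz,
    ax_ms2 = x$ax, ay_ms2 = x$ay, az_ms2 = x$az
  )
}

#' Read tool vibration spectra from CSV
#'
#' Format: comma-separated UTF-8, header `tool,freq_hz,ax_ms2,ay_ms2,az_ms2`,
#' one row per tool and band; nominal band labels are accepted and mapped to
#' exact midband frequencies. Every tool must provide all three axes in every
#' listed band; bands a tool does not list are not invented here (apply
#' [zero_fill()] to complete a grid).
#'
#' @param path CSV file path.
#' @param policy `"strict"` rejects tools with an all-zero axis; `"lenient"`
#'   only warns (several literature spectra genuinely lack axes' energy at
#'   high frequency).
#' @return A named list of `tool_spectrum` objects.
#' @export
read_tool_spectra <- function(path, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("tool", "freq_hz", "ax_ms2", "ay_ms2", "az_ms2")
  miss <- setdiff(req, names(tbl))
  if (length(miss) > 0) {
    stop("tool spectra file lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (id in unique(tbl$tool)) {
    rows <- tbl[tbl$tool == id, ]
    for (axis in c("ax_ms2", "ay_ms2", "az_ms2")) {
      if (any(is.na(rows[[axis]]))) {
        stop(sprintf("tool %s: axis %s has missing values", id, substr(axis, 2, 2)),
          call. = FALSE
        )
      }
      if (any(rows[[axis]] < 0)) {
        stop(sprintf("tool %s: axis %s has negative accelerations", id, substr(axis, 2, 2)),
          call. = FALSE
        )
      }
    }
    idx <- vapply(rows$freq_hz, band_index_for_nominal, integer(1))
    if (anyDuplicated(idx)) stop(sprintf("tool %s: duplicated bands", id), call. = FALSE)
    span <- band_grid(
      band_nominal_for_index(min(idx)),
      band_nominal_for_index(max(idx))
    )
    ax <- ay <- az <- numeric(nrow(span))
    pos <- match(idx, span$index)
    ax[pos] <- rows$ax_ms2
    ay[pos] <- rows$ay_ms2
    az[pos] <- rows$az_ms2
    for (axis in c("ax", "ay", "az")) {
      if (all(get(axis) == 0)) {
        msg <- sprintf("tool %s: axis %s carries no energy", id, sub("a", "", axis))
        if (policy == "strict") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      }
    }
    out[[id]] <- tool_spectrum(id, span, ax, ay, az)
  }
  out
}

#' Write tool vibration spectra to CSV
#'
#' @param tools A `tool_spectrum` or list of them.
#' @param path Output file path.
#' @export
write_tool_spectra <- function(tools, path) {
  if (inherits(tools, "tool_spectrum")) tools <- list(tools)
  tbl <- dplyr::bind_rows(lapply(tools, function(t) {
    tibble::as_tibble(as.data.frame(t))
  }))
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Zero-fill a tool spectrum onto a full grid
#'
#' Bands of `grid` absent from the tool's spectrum are set to zero on all
#' three axes (literature spectra often omit bands with no reported energy);
#' bands already present are unchanged. Idempotent.
#'
#' @param t A `tool_spectrum`.
#' @param grid Target [band_grid()]; the tool's bands must be a subset.
#' @return The tool spectrum on `grid`.
#' @export
zero_fill <- function(t, grid) {
  stopifnot(inherits(t, "tool_spectrum"), is_band_grid(grid))
  if (!all(t$grid$index %in% grid$index)) {
    stop("tool spectrum contains bands outside the target grid", call. = FALSE)
  }
  ax <- ay <- az <- numeric(nrow(grid))
  pos <- match(t$grid$index, grid$index)
  ax[pos] <- t$ax
  ay[pos] <- t$ay
  az[pos] <- t$az
  tool_spectrum(
    t$tool_id, grid, ax, ay, az,
    display_name = t$display_name, shear_axis_note = t$shear_axis_note,
    source_citation = t$source_citation
  )
}

#' Summarize a tool spectrum into shear, compression and total accelerations
#'
#' Computes the overall (optionally frequency-weighted) RMS accelerations over
#' a band range: `Ay` in shear, `Axz = sqrt(Ax^2 + Az^2)` in the combined
#' compression directions, and the vector total `At = sqrt(Ay^2 + Axz^2)`.
#'
#' @param t A `tool_spectrum`.
#' @param weights A [wh_weights()] vector on the tool's grid restricted to the
#'   band range (unity mode gives the unweighted summary).
#' @param fmin,fmax Nominal band range (default 6.3--500 Hz, the range over
#'   which glove transfer functions are available).
#' @return A `tool_summary`: list with `mode`, `Ay`, `Axz`, `At` (m/s^2).
#' @examples
#' \dontrun{
#' tool_summary(t, wh_weights(restrict_grid(t$grid, 6.3, 500), "unity"))
#' }
#' @export
tool_summary <- function(t, weights, fmin = 6.3, fmax = 500) {
  stopifnot(inherits(t, "tool_spectrum"))
  sub <- restrict_grid(t$grid, fmin, fmax)
  keep <- t$grid$index %in% sub$index
  check_weights_on_grid(numeric(nrow(sub)), weights, grid = sub)
  ax_rms <- weighted_band_rms(t$ax[keep], weights)
  ay_rms <- weighted_band_rms(t$ay[keep], weights)
  az_rms <- weighted_band_rms(t$az[keep], weights)
  axz <- sqrt(ax_rms^2 + az_rms^2)
  structure(
    list(
      mode = summary_mode_label(weights),
      Ay = ay_rms, Axz = axz, At = sqrt(ay_rms^2 + axz^2)
    ),
    class = "tool_summary"
  )
}

#' @export
print.tool_summary <- function(x, ...) {
  cat(sprintf(
    "<tool_summary> %s: Ay = %.2f, Axz = %.2f, At = %.2f m/s^2\n",
    x$mode, x$Ay, x$Axz, x$At
  ))
  invisible(x)
}
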