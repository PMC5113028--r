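# Tool-specific glove effectiveness: energy-weighted transmissibility values,
# percent reductions, full-finger aggregation and glove-tool match reports.

#' Tool-specific transmissibility values for one glove x tool pair
#'
#' Collapses a glove's transmissibility spectra against a tool's vibration
#' spectrum into single (optionally frequency-weighted) transmissibility
#' values, the band-domain analogue of the standardized glove test:
#'
#' * shear: `T_y = sqrt( sum[(Ty_i a_y_i Wh_i)^2] / sum[(a_y_i Wh_i)^2] )`
#' * compression: `T_xz = sqrt( sum[Txz_i^2 (a_x_i^2 + a_z_i^2) Wh_i^2] /
#'   sum[(a_x_i^2 + a_z_i^2) Wh_i^2] )`
#' * total: `T_xzy = sqrt( sum[{Txz_i^2 (a_x_i^2 + a_z_i^2) + Ty_i^2 a_y_i^2}
#'   Wh_i^2] / sum[(a_x_i^2 + a_y_i^2 + a_z_i^2) Wh_i^2] )`
#'
#' i.e. each value is the square root of an energy-weighted mean of the
#' squared per-band transmissibility, with the tool's (weighted) band energy
#' as the weight. A direction with zero energy yields `NA` for its directional
#' value; the total remains defined whenever the tool has any energy in range.
#'
#' @param t_y Shear-direction `trans_spectrum` (direction `"y"`).
#' @param t_xz Combined-compression `trans_spectrum` (direction `"xz"`).
#' @param tool A `tool_spectrum` (zero-filled; its grid restricted to the
#'   spectra's range must match them).
#' @param weights A [wh_weights()] vector on the spectra's grid (unity mode
#'   gives the unweighted values).
#' @return An `effectiveness_result`: list with `glove`, `tool`, `location`,
#'   `mode`, `T_y`, `T_xz`, `T_xzy` and `R` (percent reduction of the total).
#' @export
tool_specific_values <- function(t_y, t_xz, tool, weights) {
  stopifnot(
    inherits(t_y, "trans_spectrum"), inherits(t_xz, "trans_spectrum"),
    inherits(tool, "tool_spectrum")
  )
  if (t_y$direction != "y" || t_xz$direction != "xz") {
    stop("need a y-direction and an xz-direction spectrum", call. = FALSE)
  }
  check_same_tags(t_y, t_xz, what = c("glove", "location"))
  grid <- t_y$grid
  keep <- tool$grid$index %in% grid$index
  if (sum(keep) != nrow(grid)) {
    stop("tool spectrum does not cover the transmissibility grid (zero_fill first?)",
      call. = FALSE
    )
  }
  check_weights_on_grid(t_y$values, weights, grid = grid)
  wh2 <- weights$wh^2
  e_y <- tool$ay[keep]^2 * wh2
  e_xz <- (tool$ax[keep]^2 + tool$az[keep]^2) * wh2
  s_y <- sum(t_y$values^2 * e_y)
  s_xz <- sum(t_xz$values^2 * e_xz)
  tot <- sum(e_y) + sum(e_xz)
  if (tot == 0) {
    stop(sprintf("tool %s has no energy in the assessment band range", tool$tool_id),
      call. = FALSE
    )
  }
  T_y <- if (sum(e_y) > 0) sqrt(s_y / sum(e_y)) else NA_real_
  T_xz <- if (sum(e_xz) > 0) sqrt(s_xz / sum(e_xz)) else NA_real_
  T_xzy <- sqrt((s_y + s_xz) / tot)
  structure(
    list(
      glove = t_y$glove, tool = tool$tool_id, location = t_y$location,
      mode = summary_mode_label(weights),
      T_y = T_y, T_xz = T_xz, T_xzy = T_xzy,
      R = (1 - T_xzy) * 100
    ),
    class = "effectiveness_result"
  )
}

#' @export
print.effectiveness_result <- function(x, ...) {
  cat(sprintf(
    "<effectiveness_result> %s on %s (%s, %s): T_y = %.3f, T_xz = %.3f, T_xzy = %.3f, R = %+.1f%%\n",
    x$glove, x$tool, x$location, x$mode, x$T_y, x$T_xz, x$T_xzy, x$R
  ))
  invisible(x)
}

#' @export
as.data.frame.effectiveness_result <- function(x, ...) {
  data.frame(
    tool = x$tool, glove = x$glove, location = x$location, mode = x$mode,
    T_y = x$T_y, T_xz = x$T_xz, T_xzy = x$T_xzy, R_percent = x$R
  )
}

#' Percent vibration reduction
#'
#' `R = (1 - T) * 100`: positive values mean the glove attenuates the total
#' vibration, negative values mean it amplifies it.
#'
#' @param x An `effectiveness_result` (uses its total value) or a numeric
#'   transmissibility value.
#' @return Percent reduction.
#' @export
percent_reduction <- function(x) {
  t <- if (inherits(x, "effectiveness_result")) x$T_xzy else x
  stopifnot(is.numeric(t))
  (1 - t) * 100
}

#' Total-vibration transmissibility value from directional values
#'
#' Algebraic identity linking the directional transmissibility values to the
#' total: `T_xzy = sqrt((T_y^2 Ay^2 + T_xz^2 Axz^2) / (Ay^2 + Axz^2))`, where
#' `Ay` and `Axz` are the same-mode overall accelerations in shear and
#' combined compression. Useful for cross-checking published per-direction
#' values against published totals.
#'
#' @param t_y,t_xz Directional transmissibility values.
#' @param a_y,a_xz Overall accelerations (m/s^2) in shear and compression.
#' @return The total transmissibility value.
#' @examples
#' total_transmissibility_value(0.92, 0.59, 36.53, 86.26)  # ~0.65
#' @export
total_transmissibility_value <- function(t_y, t_xz, a_y, a_xz) {
  stopifnot(a_y >= 0, a_xz >= 0, a_y + a_xz > 0)
  sqrt((t_y^2 * a_y^2 + t_xz^2 * a_xz^2) / (a_y^2 + a_xz^2))
}

#' Full-finger effectiveness from fingertip and proximal inputs
#'
#' Aggregates the two finger areas into a full-finger result for one glove x
#' tool pair. The default strategy, `"spectrum_mean"`, averages the fingertip
#' and proximal transmissibility spectra per band (the same order as the
#' spectra synthesis chain) and then computes the tool-specific values;
#' `"value_mean"` instead computes per-location values and takes their
#' arithmetic mean.
#'
#' @param fingertip,proximal Lists with elements `t_y` and `t_xz`
#'   (`trans_spectrum` objects at the respective location).
#' @param tool A `tool_spectrum`.
#' @param weights A [wh_weights()] vector (as in [tool_specific_values()]).
#' @param strategy `"spectrum_mean"` (default) or `"value_mean"`.
#' @return An `effectiveness_result` with location `"full"`.
#' @export
full_finger_result <- function(fingertip, proximal, tool, weights,
                               strategy = c("spectrum_mean", "value_mean")) {
  strategy <- match.arg(strategy)
  for (inp in list(fingertip, proximal)) {
    if (!is.list(inp) || !all(c("t_y", "t_xz") %in% names(inp))) {
      stop("fingertip/proximal inputs must be lists with t_y and t_xz spectra",
        call. = FALSE
      )
    }
  }
  if (strategy == "spectrum_mean") {
    t_y <- average_spectra(list(fingertip$t_y, proximal$t_y), level = "areas")
    t_xz <- average_spectra(list(fingertip$t_xz, proximal$t_xz), level = "areas")
    return(tool_specific_values(t_y, t_xz, tool, weights))
  }
  r_tip <- tool_specific_values(fingertip$t_y, fingertip$t_xz, tool, weights)
  r_prox <- tool_specific_values(proximal$t_y, proximal$t_xz, tool, weights)
  T_y <- mean(c(r_tip$T_y, r_prox$T_y))
  T_xz <- mean(c(r_tip$T_xz, r_prox$T_xz))
  T_xzy <- mean(c(r_tip$T_xzy, r_prox$T_xzy))
  structure(
    list(
      glove = r_tip$glove, tool = r_tip$tool, location = "full",
      mode = r_tip$mode, T_y = T_y, T_xz = T_xz, T_xzy = T_xzy,
      R = (1 - T_xzy) * 100
    ),
    class = "effectiveness_result"
  )
}

# Half-away-from-zero rounding (the convention of printed tables; base R
# round() is half-to-even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify glove-tool matches by percent reduction
#'
#' Counts, per glove, the tools whose total-vibration percent reduction meets
#' a threshold: `reduced` (R at/above the threshold), `amplified` (R at/below
#' minus the threshold) and `neutral` (the rest). R values are rounded to
#' integer percent (half away from zero, the precision of published reduction
#' tables) before comparison. `comparison = "inclusive"` uses `>=`/`<=`
#' ("10% or more"); `"strict"` uses `>`/`<`.
#'
#' @param results Tibble with columns `glove`, `tool`, `R_percent` (and
#'   optionally `mode`; if several modes are present they are counted
#'   separately).
#' @param threshold Percent threshold (>= 0), default 10.
#' @param comparison `"inclusive"` (default) or `"strict"`.
#' @return A `match_report`: list with `threshold`, `comparison`, `counts`
#'   (per glove and mode) and the rounded `r_table`.
#' @export
classify_matches <- function(results, threshold = 10,
                             comparison = c("inclusive", "strict")) {
  comparison <- match.arg(comparison)
  stopifnot(is.numeric(threshold), threshold >= 0)
  req <- c("glove", "tool", "R_percent")
  miss <- setdiff(req, names(results))
  if (length(miss) > 0) {
    stop("results lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"mode" %in% names(results)) results$mode <- "unweighted"
  r <- round_half_away(results$R_percent, 0)
  cls <- if (comparison == "inclusive") {
    ifelse(r >= threshold, "reduced", ifelse(r <= -threshold, "amplified", "neutral"))
  } else {
    ifelse(r > threshold, "reduced", ifelse(r < -threshold, "amplified", "neutral"))
  }
  tbl <- results
  tbl$R_rounded <- r
  tbl$classification <- cls
  counts <- tbl |>
    dplyr::summarise(
      n_tools = dplyr::n(),
      reduced = sum(.data$classification == "reduced"),
      amplified = sum(.data$classification == "amplified"),
      neutral = sum(.data$classification == "neutral"),
      mean_R = mean(.data$R_percent),
      .by = c("glove", "mode")
    )
  structure(
    list(
      threshold = threshold, comparison = comparison,
      counts = counts, r_table = tibble::as_tibble(tbl)
    ),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> threshold = %g%% (%s comparison)\n", x$threshold, x$comparison
  ))
  print(x$counts)
  invisible(x)
}

#' Render an effectiveness/match report
#'
#' Formats results at the precision of published assessment tables:
#' transmissibility values to two decimals, percent reductions to integer
#' percent (half away from zero), plus per-glove summary counts and a mean-R
#' row.
#'
#' @param report A `match_report` from [classify_matches()].
#' @param format `"tibble"` returns a list of two tibbles (`per_tool`,
#'   `per_glove`); `"text"` returns printable character lines.
#' @return See `format`.
#' @export
render_report <- function(report, format = c("tibble", "text")) {
  stopifnot(inherits(report, "match_report"))
  format <- match.arg(format)
  if (nrow(report$r_table) == 0) stop("report holds no results", call. = FALSE)
  per_tool <- report$r_table
  for (col in intersect(c("T_y", "T_xz", "T_xzy"), names(per_tool))) {
    per_tool[[col]] <- round_half_away(per_tool[[col]], 2)
  }
  per_tool$R_percent <- round_half_away(per_tool$R_percent, 0)
  per_glove <- report$counts
  per_glove$mean_R <- round_half_away(per_glove$mean_R, 1)
  if (format == "tibble") {
    return(list(per_tool = tibble::as_tibble(per_tool), per_glove = per_glove))
  }
  lines <- c(
    sprintf(
      "Glove-tool match report (threshold %g%%, %s comparison)",
      report$threshold, report$comparison
    ),
    utils::capture.output(print(as.data.frame(per_tool), row.names = FALSE)),
    "",
    utils::capture.output(print(as.data.frame(per_glove), row.names = FALSE))
  )
  lines
}
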