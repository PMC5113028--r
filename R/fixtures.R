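# Packaged fixture tables transcribed from the published glove/tool assessment
# tables, with checksum-verified loading.

FIXTURE_FILES <- c(
  table1 = "table1_gloves.csv",
  table3 = "table3_transmissibilities.csv",
  table4 = "table4_reductions.csv",
  table5 = "table5_transmissibilities.csv",
  tool_summaries = "tool_accel_summaries.csv"
)

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "havglove")
  if (identical(path, "")) stop("fixture file missing: ", file, call. = FALSE)
  path
}

#' Load a packaged fixture table
#'
#' Available fixtures (all transcriptions of published tables; md5-verified
#' against the packaged manifest):
#'
#' * `"table1"`: glove metadata (mechanism, AV certification, grip-strength
#'   reduction percent).
#' * `"table3"`, `"table5"`: per glove x tool x location x mode directional
#'   (`ty`), compression (`txz`) and total (`txzy`) transmissibility values.
#' * `"table4"`: percent reductions of the total full-finger vibration for 79
#'   tools x 4 gloves x 2 modes (returned long: `tool, aw_ms2, mode, glove,
#'   r_percent`).
#' * `"tool_summaries"`: overall shear/compression/total accelerations
#'   (`ay_ms2, axz_ms2, at_ms2`) per tool and mode, with an `identity_ok` flag
#'   marking rows whose printed values satisfy `At = sqrt(Ay^2 + Axz^2)`
#'   within print precision (known print inconsistencies are flagged FALSE,
#'   not silently dropped).
#'
#' @param name One of `"table1"`, `"table3"`, `"table4"`, `"table5"`,
#'   `"tool_summaries"`.
#' @return A tibble with attribute `provenance`.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(FIXTURE_FILES)) {
    stop(
      "unknown fixture \"", name, "\"; available: ",
      paste(names(FIXTURE_FILES), collapse = ", "),
      call. = FALSE
    )
  }
  file <- FIXTURE_FILES[[name]]
  path <- fixture_path(file)
  manifest <- readr::read_csv(fixture_path("fixture_manifest.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  expected <- manifest$md5[manifest$file == file]
  if (length(expected) != 1) {
    stop("fixture ", file, " is not listed in the manifest", call. = FALSE)
  }
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, expected)) {
    stop("checksum mismatch for fixture ", file, call. = FALSE)
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (name == "table4") {
    tbl <- tidyr::pivot_longer(tbl,
      cols = -c("tool", "aw_ms2"),
      names_to = c("mode", "glove"), names_sep = "_",
      values_to = "r_percent"
    )
    tbl$mode <- ifelse(tbl$mode == "ru", "unweighted", "weighted")
  }
  attr(tbl, "provenance") <- paste0("published table fixture: ", name)
  tbl
}
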