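#' Read tabular 3-day food records
#'
#' Food records are daily intake rows: one participant-day with grams/day
#' for each food-group component, total energy in kcal/day, and optional
#' nutrient columns. Two CSV dialects are supported:
#'
#' * `wide` — one row per participant-day; columns `participant_id`, `day`,
#'   one column per component (g/day), `energy_kcal`, and any nutrient
#'   columns.
#' * `long` — one row per participant-day-variable; columns
#'   `participant_id`, `day`, `component`, `grams`. Energy may be carried
#'   as the pseudo-component `energy_kcal`. The long form is pivoted to
#'   wide on read.
#'
#' Units are fixed: g/day for intakes, kcal/day for energy. No unit
#' inference is attempted.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, header row).
#' @param dialect `"wide"` or `"long"`.
#' @param index Index definition whose components must be present.
#' @return A validated tibble of food records in wide form.
#' @export
read_food_records <- function(path, dialect = c("wide", "long"),
                              index = tcrad_index()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "long") {
    needed <- c("participant_id", "day", "component", "grams")
    missing_cols <- setdiff(needed, names(raw))
    if (length(missing_cols)) {
      abort(paste0("Long-dialect CSV lacks column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    dup <- raw |>
      dplyr::count(.data$participant_id, .data$day, .data$component) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup)) {
      abort(paste0(
        "Duplicated (participant, day, component) cell(s), first: ",
        dup$participant_id[1], "/day ", dup$day[1], "/", dup$component[1]
      ))
    }
    raw <- tidyr::pivot_wider(raw, names_from = "component",
                              values_from = "grams")
  }
  validate_food_records(raw, index)
}

#' Validate a food-record table
#'
#' Enforces the invariants of the record format: mandatory columns, day
#' indices in 1-3, at most one row per participant-day, non-negative finite
#' intakes and energy, and 1-3 day rows per participant. Participants with
#' fewer than 3 recorded days are allowed (downstream estimation uses the
#' available days); unknown extra columns are kept and reported.
#'
#' @param records A data frame of daily records in wide form.
#' @param index Index definition whose components must be present.
#' @param require_energy Should an `energy_kcal` column be required?
#' @return The validated records as a tibble.
#' @export
validate_food_records <- function(records, index = tcrad_index(),
                                  require_energy = TRUE) {
  records <- as_tibble(records)
  needed <- c("participant_id", "day", index$component,
              if (require_energy) "energy_kcal")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("Food records lack mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  records$participant_id <- as.character(records$participant_id)
  if (any(!records$day %in% 1:3)) {
    abort("`day` must be 1, 2 or 3.")
  }
  dup <- records |>
    dplyr::count(.data$participant_id, .data$day) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("Duplicated participant-day row(s), first: ",
                 dup$participant_id[1], " day ", dup$day[1]))
  }
  value_cols <- intersect(c(index$component, "energy_kcal"), names(records))
  for (col in value_cols) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      abort(paste0("Column `", col, "` must be numeric."))
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      abort(paste0("Negative or non-finite value in `", col, "` at row ",
                   bad[1], "."))
    }
  }
  extra <- setdiff(names(records), c("participant_id", "day", "weekday_type",
                                     index$component, "energy_kcal"))
  if (length(extra)) {
    inform(paste0("Extra (nutrient or metadata) column(s) kept as-is: ",
                  paste(extra, collapse = ", ")))
  }
  records
}

#' Write food records to CSV
#'
#' @param records A food-record tibble (wide form).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_food_records <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Write a scored cohort to CSV
#'
#' One row per participant: id, strata, per-component points, total score,
#' category, and SES class, in a deterministic column order.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scored_cohort <- function(scored, path) {
  point_cols <- grep("^points_", names(scored), value = TRUE)
  lead <- intersect(
    c("participant_id", "sex", "age", "area", "school_type", "ses_points",
      "ses_class"),
    names(scored)
  )
  out <- scored[, c(lead, sort(point_cols), "total_score", "category")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a scored cohort CSV
#'
#' @param path CSV written by [write_scored_cohort()].
#' @return A tibble.
#' @export
read_scored_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
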