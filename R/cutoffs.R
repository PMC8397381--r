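#' Load a cutoff table
#'
#' A cutoff table maps each (component, sex) pair of an index definition to
#' the median intake threshold in g/day used for binary scoring. The bundled
#' reference table carries the sex-specific medians of the TCRAD development
#' sample (804 Costa Rican adolescents).
#'
#' @param source Either `"table1_fixture"` for the bundled reference
#'   cutoffs, or a path to a CSV with columns `component`, `sex`,
#'   `cutoff_g_per_day`.
#' @param index Index definition the table must cover; completeness is
#'   checked against it.
#' @return A tibble with columns `component`, `sex`, `cutoff` (g/day) and
#'   attribute `provenance`.
#' @examples
#' load_cutoffs()
#' @export
load_cutoffs <- function(source = "table1_fixture", index = tcrad_index()) {
  if (identical(source, "table1_fixture")) {
    path <- system.file("extdata", "table1_cutoffs.csv", package = "tcrad",
                        mustWork = TRUE)
    provenance <- "table1_fixture"
  } else {
    path <- source
    provenance <- source
    if (!file.exists(path)) abort(paste0("Cutoff file not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("component", "sex", "cutoff_g_per_day")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Cutoff CSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- raw |>
    dplyr::transmute(
      component = as.character(.data$component),
      sex = as.character(.data$sex),
      cutoff = as.numeric(.data$cutoff_g_per_day)
    )
  validate_cutoffs(out, index)
  attr(out, "provenance") <- provenance
  out
}

#' Validate a cutoff table against an index
#'
#' Checks that every (component, sex) pair of the index is present exactly
#' once and all cutoffs are non-negative and finite.
#'
#' @param cutoffs Tibble with columns `component`, `sex`, `cutoff`.
#' @param index Index definition to check coverage against.
#' @param sexes Sexes that must be covered.
#' @return `cutoffs`, invisibly, if valid; otherwise an error.
#' @export
validate_cutoffs <- function(cutoffs, index = tcrad_index(),
                             sexes = c("male", "female")) {
  needed <- tidyr::expand_grid(component = index$component, sex = sexes)
  have <- dplyr::distinct(cutoffs, .data$component, .data$sex)
  missing_pairs <- dplyr::anti_join(needed, have, by = c("component", "sex"))
  if (nrow(missing_pairs)) {
    abort(paste0(
      "Cutoff table is incomplete; missing (component, sex) pair(s): ",
      paste(missing_pairs$component, missing_pairs$sex,
            sep = "/", collapse = ", ")
    ))
  }
  dups <- cutoffs |>
    dplyr::count(.data$component, .data$sex) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dups)) {
    abort(paste0("Duplicated cutoff entries for: ",
                 paste(dups$component, dups$sex, sep = "/", collapse = ", ")))
  }
  if (any(!is.finite(cutoffs$cutoff)) || any(cutoffs$cutoff < 0)) {
    abort("All cutoffs must be finite and >= 0 g/day.")
  }
  invisible(cutoffs)
}

#' Look up a single cutoff
#'
#' @param cutoffs A cutoff table from [load_cutoffs()] or [derive_cutoffs()].
#' @param component Component identifier.
#' @param sex `"male"` or `"female"`.
#' @return The cutoff in g/day.
#' @export
cutoff_for <- function(cutoffs, component, sex) {
  row <- cutoffs[cutoffs$component == component & cutoffs$sex == sex, ]
  if (nrow(row) != 1) {
    abort(paste0("No unique cutoff for (", component, ", ", sex, ")."))
  }
  row$cutoff
}
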