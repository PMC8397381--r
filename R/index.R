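#' The TCRAD index definition
#'
#' The Traditional Costa Rican Adolescents Diet (TCRAD) score is a binary
#' adherence index over 14 food groups: six scored as healthy (a point is
#' earned at or above the sex-specific median intake) and eight scored as
#' unhealthy (inverse scoring: a point is earned below the median). The
#' total therefore ranges from 0 to 14.
#'
#' `tcrad_index()` returns the default definition as a tibble of ordered
#' component specifications. Alternate indices can be built with
#' [index_definition()] from any set of components and directions.
#'
#' @return A tibble with one row per component and columns
#'   `component` (canonical snake_case identifier), `direction`
#'   (`"healthy"` or `"unhealthy"`), and `label` (the human-readable food
#'   group name), carrying attribute `max_score` equal to the number of
#'   components.
#' @examples
#' tcrad_index()
#' @export
tcrad_index <- function() {
  def <- dplyr::bind_rows(
    tibble(component = "legumes",        direction = "healthy",   label = "Legumes"),
    tibble(component = "vegetables",     direction = "healthy",   label = "Vegetables"),
    tibble(component = "fruits",         direction = "healthy",   label = "Fruits"),
    tibble(component = "vegetable_oils", direction = "healthy",   label = "Vegetable oils"),
    tibble(component = "dairy",          direction = "healthy",   label = "Dairy"),
    tibble(component = "tortillas",      direction = "healthy",   label = "Corn tortilla"),
    tibble(component = "white_rice",     direction = "unhealthy", label = "White rice"),
    tibble(component = "red_meat",       direction = "unhealthy", label = "Red/processed meat"),
    tibble(component = "solid_fats",     direction = "unhealthy", label = "Solid fats"),
    tibble(component = "desserts",       direction = "unhealthy", label = "Desserts/pastries"),
    tibble(component = "sugary_drinks",  direction = "unhealthy", label = "Sugary drinks"),
    tibble(component = "snacks",         direction = "unhealthy", label = "Snacks"),
    tibble(component = "fast_food",      direction = "unhealthy", label = "Fast food"),
    tibble(component = "refined_bread",  direction = "unhealthy", label = "Refined bread/cookies")
  )
  index_definition(def$component, def$direction, def$label)
}

#' Build an index definition
#'
#' @param components Character vector of unique component identifiers.
#' @param directions Character vector, `"healthy"` or `"unhealthy"`, one per
#'   component. Healthy components score 1 at or above the cutoff; unhealthy
#'   components score 1 below it.
#' @param labels Optional human-readable labels (defaults to `components`).
#' @return A tibble of class `tcrad_index` with attribute `max_score`.
#' @export
index_definition <- function(components, directions, labels = components) {
  if (anyDuplicated(components)) {
    abort("Component names must be unique within an index definition.")
  }
  if (length(directions) != length(components)) {
    abort("`directions` must have one entry per component.")
  }
  bad <- setdiff(unique(directions), c("healthy", "unhealthy"))
  if (length(bad)) {
    abort(paste0("Unknown direction(s): ", paste(bad, collapse = ", ")))
  }
  out <- tibble(
    component = as.character(components),
    direction = as.character(directions),
    label = as.character(labels)
  )
  attr(out, "max_score") <- nrow(out)
  class(out) <- c("tcrad_index", class(out))
  out
}

#' @export
print.tcrad_index <- function(x, ...) {
  cat("<tcrad_index> ", nrow(x), " components (",
      sum(x$direction == "healthy"), " healthy / ",
      sum(x$direction == "unhealthy"), " unhealthy), max score ",
      max_score(x), "\n", sep = "")
  NextMethod()
}

#' Maximum attainable score of an index
#'
#' @param index An index definition from [tcrad_index()] or
#'   [index_definition()].
#' @return Integer, the number of components.
#' @export
max_score <- function(index) {
  attr(index, "max_score") %||% nrow(index)
}

#' Score category bands
#'
#' The continuous TCRAD score is categorized as low (score below 6),
#' moderate (6-7), or high (8 up to the maximum), bands drawn from the
#' interquartile range of the development sample.
#'
#' @param low_below Scores strictly below this value are "low".
#' @param high_from Scores at or above this value are "high"; the band in
#'   between is "moderate".
#' @return A list of class `tcrad_category_rule`.
#' @export
score_category_rule <- function(low_below = 6, high_from = 8) {
  if (high_from <= low_below) {
    abort("`high_from` must exceed `low_below` so bands partition the range.")
  }
  structure(list(low_below = low_below, high_from = high_from),
            class = "tcrad_category_rule")
}

#' Socioeconomic status bands
#'
#' SES is classified from a 0-100 household point score: low at 29 points
#' or below, medium between 30 and 84, high at 85 points or above.
#'
#' @param low_max Highest point score still classified "low".
#' @param high_min Lowest point score classified "high".
#' @return A list of class `tcrad_ses_rule`.
#' @export
ses_rule <- function(low_max = 29, high_min = 85) {
  if (high_min <= low_max + 1) {
    abort("SES bands must leave room for a medium class.")
  }
  structure(list(low_max = low_max, high_min = high_min),
            class = "tcrad_ses_rule")
}

#' Assign a score category
#'
#' @param score Integer vector of total scores.
#' @param rule A [score_category_rule()].
#' @param max Maximum attainable score (for range validation).
#' @return Factor with levels low < moderate < high.
#' @export
categorize_score <- function(score, rule = score_category_rule(), max = 14) {
  if (any(!is.finite(score)) || any(score < 0 | score > max)) {
    abort(paste0("Scores must lie in [0, ", max, "]."))
  }
  out <- dplyr::case_when(
    score < rule$low_below ~ "low",
    score >= rule$high_from ~ "high",
    TRUE ~ "moderate"
  )
  factor(out, levels = c("low", "moderate", "high"), ordered = TRUE)
}

#' Classify socioeconomic status
#'
#' @param points Integer vector of SES points on the 0-100 scale.
#' @param rule A [ses_rule()].
#' @return Factor with levels low < medium < high.
#' @export
classify_ses <- function(points, rule = ses_rule()) {
  if (any(!is.finite(points)) || any(points < 0 | points > 100)) {
    abort("SES points must lie in [0, 100].")
  }
  out <- dplyr::case_when(
    points <= rule$low_max ~ "low",
    points >= rule$high_min ~ "high",
    TRUE ~ "medium"
  )
  factor(out, levels = c("low", "medium", "high"), ordered = TRUE)
}
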