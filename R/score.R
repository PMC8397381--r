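#' Derive sex-specific median cutoffs from a cohort
#'
#' The scoring threshold for each component is the within-sex sample median
#' of the cohort's intake — the construction used to build the index in its
#' development sample. Use this to re-anchor the score in a new population,
#' or [load_cutoffs()] to score against the published thresholds.
#'
#' @param intakes Per-participant tibble with one column per component
#'   (usual or energy-adjusted intakes, g/day).
#' @param participants Participant tibble with `participant_id` and `sex`.
#' @param index Index definition listing the components.
#' @return A cutoff tibble (`component`, `sex`, `cutoff`) with attribute
#'   `provenance = "derived"`. Warns if any derived cutoff is 0, since a
#'   zero cutoff makes a healthy component a free point.
#' @export
derive_cutoffs <- function(intakes, participants, index = tcrad_index()) {
  missing_comp <- setdiff(index$component, names(intakes))
  if (length(missing_comp)) {
    abort(paste0("Intake table lacks component(s): ",
                 paste(missing_comp, collapse = ", ")))
  }
  joined <- dplyr::inner_join(
    intakes, dplyr::select(participants, "participant_id", "sex"),
    by = "participant_id"
  )
  sexes <- c("male", "female")
  absent <- setdiff(sexes, unique(joined$sex))
  if (length(absent)) {
    abort(paste0("Cannot derive cutoffs: no participants of sex ",
                 paste(absent, collapse = ", "), "."))
  }
  counts <- dplyr::count(joined, .data$sex)
  if (any(counts$n < 2)) {
    abort("Cutoff derivation needs at least 2 participants per sex.")
  }
  out <- joined |>
    tidyr::pivot_longer(dplyr::all_of(index$component),
                        names_to = "component", values_to = "intake") |>
    dplyr::summarise(cutoff = median(.data$intake),
                     .by = c("component", "sex")) |>
    dplyr::arrange(match(.data$component, index$component), .data$sex)
  zero <- out$component[out$cutoff == 0]
  if (length(zero)) {
    warn(paste0("Derived cutoff is 0 g/day for: ",
                paste(unique(zero), collapse = ", "),
                ". Healthy components with a zero cutoff score 1 for everyone."))
  }
  attr(out, "provenance") <- "derived"
  out
}

#' Score one component
#'
#' Binary point assignment against a median cutoff. Healthy components earn
#' the point for meeting or exceeding the cutoff; unhealthy components are
#' inversely scored and earn the point strictly below it. At exactly the
#' cutoff a healthy component scores 1 and an unhealthy component 0 (the
#' strict logical inverse).
#'
#' @param intake Intake in g/day (vectorized).
#' @param cutoff Cutoff in g/day.
#' @param direction `"healthy"` or `"unhealthy"`.
#' @return Integer 0/1 points.
#' @examples
#' score_component(42.9, 42.9, "healthy")   # meets the cutoff -> 1
#' score_component(42.8, 42.9, "healthy")   # below -> 0
#' score_component(0, 230.1, "unhealthy")   # below -> 1 (inverse scoring)
#' @export
score_component <- function(intake, cutoff, direction) {
  if (any(!is.finite(intake)) || any(!is.finite(cutoff))) {
    abort("Intakes and cutoffs must be finite.")
  }
  direction <- match.arg(direction, c("healthy", "unhealthy"))
  if (direction == "healthy") {
    as.integer(intake >= cutoff)
  } else {
    as.integer(intake < cutoff)
  }
}

#' Compute the total score for one participant
#'
#' Sums the 14 binary component points for a single intake profile scored
#' against that participant's sex-specific cutoffs.
#'
#' @param intakes Named numeric vector (or one-row data frame) of g/day
#'   intakes covering every index component.
#' @param sex `"male"` or `"female"`.
#' @param cutoffs Cutoff table.
#' @param index Index definition.
#' @return Integer total score in `[0, max_score(index)]`.
#' @examples
#' cuts <- load_cutoffs()
#' idx <- tcrad_index()
#' prof <- setNames(ifelse(idx$direction == "healthy",
#'                         cuts$cutoff[cuts$sex == "male"][match(idx$component,
#'                           cuts$component[cuts$sex == "male"])], 0),
#'                  idx$component)
#' compute_tcrad(prof, "male", cuts, idx)  # 14, the maximum
#' @export
compute_tcrad <- function(intakes, sex, cutoffs = load_cutoffs(),
                          index = tcrad_index()) {
  if (is.data.frame(intakes)) {
    stopifnot(nrow(intakes) == 1)
    intakes <- unlist(intakes[intersect(names(intakes), index$component)])
  }
  missing_comp <- setdiff(index$component, names(intakes))
  if (length(missing_comp)) {
    abort(paste0("No intake provided for component(s): ",
                 paste(missing_comp, collapse = ", ")))
  }
  cuts <- cutoffs[cutoffs$sex == sex, ]
  total <- 0L
  for (i in seq_len(nrow(index))) {
    comp <- index$component[i]
    cut <- cuts$cutoff[cuts$component == comp]
    if (length(cut) != 1) {
      abort(paste0("No unique cutoff for (", comp, ", ", sex, ")."))
    }
    total <- total + score_component(intakes[[comp]], cut, index$direction[i])
  }
  total
}

#' Score a cohort
#'
#' Assigns per-component points, total score, score category and SES class
#' to every participant. Cutoffs can be supplied (e.g. the bundled
#' development-sample table, to reproduce the published scoring) or derived
#' from this cohort's own sex-specific medians.
#'
#' @param intakes Per-participant tibble (`participant_id` plus one column
#'   per component) of usual or energy-adjusted intakes.
#' @param participants Participant tibble (`participant_id`, `sex`, and any
#'   strata; `ses_points` enables SES classification).
#' @param cutoffs A cutoff tibble, or `"derive"` to compute sex-specific
#'   medians from `intakes`.
#' @param index Index definition.
#' @param category_rule Score band rule from [score_category_rule()].
#' @param ses_rule_def SES band rule from [ses_rule()].
#' @return A tibble of class `tcrad_scored`: one row per participant with
#'   strata, `points_<component>` columns, `total_score`, `category`, and
#'   (when `ses_points` is available) `ses_class`. The cutoffs actually
#'   used, their provenance, and the rules are attached as attributes.
#' @export
score_cohort <- function(intakes, participants, cutoffs = "derive",
                         index = tcrad_index(),
                         category_rule = score_category_rule(),
                         ses_rule_def = ses_rule()) {
  if (identical(cutoffs, "derive")) {
    cutoffs <- derive_cutoffs(intakes, participants, index)
  } else {
    validate_cutoffs(cutoffs, index)
  }
  provenance <- attr(cutoffs, "provenance") %||% "supplied"
  keep <- intersect(
    c("participant_id", "sex", "age", "area", "school_type", "ses_points",
      "ses_class"),
    names(participants)
  )
  base <- dplyr::inner_join(dplyr::select(participants, dplyr::all_of(keep)),
                            intakes, by = "participant_id")
  if (nrow(base) == 0) {
    out <- dplyr::select(base, dplyr::all_of(keep)) |>
      dplyr::mutate(total_score = integer(),
                    category = factor(character(),
                                      levels = c("low", "moderate", "high"),
                                      ordered = TRUE))
  } else {
    missing_comp <- setdiff(index$component, names(base))
    if (length(missing_comp)) {
      abort(paste0("Intake table lacks component(s): ",
                   paste(missing_comp, collapse = ", ")))
    }
    pts <- purrr::map(seq_len(nrow(index)), function(i) {
      comp <- index$component[i]
      cut_m <- cutoff_for(cutoffs, comp, "male")
      cut_f <- cutoff_for(cutoffs, comp, "female")
      cut <- ifelse(base$sex == "male", cut_m, cut_f)
      score_component(base[[comp]], cut, index$direction[i])
    })
    names(pts) <- paste0("points_", index$component)
    pts <- as_tibble(pts)
    out <- dplyr::bind_cols(dplyr::select(base, dplyr::all_of(keep)), pts) |>
      dplyr::mutate(
        total_score = rowSums(pts),
        category = categorize_score(.data$total_score, category_rule,
                                    max = max_score(index))
      )
    if ("ses_points" %in% names(out) && !"ses_class" %in% names(out)) {
      out$ses_class <- classify_ses(out$ses_points, ses_rule_def)
    }
  }
  attr(out, "cutoffs") <- cutoffs
  attr(out, "cutoff_provenance") <- provenance
  attr(out, "category_rule") <- category_rule
  attr(out, "ses_rule") <- ses_rule_def
  attr(out, "index") <- index
  class(out) <- c("tcrad_scored", class(out))
  out
}

#' @rdname score_cohort
#' @param x A `tcrad_scored` cohort.
#' @param ... Unused.
#' @export
tidy.tcrad_scored <- function(x, ...) {
  point_cols <- grep("^points_", names(x), value = TRUE)
  as_tibble(x) |>
    dplyr::select("participant_id", "total_score", "category",
                  dplyr::all_of(point_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(point_cols),
                        names_to = "component", values_to = "points",
                        names_prefix = "points_")
}

#' @rdname score_cohort
#' @export
glance.tcrad_scored <- function(x, ...) {
  tibble(
    n = nrow(x),
    mean_score = mean(x$total_score),
    sd_score = sd(x$total_score),
    median_score = median(x$total_score),
    pct_low = 100 * mean(x$category == "low"),
    pct_moderate = 100 * mean(x$category == "moderate"),
    pct_high = 100 * mean(x$category == "high"),
    cutoff_provenance = attr(x, "cutoff_provenance")
  )
}
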