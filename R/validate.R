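significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

# Two-sample Wilcoxon rank-sum p-value: exact for small tie-free groups,
# otherwise normal approximation with tie correction and no continuity
# correction (the "standardized Wilcoxon statistic").
pairwise_wilcox_p <- function(x, y, exact_below = 20) {
  if (length(x) < 1 || length(y) < 1) return(NA_real_)
  use_exact <- length(x) < exact_below && length(y) < exact_below &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = FALSE)$p.value
  )
}

#' Correlate nutrient intakes with the total score
#'
#' Spearman rank correlation (average ranks for ties) of each nutrient with
#' the total score, with two-tailed p-values and the conventional
#' significance stars, alongside the nutrient's median, mean (SD) and
#' interquartile range — the internal-validity check that a diet-quality
#' score tracks the nutrients its healthy components carry.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param nutrients Per-participant tibble: `participant_id` plus one
#'   numeric column per nutrient.
#' @return A tibble with one row per nutrient: `nutrient`, `median`,
#'   `mean`, `sd`, `q25`, `q75`, `rho`, `p_value`, `stars`. A constant
#'   nutrient (or constant score) has an undefined correlation and is
#'   reported as `NA`, not 0.
#' @export
correlate_score_nutrients <- function(scored, nutrients) {
  joined <- dplyr::inner_join(
    dplyr::select(as_tibble(scored), "participant_id", "total_score"),
    nutrients, by = "participant_id"
  )
  if (nrow(joined) < 3) abort("Need at least 3 participants to correlate.")
  vars <- setdiff(names(nutrients), "participant_id")
  score <- joined$total_score
  purrr::map(vars, function(v) {
    x <- joined[[v]]
    ok <- is.finite(x)
    xs <- x[ok]
    sc <- score[ok]
    if (length(xs) < 3 || sd(xs) == 0 || sd(sc) == 0) {
      rho <- NA_real_
      p <- NA_real_
    } else {
      rho <- cor(sc, xs, method = "spearman")
      p <- suppressWarnings(
        cor.test(sc, xs, method = "spearman", exact = FALSE)$p.value
      )
    }
    tibble(
      nutrient = v, n = length(xs),
      median = median(xs), mean = mean(xs), sd = sd(xs),
      q25 = quantile(xs, 0.25, names = FALSE),
      q75 = quantile(xs, 0.75, names = FALSE),
      rho = rho, p_value = p, stars = significance_stars(p)
    )
  }) |> dplyr::bind_rows()
}

#' Component medians across score categories
#'
#' For each component, the median (min-max) of energy-adjusted intake
#' within each score category and overall, a Kruskal-Wallis test across
#' categories, and the three pairwise Wilcoxon rank-sum comparisons
#' (low-moderate, moderate-high, low-high). The development analysis
#' expects healthy-component medians to rise and most unhealthy-component
#' medians to fall from low to high scores.
#'
#' @param scored A scored cohort.
#' @param adjusted Per-participant tibble of energy-adjusted component
#'   intakes (`participant_id` plus component columns).
#' @param index Index definition.
#' @param p_adjust Multiplicity correction for the pairwise p-values
#'   (default `"none"`, with `"bonferroni"` available).
#' @return A tibble with one row per component x category (including an
#'   `"overall"` pseudo-category): `component`, `category`, `n`, `median`,
#'   `min`, `max`, plus per-component test columns repeated on each row:
#'   `kw_p`, `p_low_moderate`, `p_moderate_high`, `p_low_high`, and
#'   `underpowered` (TRUE when any non-empty category has fewer than 2
#'   participants).
#' @export
medians_by_category <- function(scored, adjusted, index = tcrad_index(),
                                p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  joined <- dplyr::inner_join(
    dplyr::select(as_tibble(scored), "participant_id", "category"),
    adjusted, by = "participant_id"
  )
  non_empty <- levels(droplevels(joined$category))
  if (length(non_empty) < 2) {
    abort("Need at least 2 non-empty score categories.")
  }
  comps <- intersect(index$component, names(adjusted))
  purrr::map(comps, function(comp) {
    x <- joined[[comp]]
    cat_stats <- joined |>
      dplyr::summarise(n = dplyr::n(), median = median(.data[[comp]]),
                       min = min(.data[[comp]]), max = max(.data[[comp]]),
                       .by = "category") |>
      dplyr::mutate(category = as.character(.data$category))
    overall <- tibble(category = "overall", n = length(x),
                      median = median(x), min = min(x), max = max(x))
    kw_p <- if (length(non_empty) >= 2) {
      kruskal.test(x, droplevels(joined$category))$p.value
    } else NA_real_
    grp <- function(lev) x[joined$category == lev]
    pw <- c(
      p_low_moderate = pairwise_wilcox_p(grp("low"), grp("moderate")),
      p_moderate_high = pairwise_wilcox_p(grp("moderate"), grp("high")),
      p_low_high = pairwise_wilcox_p(grp("low"), grp("high"))
    )
    if (p_adjust != "none") pw <- p.adjust(pw, method = p_adjust)
    dplyr::bind_rows(overall, cat_stats) |>
      dplyr::mutate(
        component = comp, .before = 1
      ) |>
      dplyr::mutate(
        kw_p = kw_p,
        p_low_moderate = pw[["p_low_moderate"]],
        p_moderate_high = pw[["p_moderate_high"]],
        p_low_high = pw[["p_low_high"]],
        underpowered = any(cat_stats$n < 2)
      )
  }) |> dplyr::bind_rows()
}

#' Compare score and components across sociodemographic strata
#'
#' Means and SDs of the total score and each component within the levels of
#' each stratifying factor (sex, area of residence, SES class, age group,
#' school type where present), with a Kruskal-Wallis p-value per factor and
#' variable. Age groups follow the 12-15 / 16-19 split.
#'
#' @param scored A scored cohort (carrying the strata columns).
#' @param intakes Per-participant component intakes to summarise (typically
#'   energy-adjusted); `NULL` summarises the total score only.
#' @param factors Stratifying columns to use; single-level factors are
#'   skipped with a warning.
#' @param index Index definition.
#' @return A tidy tibble: `factor`, `level`, `variable`, `n`, `mean`, `sd`,
#'   `kw_p` (the factor-wide test, repeated across its levels), `stars`.
#' @export
compare_by_strata <- function(scored, intakes = NULL,
                              factors = c("sex", "area", "ses_class",
                                          "age_group", "school_type"),
                              index = tcrad_index()) {
  data <- as_tibble(scored)
  if ("age" %in% names(data) && !"age_group" %in% names(data)) {
    data$age_group <- ifelse(data$age <= 15, "12-15", "16-19")
  }
  if (!is.null(intakes)) {
    data <- dplyr::inner_join(
      data, dplyr::select(intakes, "participant_id",
                          dplyr::any_of(index$component)),
      by = "participant_id"
    )
  }
  vars <- c("total_score", intersect(index$component, names(data)))
  factors <- intersect(factors, names(data))
  purrr::map(factors, function(f) {
    fac <- as.factor(data[[f]])
    if (nlevels(droplevels(fac)) < 2) {
      warn(paste0("Factor `", f, "` has a single level; skipped."))
      return(NULL)
    }
    purrr::map(vars, function(v) {
      kw_p <- kruskal.test(data[[v]], droplevels(fac))$p.value
      data |>
        dplyr::summarise(n = dplyr::n(), mean = mean(.data[[v]]),
                         sd = sd(.data[[v]]), .by = dplyr::all_of(f)) |>
        dplyr::rename(level = dplyr::all_of(f)) |>
        dplyr::mutate(factor = f, variable = v, kw_p = kw_p,
                      stars = significance_stars(kw_p),
                      level = as.character(.data$level), .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Compare sample characteristics between groups
#'
#' The sample-characterization tests: chi-square (without continuity
#' correction by default) for categorical characteristics and Student's
#' t-test for continuous ones, comparing the levels of a grouping factor.
#'
#' @param participants Participant tibble.
#' @param by Grouping column (e.g. `"sex"` or `"area"`).
#' @param variables Characteristic columns to test; defaults to all columns
#'   except the id and the grouping column.
#' @param correct Continuity correction for 2x2 chi-square tables.
#' @return A tibble: `variable`, `test` ("chi-square" or "t-test"),
#'   `statistic`, `p_value`, `stars`.
#' @export
compare_characteristics <- function(participants, by,
                                    variables = NULL, correct = FALSE) {
  if (!by %in% names(participants)) {
    abort(paste0("Grouping column `", by, "` not found."))
  }
  g <- as.factor(participants[[by]])
  if (nlevels(droplevels(g)) < 2) abort("Grouping factor needs >= 2 levels.")
  if (is.null(variables)) {
    variables <- setdiff(names(participants), c("participant_id", by))
  }
  purrr::map(variables, function(v) {
    x <- participants[[v]]
    if (is.numeric(x)) {
      if (nlevels(droplevels(g)) != 2) {
        warn(paste0("t-test for `", v, "` needs exactly 2 groups; skipped."))
        return(NULL)
      }
      ht <- t.test(x ~ g)
      tibble(variable = v, test = "t-test",
             statistic = unname(ht$statistic), p_value = ht$p.value)
    } else {
      tab <- table(x, g)
      ht <- suppressWarnings(chisq.test(tab, correct = correct))
      tibble(variable = v, test = "chi-square",
             statistic = unname(ht$statistic), p_value = ht$p.value)
    }
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(stars = significance_stars(.data$p_value))
}

#' Score-category proportions by stratum
#'
#' Row-normalized percentages of low/moderate/high scores within each level
#' of a stratifying factor, rounded to 1 decimal — the crosstab used to
#' identify sociodemographic groups with suboptimal diet.
#'
#' @param scored A scored cohort.
#' @param factor_name Stratifying column (e.g. `"area"`, `"sex"`,
#'   `"ses_class"`).
#' @return A tibble: `level`, `n`, `pct_low`, `pct_moderate`, `pct_high`.
#'   Each row sums to 100 within rounding. Empty strata are omitted with a
#'   warning.
#' @export
category_proportions <- function(scored, factor_name) {
  data <- as_tibble(scored)
  if ("age" %in% names(data) && !"age_group" %in% names(data)) {
    data$age_group <- ifelse(data$age <= 15, "12-15", "16-19")
  }
  if (!factor_name %in% names(data)) {
    abort(paste0("Factor `", factor_name, "` not found in the cohort."))
  }
  if (anyNA(data[[factor_name]])) {
    warn("Participants with a missing stratum were dropped.")
    data <- data[!is.na(data[[factor_name]]), ]
  }
  data |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_low = round(100 * mean(.data$category == "low"), 1),
      pct_moderate = round(100 * mean(.data$category == "moderate"), 1),
      pct_high = round(100 * mean(.data$category == "high"), 1),
      .by = dplyr::all_of(factor_name)
    ) |>
    dplyr::rename(level = dplyr::all_of(factor_name)) |>
    dplyr::mutate(level = as.character(.data$level)) |>
    dplyr::arrange(.data$level)
}
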