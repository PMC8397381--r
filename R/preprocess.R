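#' Exclude energy-intake outliers by sex-specific percentiles
#'
#' Participants whose mean daily energy intake falls strictly below their
#' sex's 1st percentile or strictly above the 99th percentile are removed,
#' the standard screen for implausible reported intakes. Thresholds are
#' computed on the pre-exclusion distribution of per-participant mean
#' energies, separately by sex; values exactly equal to a threshold are
#' retained.
#'
#' @param records Wide food-record tibble (daily rows).
#' @param participants Participant tibble with `participant_id` and `sex`.
#' @param lower,upper Percentile bounds (defaults 0.01 and 0.99).
#' @param quantile_type Percentile definition passed to [stats::quantile()];
#'   type 7 is linear interpolation between order statistics.
#' @param min_per_sex Below this many participants of a sex, percentiles are
#'   unstable: that sex is left unfiltered with a warning.
#' @return A list with `records` (filtered daily rows) and `report`, a list
#'   of class `tcrad_exclusion` holding per-sex thresholds (kcal/day),
#'   excluded ids, and participant counts before/after.
#' @export
exclude_energy_outliers <- function(records, participants,
                                    lower = 0.01, upper = 0.99,
                                    quantile_type = 7, min_per_sex = 10) {
  mean_energy <- records |>
    dplyr::summarise(mean_energy = mean(.data$energy_kcal),
                     .by = "participant_id") |>
    dplyr::inner_join(
      dplyr::select(participants, "participant_id", "sex"),
      by = "participant_id"
    )
  if (anyNA(mean_energy$sex)) {
    abort("Every participant with records needs a known sex.")
  }
  thresholds <- mean_energy |>
    dplyr::summarise(
      n = dplyr::n(),
      lower_kcal = quantile(.data$mean_energy, lower, type = quantile_type,
                            names = FALSE),
      upper_kcal = quantile(.data$mean_energy, upper, type = quantile_type,
                            names = FALSE),
      .by = "sex"
    )
  small <- thresholds$sex[thresholds$n < min_per_sex]
  if (length(small)) {
    warn(paste0("Fewer than ", min_per_sex, " participants for sex: ",
                paste(small, collapse = ", "), "; no exclusion applied."))
  }
  flagged <- mean_energy |>
    dplyr::left_join(thresholds, by = "sex") |>
    dplyr::filter(!(.data$sex %in% small),
                  .data$mean_energy < .data$lower_kcal |
                    .data$mean_energy > .data$upper_kcal)
  n_before <- nrow(mean_energy)
  report <- structure(list(
    thresholds = dplyr::select(thresholds, "sex", "lower_kcal", "upper_kcal"),
    excluded_ids = flagged$participant_id,
    n_before = n_before,
    n_after = n_before - nrow(flagged)
  ), class = "tcrad_exclusion")
  list(
    records = dplyr::filter(records,
                            !.data$participant_id %in% flagged$participant_id),
    report = report
  )
}

#' @export
print.tcrad_exclusion <- function(x, ...) {
  cat("<tcrad_exclusion> ", length(x$excluded_ids), " of ", x$n_before,
      " participants excluded (", x$n_after, " remain)\n", sep = "")
  print(x$thresholds)
  invisible(x)
}

#' Estimate usual intake from repeated daily records
#'
#' Collapses 1-3 daily records per participant to one usual-intake value
#' per variable (food-group grams, energy, nutrients), either as the plain
#' person mean or by a one-way shrinkage estimator that pulls noisy person
#' means toward the population mean:
#' \deqn{u_i = \hat\mu + \lambda_i (\bar x_i - \hat\mu), \quad
#'       \lambda_i = \hat\sigma^2_b / (\hat\sigma^2_b + \hat\sigma^2_w / k_i)}
#' with variance components from the one-way person/day decomposition
#' (method of moments; a negative between-person estimate is truncated at
#' 0) and \eqn{k_i} the participant's number of recorded days. The
#' shrinkage estimator is a deliberately simple stand-in for full
#' usual-intake modeling; the default is the person mean.
#'
#' @param records Wide daily food-record tibble.
#' @param method `"mean"` or `"shrinkage"`.
#' @param variables Columns to collapse; defaults to every numeric column
#'   except `day`.
#' @return A tibble with one row per participant (`participant_id`,
#'   `n_days`, one column per variable). For the shrinkage method the
#'   per-variable variance components are attached as attribute
#'   `variance_components` (tibble: variable, sigma2_b, sigma2_w). The
#'   method used is attribute `method`.
#' @export
estimate_usual_intake <- function(records, method = c("mean", "shrinkage"),
                                  variables = NULL) {
  method <- match.arg(method)
  if (is.null(variables)) {
    variables <- setdiff(
      names(records)[vapply(records, is.numeric, logical(1))], "day"
    )
  }
  if (!nrow(records)) abort("No day rows to estimate from.")
  person <- records |>
    dplyr::summarise(
      n_days = dplyr::n(),
      dplyr::across(dplyr::all_of(variables), mean),
      .by = "participant_id"
    )
  if (method == "mean") {
    attr(person, "method") <- "mean"
    return(person)
  }
  N <- nrow(records)
  n <- nrow(person)
  if (all(person$n_days < 2)) {
    warn("Shrinkage needs repeated days for at least some participants; falling back to person means.")
    attr(person, "method") <- "mean"
    return(person)
  }
  # unbalanced one-way ANOVA coefficient for E[MSB] = sigma2_w + k0 sigma2_b
  k0 <- (N - sum(person$n_days^2) / N) / (n - 1)
  vc <- purrr::map(variables, function(v) {
    x <- records[[v]]
    idx <- match(records$participant_id, person$participant_id)
    xbar <- person[[v]][idx]
    ssw <- sum((x - xbar)^2)
    msw <- ssw / (N - n)
    grand <- sum(person$n_days * person[[v]]) / N
    msb <- sum(person$n_days * (person[[v]] - grand)^2) / (n - 1)
    s2b <- max(0, (msb - msw) / k0)
    tibble(variable = v, sigma2_b = s2b, sigma2_w = msw)
  }) |> dplyr::bind_rows()
  out <- person
  mu_hat <- vapply(variables, function(v) mean(person[[v]]), numeric(1))
  for (i in seq_along(variables)) {
    v <- variables[i]
    s2b <- vc$sigma2_b[i]
    s2w <- vc$sigma2_w[i]
    lambda <- if (s2b + s2w == 0) 1 else s2b / (s2b + s2w / person$n_days)
    out[[v]] <- mu_hat[i] + lambda * (person[[v]] - mu_hat[i])
  }
  attr(out, "method") <- "shrinkage"
  attr(out, "variance_components") <- vc
  out
}

#' Energy-adjust intake variables by the residual method
#'
#' Each variable is regressed on total energy by ordinary least squares and
#' replaced by its residual plus the value predicted at the sample mean
#' energy, so adjusted values sit on the variable's original scale, keep its
#' sample mean exactly, and are uncorrelated with energy. Negative adjusted
#' values can occur and are retained: scoring compares each participant to
#' the median of the same adjusted distribution, so only ranks matter.
#'
#' @param data Per-participant tibble containing the variables and an
#'   energy column.
#' @param variables Columns to adjust; defaults to every numeric column
#'   except the energy column and `n_days`.
#' @param energy_col Name of the energy column (kcal/day).
#' @return A tibble with `participant_id`, the energy column, and one
#'   adjusted column per variable; per-variable OLS intercepts and slopes
#'   are attached as attribute `fits`.
#' @export
energy_adjust <- function(data, variables = NULL, energy_col = "energy_kcal") {
  if (!energy_col %in% names(data)) {
    abort(paste0("Energy column `", energy_col, "` not found."))
  }
  if (nrow(data) < 3) abort("Energy adjustment needs at least 3 participants.")
  energy <- data[[energy_col]]
  if (sd(energy) == 0) {
    abort("Energy is constant; the regressor is degenerate.")
  }
  if (is.null(variables)) {
    variables <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(energy_col, "n_days", "day")
    )
  }
  mean_e <- mean(energy)
  fits <- vector("list", length(variables))
  out <- dplyr::select(data, dplyr::any_of("participant_id"),
                       dplyr::all_of(energy_col))
  for (i in seq_along(variables)) {
    v <- variables[i]
    ok <- is.finite(data[[v]])
    fit <- lm(data[[v]][ok] ~ energy[ok])
    adj <- rep(NA_real_, nrow(data))
    adj[ok] <- resid(fit) + (coef(fit)[1] + coef(fit)[2] * mean_e)
    out[[v]] <- adj
    fits[[i]] <- tibble(variable = v, intercept = unname(coef(fit)[1]),
                        slope = unname(coef(fit)[2]))
  }
  attr(out, "fits") <- dplyr::bind_rows(fits)
  out
}
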