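#' Configuration for the synthetic food-record cohort generator
#'
#' The generator emulates the structure of a 3-day food-record survey of
#' adolescents: per-person log-normal usual intakes for the 14 index food
#' groups, anchored at the sex-specific development-sample medians, with
#' multiplicative area-of-residence and socioeconomic-status effects sized
#' from the observed stratum means; within-person day-to-day variation on
#' the log scale; energy as a composition-weighted sum of food groups plus
#' a basal term and noise; and nutrients as linear combinations of food
#' groups plus noise.
#'
#' Stratum effects are centered on the log scale (rural and urban get
#' half the log-ratio with opposite signs; SES classes get -1/0/+1 times a
#' trend), so the population medians remain on the configured anchors.
#'
#' @param n Number of participants.
#' @param sex_prop Named proportions for `male`/`female` (must sum to 1).
#' @param area_prop Named proportions for `urban`/`rural`.
#' @param ses_prop Named proportions for SES classes `low`/`medium`/`high`;
#'   point scores are drawn uniformly within each class band.
#' @param median_anchors Tibble `component`, `sex`, `median_g_day`; defaults
#'   to the bundled development-sample medians.
#' @param sigma_b Between-person log-scale SD, recycled across components.
#' @param sigma_w Within-person (day-to-day) log-scale SD.
#' @param area_effect Named numeric, log(rural/urban) usual-intake ratio per
#'   component.
#' @param ses_trend Named numeric, per-class log step (low gets minus one
#'   step, high plus one) per component.
#' @param zero_inflation Named per-component probability that a person never
#'   consumes the food (usual intake 0). Default 0 for all.
#' @param kcal_per_g Named energy density per component, kcal/g.
#' @param basal_kcal Energy intake not captured by the 14 groups, kcal/day.
#' @param energy_noise_sd Day-level energy noise SD, kcal.
#' @param nutrient_loadings Matrix (nutrient x component) of nutrient units
#'   per gram of food group.
#' @param nutrient_noise_sd Named day-level noise SD per nutrient.
#' @param n_days Recorded days per participant (1-3).
#' @param seed Integer seed; all draws come from one stream seeded with it.
#' @return A list of class `tcrad_config`.
#' @export
cohort_config <- function(n = 804,
                          sex_prop = c(male = 0.36, female = 0.64),
                          area_prop = c(urban = 0.5, rural = 0.5),
                          ses_prop = c(low = 0.32, medium = 0.40, high = 0.28),
                          median_anchors = default_median_anchors(),
                          sigma_b = 0.5,
                          sigma_w = 0.6,
                          area_effect = default_area_effects(),
                          ses_trend = default_ses_trends(),
                          zero_inflation = NULL,
                          kcal_per_g = default_energy_densities(),
                          basal_kcal = 700,
                          energy_noise_sd = 150,
                          nutrient_loadings = default_nutrient_loadings(),
                          nutrient_noise_sd = default_nutrient_noise(),
                          n_days = 3,
                          seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a positive participant count.")
  }
  check_prop <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      abort(paste0("`", what, "` must be non-negative and sum to 1."))
    }
  }
  check_prop(sex_prop, "sex_prop")
  check_prop(area_prop, "area_prop")
  check_prop(ses_prop, "ses_prop")
  if (any(sigma_b < 0) || any(sigma_w < 0)) {
    abort("Log-scale SDs must be >= 0.")
  }
  if (any(median_anchors$median_g_day < 0)) {
    abort("Median anchors must be >= 0 g/day.")
  }
  components <- unique(median_anchors$component)
  zi <- setNames(rep(0, length(components)), components)
  if (!is.null(zero_inflation)) zi[names(zero_inflation)] <- zero_inflation
  structure(list(
    n = as.integer(n), sex_prop = sex_prop, area_prop = area_prop,
    ses_prop = ses_prop, median_anchors = median_anchors,
    sigma_b = expand_named(sigma_b, components, "sigma_b"),
    sigma_w = expand_named(sigma_w, components, "sigma_w"),
    area_effect = expand_named(area_effect, components, "area_effect", 0),
    ses_trend = expand_named(ses_trend, components, "ses_trend", 0),
    zero_inflation = zi,
    kcal_per_g = expand_named(kcal_per_g, components, "kcal_per_g"),
    basal_kcal = basal_kcal, energy_noise_sd = energy_noise_sd,
    nutrient_loadings = nutrient_loadings,
    nutrient_noise_sd = nutrient_noise_sd,
    n_days = as.integer(n_days), seed = as.integer(seed),
    components = components
  ), class = "tcrad_config")
}

# Recycle a scalar or fill a partially-named vector over all components.
expand_named <- function(x, components, what, fill = NA_real_) {
  if (is.null(names(x))) {
    if (length(x) == 1) return(setNames(rep(x, length(components)), components))
    if (length(x) == length(components)) return(setNames(x, components))
    abort(paste0("`", what, "` must be scalar, named, or full-length."))
  }
  out <- setNames(rep(fill, length(components)), components)
  known <- intersect(names(x), components)
  out[known] <- x[known]
  if (anyNA(out)) {
    abort(paste0("`", what, "` missing value for: ",
                 paste(components[is.na(out)], collapse = ", ")))
  }
  out
}

#' Default usual-intake median anchors (g/day)
#'
#' Sex-specific medians of the 14 TCRAD food groups in the development
#' sample, used as the generator's central anchors.
#'
#' @return Tibble `component`, `sex`, `median_g_day`.
#' @export
default_median_anchors <- function() {
  load_cutoffs("table1_fixture") |>
    dplyr::rename(median_g_day = "cutoff")
}

#' Default area-of-residence effects
#'
#' log(rural/urban) usual-intake ratios per component, sized from the
#' development sample's stratum means: rural adolescents eat more beans,
#' vegetables, oils and white rice; urban adolescents more dairy, solid
#' fats, sugary drinks, bread, snacks and fast food.
#'
#' @return Named numeric vector.
#' @export
default_area_effects <- function() {
  c(legumes = 0.352, vegetables = 0.409, fruits = 0.092,
    vegetable_oils = 0.249, dairy = -0.213, tortillas = 0.059,
    white_rice = 0.303, red_meat = -0.089, solid_fats = -0.420,
    desserts = 0.103, sugary_drinks = -0.298, snacks = -0.144,
    fast_food = -0.196, refined_bread = -0.190)
}

#' Default socioeconomic-status trends
#'
#' Per-class log steps (half the observed log high/low ratio): high-SES
#' adolescents eat more dairy, sugary drinks, bread and fast food, and less
#' white rice, beans and vegetable oils.
#'
#' @return Named numeric vector.
#' @export
default_ses_trends <- function() {
  c(legumes = -0.258, vegetables = -0.072, fruits = -0.058,
    vegetable_oils = -0.123, dairy = 0.185, tortillas = 0.103,
    white_rice = -0.279, red_meat = 0.039, solid_fats = 0.013,
    desserts = 0.031, sugary_drinks = 0.069, snacks = 0.001,
    fast_food = 0.281, refined_bread = 0.063)
}

#' Default energy densities (kcal per g)
#'
#' Typical as-consumed energy densities for each food group; oils and solid
#' fats are near pure fat, beverages are dilute.
#'
#' @return Named numeric vector.
#' @export
default_energy_densities <- function() {
  c(legumes = 1.2, vegetables = 0.3, fruits = 0.5, vegetable_oils = 8.8,
    dairy = 0.8, tortillas = 2.2, white_rice = 1.3, red_meat = 2.5,
    solid_fats = 7.2, desserts = 3.5, sugary_drinks = 0.45, snacks = 5.0,
    fast_food = 2.8, refined_bread = 3.0)
}

#' Default nutrient loading matrix
#'
#' Nutrient units per gram of food group, with fiber, folate, magnesium and
#' potassium concentrated on legumes, vegetables and fruits, and saturated
#' fat on solid fats, red meat, desserts, snacks and fast food — the sign
#' structure a traditional-diet score should detect.
#'
#' @return Matrix, nutrients in rows, components in columns.
#' @export
default_nutrient_loadings <- function() {
  comps <- c("legumes", "vegetables", "fruits", "vegetable_oils", "dairy",
             "tortillas", "white_rice", "red_meat", "solid_fats", "desserts",
             "sugary_drinks", "snacks", "fast_food", "refined_bread")
  L <- rbind(
    fiber_g         = c(0.055, 0.020, 0.017, 0, 0, 0.050, 0.004, 0, 0, 0.005, 0, 0.020, 0.005, 0.010),
    folate_ug       = c(1.50, 0.40, 0.20, 0, 0.05, 0.30, 0.05, 0.05, 0, 0.10, 0, 0.05, 0.10, 0.20),
    magnesium_mg    = c(0.45, 0.20, 0.12, 0, 0.11, 0.70, 0.12, 0.10, 0, 0.10, 0.01, 0.20, 0.10, 0.15),
    potassium_mg    = c(3.60, 2.40, 1.90, 0, 1.50, 1.00, 0.30, 2.00, 0.10, 0.80, 0.05, 2.00, 1.50, 0.80),
    saturated_fat_g = c(0.001, 0, 0, 0.14, 0.017, 0.002, 0.001, 0.070, 0.350, 0.050, 0, 0.030, 0.040, 0.015),
    protein_g       = c(0.085, 0.012, 0.007, 0, 0.035, 0.025, 0.025, 0.200, 0.005, 0.040, 0.001, 0.060, 0.080, 0.090),
    carbohydrate_g  = c(0.200, 0.050, 0.120, 0, 0.050, 0.450, 0.280, 0, 0.010, 0.450, 0.110, 0.550, 0.250, 0.550),
    total_fat_g     = c(0.005, 0.002, 0.002, 1.00, 0.030, 0.020, 0.003, 0.120, 0.800, 0.120, 0, 0.300, 0.120, 0.050)
  )
  colnames(L) <- comps
  L
}

#' Default nutrient day-level noise SDs
#'
#' @return Named numeric vector, units of each nutrient.
#' @export
default_nutrient_noise <- function() {
  c(fiber_g = 0.8, folate_ug = 25, magnesium_mg = 10, potassium_mg = 80,
    saturated_fat_g = 1.0, protein_g = 3, carbohydrate_g = 10,
    total_fat_g = 2)
}

#' Generate a synthetic 3-day food-record cohort
#'
#' For participant i in stratum (sex, area, SES class), true usual intake of
#' component c is
#' \deqn{T_{ic} = m_{c,sex(i)} \exp(\delta_c a_i + \theta_c s_i + \sigma_b z_{ic})}
#' with \eqn{a_i = \pm 1/2} for rural/urban, \eqn{s_i \in \{-1,0,1\}} for
#' SES class, and \eqn{z} standard normal. Daily intake is
#' \eqn{x_{icd} = T_{ic}\exp(\sigma_w \varepsilon_{icd} - \sigma_w^2/2)},
#' so day-level means are unbiased for the usual intake and population
#' medians stay on the configured anchors. Daily energy is
#' \eqn{E_{id} = \sum_c K_c x_{icd} + \mathrm{basal} + \mathrm{noise}} and
#' each nutrient a linear combination of the day's food groups plus noise.
#' Negative energy/nutrient noise excursions are truncated at 0.
#'
#' @param config A [cohort_config()].
#' @return A list of class `tcrad_cohort` with elements
#'   * `records` — wide daily food-record tibble (participant_id, day,
#'     weekday_type, component g/day columns, energy_kcal, nutrients);
#'   * `participants` — one row per participant with sex, age, area,
#'     school_type, ses_points, ses_class;
#'   * `truth` — the true usual intakes actually drawn, long form, plus the
#'     applied stratum multipliers as attribute `stratum_effects`.
#' @examples
#' sim <- generate_cohort(cohort_config(n = 50, seed = 42))
#' dplyr::glimpse(sim$records)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "tcrad_config"))
  set.seed(config$seed)
  n <- config$n
  comps <- config$components
  p <- length(comps)

  sex <- sample(names(config$sex_prop), n, replace = TRUE,
                prob = config$sex_prop)
  area <- sample(names(config$area_prop), n, replace = TRUE,
                 prob = config$area_prop)
  ses_class <- sample(names(config$ses_prop), n, replace = TRUE,
                      prob = config$ses_prop)
  ses_points <- integer(n)
  ses_points[ses_class == "low"] <- sample(0:29, sum(ses_class == "low"), TRUE)
  ses_points[ses_class == "medium"] <- sample(30:84, sum(ses_class == "medium"), TRUE)
  ses_points[ses_class == "high"] <- sample(85:100, sum(ses_class == "high"), TRUE)
  age <- sample(13:18, n, replace = TRUE)
  school_type <- sample(c("public", "private"), n, replace = TRUE,
                        prob = c(0.8, 0.2))
  id <- sprintf("P%04d", seq_len(n))

  anchors <- config$median_anchors |>
    tidyr::pivot_wider(names_from = "sex", values_from = "median_g_day")
  anchors <- anchors[match(comps, anchors$component), ]
  m <- ifelse(matrix(sex == "male", n, p),
              matrix(anchors$male, n, p, byrow = TRUE),
              matrix(anchors$female, n, p, byrow = TRUE))

  a_sign <- ifelse(area == "rural", 0.5, -0.5)
  s_sign <- c(low = -1, medium = 0, high = 1)[ses_class]
  log_effect <- outer(a_sign, config$area_effect) +
    outer(s_sign, config$ses_trend)
  z <- matrix(rnorm(n * p), n, p)
  truth <- m * exp(log_effect + sweep(z, 2, config$sigma_b, `*`))
  zi <- config$zero_inflation
  if (any(zi > 0)) {
    never <- matrix(runif(n * p), n, p) <
      matrix(zi, n, p, byrow = TRUE)
    truth[never] <- 0
  }
  colnames(truth) <- comps

  k <- config$n_days
  day_rows <- vector("list", k)
  for (d in seq_len(k)) {
    eps <- matrix(rnorm(n * p), n, p)
    x <- truth * exp(sweep(eps, 2, config$sigma_w, `*`) -
                       matrix(config$sigma_w^2 / 2, n, p, byrow = TRUE))
    energy <- pmax(0, drop(x %*% config$kcal_per_g) + config$basal_kcal +
                     rnorm(n, 0, config$energy_noise_sd))
    L <- config$nutrient_loadings[, comps, drop = FALSE]
    nut <- x %*% t(L)
    for (j in rownames(L)) {
      nut[, j] <- pmax(0, nut[, j] + rnorm(n, 0, config$nutrient_noise_sd[[j]]))
    }
    day_rows[[d]] <- dplyr::bind_cols(
      tibble(participant_id = id, day = d,
             weekday_type = if (d < 3) "weekday" else "weekend"),
      as_tibble(x), tibble(energy_kcal = energy), as_tibble(nut)
    )
  }
  records <- dplyr::bind_rows(day_rows) |>
    dplyr::arrange(.data$participant_id, .data$day)

  participants <- tibble(
    participant_id = id, sex = sex, age = age, area = area,
    school_type = school_type, ses_points = ses_points,
    ses_class = factor(ses_class, levels = c("low", "medium", "high"),
                       ordered = TRUE)
  )
  truth_tbl <- as_tibble(truth) |>
    dplyr::mutate(participant_id = id, .before = 1) |>
    tidyr::pivot_longer(-"participant_id", names_to = "component",
                        values_to = "true_usual")
  attr(truth_tbl, "stratum_effects") <- list(
    area_effect = config$area_effect, ses_trend = config$ses_trend
  )
  structure(list(records = records, participants = participants,
                 truth = truth_tbl, config = config),
            class = "tcrad_cohort")
}

#' @export
print.tcrad_cohort <- function(x, ...) {
  cat("<tcrad_cohort> ", nrow(x$participants), " participants x ",
      x$config$n_days, " days, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Inject implausible energy intakes
#'
#' Scales the reported energy of a small fraction of participants by a
#' multiplier (half of them upward, half downward by the reciprocal), to
#' exercise the percentile-based outlier exclusion. The fraction is capped
#' at 5% so the 1st/99th-percentile semantics stay meaningful.
#'
#' @param records Wide food-record tibble.
#' @param fraction Proportion of participants to contaminate (0 to 0.05).
#' @param magnitude Multiplier (> 1) applied to energy.
#' @param seed Integer seed for selecting participants.
#' @param participants Optional participant tibble with `sex`; when given,
#'   contamination is stratified by sex (the outlier filter is sex-specific,
#'   so unstratified contamination can overload one sex's 1% tail).
#' @return The records with modified `energy_kcal`; the contaminated ids and
#'   directions are attached as attribute `injected`.
#' @export
inject_energy_outliers <- function(records, fraction, magnitude, seed = 1L,
                                   participants = NULL) {
  if (fraction < 0 || fraction > 0.05) {
    abort("`fraction` must lie in [0, 0.05].")
  }
  if (magnitude <= 1) abort("`magnitude` must exceed 1.")
  ids <- unique(records$participant_id)
  set.seed(seed)
  if (is.null(participants)) {
    strata <- list(ids)
  } else {
    sex <- participants$sex[match(ids, participants$participant_id)]
    strata <- split(ids, sex)
  }
  chosen <- character()
  dir <- character()
  for (st in strata) {
    k <- round(fraction * length(st))
    if (k == 0) next
    pick <- sample(st, k)
    chosen <- c(chosen, pick)
    dir <- c(dir, rep(c("up", "down"), length.out = k))
  }
  n_inj <- length(chosen)
  if (n_inj == 0) {
    attr(records, "injected") <- tibble(participant_id = character(),
                                        direction = character())
    return(records)
  }
  mult <- setNames(ifelse(dir == "up", magnitude, 1 / magnitude), chosen)
  hit <- records$participant_id %in% chosen
  records$energy_kcal[hit] <-
    records$energy_kcal[hit] * mult[records$participant_id[hit]]
  attr(records, "injected") <- tibble(participant_id = chosen, direction = dir)
  records
}
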