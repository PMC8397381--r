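test_that("derived cutoffs are within-sex sample medians", {
  idx <- tcrad_index()
  ids <- c(sprintf("m%d", 1:5), sprintf("f%d", 1:4))
  intakes <- flat_records(ids, energy = rep(2000, 9))[, -2] |>
    dplyr::mutate(energy_kcal = NULL)
  intakes$legumes <- c(10, 20, 30, 40, 50, 10, 20, 30, 40)
  parts <- small_participants(ids, c(rep("male", 5), rep("female", 4)))
  cuts <- derive_cutoffs(intakes, parts, idx)
  expect_equal(cutoff_for(cuts, "legumes", "male"), 30)   # odd n
  expect_equal(cutoff_for(cuts, "legumes", "female"), 25) # even n midpoint
  expect_equal(cutoff_for(cuts, "dairy", "female"), 10)   # constant intake
  expect_equal(attr(cuts, "provenance"), "derived")
})

test_that("derivation requires both sexes and warns on zero cutoffs", {
  idx <- tcrad_index()
  ids <- sprintf("m%d", 1:5)
  intakes <- flat_records(ids, energy = rep(2000, 5)) |>
    dplyr::select(-"day", -"energy_kcal")
  expect_error(derive_cutoffs(intakes, small_participants(ids, "male"), idx),
               "female")
  ids2 <- c("m1", "m2", "f1", "f2")
  intakes2 <- flat_records(ids2, energy = rep(2000, 4), intake = 0) |>
    dplyr::select(-"day", -"energy_kcal")
  parts2 <- small_participants(ids2, c("male", "male", "female", "female"))
  expect_warning(derive_cutoffs(intakes2, parts2, idx), "zero cutoff|0 g/day")
})

test_that("component points follow the meeting-or-exceeding rule with strict inversion", {
  expect_equal(score_component(42.9, 42.9, "healthy"), 1L)
  expect_equal(score_component(42.8, 42.9, "healthy"), 0L)
  expect_equal(score_component(230.10, 230.10, "unhealthy"), 0L)
  expect_equal(score_component(0, 230.10, "unhealthy"), 1L)
  expect_equal(score_component(c(5, 10, 15), 10, "healthy"), c(0L, 1L, 1L))
})

test_that("worked profiles built from the reference cutoffs score 14, 0 and 6", {
  cuts <- load_cutoffs()
  idx <- tcrad_index()
  best <- profile_at_cutoffs(cuts, idx, healthy_mult = 1, unhealthy_val = 0)
  expect_equal(compute_tcrad(best, "male", cuts, idx), 14L)
  worst <- sapply(idx$component, function(comp) {
    cut <- cutoff_for(cuts, comp, "male")
    if (idx$direction[idx$component == comp] == "healthy") cut * 0.5 else cut
  })
  expect_equal(compute_tcrad(worst, "male", cuts, idx), 0L)
  at_cut <- sapply(idx$component, function(comp) cutoff_for(cuts, comp, "male"))
  expect_equal(compute_tcrad(at_cut, "male", cuts, idx), 6L)
})

test_that("a missing component intake is a scoring error naming the component", {
  cuts <- load_cutoffs()
  idx <- tcrad_index()
  prof <- profile_at_cutoffs(cuts, idx)
  expect_error(compute_tcrad(prof[-1], "male", cuts, idx), "legumes")
})

test_that("compute_tcrad agrees exactly with the brute-force oracle on random profiles", {
  cuts <- load_cutoffs()
  idx <- tcrad_index()
  set.seed(41)
  for (i in 1:200) {
    sex <- sample(c("male", "female"), 1)
    prof <- setNames(runif(14, 0, 2) *
                       sapply(idx$component, cutoff_for, cutoffs = cuts,
                              sex = sex),
                     idx$component)
    expect_identical(compute_tcrad(prof, sex, cuts, idx),
                     as.integer(brute_score(as.list(prof), sex, cuts, idx)))
  }
})

test_that("raising healthy intake never lowers the score; raising unhealthy never raises it", {
  cuts <- load_cutoffs()
  idx <- tcrad_index()
  set.seed(43)
  for (i in 1:50) {
    prof <- setNames(runif(14, 0, 300), idx$component)
    s0 <- compute_tcrad(prof, "female", cuts, idx)
    comp <- sample(idx$component, 1)
    bumped <- prof
    bumped[comp] <- bumped[comp] + runif(1, 0, 200)
    s1 <- compute_tcrad(bumped, "female", cuts, idx)
    if (idx$direction[idx$component == comp] == "healthy") {
      expect_gte(s1, s0)
    } else {
      expect_lte(s1, s0)
    }
  }
})

test_that("component order in the index does not change totals", {
  cuts <- load_cutoffs()
  idx <- tcrad_index()
  set.seed(47)
  shuffled <- index_definition(
    rev(idx$component), rev(idx$direction), rev(idx$label)
  )
  for (i in 1:20) {
    prof <- setNames(runif(14, 0, 300), idx$component)
    expect_equal(compute_tcrad(prof, "male", cuts, idx),
                 compute_tcrad(prof, "male", cuts, shuffled))
  }
})

test_that("score bands and SES bands follow the published rules", {
  expect_equal(as.character(categorize_score(c(0, 5, 6, 7, 8, 14))),
               c("low", "low", "moderate", "moderate", "high", "high"))
  expect_error(categorize_score(15), "\\[0, 14\\]")
  expect_equal(as.character(classify_ses(c(0, 29, 30, 84, 85, 100))),
               c("low", "low", "medium", "medium", "high", "high"))
  expect_error(classify_ses(101), "\\[0, 100\\]")
})

test_that("cohort scoring composes the verified parts and keeps the sum identity", {
  cuts <- load_cutoffs()
  idx <- tcrad_index()
  best <- profile_at_cutoffs(cuts, idx, healthy_mult = 1, unhealthy_val = 0)
  worst <- sapply(idx$component, function(comp) {
    cut <- cutoff_for(cuts, comp, "male")
    if (idx$direction[idx$component == comp] == "healthy") cut * 0.5 else cut
  })
  at_cut <- sapply(idx$component, function(comp) cutoff_for(cuts, comp, "male"))
  intakes <- dplyr::bind_rows(as.list(best), as.list(worst),
                              as.list(at_cut)) |>
    dplyr::mutate(participant_id = c("a", "b", "c"), .before = 1)
  parts <- tibble::tibble(participant_id = c("a", "b", "c"), sex = "male",
                          ses_points = c(10L, 50L, 90L))
  sc <- score_cohort(intakes, parts, cutoffs = cuts)
  expect_equal(sc$total_score, c(14, 0, 6))
  expect_equal(as.character(sc$category), c("high", "low", "moderate"))
  expect_equal(as.character(sc$ses_class), c("low", "medium", "high"))
  pts <- dplyr::select(tibble::as_tibble(sc), dplyr::starts_with("points_"))
  expect_equal(rowSums(pts), sc$total_score)
})

test_that("an empty cohort scores to an empty result without error", {
  idx <- tcrad_index()
  empty_intakes <- flat_records(character(), numeric())[0, ] |>
    dplyr::select(-"day", -"energy_kcal")
  empty_parts <- tibble::tibble(participant_id = character(),
                                sex = character())
  sc <- score_cohort(empty_intakes, empty_parts, cutoffs = load_cutoffs())
  expect_equal(nrow(sc), 0)
  expect_true(all(c("total_score", "category") %in% names(sc)))
})

test_that("derived-cutoff scoring halves each component at moderate n", {
  sim <- generate_cohort(cohort_config(n = 2000, seed = 17))
  u <- estimate_usual_intake(sim$records)
  sc <- score_cohort(u, sim$participants, cutoffs = "derive")
  pts <- dplyr::select(tibble::as_tibble(sc), dplyr::starts_with("points_"))
  prev <- 100 * colMeans(pts)
  expect_true(all(prev >= 45 & prev <= 55))
})

test_that("tidy and glance views are consistent with the scored tibble", {
  sim <- generate_cohort(cohort_config(n = 60, seed = 19))
  u <- estimate_usual_intake(sim$records)
  sc <- score_cohort(u, sim$participants, cutoffs = load_cutoffs())
  td <- tidy(sc)
  expect_equal(nrow(td), 60 * 14)
  totals <- td |>
    dplyr::summarise(s = sum(points), .by = "participant_id")
  expect_equal(totals$s[match(sc$participant_id, totals$participant_id)],
               sc$total_score)
  gl <- glance(sc)
  expect_equal(gl$n, 60)
  expect_equal(gl$mean_score, mean(sc$total_score))
  expect_equal(gl$pct_low + gl$pct_moderate + gl$pct_high, 100)
})
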