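make_scored <- function(n = 60, seed = 23) {
  sim <- generate_cohort(cohort_config(n = n, seed = seed))
  u <- estimate_usual_intake(sim$records)
  list(sim = sim, usual = u,
       scored = score_cohort(u, sim$participants, cutoffs = load_cutoffs()))
}

test_that("monotone nutrients give rank correlation +/-1 and ties match the rank oracle", {
  s <- make_scored(40)
  nut <- tibble::tibble(
    participant_id = s$scored$participant_id,
    up = s$scored$total_score * 2 + 1,
    down = -s$scored$total_score
  )
  ct <- correlate_score_nutrients(s$scored, nut)
  expect_equal(ct$rho[ct$nutrient == "up"], 1)
  expect_equal(ct$rho[ct$nutrient == "down"], -1)

  toy_score <- c(3, 5, 5, 8, 10)
  toy_nut <- c(1.2, 4.4, 2.2, 4.4, 9.0)  # one tie
  sc_toy <- structure(
    tibble::tibble(participant_id = letters[1:5], total_score = toy_score,
                   category = categorize_score(toy_score)),
    class = c("tcrad_scored", class(tibble::tibble()))
  )
  ct_toy <- correlate_score_nutrients(
    sc_toy, tibble::tibble(participant_id = letters[1:5], v = toy_nut)
  )
  expect_equal(ct_toy$rho, spearman_oracle(toy_score, toy_nut))
})

test_that("a constant nutrient reports an undefined correlation, not zero", {
  s <- make_scored(30)
  nut <- tibble::tibble(participant_id = s$scored$participant_id, flat = 5)
  ct <- correlate_score_nutrients(s$scored, nut)
  expect_true(is.na(ct$rho))
  expect_true(is.na(ct$p_value))
})

test_that("significance stars are monotone in p and p-values lie in [0, 1]", {
  s <- make_scored(120, seed = 29)
  nutrient_cols <- c("fiber_g", "folate_ug", "saturated_fat_g")
  ct <- correlate_score_nutrients(
    s$scored, dplyr::select(s$usual, "participant_id",
                            dplyr::all_of(nutrient_cols))
  )
  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))
  ord <- order(ct$p_value)
  expect_true(all(diff(nchar(ct$stars[ord])) <= 0))
})

test_that("category medians report per-category cells with group and pairwise tests", {
  s <- make_scored(300, seed = 31)
  adj <- energy_adjust(s$usual)
  tab <- medians_by_category(s$scored, adj)
  leg <- tab[tab$component == "legumes", ]
  overall <- leg[leg$category == "overall", ]
  expect_equal(overall$n, sum(leg$n[leg$category != "overall"]))
  expect_true(all(is.finite(leg$kw_p)))
  expect_true(all(c("p_low_moderate", "p_moderate_high", "p_low_high")
                  %in% names(tab)))
})

test_that("single-participant categories yield their own values and an underpowered flag", {
  idx <- tcrad_index()
  intakes <- flat_records(c("a", "b", "c"), energy = c(1, 2, 3)) |>
    dplyr::select(-"day", -"energy_kcal")
  intakes$legumes <- c(5, 50, 500)
  scored <- structure(
    tibble::tibble(participant_id = c("a", "b", "c"),
                   total_score = c(2, 6, 10),
                   category = categorize_score(c(2, 6, 10))),
    class = c("tcrad_scored", class(tibble::tibble()))
  )
  tab <- medians_by_category(scored, intakes, idx)
  leg <- tab[tab$component == "legumes", ]
  expect_equal(leg$median[leg$category == "low"], 5)
  expect_equal(leg$median[leg$category == "high"], 500)
  expect_true(all(leg$underpowered))
})

test_that("an upward-shifted component separates low and high categories", {
  set.seed(37)
  n <- 200
  category <- categorize_score(rep(c(2, 6, 9), length.out = n))
  legumes <- rlnorm(n, log(40), 0.4)
  legumes[category == "high"] <- legumes[category == "high"] * 1.5
  scored <- structure(
    tibble::tibble(participant_id = as.character(1:n),
                   total_score = rep(c(2, 6, 9), length.out = n),
                   category = category),
    class = c("tcrad_scored", class(tibble::tibble()))
  )
  intakes <- flat_records(as.character(1:n), energy = rep(1, n)) |>
    dplyr::select(-"day", -"energy_kcal")
  intakes$legumes <- legumes[match(intakes$participant_id, as.character(1:n))]
  tab <- medians_by_category(scored, intakes)
  expect_lt(tab$p_low_high[tab$component == "legumes"][1], 0.05)
})

test_that("stratum summaries cover every factor level and detect the rural score gap", {
  s <- make_scored(2000, seed = 39)
  sc <- score_cohort(s$usual, s$sim$participants, cutoffs = "derive")
  tab <- compare_by_strata(sc)
  area <- tab[tab$factor == "area" & tab$variable == "total_score", ]
  expect_equal(sum(area$n), nrow(sc))
  expect_gt(area$mean[area$level == "rural"],
            area$mean[area$level == "urban"])
  sexes <- tab[tab$factor == "sex" & tab$variable == "total_score", ]
  expect_equal(sum(sexes$n), nrow(sc))
})

test_that("single-level factors are skipped with a warning", {
  s <- make_scored(40, seed = 41)
  sc <- s$scored
  sc$area <- "urban"
  expect_warning(tab <- compare_by_strata(sc), "area")
  expect_false("area" %in% tab$factor)
})

test_that("characteristic comparisons match closed-form chi-square and degenerate t", {
  parts <- tibble::tibble(
    participant_id = as.character(1:60),
    grp = rep(c("g1", "g2"), each = 30),
    cat = c(rep("x", 10), rep("y", 20), rep("x", 20), rep("y", 10)),
    cont = rep(c(1, 2, 3), 20)
  )
  res <- compare_characteristics(parts, by = "grp")
  # 2x2 table {{10,20},{20,10}}: chi-square without continuity correction
  # is N (ad-bc)^2 / (r1 r2 c1 c2) = 60*(100-400)^2/30^4 = 20/3
  expect_equal(res$statistic[res$variable == "cat"], 20 / 3,
               tolerance = 1e-12)
  expect_equal(res$statistic[res$variable == "cont"], 0)
  expect_equal(res$p_value[res$variable == "cont"], 1)
})

test_that("category proportions are row-normalized percentages", {
  scored <- structure(
    tibble::tibble(participant_id = as.character(1:40),
                   total_score = rep(14, 40),
                   category = categorize_score(rep(14, 40)),
                   area = rep(c("urban", "rural"), 20)),
    class = c("tcrad_scored", class(tibble::tibble()))
  )
  tab <- category_proportions(scored, "area")
  expect_equal(tab$pct_low, c(0, 0))
  expect_equal(tab$pct_moderate, c(0, 0))
  expect_equal(tab$pct_high, c(100, 100))

  set.seed(43)
  mixed <- structure(
    tibble::tibble(participant_id = as.character(1:500),
                   total_score = sample(0:14, 500, TRUE),
                   category = categorize_score(sample(0:14, 500, TRUE)),
                   area = sample(c("urban", "rural"), 500, TRUE)),
    class = c("tcrad_scored", class(tibble::tibble()))
  )
  tab2 <- category_proportions(mixed, "area")
  expect_true(all(abs(tab2$pct_low + tab2$pct_moderate + tab2$pct_high - 100)
                  <= 0.1))
})

test_that("uniform random scores put about 7/15 of participants in the high band", {
  set.seed(47)
  scores <- sample(0:14, 10000, TRUE)
  scored <- structure(
    tibble::tibble(participant_id = as.character(1:10000),
                   total_score = scores,
                   category = categorize_score(scores),
                   area = "all"),
    class = c("tcrad_scored", class(tibble::tibble()))
  )
  tab <- category_proportions(scored, "area")
  expect_lt(abs(tab$pct_high - 100 * 7 / 15), 2)
})
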