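# Independent brute-force scorer: explicit 14-term loop with hand-written
# comparisons, deliberately not sharing code with compute_tcrad().
brute_score <- function(intakes, sex, cutoffs, index) {
  total <- 0
  for (comp in index$component) {
    cut <- cutoffs$cutoff[cutoffs$component == comp & cutoffs$sex == sex]
    dir <- index$direction[index$component == comp]
    x <- intakes[[comp]]
    pt <- if (dir == "healthy") {
      if (x >= cut) 1 else 0
    } else {
      if (x < cut) 1 else 0
    }
    total <- total + pt
  }
  total
}

# Spearman rho by explicit average-rank computation + Pearson on ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# A male profile at the cutoff for healthy components and `unhealthy_at`
# times the cutoff for unhealthy ones.
profile_at_cutoffs <- function(cutoffs, index, sex = "male",
                               healthy_mult = 1, unhealthy_val = 0) {
  sapply(index$component, function(comp) {
    cut <- cutoffs$cutoff[cutoffs$component == comp & cutoffs$sex == sex]
    if (index$direction[index$component == comp] == "healthy") {
      healthy_mult * cut
    } else {
      unhealthy_val
    }
  })
}

# Minimal daily-record tibble: one participant per row of `energy` with
# `days` identical day rows, all components at a constant intake.
flat_records <- function(ids, energy, days = 1, intake = 10,
                         index = tcrad_index()) {
  grid <- tidyr::expand_grid(participant_id = ids, day = seq_len(days))
  comp_cols <- setNames(
    lapply(index$component, function(x) rep(intake, nrow(grid))),
    index$component
  )
  dplyr::bind_cols(
    grid,
    tibble::as_tibble(comp_cols),
    tibble::tibble(energy_kcal = rep(energy, each = days))
  )
}

small_participants <- function(ids, sex = "male") {
  tibble::tibble(participant_id = ids,
                 sex = rep_len(sex, length(ids)))
}
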