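# Small deterministic fixture cohort built in code: two females and two
# males spanning the three groups, with one skipped endpoint activity
# test and one death, so missing-data paths are exercised everywhere.

fixture_animals <- function() {
  tibble::tibble(
    animal_id = c("f_a1", "f_o1", "m_a1", "m_o1"),
    sex = c("female", "female", "male", "male"),
    group = c("adult", "old_vehicle", "adult", "old_pdx"),
    alive_at_endpoint = c(TRUE, TRUE, TRUE, FALSE)
  )
}

fixture_trial_block <- function(id, tp, ws, grip, td, act) {
  dplyr::bind_rows(
    tibble::tibble(animal_id = id, timepoint = tp, test = "walking_speed",
                   trial_index = 1:3, value = ws),
    tibble::tibble(animal_id = id, timepoint = tp, test = "grip_strength",
                   trial_index = 1:5, value = grip),
    tibble::tibble(animal_id = id, timepoint = tp, test = "endurance",
                   trial_index = 1L, value = td),
    if (!is.null(act)) {
      tibble::tibble(animal_id = id, timepoint = tp, test = "activity",
                     trial_index = 1:4, value = act)
    }
  )
}

fixture_trials <- function() {
  dplyr::bind_rows(
    fixture_trial_block("f_a1", "baseline",
                        c(10, 14, 12), c(10, 12, 14, 16, 18), 116,
                        c(2, 3, 4, 3)),
    fixture_trial_block("f_a1", "endpoint",
                        c(11, 13, 12), c(11, 12, 14, 16, 17), 118,
                        c(3, 3, 4, 2)),
    fixture_trial_block("f_o1", "baseline",
                        c(7, 7, 7), c(8, 8, 8, 8, 20), 70,
                        c(1, 1, 1, 5)),
    # endpoint activity skipped -> vrw missing at endpoint
    fixture_trial_block("f_o1", "endpoint",
                        c(6, 8, 7), c(7, 8, 8, 9, 10), 56, NULL),
    fixture_trial_block("m_a1", "baseline",
                        c(0, 0, 5), c(20, 21, 22, 23, 24), 126,
                        c(0, 0, 0, 0)),
    fixture_trial_block("m_a1", "endpoint",
                        c(4, 5, 6), c(20, 20, 22, 24, 24), 120,
                        c(1, 0, 1, 0)),
    # m_o1 died before endpoint: baseline only
    fixture_trial_block("m_o1", "baseline",
                        c(5, 6, 4), c(15, 16, 17, 18, 19), 75,
                        c(1, 2, 1, 2))
  )
}

fixture_deficits <- function() {
  items <- deficit_items()
  score_set <- function(id, tp, scores) {
    tibble::tibble(animal_id = id, timepoint = tp, item = items,
                   score = scores)
  }
  dplyr::bind_rows(
    score_set("f_a1", "baseline", rep(0, 27)),
    score_set("f_a1", "endpoint", c(0.5, rep(0, 26))),
    score_set("f_o1", "baseline", c(1, 0.5, 0.5, rep(0, 24))),
    score_set("f_o1", "endpoint", c(1, 1, 0.5, 0.5, rep(0, 23))),
    score_set("m_a1", "baseline", rep(0, 27)),
    score_set("m_a1", "endpoint", rep(0, 27)),
    score_set("m_o1", "baseline", c(rep(0.5, 4), rep(0, 23)))
  )
}

fixture_bodyweight <- function() {
  dplyr::bind_rows(
    tibble::tibble(animal_id = "f_a1", week = 1:13,
                   weight_g = 25 * 1.002^(0:12)),
    tibble::tibble(animal_id = "f_o1", week = 1:13,
                   weight_g = c(25.0, 24.5, 24.0, 23.8, 23.5, 23.3, 23.0,
                                22.8, 22.5, 22.3, 22.0, 21.8, 21.5)),
    tibble::tibble(animal_id = "m_a1", week = 1:13,
                   weight_g = rep(32, 13)),
    tibble::tibble(animal_id = "m_o1", week = 1:8,
                   weight_g = seq(38, 36, length.out = 8))
  )
}

fixture_cohort <- function() {
  frailty_cohort(fixture_animals(), fixture_trials(), fixture_bodyweight(),
                 fixture_deficits())
}

# Independent 20th-percentile oracle: sort, interpolate at index
# (n - 1) * p between order statistics, then count strictly below.
oracle_quantile_count_below <- function(x, p = 0.2) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  q <- s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
  list(cutoff = q, n_below = sum(x < q))
}
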