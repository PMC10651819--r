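#' Default simulation configuration for an aging-and-treatment cohort
#'
#' Returns the generator configuration that emulates a two-timepoint
#' (baseline/endpoint), two-sex, three-group mouse study: a mature Adult
#' reference group, an Old vehicle-treated group, and an Old group
#' receiving a candidate pro-resolving lipid treatment (PDX). Group
#' means are calibrated to the published effect sizes the pipeline was
#' designed around:
#'
#' * baseline treadmill distance to exhaustion 116 m (Adult female) vs
#'   70 m (Old female), 126 m vs 75 m in males, with the gap maintained
#'   at endpoint;
#' * grip strength of Old females 12.5% below Adult at baseline and 16%
#'   below at endpoint; Old males about 28% below Adult at endpoint;
#' * Old voluntary wheel activity about one third below Adult at both
#'   timepoints;
#' * Old frailty index above Adult at both timepoints;
#' * body weight drifting down in Old groups and up in Adults;
#' * 90% / 95% endpoint survival for vehicle-treated Old females/males,
#'   100% elsewhere.
#'
#' Dispersions (coefficients of variation), trial-level noise and the
#' latent-vigor loading are free parameters chosen at realistic
#' magnitudes; published group summaries constrain means only.
#'
#' @return A `sim_config` list; see [sim_config()] for the fields.
#' @export
default_sim_config <- function() {
  means <- dplyr::bind_rows(
    # endurance: treadmill distance to exhaustion (m)
    perf_means("endurance",
               female = c(adult = 116, old_vehicle = 70, old_pdx = 70),
               male   = c(adult = 126, old_vehicle = 75, old_pdx = 75),
               endpoint_female = c(adult = 116, old_vehicle = 56,
                                   old_pdx = 66),
               endpoint_male   = c(adult = 126, old_vehicle = 60,
                                   old_pdx = 71)),
    # grip strength, trimmed-mean maximal force (g)
    perf_means("grip_strength",
               female = c(adult = 100, old_vehicle = 87.5, old_pdx = 87.5),
               male   = c(adult = 110, old_vehicle = 104.5, old_pdx = 104.5),
               endpoint_female = c(adult = 100, old_vehicle = 84,
                                   old_pdx = 86),
               endpoint_male   = c(adult = 110, old_vehicle = 79.2,
                                   old_pdx = 100)),
    # voluntary wheel activity (km/day)
    perf_means("activity",
               female = c(adult = 6.0, old_vehicle = 4.0, old_pdx = 4.0),
               male   = c(adult = 5.0, old_vehicle = 3.3, old_pdx = 3.3),
               endpoint_female = c(adult = 5.4, old_vehicle = 3.6,
                                   old_pdx = 3.6),
               endpoint_male   = c(adult = 4.5, old_vehicle = 3.0,
                                   old_pdx = 3.0)),
    # rotarod walking speed (rpm); no systematic group differences
    perf_means("walking_speed",
               female = c(adult = 30, old_vehicle = 30, old_pdx = 30),
               male   = c(adult = 28, old_vehicle = 28, old_pdx = 28),
               endpoint_female = c(adult = 30, old_vehicle = 28,
                                   old_pdx = 29),
               endpoint_male   = c(adult = 28, old_vehicle = 26,
                                   old_pdx = 27))
  )
  sim_config(
    n = c(adult = 15, old_vehicle = 19, old_pdx = 14),
    means = means,
    cv = c(walking_speed = 0.10, grip_strength = 0.12,
           endurance = 0.25, activity = 0.30),
    trial_cv = c(walking_speed = 0.05, grip_strength = 0.06,
                 endurance = 0, activity = 0.15),
    vigor_loading = 0.6,
    fi = tibble::tribble(
      ~group,        ~timepoint, ~p_mild, ~p_severe,
      "adult",       "baseline",  0.08,    0.01,
      "adult",       "endpoint",  0.08,    0.01,
      "old_vehicle", "baseline",  0.16,    0.04,
      "old_vehicle", "endpoint",  0.22,    0.06,
      "old_pdx",     "baseline",  0.14,    0.03,
      "old_pdx",     "endpoint",  0.18,    0.04
    ),
    fi_vigor = 0.5,
    bw = tibble::tribble(
      ~sex,     ~group,        ~start_mean_g, ~start_cv, ~drift_pct, ~noise_pct,
      "female", "adult",        25,            0.08,       0.25,       0.6,
      "female", "old_vehicle",  30,            0.08,      -0.35,       0.6,
      "female", "old_pdx",      30,            0.08,      -0.30,       0.6,
      "male",   "adult",        32,            0.08,       0.25,       0.6,
      "male",   "old_vehicle",  38,            0.08,      -0.35,       0.6,
      "male",   "old_pdx",      38,            0.08,      -0.30,       0.6
    ),
    mortality = tibble::tribble(
      ~sex,     ~group,        ~p_death,
      "female", "adult",        0,
      "female", "old_vehicle",  0.10,
      "female", "old_pdx",      0,
      "male",   "adult",        0,
      "male",   "old_vehicle",  0.05,
      "male",   "old_pdx",      0
    ),
    weeks = 1:13
  )
}

perf_means <- function(test, female, male, endpoint_female, endpoint_male) {
  one <- function(sex, timepoint, v) {
    tibble::tibble(sex = sex, group = names(v), test = test,
                   timepoint = timepoint, mean = unname(v))
  }
  dplyr::bind_rows(
    one("female", "baseline", female),
    one("male", "baseline", male),
    one("female", "endpoint", endpoint_female),
    one("male", "endpoint", endpoint_male)
  )
}

#' Construct and validate a simulation configuration
#'
#' @param n Named integer vector of animals per group *per sex*
#'   (`adult`, `old_vehicle`, `old_pdx`).
#' @param means Tibble `sex`, `group`, `test`, `timepoint`, `mean` with
#'   one positive mean per combination, for all four performance tests.
#' @param cv Named between-animal coefficient of variation per test
#'   (lognormal latent ability).
#' @param trial_cv Named within-animal trial-to-trial coefficient of
#'   variation per test.
#' @param vigor_loading Loading in \[0, 1\] of the single latent "vigor"
#'   factor shared by all of an animal's performance tests; induces the
#'   within-animal correlation that makes multi-criterion positives
#'   realistic.
#' @param fi Tibble `group`, `timepoint`, `p_mild`, `p_severe`: per-item
#'   probabilities of a mild (0.5) or severe (1) deficit score; the
#'   expected frailty index is `0.5 * p_mild + p_severe`.
#' @param fi_vigor Strength (>= 0) of the vigor tilt on deficit
#'   probabilities (frailer items for low-vigor animals).
#' @param bw Tibble `sex`, `group`, `start_mean_g`, `start_cv`,
#'   `drift_pct`, `noise_pct`: weekly body-weight geometric random walk,
#'   drift and noise in percent per week.
#' @param mortality Tibble `sex`, `group`, `p_death`: probability of
#'   death between baseline and endpoint.
#' @param weeks Integer study weeks for the body-weight series.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n, means, cv, trial_cv, vigor_loading, fi, fi_vigor,
                       bw, mortality, weeks) {
  cfg <- structure(
    list(n = n, means = tibble::as_tibble(means), cv = cv,
         trial_cv = trial_cv, vigor_loading = vigor_loading,
         fi = tibble::as_tibble(fi), fi_vigor = fi_vigor,
         bw = tibble::as_tibble(bw),
         mortality = tibble::as_tibble(mortality), weeks = as.integer(weeks)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!setequal(names(cfg$n), fm_groups) || any(cfg$n < 0)) {
    fail_validation("sim_config: n must name all groups with counts >= 0")
  }
  need <- tidyr::expand_grid(sex = fm_sexes, group = fm_groups,
                             test = fm_tests, timepoint = fm_timepoints)
  have <- dplyr::semi_join(need, cfg$means,
                           by = c("sex", "group", "test", "timepoint"))
  if (nrow(have) != nrow(need) || nrow(cfg$means) != nrow(need)) {
    fail_validation(
      "sim_config: means must cover every (sex, group, test, timepoint) exactly once")
  }
  if (any(cfg$means$mean <= 0)) {
    fail_validation("sim_config: performance means must be > 0")
  }
  for (field in c("cv", "trial_cv")) {
    v <- cfg[[field]]
    if (!setequal(names(v), fm_tests) || any(v < 0)) {
      fail_validation("sim_config: %s must name all tests with values >= 0",
                      field)
    }
  }
  if (cfg$vigor_loading < 0 || cfg$vigor_loading > 1) {
    fail_validation("sim_config: vigor_loading must lie in [0, 1]")
  }
  if (any(cfg$fi$p_mild < 0 | cfg$fi$p_severe < 0 |
          cfg$fi$p_mild + cfg$fi$p_severe > 1)) {
    fail_validation(
      "sim_config: fi probabilities must be >= 0 with p_mild + p_severe <= 1")
  }
  if (any(cfg$bw$start_mean_g <= 0) || any(cfg$bw$start_cv < 0) ||
      any(cfg$bw$noise_pct < 0)) {
    fail_validation("sim_config: bw start means must be > 0, dispersions >= 0")
  }
  if (any(cfg$mortality$p_death < 0 | cfg$mortality$p_death > 1)) {
    fail_validation("sim_config: mortality probabilities must lie in [0, 1]")
  }
  if (length(cfg$weeks) < 2 || is.unsorted(cfg$weeks, strictly = TRUE)) {
    fail_validation("sim_config: weeks must be >= 2 strictly increasing integers")
  }
  invisible(cfg)
}

# lognormal draw with expectation `mean` and coefficient of variation
# `cv`; deterministic (== mean) when cv is 0
rlnorm_mean <- function(noise_std, mean, cv) {
  if (cv == 0) return(rep(mean, length(noise_std)))
  sdlog <- sqrt(log1p(cv^2))
  mean * exp(sdlog * noise_std - sdlog^2 / 2)
}

#' Simulate a longitudinal frailty cohort
#'
#' Generates the full CSV table set of a two-timepoint cohort under a
#' [sim_config()]. Each animal carries a latent "vigor" factor shared
#' across its performance tests; per-test latent ability is lognormal
#' around the configured group mean, and raw trials are lognormal
#' around the latent ability, so the trial-summarisation rules (best of
#' 3, trimmed mean of 5, mean of 4) are genuinely exercised. Deficit
#' items are drawn per item with group-specific mild/severe
#' probabilities tilted by vigor; body weight follows a geometric
#' weekly random walk with group drift; deaths between baseline and
#' endpoint are sampled per group and sex, and dead animals lose their
#' endpoint measurements and late body weights.
#'
#' @param config A [sim_config()]; default [default_sim_config()].
#' @param seed Optional integer seed; identical config + seed gives an
#'   identical cohort.
#' @param items Instrument item names (default [deficit_items()]).
#' @return A [frailty_cohort()].
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' cohort
simulate_cohort <- function(config = default_sim_config(), seed = NULL,
                            items = deficit_items()) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)

  roster <- tidyr::expand_grid(sex = fm_sexes, group = fm_groups) |>
    dplyr::mutate(n = config$n[.data$group]) |>
    tidyr::uncount(.data$n, .id = "idx") |>
    dplyr::mutate(animal_id = sprintf("%s_%s_%03d",
                                      toupper(substr(.data$sex, 1, 1)),
                                      .data$group, .data$idx))

  mort <- dplyr::left_join(roster, config$mortality, by = c("sex", "group"))
  died <- runif(nrow(roster)) < mort$p_death
  death_week <- ifelse(died, sample(5:12, nrow(roster), replace = TRUE), NA)

  animals <- tibble::tibble(
    animal_id = roster$animal_id, sex = roster$sex, group = roster$group,
    alive_at_endpoint = !died
  )

  lambda <- config$vigor_loading
  vigor <- rnorm(nrow(roster))

  trials <- purrr::pmap_dfr(
    list(roster$animal_id, roster$sex, roster$group, seq_len(nrow(roster))),
    function(id, sex, group, i) {
      purrr::map_dfr(fm_tests, function(test) {
        # per-animal, per-test persistent ability component, shared by
        # both timepoints so endpoint deltas reflect group means
        eps <- rnorm(1)
        ability_std <- lambda * vigor[i] + sqrt(1 - lambda^2) * eps
        tps <- if (died[i]) "baseline" else fm_timepoints
        purrr::map_dfr(tps, function(tp) {
          m <- config$means$mean[config$means$sex == sex &
                                   config$means$group == group &
                                   config$means$test == test &
                                   config$means$timepoint == tp]
          latent <- rlnorm_mean(ability_std, m, config$cv[[test]])
          k <- fm_trial_counts[[test]]
          vals <- rlnorm_mean(rnorm(k), latent, config$trial_cv[[test]])
          tibble::tibble(animal_id = id, timepoint = tp, test = test,
                         trial_index = seq_len(k), value = vals)
        })
      })
    })

  deficits <- purrr::pmap_dfr(
    list(roster$animal_id, roster$group, seq_len(nrow(roster))),
    function(id, group, i) {
      tps <- if (died[i]) "baseline" else fm_timepoints
      purrr::map_dfr(tps, function(tp) {
        p <- config$fi[config$fi$group == group & config$fi$timepoint == tp, ]
        # mean-one multiplicative tilt: low-vigor animals accumulate
        # deficits at a higher per-item rate
        a <- config$fi_vigor
        tilt <- exp(-a * vigor[i] - a^2 / 2)
        p_sev <- min(1, p$p_severe * tilt)
        p_mld <- min(1 - p_sev, p$p_mild * tilt)
        u <- runif(27)
        score <- ifelse(u < p_sev, 1, ifelse(u < p_sev + p_mld, 0.5, 0))
        tibble::tibble(animal_id = id, timepoint = tp, item = items,
                       score = score)
      })
    })

  bodyweight <- purrr::pmap_dfr(
    list(roster$animal_id, roster$sex, roster$group, seq_len(nrow(roster))),
    function(id, sex, group, i) {
      b <- config$bw[config$bw$sex == sex & config$bw$group == group, ]
      weeks <- config$weeks
      if (died[i]) weeks <- weeks[weeks <= death_week[i]]
      start <- rlnorm_mean(rnorm(1), b$start_mean_g, b$start_cv)
      steps <- 1 + (b$drift_pct + b$noise_pct * rnorm(length(weeks) - 1)) / 100
      w <- start * cumprod(c(1, pmax(steps, 0.5)))
      tibble::tibble(animal_id = id, week = weeks, weight_g = w)
    })

  frailty_cohort(animals, trials, bodyweight, deficits, items = items)
}
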