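#' Best walking speed from repeated rotarod trials
#'
#' The rotarod protocol records the maximal speed reached in each of
#' three trials; the animal's walking speed is the best of the three.
#'
#' @param trials Numeric vector of exactly 3 non-negative maximal
#'   speeds (rpm). An `NA` trial marks a missing recording.
#' @return Best speed (rpm), or `NA` if all trials are missing.
#' @export
#' @examples
#' best_walking_speed(c(10, 14, 12)) # 14
best_walking_speed <- function(trials) {
  check_trials(trials, 3L, "walking_speed")
  if (all(is.na(trials))) return(NA_real_)
  max(trials, na.rm = TRUE)
}

#' Trimmed-mean grip strength from five trials
#'
#' Five grip trials are taken; the single highest and single lowest are
#' discarded and the remaining three averaged. With tied values exactly
#' one occurrence of the maximum and one of the minimum are removed, so
#' the result is permutation-invariant and bounded by the input range.
#'
#' @param trials Numeric vector of exactly 5 non-negative forces.
#' @return Mean of the middle three trials, or `NA` if any trial is
#'   missing (the trim is undefined on an incomplete set).
#' @export
#' @examples
#' trimmed_grip_strength(c(10, 12, 14, 16, 18)) # 14
trimmed_grip_strength <- function(trials) {
  check_trials(trials, 5L, "grip_strength")
  if (anyNA(trials)) return(NA_real_)
  s <- sort(trials)
  mean(s[2:4])
}

#' Mean daily voluntary wheel activity
#'
#' Voluntary activity is monitored over four experimental days (a prior
#' acclimation day is excluded upstream) and reported as kilometres/day.
#'
#' @param days Numeric vector of exactly 4 non-negative daily distances
#'   (km).
#' @return Arithmetic mean (km/day), `NA` if all days are missing.
#' @export
mean_daily_activity <- function(days) {
  check_trials(days, 4L, "activity")
  if (all(is.na(days))) return(NA_real_)
  mean(days, na.rm = TRUE)
}

#' Frailty index score from 27 deficit items
#'
#' Deficit-accumulation score: the sum of the 27 item scores (each 0,
#' 0.5 or 1) divided by 27, giving a fraction in \[0, 1\]; higher means
#' frailer.
#'
#' @param scores Numeric vector of exactly 27 scores in \{0, 0.5, 1\}.
#' @return Frailty index in \[0, 1\].
#' @export
#' @examples
#' frailty_index(c(1, 0.5, 0.5, rep(0, 24))) # 2/27
frailty_index <- function(scores) {
  if (length(scores) != 27) {
    fail_validation("frailty_index: expected exactly 27 item scores, got %d",
                    length(scores))
  }
  if (!all(scores %in% c(0, 0.5, 1))) {
    fail_validation(
      "frailty_index: scores must be in allowed set {0, 0.5, 1}")
  }
  sum(scores) / 27
}

#' Average weekly percent change in body weight
#'
#' For consecutive recorded weeks the percent change
#' `100 * (w[i+1] - w[i]) / w[i]` is computed and averaged, using the
#' earlier week as denominator. Negative values indicate weight loss.
#'
#' @param weeks Integer week indices, strictly increasing.
#' @param weights_g Matching body weights (g).
#' @param window Length-2 numeric, inclusive week range to use
#'   (default: all recorded weeks).
#' @return Mean percent change per recorded interval (%/week), or `NA`
#'   (with a warning) when fewer than two weights fall in the window.
#' @export
#' @examples
#' avg_weekly_bw_change(1:3, c(25.0, 24.5, 24.0)) # about -2.02
avg_weekly_bw_change <- function(weeks, weights_g, window = NULL) {
  stopifnot(length(weeks) == length(weights_g))
  if (is.unsorted(weeks, strictly = TRUE)) {
    fail_validation("avg_weekly_bw_change: weeks must be strictly increasing")
  }
  if (!is.null(window)) {
    keep <- weeks >= window[1] & weeks <= window[2]
    weeks <- weeks[keep]
    weights_g <- weights_g[keep]
  }
  if (length(weights_g) < 2) {
    warn("avg_weekly_bw_change: fewer than 2 weights in window; returning NA")
    return(NA_real_)
  }
  steps <- 100 * diff(weights_g) / head(weights_g, -1)
  mean(steps)
}

#' Endpoint-minus-baseline delta
#'
#' @param baseline,endpoint Numeric values of the same metric at the two
#'   assessments.
#' @return `endpoint - baseline`; `NA` if either is missing.
#' @export
delta_metric <- function(baseline, endpoint) {
  endpoint - baseline
}

#' Area under the curve by the composite trapezoidal rule
#'
#' @param times Strictly increasing numeric time coordinates (at least
#'   two).
#' @param values Matching numeric values.
#' @return AUC in value x time units.
#' @export
#' @examples
#' trapezoid_auc(c(0, 15, 30), c(100, 150, 120)) # 3900
trapezoid_auc <- function(times, values) {
  if (length(times) < 2 || length(times) != length(values)) {
    fail_validation(
      "trapezoid_auc: need >= 2 points with matching times and values")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    fail_validation("trapezoid_auc: times must be strictly increasing")
  }
  sum(diff(times) * (head(values, -1) + tail(values, -1)) / 2)
}

check_trials <- function(x, n, test) {
  if (length(x) != n) {
    fail_validation("%s: expected exactly %d value(s), got %d",
                    test, n, length(x))
  }
  if (any(!is.na(x) & x < 0)) {
    fail_validation("%s: values must be >= 0", test)
  }
  invisible(x)
}

# Body-weight window per assessment. Baseline testing closes at week 4,
# so only weeks 1-4 exist then; the endpoint assessment sees the whole
# 13-week series.
default_bw_windows <- list(baseline = c(1, 4), endpoint = c(1, 13))

#' Build the six-criterion panel for one timepoint
#'
#' Reduces each living animal's raw measurements at `timepoint` to the
#' six frailty criteria: best walking speed (`ws`, rpm), trimmed-mean
#' grip force (`gft`), treadmill distance to exhaustion (`td`, m), mean
#' daily wheel activity (`vrw`, km/day), frailty index (`fi`, 0-1) and
#' average weekly percent body-weight change (`dbw`, %/week). A test an
#' animal skipped yields `NA` for that criterion, flagged in
#' `any_missing` and reported via a warning.
#'
#' @param cohort A [frailty_cohort()].
#' @param timepoint `"baseline"` or `"endpoint"`. At endpoint only
#'   animals alive at endpoint are panelled.
#' @param bw_window Inclusive week range for the `dbw` criterion;
#'   defaults to weeks 1-4 at baseline and 1-13 at endpoint.
#' @return Tibble with one row per panelled animal: `animal_id`,
#'   `timepoint`, the six criteria, and `any_missing`.
#' @export
build_criterion_panel <- function(cohort, timepoint,
                                  bw_window = default_bw_windows[[timepoint]]) {
  stopifnot(inherits(cohort, "frailty_cohort"))
  timepoint <- match.arg(timepoint, fm_timepoints)

  animals <- cohort$animals
  if (timepoint == "endpoint") {
    animals <- dplyr::filter(animals, .data$alive_at_endpoint)
  }

  trials_tp <- dplyr::filter(cohort$trials, .data$timepoint == !!timepoint)
  deficits_tp <- dplyr::filter(cohort$deficits, .data$timepoint == !!timepoint)

  reduce_test <- function(id, test_name, fn) {
    v <- trials_tp$value[trials_tp$animal_id == id &
                           trials_tp$test == test_name]
    if (length(v) == 0) return(NA_real_)
    fn(v[order(trials_tp$trial_index[trials_tp$animal_id == id &
                                       trials_tp$test == test_name])])
  }

  panel <- purrr::map_dfr(animals$animal_id, function(id) {
    fi_scores <- deficits_tp$score[deficits_tp$animal_id == id]
    bw <- cohort$bodyweight[cohort$bodyweight$animal_id == id, ]
    dbw <- if (sum(bw$week >= bw_window[1] & bw$week <= bw_window[2]) >= 2) {
      avg_weekly_bw_change(bw$week, bw$weight_g, window = bw_window)
    } else {
      NA_real_
    }
    tibble::tibble(
      animal_id = id,
      timepoint = timepoint,
      ws  = reduce_test(id, "walking_speed", best_walking_speed),
      gft = reduce_test(id, "grip_strength", trimmed_grip_strength),
      td  = reduce_test(id, "endurance", function(v) v[1]),
      vrw = reduce_test(id, "activity", mean_daily_activity),
      fi  = if (length(fi_scores) == 27) frailty_index(fi_scores)
            else NA_real_,
      dbw = dbw
    )
  })
  panel$any_missing <- apply(is.na(panel[fm_criteria]), 1, any)
  if (any(panel$any_missing)) {
    flagged <- panel$animal_id[panel$any_missing]
    shown <- paste(head(flagged, 5), collapse = ", ")
    if (length(flagged) > 5) shown <- paste0(shown, ", ...")
    warn(sprintf(
      "criterion panel (%s): %d animal(s) have missing criteria: %s",
      timepoint, sum(panel$any_missing), shown
    ))
  }
  panel
}
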