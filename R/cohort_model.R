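#' Default 27-item frailty index instrument
#'
#' The deficit-accumulation frailty index used here scores 27 visually
#' assessed health deficits, each graded 0 (absent), 0.5 (mild) or
#' 1 (severe). The item list is an adaptation of the clinical 31-item
#' mouse frailty instrument with four items removed (forelimb grip
#' strength, tail stiffening, body temperature and body weight), because
#' those quantities enter the composite classification through the
#' physical-performance and body-weight criteria instead.
#'
#' The exact wording of the 27 retained items is not fixed by any single
#' reference; this list is a faithful reconstruction of the standard
#' instrument minus the four exclusions, and is configurable: any
#' character vector of 27 unique names may be passed wherever `items`
#' is accepted.
#'
#' @return Character vector of 27 deficit item names.
#' @export
#' @examples
#' length(deficit_items())
deficit_items <- function() {
  c(
    # integument
    "alopecia", "loss_of_fur_colour", "dermatitis", "loss_of_whiskers",
    "coat_condition", "piloerection",
    # ocular / nasal
    "cataracts", "corneal_opacity", "eye_discharge", "microphthalmia",
    "vision_loss", "menace_reflex", "nasal_discharge",
    # digestive / urogenital
    "malocclusions", "distended_abdomen", "rectal_prolapse",
    "genital_prolapse", "diarrhea",
    # musculoskeletal
    "kyphosis", "gait_disorders", "tremor", "body_condition",
    # vestibular / auditory
    "vestibular_disturbance", "hearing_loss",
    # respiratory and other
    "breathing_rate", "tumours", "grimace"
  )
}

#' Assemble and validate a longitudinal frailty cohort
#'
#' Bundles the four tables the pipeline consumes into a single validated
#' object. All invariants are enforced on construction: a malformed input
#' raises a classed error and never yields a partially built cohort.
#'
#' @param animals Tibble with columns `animal_id` (unique), `sex`
#'   (`"female"`/`"male"`), `group` (`"adult"`, `"old_vehicle"`,
#'   `"old_pdx"`), `alive_at_endpoint` (logical).
#' @param trials Tibble with columns `animal_id`, `timepoint`
#'   (`"baseline"`/`"endpoint"`), `test`, `trial_index`, `value`. Each
#'   present (animal, timepoint, test) block must carry the protocol's
#'   trial count: 3 walking-speed, 5 grip, 1 endurance, 4 activity
#'   values, all non-negative. A skipped test is simply absent; an `NA`
#'   value marks a trial recorded as missing.
#' @param bodyweight Tibble with columns `animal_id`, `week`, `weight_g`;
#'   weeks strictly increasing within animal, weights positive.
#' @param deficits Tibble with columns `animal_id`, `timepoint`, `item`,
#'   `score`; exactly the 27 instrument items per present
#'   (animal, timepoint), each score in \{0, 0.5, 1\}.
#' @param items Character vector of the instrument's item names
#'   (default [deficit_items()]).
#'
#' @return A `frailty_cohort`: a list of the four validated tibbles.
#' @export
frailty_cohort <- function(animals, trials, bodyweight, deficits,
                           items = deficit_items()) {
  cohort <- structure(
    list(
      animals    = as_cohort_tbl(animals, animals_schema()),
      trials     = as_cohort_tbl(trials, trials_schema()),
      bodyweight = as_cohort_tbl(bodyweight, bodyweight_schema()),
      deficits   = as_cohort_tbl(deficits, deficits_schema()),
      items      = items
    ),
    class = "frailty_cohort"
  )
  validate_cohort(cohort)
  cohort
}

#' @export
print.frailty_cohort <- function(x, ...) {
  cat("<frailty_cohort>\n")
  cat("  animals:   ", nrow(x$animals), "\n")
  cat("  trials:    ", nrow(x$trials), " rows\n")
  cat("  bodyweight:", nrow(x$bodyweight), " rows\n")
  cat("  deficits:  ", nrow(x$deficits), " rows (",
      length(x$items), "-item instrument)\n", sep = "")
  invisible(x)
}

# ---- schemas ----------------------------------------------------------

animals_schema <- function() {
  list(cols = c("animal_id", "sex", "group", "alive_at_endpoint"),
       table = "animals")
}
trials_schema <- function() {
  list(cols = c("animal_id", "timepoint", "test", "trial_index", "value"),
       table = "trials")
}
bodyweight_schema <- function() {
  list(cols = c("animal_id", "week", "weight_g"), table = "bodyweight")
}
deficits_schema <- function() {
  list(cols = c("animal_id", "timepoint", "item", "score"),
       table = "deficits")
}

as_cohort_tbl <- function(x, schema) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(schema$cols, names(x))
  extra_cols   <- setdiff(names(x), schema$cols)
  if (length(missing_cols) > 0) {
    abort(
      sprintf("table '%s' is missing column(s): %s",
              schema$table, paste(missing_cols, collapse = ", ")),
      class = "frailtymouse_schema_error"
    )
  }
  if (length(extra_cols) > 0) {
    abort(
      sprintf("table '%s' has unexpected column(s): %s",
              schema$table, paste(extra_cols, collapse = ", ")),
      class = "frailtymouse_schema_error"
    )
  }
  x[schema$cols]
}

# ---- validation -------------------------------------------------------

fail_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "frailtymouse_validation_error")
}

validate_cohort <- function(cohort) {
  validate_animals(cohort$animals)
  validate_trials(cohort$trials, cohort$animals)
  validate_bodyweight(cohort$bodyweight, cohort$animals)
  validate_deficits(cohort$deficits, cohort$animals, cohort$items)
  invisible(cohort)
}

validate_animals <- function(animals) {
  dup <- animals$animal_id[duplicated(animals$animal_id)]
  if (length(dup) > 0) {
    fail_validation("duplicate animal_id: %s",
                    paste(unique(dup), collapse = ", "))
  }
  bad_sex <- !animals$sex %in% fm_sexes
  if (any(bad_sex)) {
    fail_validation("animal %s: sex must be one of {%s}",
                    animals$animal_id[bad_sex][1],
                    paste(fm_sexes, collapse = ", "))
  }
  bad_grp <- !animals$group %in% fm_groups
  if (any(bad_grp)) {
    fail_validation("animal %s: group must be one of {%s}",
                    animals$animal_id[bad_grp][1],
                    paste(fm_groups, collapse = ", "))
  }
  if (!is.logical(animals$alive_at_endpoint) ||
      anyNA(animals$alive_at_endpoint)) {
    fail_validation("animals: alive_at_endpoint must be TRUE/FALSE, no NA")
  }
  invisible(animals)
}

validate_trials <- function(trials, animals) {
  if (nrow(trials) == 0) return(invisible(trials))
  check_known_animals(trials$animal_id, animals, "trials")
  bad_tp <- !trials$timepoint %in% fm_timepoints
  if (any(bad_tp)) {
    fail_validation("trials, animal %s: timepoint must be one of {%s}",
                    trials$animal_id[bad_tp][1],
                    paste(fm_timepoints, collapse = ", "))
  }
  bad_test <- !trials$test %in% fm_tests
  if (any(bad_test)) {
    fail_validation("trials, animal %s: unknown test '%s'",
                    trials$animal_id[bad_test][1],
                    trials$test[bad_test][1])
  }
  neg <- !is.na(trials$value) & trials$value < 0
  if (any(neg)) {
    fail_validation("trials, animal %s: value must be >= 0 (test %s)",
                    trials$animal_id[neg][1], trials$test[neg][1])
  }
  counts <- dplyr::count(trials, .data$animal_id, .data$timepoint, .data$test)
  counts$expected <- fm_trial_counts[counts$test]
  off <- counts$n != counts$expected
  if (any(off)) {
    i <- which(off)[1]
    fail_validation(
      "trials, animal %s, %s %s: expected exactly %d trial value(s), got %d",
      counts$animal_id[i], counts$timepoint[i], counts$test[i],
      counts$expected[i], counts$n[i]
    )
  }
  invisible(trials)
}

validate_bodyweight <- function(bodyweight, animals) {
  if (nrow(bodyweight) == 0) return(invisible(bodyweight))
  check_known_animals(bodyweight$animal_id, animals, "bodyweight")
  bad_w <- is.na(bodyweight$weight_g) | bodyweight$weight_g <= 0
  if (any(bad_w)) {
    fail_validation("bodyweight, animal %s: weight_g must be > 0",
                    bodyweight$animal_id[bad_w][1])
  }
  non_inc <- bodyweight |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(ok = all(diff(.data$week) > 0), .groups = "drop")
  if (any(!non_inc$ok)) {
    fail_validation("bodyweight, animal %s: weeks must be strictly increasing",
                    non_inc$animal_id[!non_inc$ok][1])
  }
  invisible(bodyweight)
}

validate_deficits <- function(deficits, animals, items) {
  if (length(items) != 27 || anyDuplicated(items) > 0) {
    fail_validation("instrument must have exactly 27 unique items, got %d",
                    length(unique(items)))
  }
  if (nrow(deficits) == 0) return(invisible(deficits))
  check_known_animals(deficits$animal_id, animals, "deficits")
  bad_score <- !deficits$score %in% c(0, 0.5, 1)
  if (any(bad_score)) {
    fail_validation(
      "deficits, animal %s, item %s: score %s not in allowed set {0, 0.5, 1}",
      deficits$animal_id[bad_score][1], deficits$item[bad_score][1],
      format(deficits$score[bad_score][1])
    )
  }
  unknown <- !deficits$item %in% items
  if (any(unknown)) {
    fail_validation("deficits, animal %s: unknown item '%s'",
                    deficits$animal_id[unknown][1],
                    deficits$item[unknown][1])
  }
  per_assessment <- deficits |>
    dplyr::group_by(.data$animal_id, .data$timepoint) |>
    dplyr::summarise(n = dplyr::n(),
                     n_unique = dplyr::n_distinct(.data$item),
                     .groups = "drop")
  off <- per_assessment$n != 27 | per_assessment$n_unique != 27
  if (any(off)) {
    i <- which(off)[1]
    fail_validation(
      "deficits, animal %s, %s: expected exactly 27 distinct items, got %d",
      per_assessment$animal_id[i], per_assessment$timepoint[i],
      per_assessment$n[i]
    )
  }
  invisible(deficits)
}

check_known_animals <- function(ids, animals, table) {
  unknown <- setdiff(unique(ids), animals$animal_id)
  if (length(unknown) > 0) {
    fail_validation("table '%s' references unknown animal_id: %s",
                    table, paste(unknown, collapse = ", "))
  }
}

# ---- CSV I/O ----------------------------------------------------------

cohort_files <- c(animals = "animals.csv", trials = "trials.csv",
                  bodyweight = "bodyweight.csv", deficits = "deficits.csv")

#' Read a cohort from its CSV table set
#'
#' Reads `animals.csv`, `trials.csv`, `bodyweight.csv` and `deficits.csv`
#' from a directory and returns a fully validated [frailty_cohort()].
#' Missing measurement values are written as empty CSV fields and read
#' back as `NA`.
#'
#' @param dir Directory containing the four CSV files.
#' @param items Instrument item names (default [deficit_items()]).
#' @return A `frailty_cohort`.
#' @export
read_cohort <- function(dir, items = deficit_items()) {
  paths <- file.path(dir, cohort_files)
  missing_files <- !file.exists(paths)
  if (any(missing_files)) {
    abort(sprintf("missing cohort file(s): %s",
                  paste(cohort_files[missing_files], collapse = ", ")),
          class = "frailtymouse_io_error")
  }
  col_specs <- list(
    animals = readr::cols(
      animal_id = readr::col_character(), sex = readr::col_character(),
      group = readr::col_character(),
      alive_at_endpoint = readr::col_logical()
    ),
    trials = readr::cols(
      animal_id = readr::col_character(),
      timepoint = readr::col_character(), test = readr::col_character(),
      trial_index = readr::col_integer(), value = readr::col_double()
    ),
    bodyweight = readr::cols(
      animal_id = readr::col_character(), week = readr::col_integer(),
      weight_g = readr::col_double()
    ),
    deficits = readr::cols(
      animal_id = readr::col_character(),
      timepoint = readr::col_character(), item = readr::col_character(),
      score = readr::col_double()
    )
  )
  tables <- purrr::imap(col_specs, function(spec, name) {
    readr::read_csv(file.path(dir, cohort_files[[name]]),
                    col_types = spec, progress = FALSE)
  })
  frailty_cohort(tables$animals, tables$trials, tables$bodyweight,
                 tables$deficits, items = items)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writes the four tables so that reading
#' them back reproduces the cohort value-for-value (`NA` measurement
#' values round-trip as empty fields).
#'
#' @param cohort A `frailty_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "frailty_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (name in names(cohort_files)) {
    readr::write_csv(cohort[[name]], file.path(dir, cohort_files[[name]]),
                     na = "")
  }
  invisible(dir)
}
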