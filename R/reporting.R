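#' Group-level summaries of the criterion panels
#'
#' Mean, SEM (`sd/sqrt(n)`), endpoint-minus-baseline delta of group
#' means, and a two-point trapezoidal AUC over the assessment weeks for
#' every (sex, group, metric) cell. `n` counts non-missing values; a
#' single-value cell has `sem = NA`; cells with no data are omitted
#' with a warning.
#'
#' @param panels Criterion panels from both timepoints, row-bound.
#' @param animals The cohort's animals table.
#' @param assessment_weeks Length-2 numeric: the study weeks of the
#'   baseline and endpoint assessments (time axis of the AUC).
#' @return Tibble `sex`, `group`, `timepoint`, `metric`, `n`, `mean`,
#'   `sem`, `delta`, `auc` (delta and AUC repeated across the two
#'   timepoint rows of a cell; `NA` when either timepoint is absent).
#' @export
summarize_groups <- function(panels, animals, assessment_weeks = c(4, 13)) {
  long <- panels |>
    dplyr::inner_join(dplyr::select(animals, "animal_id", "sex", "group"),
                      by = "animal_id") |>
    tidyr::pivot_longer(dplyr::all_of(fm_criteria), names_to = "metric",
                        values_to = "value")
  cells <- long |>
    dplyr::group_by(.data$sex, .data$group, .data$timepoint, .data$metric) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = if (n > 0) mean(.data$value, na.rm = TRUE) else NA_real_,
      sem = if (n > 1) sd(.data$value, na.rm = TRUE) / sqrt(n) else NA_real_,
      .groups = "drop"
    )
  empty <- cells$n == 0
  if (any(empty)) {
    warn(sprintf("summarize_groups: %d empty cell(s) omitted", sum(empty)))
    cells <- cells[!empty, ]
  }
  wide <- cells |>
    dplyr::select("sex", "group", "metric", "timepoint", "mean") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "mean")
  for (tp in fm_timepoints) {
    if (!tp %in% names(wide)) wide[[tp]] <- NA_real_
  }
  wide <- wide |>
    dplyr::mutate(
      delta = delta_metric(.data$baseline, .data$endpoint),
      auc = ifelse(
        is.na(.data$baseline) | is.na(.data$endpoint), NA_real_,
        diff(assessment_weeks) * (.data$baseline + .data$endpoint) / 2)
    ) |>
    dplyr::select("sex", "group", "metric", "delta", "auc")
  out <- dplyr::left_join(cells, wide, by = c("sex", "group", "metric"))
  dplyr::arrange(out, .data$sex, .data$group, .data$metric, .data$timepoint)
}

#' Run the full frailty pipeline and write its artifact set
#'
#' Drives every stage: criterion panels at both timepoints, sex-specific
#' Old-baseline cutoffs, per-animal classifications, baseline-to-endpoint
#' transitions per sex and group, group summaries and survival rates.
#' Writes `panel.csv`, `cutoffs.csv`, `classifications.csv`,
#' `transitions.csv`, `summary.csv`, `survival.csv` and a `run_log.txt`
#' manifest to `outdir`; re-running on identical input is byte-identical.
#'
#' @param input A [frailty_cohort()], a directory of cohort CSVs, or a
#'   [sim_config()] (simulated with `seed`).
#' @param outdir Output directory, created if absent.
#' @param seed Integer seed used when `input` is a config.
#' @param orientation Criterion orientations.
#' @param reference Cutoff reference population; see [derive_cutoffs()].
#' @return Named list of the computed tables, invisibly.
#' @export
run_pipeline <- function(input, outdir, seed = NULL,
                         orientation = default_orientation(),
                         reference = "old_baseline") {
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  cohort <- if (inherits(input, "frailty_cohort")) {
    input
  } else if (inherits(input, "sim_config")) {
    note("input: simulated cohort (seed=%s)",
         if (is.null(seed)) "none" else seed)
    simulate_cohort(input, seed = seed)
  } else if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    note("input: cohort read from %s", input)
    read_cohort(input)
  } else {
    abort("run_pipeline: input must be a frailty_cohort, sim_config or directory",
          class = "frailtymouse_io_error")
  }

  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", stage,
                      conditionMessage(e)),
              class = "frailtymouse_pipeline_error", parent = e)
      }),
      warning = function(w) {
        note("[%s] warning: %s", stage, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  panels <- run_stage("score", dplyr::bind_rows(
    build_criterion_panel(cohort, "baseline"),
    build_criterion_panel(cohort, "endpoint")
  ))
  cutoffs <- run_stage("cutoffs", derive_cutoffs(
    panels, cohort$animals, orientation, reference = reference))
  classifications <- run_stage("classify", dplyr::bind_rows(lapply(
    fm_timepoints, function(tp) {
      classify_cohort(panels[panels$timepoint == tp, ], cutoffs,
                      cohort$animals, orientation)
    })))

  strata <- dplyr::distinct(cohort$animals, .data$sex, .data$group)
  transitions <- run_stage("transitions", purrr::pmap_dfr(
    strata, function(sex, group) {
      ids <- cohort$animals$animal_id[cohort$animals$sex == sex &
                                        cohort$animals$group == group]
      cls <- classifications[classifications$animal_id %in% ids, ]
      tm <- track_transitions(cls[cls$timepoint == "baseline", ],
                              cls[cls$timepoint == "endpoint", ])
      dplyr::mutate(tm, sex = sex, group = group, .before = 1)
    }))

  summary_tbl <- run_stage("summarize",
                           summarize_groups(panels, cohort$animals))
  survival <- run_stage("survival", purrr::pmap_dfr(
    strata, function(sex, group) {
      tibble::tibble(sex = sex, group = group,
                     survival_pct = survival_rate(cohort$animals, group, sex))
    }))

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list(panel = panels, cutoffs = cutoffs,
                    classifications = classifications,
                    transitions = transitions, summary = summary_tbl,
                    survival = survival)
  for (name in names(artifacts)) {
    readr::write_csv(artifacts[[name]],
                     file.path(outdir, paste0(name, ".csv")), na = "")
  }
  note("artifacts: %s", paste(names(artifacts), collapse = ", "))
  note("animals: %d; classified at baseline: %d; at endpoint: %d",
       nrow(cohort$animals),
       sum(classifications$timepoint == "baseline"),
       sum(classifications$timepoint == "endpoint"))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  message(paste(log_lines, collapse = "\n"))
  invisible(artifacts)
}
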