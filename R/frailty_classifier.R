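#' Default criterion orientations
#'
#' Each criterion has a direction in which its value indicates greater
#' frailty. Performance criteria (`ws`, `gft`, `td`, `vrw`) and weekly
#' body-weight change (`dbw`, more negative = more weight loss) are
#' frailer when lower; the frailty index (`fi`) is frailer when higher.
#' Cutoff derivation and marker flagging internally place every
#' criterion on a common "frailer = lower" oriented scale by negating
#' `higher_is_frailer` criteria.
#'
#' @return Named character vector over the six criteria with values
#'   `"lower_is_frailer"` or `"higher_is_frailer"`.
#' @export
default_orientation <- function() {
  c(ws = "lower_is_frailer", gft = "lower_is_frailer",
    td = "lower_is_frailer", vrw = "lower_is_frailer",
    fi = "higher_is_frailer", dbw = "lower_is_frailer")
}

check_orientation <- function(orientation) {
  if (!setequal(names(orientation), fm_criteria) ||
      !all(orientation %in% c("lower_is_frailer", "higher_is_frailer"))) {
    fail_validation(
      "orientation must map all six criteria (%s) to lower_is_frailer/higher_is_frailer",
      paste(fm_criteria, collapse = ", "))
  }
  orientation[fm_criteria]
}

orient_values <- function(values, criterion, orientation) {
  if (orientation[[criterion]] == "higher_is_frailer") -values else values
}

# Pinned quantile rule: linear interpolation between order statistics at
# index (n - 1) * p (stats::quantile type 7), so results are
# bit-reproducible.
frail_quantile <- function(x, p = 0.2) {
  unname(quantile(x, probs = p, type = 7, names = FALSE))
}

#' Derive sex-specific 20th-percentile frailty cutoffs
#'
#' For each sex and criterion, the reference distribution is the Old
#' group (vehicle- and PDX-assigned animals pooled, since baseline
#' testing precedes treatment) at baseline. Values are oriented so that
#' frailer = lower, and the cutoff is the 0.20 empirical quantile of the
#' oriented values (linear interpolation between order statistics).
#' Cutoffs are stored on the oriented scale.
#'
#' @param panels Criterion panel rows ([build_criterion_panel()]) at
#'   baseline; rows from non-reference animals are ignored unless
#'   `reference = "all_animals"`.
#' @param animals The cohort's animals table (for sex and group).
#' @param orientation Criterion orientations ([default_orientation()]).
#' @param reference `"old_baseline"` (default): sex-matched Old animals
#'   at baseline, the primary rule. `"all_animals"`: the frailest
#'   quintile across every panelled animal pooled over sexes and groups,
#'   an alternative reference population offered for sensitivity
#'   analyses.
#' @param min_n Minimum non-missing reference values required per
#'   (sex, criterion).
#' @return Tibble `sex`, `criterion`, `cutoff` (oriented scale),
#'   `orientation`, `n_used`.
#' @export
derive_cutoffs <- function(panels, animals,
                           orientation = default_orientation(),
                           reference = c("old_baseline", "all_animals"),
                           min_n = 5) {
  orientation <- check_orientation(orientation)
  reference <- match.arg(reference)
  panels <- dplyr::inner_join(panels, animals, by = "animal_id")

  if (reference == "old_baseline") {
    ref <- dplyr::filter(panels, .data$group %in% c("old_vehicle", "old_pdx"),
                         .data$timepoint == "baseline")
    sexes <- sort(unique(animals$sex))
  } else {
    ref <- panels
    sexes <- "all"
  }

  grid <- tidyr::expand_grid(sex = sexes, criterion = fm_criteria)
  cutoffs <- purrr::pmap_dfr(grid, function(sex, criterion) {
    pool <- if (identical(sex, "all")) ref else ref[ref$sex == sex, ]
    vals <- pool[[criterion]]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
      fail_validation("derive_cutoffs: all values missing for sex=%s, criterion=%s",
                      sex, criterion)
    }
    if (length(vals) < min_n) {
      fail_validation(
        "derive_cutoffs: only %d reference animal(s) for sex=%s, criterion=%s (need >= %d)",
        length(vals), sex, criterion, min_n)
    }
    tibble::tibble(
      sex = sex, criterion = criterion,
      cutoff = frail_quantile(orient_values(vals, criterion, orientation)),
      orientation = orientation[[criterion]],
      n_used = length(vals)
    )
  })
  if (identical(sexes, "all")) {
    # replicate the pooled cutoff for each sex so downstream joins are uniform
    cutoffs <- tidyr::expand_grid(sex2 = sort(unique(animals$sex)),
                                  dplyr::select(cutoffs, -"sex")) |>
      dplyr::rename(sex = "sex2")
  }
  cutoffs
}

#' Flag positive frailty markers for one panel of animals
#'
#' A criterion is a positive marker when the animal's oriented value
#' falls strictly below the sex-matched cutoff ("fell below the 20th
#' percentile"); a value exactly at the cutoff is not positive. A
#' missing criterion is counted as not positive (the animal stays
#' classifiable) and reported via a warning.
#'
#' @param panels Criterion panel rows at one timepoint.
#' @param cutoffs Cutoff table from [derive_cutoffs()].
#' @param animals The cohort's animals table.
#' @param orientation Criterion orientations.
#' @return Tibble `animal_id`, `timepoint`, one logical `pos_*` column
#'   per criterion.
#' @export
flag_positive <- function(panels, cutoffs, animals,
                          orientation = default_orientation()) {
  orientation <- check_orientation(orientation)
  panels <- dplyr::inner_join(
    panels, dplyr::select(animals, "animal_id", "sex"), by = "animal_id")
  unknown_sex <- setdiff(unique(panels$sex), unique(cutoffs$sex))
  if (length(unknown_sex) > 0) {
    fail_validation("flag_positive: no cutoffs for sex: %s",
                    paste(unknown_sex, collapse = ", "))
  }
  out <- panels[c("animal_id", "timepoint")]
  n_missing <- 0L
  for (criterion in fm_criteria) {
    cut_by_sex <- setNames(
      cutoffs$cutoff[cutoffs$criterion == criterion],
      cutoffs$sex[cutoffs$criterion == criterion])
    oriented <- orient_values(panels[[criterion]], criterion, orientation)
    pos <- oriented < cut_by_sex[panels$sex]
    n_missing <- n_missing + sum(is.na(pos))
    pos[is.na(pos)] <- FALSE
    out[[paste0("pos_", criterion)]] <- unname(pos)
  }
  if (n_missing > 0) {
    warn(sprintf(
      "flag_positive: %d missing criterion value(s) counted as not positive",
      n_missing))
  }
  out
}

#' Frailty category from a marker tally
#'
#' Three or more positive frailty markers identify an animal as frail,
#' exactly two as prefrail, and one or zero as robust.
#'
#' @param tally Integer vector of positive-marker counts, each in 0..6.
#' @return Factor with levels robust < prefrail < frail.
#' @export
#' @examples
#' classify_tally(0:6)
classify_tally <- function(tally) {
  if (any(is.na(tally)) || any(tally < 0 | tally > 6) ||
      any(tally != trunc(tally))) {
    fail_validation("classify_tally: tally must be an integer in 0..6")
  }
  category <- ifelse(tally >= 3, "frail",
                     ifelse(tally == 2, "prefrail", "robust"))
  factor(category, levels = fm_categories, ordered = TRUE)
}

#' Classify every animal at one timepoint
#'
#' Composition of [flag_positive()], the marker tally and
#' [classify_tally()], applied to all groups using Old-baseline-derived
#' cutoffs.
#'
#' @inheritParams flag_positive
#' @return Tibble `animal_id`, `timepoint`, the six `pos_*` marker
#'   columns, `tally`, `category`.
#' @export
classify_cohort <- function(panels, cutoffs, animals,
                            orientation = default_orientation()) {
  markers <- flag_positive(panels, cutoffs, animals, orientation)
  pos_cols <- paste0("pos_", fm_criteria)
  markers$tally <- as.integer(rowSums(markers[pos_cols]))
  markers$category <- classify_tally(markers$tally)
  markers
}

#' Baseline-to-endpoint frailty transitions
#'
#' Counts animals moving between categories from baseline to endpoint.
#' Animals classified at baseline but absent at endpoint (death or
#' missing assessment) are tallied in a `lost` destination, so every
#' baseline animal is conserved: all cells sum to the baseline count.
#'
#' @param baseline,endpoint Classification tables
#'   ([classify_cohort()]) for the two timepoints, keyed by
#'   `animal_id`. Every endpoint animal must appear at baseline.
#' @return Tibble `from`, `to`, `count` over all 3 x 4 cells
#'   (`to` includes `"lost"`), with attribute `rates`: the fraction of
#'   robust animals that declined and of prefrail/frail animals that
#'   improved.
#' @export
track_transitions <- function(baseline, endpoint) {
  orphans <- setdiff(endpoint$animal_id, baseline$animal_id)
  if (length(orphans) > 0) {
    fail_validation("track_transitions: animal(s) at endpoint but not baseline: %s",
                    paste(orphans, collapse = ", "))
  }
  to_levels <- c(fm_categories, "lost")
  joined <- dplyr::left_join(
    dplyr::select(baseline, "animal_id", from = "category"),
    dplyr::select(endpoint, "animal_id", to = "category"),
    by = "animal_id")
  joined$to <- as.character(joined$to)
  joined$to[is.na(joined$to)] <- "lost"
  counts <- table(
    from = factor(as.character(joined$from), levels = fm_categories),
    to = factor(joined$to, levels = to_levels))
  out <- tibble::as_tibble(counts, n = "count")
  out$count <- as.integer(out$count)

  rank_of <- function(x) match(x, fm_categories) # lost handled separately
  seen_both <- joined[joined$to != "lost", ]
  robust_base <- seen_both[seen_both$from == "robust", ]
  worse_base <- seen_both[seen_both$from %in% c("prefrail", "frail"), ]
  rates <- c(
    robust_declined = if (nrow(robust_base) > 0) {
      mean(rank_of(robust_base$to) > 1)
    } else NA_real_,
    impaired_improved = if (nrow(worse_base) > 0) {
      mean(rank_of(worse_base$to) < rank_of(as.character(worse_base$from)))
    } else NA_real_
  )
  attr(out, "rates") <- rates
  out
}

#' Survival rate by group and sex
#'
#' @param animals The cohort's animals table.
#' @param group,sex Optional filters; omit to pool.
#' @return Percent of animals alive at endpoint.
#' @export
#' @examples
#' survival_rate(tibble::tibble(
#'   animal_id = as.character(1:20), sex = "female", group = "old_vehicle",
#'   alive_at_endpoint = rep(c(TRUE, FALSE), c(18, 2))))
survival_rate <- function(animals, group = NULL, sex = NULL) {
  pool <- animals
  if (!is.null(group)) pool <- pool[pool$group %in% group, ]
  if (!is.null(sex)) pool <- pool[pool$sex %in% sex, ]
  if (nrow(pool) == 0) {
    fail_validation("survival_rate: no animals in requested group/sex")
  }
  100 * mean(pool$alive_at_endpoint)
}
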