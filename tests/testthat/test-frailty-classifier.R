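# builds a panel tibble directly, with a single varying criterion
panel_of <- function(values, criterion = "td", sex = "female",
                     group = "old_vehicle", timepoint = "baseline",
                     id_prefix = "a") {
  n <- length(values)
  panel <- tibble::tibble(
    animal_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    timepoint = timepoint,
    ws = 30, gft = 100, td = 100, vrw = 5, fi = 0.1, dbw = 0,
    any_missing = FALSE
  )
  panel[[criterion]] <- values
  animals <- tibble::tibble(animal_id = panel$animal_id, sex = sex,
                            group = group, alive_at_endpoint = TRUE)
  list(panel = panel, animals = animals)
}

test_that("cutoffs interpolate the 20th percentile of oriented values", {
  p <- panel_of(1:10)
  cuts <- derive_cutoffs(p$panel, p$animals)
  expect_equal(cuts$cutoff[cuts$criterion == "td" & cuts$sex == "female"],
               2.8)  # index (n-1)p = 1.8 between 2 and 3

  p5 <- panel_of(c(10, 20, 30, 40, 50))
  cuts5 <- derive_cutoffs(p5$panel, p5$animals)
  expect_equal(cuts5$cutoff[cuts5$criterion == "td" & cuts5$sex == "female"],
               18)   # 10 + 0.8 * 10

  expect_equal(unique(cuts$n_used), 10L)
})

test_that("degenerate all-equal values give the common cutoff and no positives", {
  p <- panel_of(rep(42, 8))
  cuts <- derive_cutoffs(p$panel, p$animals)
  expect_equal(cuts$cutoff[cuts$criterion == "td" & cuts$sex == "female"], 42)
  cls <- classify_cohort(p$panel, cuts, p$animals)
  expect_false(any(cls$pos_td))   # strict inequality: ties are not positive
})

test_that("cutoff derivation requires enough reference animals and errors by name", {
  p <- panel_of(1:3)
  expect_error(derive_cutoffs(p$panel, p$animals),
               "sex=female, criterion=",
               class = "frailtymouse_validation_error")
})

test_that("marker flagging is strictly below the cutoff, on the oriented scale", {
  p <- panel_of(1:10)
  cuts <- derive_cutoffs(p$panel, p$animals)
  flags <- flag_positive(p$panel, cuts, p$animals)
  # values 1 and 2 fall strictly below 2.8
  expect_equal(p$panel$animal_id[flags$pos_td],
               p$panel$animal_id[p$panel$td < 2.8])
  expect_equal(sum(flags$pos_td), 2)

  # a value exactly at the cutoff is not positive
  at_cut <- p$panel[1, ]
  at_cut$td <- 2.8
  expect_false(flag_positive(at_cut, cuts, p$animals)$pos_td)
})

test_that("higher-is-frailer criteria are negated before comparison", {
  # fi cutoff from oriented (negated) scores around -0.35
  p <- panel_of(c(0.30, 0.32, 0.35, 0.37, 0.40), criterion = "fi")
  cuts <- derive_cutoffs(p$panel, p$animals)
  fi_cut <- cuts$cutoff[cuts$criterion == "fi" & cuts$sex == "female"]
  expect_equal(fi_cut, quantile(-c(0.30, 0.32, 0.35, 0.37, 0.40), 0.2,
                                names = FALSE))
  probe <- p$panel[1, ]
  probe$fi <- 0.40    # oriented -0.40, below the cutoff -> frailest tail
  expect_true(flag_positive(probe, cuts, p$animals)$pos_fi)
  probe$fi <- 0.30
  expect_false(flag_positive(probe, cuts, p$animals)$pos_fi)
})

test_that("missing criterion values count as not positive, with a warning", {
  p <- panel_of(1:10)
  cuts <- derive_cutoffs(p$panel, p$animals)
  probe <- p$panel[1, ]    # td = 1 would be positive
  probe$td <- NA
  expect_warning(flags <- flag_positive(probe, cuts, p$animals),
                 "missing criterion")
  expect_false(flags$pos_td)
})

test_that("tallies map to categories by the >=3 / ==2 / <=1 rule", {
  expect_equal(as.character(classify_tally(0:6)),
               c("robust", "robust", "prefrail", rep("frail", 4)))
  expect_error(classify_tally(7), "0..6",
               class = "frailtymouse_validation_error")
  expect_error(classify_tally(-1), "0..6",
               class = "frailtymouse_validation_error")
  # monotone: increasing tally never moves toward robust
  cats <- classify_tally(0:6)
  expect_true(all(diff(as.integer(cats)) >= 0))
})

test_that("percentile coverage matches a sort-and-count oracle for n = 5..200", {
  set.seed(101)
  for (n in c(5, 7, 10, 21, 50, 99, 100, 101, 150, 200)) {
    values <- sample(seq_len(10 * n), n)  # distinct, tie-free
    p <- panel_of(values)
    cuts <- derive_cutoffs(p$panel, p$animals)
    cls <- classify_cohort(p$panel, cuts, p$animals)
    oracle <- oracle_quantile_count_below(values)
    expect_equal(cuts$cutoff[cuts$criterion == "td" & cuts$sex == "female"],
                 oracle$cutoff)
    expect_equal(sum(cls$pos_td), oracle$n_below)
  }
  # for 100 distinct values, exactly 20 animals (20%) fall below
  p100 <- panel_of(sample(1:1000, 100))
  cuts100 <- derive_cutoffs(p100$panel, p100$animals)
  cls100 <- classify_cohort(p100$panel, cuts100, p100$animals)
  expect_equal(sum(cls100$pos_td), 20)
})

test_that("cutoffs are derived from Old baseline only", {
  old <- panel_of(1:10)
  cuts_old <- derive_cutoffs(old$panel, old$animals)

  # adding Adult animals must not move any cutoff
  adult <- panel_of(seq(200, 245, by = 5), group = "adult", id_prefix = "b")
  cuts_both <- derive_cutoffs(dplyr::bind_rows(old$panel, adult$panel),
                              dplyr::bind_rows(old$animals, adult$animals))
  expect_equal(cuts_both, cuts_old)

  # endpoint rows of Old animals are excluded too
  ep <- panel_of(rep(1000, 10), timepoint = "endpoint")
  cuts_ep <- derive_cutoffs(dplyr::bind_rows(old$panel, ep$panel),
                            old$animals)
  expect_equal(cuts_ep, cuts_old)
})

test_that("the all-animals reference pools groups and sexes", {
  old <- panel_of(1:10)
  adult <- panel_of(11:20, group = "adult", sex = "male", id_prefix = "b")
  panels <- dplyr::bind_rows(old$panel, adult$panel)
  animals <- dplyr::bind_rows(old$animals, adult$animals)
  cuts <- derive_cutoffs(panels, animals, reference = "all_animals")
  td <- cuts[cuts$criterion == "td", ]
  expect_equal(nrow(td), 2)                     # replicated per sex
  expect_equal(unique(td$cutoff),
               quantile(1:20, 0.2, names = FALSE))
})

test_that("negating a criterion and flipping its orientation leaves classes unchanged", {
  set.seed(33)
  p <- panel_of(round(runif(12, 40, 140), 1))
  cuts <- derive_cutoffs(p$panel, p$animals)
  cls <- classify_cohort(p$panel, cuts, p$animals)

  flipped <- p$panel
  flipped$td <- -flipped$td
  orient <- default_orientation()
  orient["td"] <- "higher_is_frailer"
  cuts_f <- derive_cutoffs(flipped, p$animals, orientation = orient)
  cls_f <- classify_cohort(flipped, cuts_f, p$animals, orientation = orient)
  expect_equal(cls_f$tally, cls$tally)
  expect_equal(cls_f$category, cls$category)
})

test_that("transitions count moves, conserve animals, and track losses", {
  cls <- function(ids, cats, tp) {
    tibble::tibble(animal_id = ids, timepoint = tp,
                   tally = 0L,
                   category = factor(cats, c("robust", "prefrail", "frail"),
                                     ordered = TRUE))
  }
  base <- cls(c("a", "b", "c"), c("robust", "robust", "prefrail"), "baseline")
  end <- cls(c("a", "b", "c"), c("robust", "frail", "robust"), "endpoint")
  tm <- track_transitions(base, end)
  lookup <- function(tm, from, to) tm$count[tm$from == from & tm$to == to]
  expect_equal(lookup(tm, "robust", "robust"), 1L)
  expect_equal(lookup(tm, "robust", "frail"), 1L)
  expect_equal(lookup(tm, "prefrail", "robust"), 1L)
  expect_equal(sum(tm$count), 3L)
  rates <- attr(tm, "rates")
  expect_equal(unname(rates["robust_declined"]), 0.5)
  expect_equal(unname(rates["impaired_improved"]), 1)

  # identical classifications -> diagonal
  tm_id <- track_transitions(base, cls(base$animal_id,
                                       as.character(base$category),
                                       "endpoint"))
  off_diag <- tm_id$from != tm_id$to
  expect_true(all(tm_id$count[off_diag] == 0))

  # a death shows up in the lost column and totals are conserved
  tm_lost <- track_transitions(base, end[1:2, ])
  expect_equal(lookup(tm_lost, "prefrail", "lost"), 1L)
  expect_equal(sum(tm_lost$count), nrow(base))

  expect_error(track_transitions(base[1:2, ], end),
               "endpoint but not baseline",
               class = "frailtymouse_validation_error")
})

test_that("survival rate is the percent alive per group and sex", {
  animals <- tibble::tibble(
    animal_id = as.character(1:25),
    sex = rep(c("female", "male"), c(20, 5)),
    group = rep(c("old_vehicle", "adult"), c(20, 5)),
    alive_at_endpoint = c(rep(TRUE, 18), FALSE, FALSE, rep(TRUE, 5))
  )
  expect_equal(survival_rate(animals, "old_vehicle", "female"), 90)
  expect_equal(survival_rate(animals, "adult"), 100)
  expect_error(survival_rate(animals, "old_pdx"), "no animals",
               class = "frailtymouse_validation_error")
  none <- animals[1:4, ]
  none$alive_at_endpoint <- FALSE
  expect_equal(survival_rate(none), 0)
})
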