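---
title: "Composite frailty assessment in longitudinal mouse cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite frailty assessment in longitudinal mouse cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtymouse)
library(dplyr)
```

## The assessment

Frailty in aging mice is measured here with two complementary
instruments, combined into a single classification.

**Deficit accumulation (frailty index).** A trained rater scores 27
visually assessed health deficits (coat condition, kyphosis, gait
disorders, cataracts, ...) as 0 (absent), 0.5 (mild) or 1 (severe).
The frailty index (FI) is the sum of scores divided by 27, a fraction
in [0, 1]; higher is frailer. The item list is an adaptation of the
standard 31-item clinical instrument for mice with four items removed —
forelimb grip strength, tail stiffening, body temperature and body
weight — because strength and weight enter the composite classification
through dedicated criteria instead. The exact 27 item names are not
fixed by a single published list; `deficit_items()` ships a faithful
reconstruction and any 27 unique names may be substituted.

**Physical frailty phenotype.** Four performance abilities are
measured from raw trials and reduced by fixed protocol rules:

* *walking speed* (`ws`, rpm): the best maximal rotarod speed of three
  trials (`best_walking_speed()`);
* *grip strength* (`gft`): five trials, the single highest and lowest
  discarded, the remaining three averaged
  (`trimmed_grip_strength()`) — with ties exactly one occurrence of
  each extreme is removed, which makes the reduction
  permutation-invariant and bounded by the observed range;
* *endurance* (`td`, m): treadmill distance to exhaustion, a single
  measured value passed through;
* *voluntary activity* (`vrw`, km/day): the mean of four experimental
  wheel days (an acclimation day is excluded upstream).

**Body-weight loss.** The sixth criterion (`dbw`, %/week) is the
average weekly percent change in body weight,
$\mathrm{mean}_i\,100\,(w_{i+1}-w_i)/w_i$ over consecutive recorded
weeks, with the earlier week as denominator. The study design defines
this quantity over the whole timeline, but the classifier needs a
value at both assessments; we evaluate it over weeks 1–4 at baseline
and weeks 1–13 at endpoint, i.e. over exactly the data available at
each assessment. This is a package design choice; a different window
can be passed to `build_criterion_panel()`.

## Classification

The six criteria are assembled per animal and timepoint into a
criterion panel. Classification then proceeds in three steps
(`derive_cutoffs()`, `flag_positive()`, `classify_tally()`):

1. **Cutoffs.** For each sex and criterion, the reference
   distribution is the *Old group at baseline* (vehicle- and
   treatment-assigned animals pooled — baseline testing precedes
   treatment). Values are oriented so that frailer is lower (the FI is
   negated), and the cutoff is the 20th percentile of the oriented
   values. The quantile estimator is pinned: linear interpolation
   between order statistics at index $(n-1)p$ (`stats::quantile`
   type 7), so cutoffs are bit-reproducible. For a tie-free reference
   sample of 100 distinct values exactly 20 animals fall strictly
   below their own cutoff.
2. **Markers.** A criterion is a positive frailty marker when the
   oriented value falls *strictly below* the sex-matched cutoff; a
   value exactly at the cutoff is not positive. A missing criterion
   counts as not positive (logged), so every surviving animal remains
   classifiable.
3. **Category.** Three or more positive markers = frail, exactly two
   = prefrail, one or zero = robust.

Sexes are processed fully independently. An alternative reference
population — the frailest quintile across *all* animals pooled over
sexes and groups — is exposed as
`derive_cutoffs(reference = "all_animals")` for sensitivity analyses;
the sex-matched Old-baseline rule is the primary one.

`track_transitions()` counts baseline-to-endpoint category moves in a
3×4 matrix whose fourth destination, `lost`, holds animals that died
or were not assessed at endpoint, so each baseline animal is conserved
across cells. Derived rates (fraction of robust animals that declined;
fraction of prefrail/frail animals that improved) are attached as an
attribute.

## The synthetic cohort generator

No phenotype-level data are deposited for studies of this design, so
`simulate_cohort()` generates cohorts with the statistical structure
the analysis assumes: two sexes, three groups (Adult reference, Old
vehicle, Old treated with the pro-resolving lipid PDX), two
assessments, weekly body weights, and deaths between baseline and
endpoint.

Per animal, a single latent standard-normal "vigor" factor is shared
by all performance tests (loading 0.6 by default), inducing the
within-animal co-decline that produces realistic multi-criterion
positives. Per-test latent ability is lognormal around the configured
(sex, group, timepoint) mean — lognormal because performance measures
are positive and right-skewed — and raw trials are lognormal around
the latent ability, so the best-of-3, trimmed-mean-of-5 and
mean-of-4 reduction rules are genuinely exercised. Deficit items are
drawn per item with group- and timepoint-specific mild/severe
probabilities, tilted multiplicatively (mean-one) by vigor. Body
weight follows a geometric weekly random walk with group drift;
deaths are sampled per (sex, group) and truncate an animal's endpoint
measurements and late body weights.

`default_sim_config()` encodes the published group-level effect sizes
this pipeline was designed around as its means: baseline treadmill
distance 116/126 m (Adult female/male) versus 70/75 m (Old), with the
gap maintained at endpoint; Old female grip 12.5% below Adult at
baseline and 16% at endpoint; Old male grip about 28% below Adult at
endpoint; Old wheel activity about one third below Adult; Old FI above
Adult throughout; body weight drifting up in Adults and down in Old
groups; and 90%/95% endpoint survival in vehicle-treated Old
females/males, 100% elsewhere. Two deliberate choices deserve
emphasis:

* *Walking speed overlaps between groups* at baseline, reflecting the
  reported absence of group differences on the rotarod. A consequence
  is that roughly 20% of Adults are positive on that single criterion
  (they are scored against the Old reference, which they match), so
  Adult cohorts under the default configuration classify about 95%
  robust rather than 100%. Where a test needs Adults *far from* the
  Old cutoffs on every criterion — the idealised condition under
  which Adults should be essentially all robust — it raises the Adult
  walking-speed means explicitly rather than changing the default.
* *Dispersions are free parameters.* Published group summaries
  constrain means only (means ± SEM at group level); coefficients of
  variation (0.10–0.30 across tests), trial-level noise (0–0.15), the
  vigor loading and the body-weight noise were chosen once at
  magnitudes typical of C57BL/6 phenotyping and are documented
  configuration fields, not estimates.

The generator is seed-deterministic: identical configuration and seed
give byte-identical CSV output. What passing tests on simulated
cohorts show is that the *pipeline* recovers what the generator
encodes; they cannot show that real cohorts satisfy the lognormal,
single-factor or independence-of-death assumptions.

## Numerical and degenerate-input choices

* Quantile estimator pinned to type 7, as above.
* "Fell below" is strict: ties at the cutoff are not positive. In the
  fully degenerate case (all reference values equal) the cutoff
  equals the common value and no animal is positive.
* Cutoff derivation requires at least 5 non-missing reference values
  per (sex, criterion) and errors by name below that.
* Trial-count invariants (3/5/1/4) are enforced at I/O; an `NA` trial
  value is a recorded-as-missing measurement and propagates to a
  missing criterion (grip, whose trim is undefined on an incomplete
  set) or is dropped (best-of / mean-of reductions).
* Fewer than two body weights in the ΔBW window yields a missing
  criterion with a warning rather than an error.
* SEM is `sd/sqrt(n)`; single-value cells report `NA`, empty cells
  are omitted with a warning.

## Problem sizes

The test suite simulates cohorts of up to 500 animals per group for
calibration-recovery checks and 60–200 per group for classification
properties; the acceptance script uses 500 per group. These sizes put
Monte-Carlo standard errors of group means well below the effect
sizes being recovered while keeping a full run to a few minutes.

## Limitations

* Criterion panels store one grip value; the underlying protocol
  records combined fore- and hindlimb pulls, and published figures
  label the metric "maximal forelimb force" — whether classification
  used forelimb-only or combined strength is ambiguous in the source
  protocol, and the package is agnostic (it classifies whatever grip
  values it is given).
* The baseline ΔBW window (weeks 1–4) is a reconstruction, as above.
* Mortality is independent of vigor in the generator; real deaths are
  plausibly selective, which would bias endpoint group means upward.
* No inferential statistics (ANOVA, logrank) are included; the
  package stops at scores, categories, transitions and descriptive
  summaries.
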