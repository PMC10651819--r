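# frailtymouse

Frailty is the age-related state of reduced physiological reserve that
makes an organism vulnerable to stressors. In preclinical aging
research two mouse instruments dominate: the **frailty index** (FI), a
deficit-accumulation score over graded health deficits, and the
Fried-style **physical frailty phenotype**, which classifies animals
from performance criteria. `frailtymouse` implements a composite of
the two for longitudinal (baseline/endpoint) cohorts, for biologists
and biostatisticians analysing intervention studies in aging mice:
raw phenotype trials → per-animal criterion values → sex-specific
percentile cutoffs → frail/prefrail/robust classification →
transition and survival reporting, plus a calibrated synthetic cohort
generator so every stage is testable without animal data.

## The assessment in brief

Six criteria per animal and timepoint:

| criterion | meaning | reduction |
|---|---|---|
| `ws` | walking speed (rotarod, rpm) | best of 3 trials |
| `gft` | grip force | 5 trials, drop max and min, mean of 3 |
| `td` | treadmill distance to exhaustion (m) | single run |
| `vrw` | voluntary wheel activity (km/day) | mean of 4 days |
| `fi` | frailty index | sum of 27 item scores in {0, 0.5, 1} / 27 |
| `dbw` | body-weight change (%/week) | mean of weekly percent changes |

For each sex and criterion, the 20th percentile of the **Old group at
baseline** (values oriented so frailer = lower; linear interpolation
at index (n−1)p) is the cutoff. An animal strictly below the cutoff is
positive for that marker; with tally *t* over the six markers,

- *t* ≥ 3 → **frail**, *t* = 2 → **prefrail**, *t* ≤ 1 → **robust**.

## Worked example

```r
library(frailtymouse)
library(dplyr)

cohort <- simulate_cohort(seed = 42)   # default three-group, two-sex study
res <- run_pipeline(cohort, "out")     # writes six artifact CSVs + run log

head(res$cutoffs, 7)
#>   sex    criterion cutoff orientation       n_used
#> 1 female ws        28.3   lower_is_frailer      33
#> 2 female gft       76.4   lower_is_frailer      33
#> 3 female td        51.8   lower_is_frailer      33
#> 4 female vrw        2.84  lower_is_frailer      33
#> 5 female fi        -0.185 higher_is_frailer     33
#> 6 female dbw       -0.467 lower_is_frailer      33
#> 7 male   ws        27.6   lower_is_frailer      33
```

Each row is the sex-specific 20th-percentile cutoff for one criterion,
derived from the 33 Old animals of that sex at baseline (vehicle and
treated pooled, since baseline precedes treatment). `fi` cutoffs are on
the negated (oriented) scale because a higher index is frailer: the
female value −0.185 means an FI above 0.185 is in the frailest
quintile.

```r
inner_join(res$classifications, cohort$animals, by = "animal_id") |>
  count(group, timepoint, category) |>
  tidyr::pivot_wider(names_from = category, values_from = n, values_fill = 0)
#>   group       timepoint robust prefrail frail
#> 1 adult       baseline      29        1     0
#> 2 adult       endpoint      30        0     0
#> 3 old_pdx     baseline      17        8     3
#> 4 old_pdx     endpoint      16        5     7
#> 5 old_vehicle baseline      22       11     5
#> 6 old_vehicle endpoint      10        8    16
```

Adults stay (almost) uniformly robust; vehicle-treated Old animals
slide toward frail between baseline and endpoint while the treated
group is partly protected — the decline pattern the generator encodes.
`res$transitions` gives the per-animal moves behind these margins
(including a `lost` column for deaths) and `res$survival` the percent
alive per group and sex:

```r
res$survival
#>   sex    group       survival_pct
#> 1 female adult              100
#> 2 female old_vehicle         94.7
#> 3 female old_pdx            100
#> 4 male   adult              100
#> 5 male   old_vehicle         84.2
#> 6 male   old_pdx            100
```

## Input format

Four UTF-8 CSVs with header rows (see `read_cohort()` /
`write_cohort()`; missing measurements are empty fields):

- `animals.csv` — `animal_id,sex,group,alive_at_endpoint`, e.g.
  `f_o1,female,old_vehicle,TRUE`
- `trials.csv` — `animal_id,timepoint,test,trial_index,value`, e.g.
  `f_o1,baseline,grip_strength,1,84.2`
- `bodyweight.csv` — `animal_id,week,weight_g`, e.g. `f_o1,1,30.1`
- `deficits.csv` — `animal_id,timepoint,item,score`, e.g.
  `f_o1,baseline,kyphosis,0.5`

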