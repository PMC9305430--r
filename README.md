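# fsanps

Scoring and analysis engine for receipt-based nutrition tracking: the British
Food Standards Agency Nutrient Profiling System (FSA-NPS, the point scheme
underlying Nutri-Score) applied to grocery products and digital loyalty-card
receipts, a future-self avatar state machine driven by recent steps and
basket history, a category-level substitution recommender, a synthetic
two-arm trial cohort generator, and the nonparametric statistics used to
analyze such trials.

## Who is this for

Researchers building or evaluating mobile-health interventions that track
nutrition automatically through grocery receipts. No participant-level data
ship with the package: the cohort simulator generates catalogs, receipts,
step streams, logins, Likert surveys and attrition so that every component
is testable end to end.

## The score at the core

A product's FSA-NPS score is computed per 100 g. Four unfavourable
components — energy density (kJ), sugars (g), saturated fat (g) and sodium
(mg) — each earn 0–10 points by threshold bands; three favourable components
— fruits/vegetables/legumes/nuts (%), fiber (g) and protein (g) — each earn
0–5 points. The total is

    score = (energy + sugars + satfat + sodium) − (fvln + fiber + protein*)

on a scale from −15 (most healthy) to +40 (least healthy), where protein
points (*) are not counted when negative points reach 11 or more unless the
fruit/vegetable component is at its 5-point maximum. A basket's dietary
index (DI) is the energy-weighted mean of its products' scores, computed
separately for solid foods and beverages.

The avatar maps behaviour to five features, each with five states: fitness
(mean steps/day, past 7 days), heart health (50% sodium + 50% saturated-fat
points), mental well-being (50% fruit/vegetable + 50% fiber points), bone
health (protein points) and blood sugar (sugar points), the nutritional
drivers averaged over the past 12 baskets. The recommender pools the last 7
baskets, ranks up to four food categories by their mass-weighted
contribution to the four negative point dimensions, and proposes
strictly-lower-scoring in-category substitutes.

## Worked example

```r
library(fsanps)

# score one product per 100 g
p <- nutrient_profile(energy_kj = 1900, sugars_g = 30, satfat_g = 8,
                      sodium_mg = 450, fvln_pct = 2, fiber_g = 2,
                      protein_g = 5)
fsa_component_points(p)
#> FSA-NPS component points
#>   negative: energy 5, sugars 6, sat fat 7, sodium 4 (total 22)
#>   positive: fvln 0, fiber 2, protein 3 (total 5)
#>   total score: +20  (-15 most healthy .. +40 least healthy)

# simulate a participant and evaluate their avatar
catal <- generate_catalog(n_products = 400, n_categories = 50, seed = 7)
cfg <- cohort_config(n_products = 400, n_categories = 50)
part <- generate_participant(cfg, "intervention", catalog = catal, seed = 7)
avatar_state(part$steps, part$receipts, catal,
             as_of = max(part$receipts$date), user_age = 44)
#> Future-self avatar (age 64) as of 2021-02-04
#>   fitness_state     state 4/5 (driver 8859.14, window 7)
#>   heart_health      state 4/5 (driver 3.21, window 12)
#>   mental_wellbeing  state 2/5 (driver 1.27, window 12)
#>   bone_health       state 4/5 (driver 3.58, window 12)
#>   blood_sugar       state 5/5 (driver 1.37, window 12)

recommendation_report(part$receipts, catal)
#> Basket analysis over 7 basket(s)
#>   1. category 46: combined contribution 0.231 pts (2 alternatives)
#>   2. category 45: combined contribution 0.181 pts (0 alternatives)
#>   3. category 8: combined contribution 0.157 pts (1 alternative)
#>   4. category 20: combined contribution 0.149 pts (1 alternative)
#>   tip: tip_generic_balance
```

The avatar's age is the participant's age +20 years; a state of 5 is best,
and drivers are the window means the state is read from — here, 8859
steps/day put fitness in state 4 (state 5 starts at 10,000), while 1.37
sugar points out of 10 earn the best blood-sugar state. The recommendation
ranks the categories whose purchases carried the most negative points per
gram of the whole basket set; "2 alternatives" means the catalog holds two
same-category products scoring strictly below the participant's purchases.

Trial-side, the design calculation behind a two-arm steps outcome:

```r
sample_size(delta = 1566, sd = 2620, alpha = 0.05, power = 0.80)$total
#> [1] 88
```

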