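# CSV schemas (version 1)

All files are comma-separated, UTF-8, dot decimal separator, with a header
row. Missing values are empty fields. Unknown columns are ignored with a
warning; missing required columns are a schema error.

## observations.csv

One row per source-group cell. Summary sources carry statistics; sources
with individual records appear as stub rows (`data_form = individual`)
whose records live in `individuals.csv` under the same `source_id`.

| column | type | notes |
|---|---|---|
| source_id | text | unique per survey |
| country | text | ISO3-style country code |
| year | decimal | survey midpoint year |
| group | enum | `children`, `pregnant`, `non_pregnant`, `women_combined` |
| coverage | enum | `national`, `subnational` |
| n_regions_covered | integer | required for subnational rows |
| data_form | enum | `individual`, `summary` |
| n | integer | sample size (>= 1) |
| mean_hb | g/L | summary rows; must lie in (40, 190) |
| sd_hb | g/L | optional, > 0 |
| prev_anaemia | proportion | optional, in [0, 1] |
| prev_severe | proportion | optional, in [0, 1] |
| altitude_adjusted | logical | whether haemoglobin is already altitude adjusted |
| smoking_adjusted | logical | whether the source adjusted for smoking |
| age_range_matches | logical | source covers 6-59 months / 15-49 years exactly |
| pregnant_fraction | proportion | required for `women_combined` summaries |

## individuals.csv

One row per measured person.

| column | type | notes |
|---|---|---|
| source_id, country, year, group | | as above |
| hb | g/L | plausibility window 25-220 after adjustment |
| altitude_m | metres | optional altitude of residence |
| gestational_weeks | weeks | optional, in [0, 44]; pregnancy is classified strictly after 8 weeks |
| age | months (children) or years (women) | |
| cluster_id | text | optional |
| coverage, n_regions_covered, altitude_adjusted, age_range_matches | | survey-level provenance |

## covariates.csv

Complete for every modelled country-year: `country`, `year`,
`maternal_education` (years), `urban_prop`, `abs_latitude` (degrees),
`hb_disorder_prev` (constant over time within a country), `mean_bmi`
(women), `mean_waz` (children).

## regions.csv

`country`, `region`; every country maps to exactly one region.

## population.csv

`country`, `year`, `group`, `population` (persons, > 0).

## altitude_bands.csv

`country`, `band_midpoint_m`, `population_share`; shares sum to 1 within a
country.

## truth.csv (synthetic worlds only)

`country`, `year`, `group`, `true_mean` (g/L), `true_prev`,
`true_severe_prev` (proportions below the group cutoffs).
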