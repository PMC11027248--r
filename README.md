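# migcost

Probabilistic cost-of-illness modelling of migraine in a working population.

`migcost` implements a prevalence-based, bottom-up (micro-costing) model of
the annual economic burden of migraine among the employees of a large
organisation, from three perspectives:

- **healthcare system** — direct medical costs: outpatient consultations (by
  facility level, public and private), diagnostic tests, acute and preventive
  medicines, and complementary therapies;
- **employer** — indirect costs: absenteeism valued by the human-capital
  approach (lost workdays × daily wage);
- **societal** — the sum of the two, also expressed per patient.

Around that cost engine the package provides a synthetic HARDSHIP-style
survey generator, utilisation summary tables with episodic-vs-chronic (EM/CM)
group comparisons, one-way (tornado) sensitivity analysis, Monte Carlo
probabilistic sensitivity analysis (PSA), and a one-call reporting pipeline
driven by a single YAML configuration.

## Model in brief

Sufferer counts come from workforce size, gender split, and gender-specific
prevalence:

    S_g = N · share_g · prevalence_g,   S = S_male + S_female

Direct costs multiply annual per-patient quantities by unit costs and scale
by `S`. Per-patient quantities are EM/CM mixture expectations,

    q = (1 − π_CM) · rate_EM · x_EM + π_CM · rate_CM · x_CM,

with the per-user statistic `x` taken as the **median** for the deterministic
point estimate and the **mean** as the centre of the PSA distributions (beta
for proportions, gamma for unit costs and quantities, lognormal for lost
workdays; parameters sampled independently, out-of-domain draws rejected and
resampled). Indirect costs are `S_g · daily_wage_g · lost_workdays_3mo_g · 4`
summed over genders. All money is in 2022 USD; `convert_to_usd_2022()`
handles deflator + PPP conversion of local-currency inputs.

The baseline configuration (`inst/extdata/default_config.yaml`) describes a
141,800-employee workforce with survey-style epidemiology and utilisation
rates; its **unit costs and fees are synthetic stand-ins**, so absolute cost
levels from the default configuration are illustrative. See the vignette
`vignettes/cost-of-illness-methods.Rmd` for full methods, assumptions, and
limitations.

## Worked example

```r
library(migcost)

cfg    <- load_config()                               # packaged baseline
params <- cost_parameters_from_config(cfg, "median")  # point inputs
point_estimate(params)
#> Annual cost of illness (thousand 2022 USD)
#>   Sufferers:           38,404.0
#>   Outpatient, public:  920.4
#>   Outpatient, private: 345.6
#>   Medicines:           618.0
#>   Therapies:           2,017.0
#>   Direct total:        3,901.1
#>   Indirect total:      38,665.1
#>   Societal total:      42,566.2
#>   Per patient (USD):   1108.4
```

One-way sensitivity (±20% per parameter, sorted by swing):

```r
head(one_way(params), 4)
#>   name                     total_low total_high    swing
#> 1 prevalence_female        38013594.  47118791. 9105197.
#> 2 daily_wage_female        38430827.  46701559. 8270732.
#> 3 lost_workdays_3mo_female 38430827.  46701559. 8270732.
#> 4 prevalence_male          38605553.  46526833. 7921280.
```

Probabilistic sensitivity analysis (10,000 draws, seeded and reproducible):

```r
run_psa(params, default_distributions(cfg), n_draws = 10000, seed = 1)
#> Probabilistic sensitivity analysis: 10000 draws (seed 1)
#>   direct       median    4249083.5  [p25    3855383.0, p75    4676934.4] USD
#>   indirect     median  101393189.8  [p25   69899488.2, p75  149156567.6] USD
#>   total        median  105846922.1  [p25   74187450.2, p75  153421415.2] USD
#>   per_patient  median       2764.9  [p25       1946.7, p75       3979.9] USD
```

Synthetic survey → summaries → survey-derived costing:

```r
survey <- generate_survey(cfg, seed = 20220501)   # 1,929 respondents
survey_prevalence(survey)                         # prevalence, EM/CM split
summarise_utilisation(survey)                     # Table-1/2 style summary
compare_groups(survey, "consult_public_tertiary") # chi-square/Fisher + Mann–Whitney
cost_parameters_from_survey(survey, cfg, "median")
```

Everything at once (writes survey.csv, utilisation_summary.csv, costs.json/csv,
tornado.csv, psa_summary.json, manifest.json):

```r
run_pipeline(mode = "all", seed = 1, out_dir = "migcost-output")
```

or from the shell:

```sh
Rscript scripts/migcost.R --mode all --seed 1 --out-dir migcost-output
```

## License

MIT (see `LICENSE`).
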