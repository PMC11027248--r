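---
title: "Methods: cost-of-illness modelling of migraine in a working population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-of-illness modelling of migraine in a working population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(migcost)
```

## Scientific problem

`migcost` estimates the annual economic burden of migraine among the employees
of a large organisation (the baseline configuration describes a banking
workforce of 141,800 people). It is a prevalence-based, bottom-up
(micro-costing) cost-of-illness model: per-patient resource-use quantities are
multiplied by unit costs and scaled up to the number of sufferers, rather than
allocating an aggregate expenditure top-down.

Costs are reported from three perspectives:

* **healthcare-system perspective** — direct medical costs: outpatient
  consultations, diagnostic tests, medicines, and complementary therapies;
* **employer perspective** — indirect productivity costs: absenteeism valued by
  the human-capital approach (lost workdays times the daily wage);
* **societal perspective** — the sum of the two.

All money is expressed in 2022 US dollars. `convert_to_usd_2022()` implements
the conversion used for any locally denominated input: inflate (or deflate) to
the 2022 price level with a GDP deflator series, then divide by a 2022
purchasing-power-parity factor (local currency units per USD).

## Model structure

Let $N$ be the workforce size, $s_m$ the male share, and $p_m, p_f$ the
gender-specific one-year migraine prevalences. The sufferer counts are

$$ S_m = N\, s_m\, p_m, \qquad S_f = N\,(1 - s_m)\, p_f, \qquad S = S_m + S_f. $$

Fractional sufferer counts are kept as-is; the model works in expectations.

**Direct costs.** With $q_j$ the annual per-patient quantity of resource $j$
and $c_j$ its unit cost,

$$ C_{\text{direct}} = S \sum_j q_j\, c_j $$

split into four components:

1. *Outpatient consultations.* Public facilities (community clinic, primary,
   secondary, tertiary hospital, traditional-medicine hospital) use a
   facility-level consultation fee per visit. Private-facility visits are
   costed with a single bundled average fee per visit
   (`avg_fee_private_visit`), standing in for an all-cause average charge that
   already includes tests and dispensing; private visits therefore contribute
   nothing to the other components.
2. *Diagnostic tests* (CT, MRI, transcranial Doppler, EEG) at a unit cost per
   scan, public-sector visits only.
3. *Medicines*: for each product, a daily cost multiplied by annual days of
   use per patient.
4. *Complementary therapies* (acupuncture, tuina, moxibustion, cupping; public
   vs informal providers): per-cell cost per treated patient multiplied by the
   share of patients treated.

**Indirect costs.** Human-capital absenteeism, by gender $g$:

$$ C_{\text{indirect}} = \sum_{g} S_g \cdot w_g \cdot L_g \cdot 4, $$

where $w_g$ is the daily wage (monthly wage / 22 working days), $L_g$ the lost
workdays over a 3-month recall window, and 4 annualises the quarter
(`lost_workdays_annualisation`). Presenteeism is deliberately excluded.

**Per-patient cost** is the societal total divided by $S$.

### Episodic vs chronic mixture

Respondent-level resource use differs sharply between episodic migraine (EM,
fewer than 15 headache days per month) and chronic migraine (CM, 15 or more).
Per-patient quantities entering the cost model are class-mixture expectations:
with $\pi$ the CM share among sufferers, a utilisation rate $r$ and a
per-user quantity statistic $x$,

$$ q = (1-\pi)\, r_{EM}\, x_{EM} + \pi\, r_{CM}\, x_{CM}. $$

`cost_parameters_from_config(cfg, statistic = c("median", "mean"))` selects
which per-user statistic is used. The package convention is **medians for the
deterministic point estimate** (survey quantity distributions are heavily
right-skewed, so the median is the robust central estimate) and **means as the
centres of the probabilistic distributions** (Monte Carlo propagation is an
expectation calculation, and the sampling distributions below are
parameterised by their means). The two conventions give deliberately different
baseline levels; this is a documented modelling choice, not an inconsistency.

## Synthetic survey generator

Real HARDSHIP-style survey microdata are not distributable, so
`generate_survey()` draws a synthetic record-level table that emulates one:
one row per respondent with gender, migraine status, EM/CM class, monthly
migraine days, per-item consultation/test/medication/therapy use, 3-month lost
workdays, and monthly wage. What it preserves by construction:

* marginal structure — gender share, gender-specific prevalence, CM share,
  and per-item utilisation rates by class are Bernoulli draws at the
  configured probabilities, so sample proportions converge to them;
* printed ranges — per-user counts come from a shifted negative-binomial
  (dispersion `size = 1.5`) centred near the configured mean and
  rejection-truncated to the configured min–max; monthly migraine days use a
  truncated geometric consistent with the EM (1–14) / CM (15–30) definition;
* skewness — therapy spending and lost workdays are gamma-distributed (lost
  workdays: shape 0.6, capped at 66, i.e. three months of 22 working days).

What it does **not** preserve: any joint dependence between utilisation
categories beyond the EM/CM stratification (published tables report only
marginals), item-level nonresponse, and within-person correlation over time.
All draws come from a single seeded RNG stream (`withr::with_seed`), so a
given configuration and seed reproduce the table byte-for-byte.

Acute-medication use is recorded over a one-month recall window and
annualised by `annualisation$acute_medicine_factor` (default 12);
preventive-medication days are already annual.

For checks against published *counts* rather than distributions,
`survey_from_counts()` builds a deterministic record-level table consistent
with a set of marginal counts (respondents, migraine-positive, CM, consulters,
tested, medicine users, no-resource users), so headline percentages can be
recomputed from rows rather than asserted.

## Utilisation summaries and group comparisons

`summarise_utilisation()` reproduces a survey-article utilisation table:
per-item user counts, percentages among all migraineurs and within EM/CM, and
per-user summary statistics by class, plus aggregate rows (any consultation,
any test, any medicine, any therapy, none of these). `compare_groups()` tests
EM vs CM differences:

* utilisation rates: Pearson chi-square without continuity correction,
  switching to Fisher's exact test when any expected cell count is below 5;
* per-user quantities: Mann–Whitney (Wilcoxon rank-sum), exact when both
  groups have at most 8 users; a fully tied comparison (zero rank variance)
  is reported as $p = 1$.

These use `stats::chisq.test`, `stats::fisher.test`, and `stats::wilcox.test`
directly rather than re-implementations.

## Sensitivity analyses

**One-way (tornado).** `one_way()` varies each selected parameter by
±20% (`delta` configurable), holding the rest at baseline, and records the
resulting societal totals and the swing (high minus low). Proportions are
capped at 1 after upward scaling. Bars are sorted by descending swing with
alphabetical tie-breaks, so output order is deterministic.

**Probabilistic (PSA).** `run_psa()` propagates parameter uncertainty with
Monte Carlo simulation, default 10,000 draws. `default_distributions()`
assigns, following standard health-economics practice:

* **beta** for proportions (prevalences, therapy-treated shares),
  moment-matched from the point value and a coefficient of variation
  (default 0.10), with the implied variance capped below the Bernoulli bound;
* **gamma** for non-negative unit costs and quantities (CV defaults 0.30);
* **lognormal** for lost workdays, `meanlog = log(mean)`, `sdlog = 0.75`,
  reflecting strong right skew.

Parameters are sampled independently; no correlation structure is imposed
because no joint information is available. Draws outside a parameter's domain
are rejected and resampled, with a warning if more than 1% of draws are
rejected. Summaries report the median and interquartile range (type-7
quantiles); the PSA median generally exceeds the median-based point estimate
because the distributions are centred on means of right-skewed inputs.

Evaluation is vectorised: each sampled parameter becomes a column of an
$n_{\text{draws}} \times k$ matrix and all draws are costed in one pass, so
10,000 draws evaluate in well under a second.

## Configuration and typical problem sizes

Every numeric input lives in one YAML file; `load_config()` reads the packaged
baseline (`inst/extdata/default_config.yaml`) and `validate_config()` rejects
out-of-range values naming the offending key. **The epidemiology, utilisation
rates, and quantity distributions in the baseline are survey-style published
statistics, but the unit costs, fees, daily medicine costs, and therapy spends
are synthetic stand-ins** chosen to be order-of-magnitude plausible for the
setting; anyone using the package for a real costing exercise must replace
them with tariffs from their own system.

Typical sizes: surveys of $10^3$–$10^4$ respondents generate in well under a
second; the full pipeline (`run_pipeline()`: simulate → summarise → cost →
tornado → 10,000-draw PSA → artefacts) completes in a few seconds.

```{r example}
cfg <- load_config()
params <- cost_parameters_from_config(cfg, statistic = "median")
point_estimate(params)
```

```{r psa}
psa <- run_psa(params, default_distributions(cfg), n_draws = 2000, seed = 1)
psa$summary
```

## Limitations

* Indirect costs cover absenteeism only; presenteeism, caregiver time, and
  informal care are excluded, so the societal total is conservative.
* Parameter independence in the PSA ignores plausible correlations (e.g.
  between prevalence and lost workdays), likely understating tail spread.
* The class-mixture expectation assumes utilisation rates and per-user
  quantities are independent within class.
* The private-sector bundled fee assumes private visits include tests and
  medicines; if they do not, direct costs are understated.
* Synthetic unit costs mean absolute cost levels from the default
  configuration are illustrative, not estimates for any real institution.
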