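# Baseline configuration: migraine cost-of-illness model for bank employees,
# Guizhou province, 2022. All monetary values are 2022 USD (PPP-converted).
#
# Survey-anchored blocks (prevalence, utilisation rates, visit/day summaries,
# therapy use rates) reproduce the published survey tables. Unit costs and
# per-patient therapy spends are SYNTHETIC stand-ins: the study's tariff-derived
# unit-cost tables are not public, so domain-plausible 2022 magnitudes
# (provincial tariff / national outpatient-fee orders of magnitude, converted
# at PPP 4.19 CNY per USD) are used instead. See the methods vignette.

survey:
  n_respondents: 1929
  prop_male: 0.504
  prevalence_male: 0.250
  prevalence_female: 0.292
  prob_cm_given_migraine: 0.112   # 59 of 525 migraine-positive
  rng_seed: 20220501

population:
  size: 141800                    # financial-sector employees, Guizhou, 2022
  prop_male: 0.504

wages:
  monthly_wage_male: 1845.8       # 2022 USD; daily wage 83.9 at 22 working days
  monthly_wage_female: 1845.8
  working_days_per_month: 22

# Lost workdays due to migraine over a 3-month recall, per migraine patient.
# Individual-level distribution is heavily right-skewed and zero-inflated:
# point estimation uses the median, PSA is centred on the mean.
# gen_shape parameterises the gamma used by the synthetic survey generator.
lost_workdays_3mo:
  male:    {median: 3.0, mean: 7.0, gen_shape: 0.6}
  female:  {median: 3.0, mean: 7.0, gen_shape: 0.6}

annualisation:
  acute_medicine_factor: 12       # preceding-month recall -> annual days
  lost_workdays_factor: 4         # 3-month recall -> annual

# Outpatient consultations within one year, by facility level.
# rate_*: proportion of the EM/CM class with >= 1 visit; visit-count summaries
# are over users. private_facility uses the bundled all-cause average fee per
# outpatient visit (consultations + tests).
consultations:
  public_clinic:
    unit_cost: 2.4
    em: {rate: 0.086, mean: 2.9, sd: 1.6, median: 2.0, min: 1, max: 6}
    cm: {rate: 0.096, mean: 1.8, sd: 0.5, median: 2.0, min: 1, max: 2}
  public_primary:
    unit_cost: 3.6
    em: {rate: 0.048, mean: 3.2, sd: 2.2, median: 2.1, min: 1, max: 9}
    cm: {rate: 0.039, mean: 3.9, sd: 2.7, median: 3.8, min: 2, max: 6}
  public_secondary:
    unit_cost: 6.0
    em: {rate: 0.063, mean: 2.8, sd: 2.0, median: 2.0, min: 1, max: 8}
    cm: {rate: 0.094, mean: 4.1, sd: 3.0, median: 3.0, min: 1, max: 9}
  public_tertiary:
    unit_cost: 9.5
    em: {rate: 0.038, mean: 1.8, sd: 0.7, median: 2.0, min: 1, max: 3}
    cm: {rate: 0.118, mean: 2.0, sd: 0.6, median: 2.0, min: 1, max: 3}
  public_tcm:
    unit_cost: 7.2
    em: {rate: 0.029, mean: 3.9, sd: 2.9, median: 3.0, min: 1, max: 9}
    cm: {rate: 0.088, mean: 2.6, sd: 1.5, median: 2.1, min: 1, max: 5}
  private_facility:
    unit_cost: 81.8               # avg all-cause fee per private outpatient visit
    em: {rate: 0.018, mean: 4.5, sd: 2.3, median: 5.0, min: 1, max: 8}
    cm: {rate: 0.048, mean: 6.2, sd: 1.8, median: 5.6, min: 5, max: 8}

# Diagnostic tests within one year, by type (public pathway).
tests:
  ct:
    unit_cost: 71.6
    em: {rate: 0.096, mean: 1.1, sd: 0.3, median: 1.0, min: 1, max: 2}
    cm: {rate: 0.216, mean: 1.3, sd: 0.9, median: 1.0, min: 1, max: 4}
  mri:
    unit_cost: 143.2
    em: {rate: 0.052, mean: 1.0, sd: 0.0, median: 1.0, min: 1, max: 1}
    cm: {rate: 0.109, mean: 1.3, sd: 0.5, median: 1.0, min: 1, max: 2}
  tcd:
    unit_cost: 38.2
    em: {rate: 0.029, mean: 1.2, sd: 0.4, median: 1.0, min: 1, max: 2}
    cm: {rate: 0.108, mean: 1.3, sd: 0.5, median: 1.0, min: 1, max: 2}
  eeg:
    unit_cost: 52.5
    em: {rate: 0.052, mean: 1.3, sd: 0.6, median: 1.0, min: 1, max: 3}
    cm: {rate: 0.099, mean: 1.6, sd: 0.9, median: 1.1, min: 1, max: 3}

# Medicines: acute = days used in the preceding month; preventive = days used
# in the preceding year. daily_cost in 2022 USD at label-recommended dose,
# cheapest available product.
medicines:
  acute:
    gastrodia_capsule:
      daily_cost: 0.80
      em: {rate: 0.044, mean: 7.2, sd: 8.7, median: 5.0, min: 1, max: 30}
      cm: {rate: 0.010, mean: 15.0, sd: 0.0, median: 15.0, min: 15, max: 15}
    toutongning_capsule:
      daily_cost: 0.90
      em: {rate: 0.023, mean: 6.5, sd: 9.1, median: 3.7, min: 1, max: 30}
      cm: {rate: 0.058, mean: 21.2, sd: 15.0, median: 30.0, min: 3, max: 30}
    zhengtian_pill:
      daily_cost: 0.70
      em: {rate: 0.010, mean: 17.0, sd: 11.3, median: 16.3, min: 3, max: 30}
      cm: {rate: 0.0, mean: 0, sd: 0, median: 0, min: 0, max: 0}
    aspirin:
      daily_cost: 0.05
      em: {rate: 0.238, mean: 4.5, sd: 5.8, median: 2.0, min: 1, max: 30}
      cm: {rate: 0.267, mean: 8.1, sd: 9.9, median: 3.0, min: 1, max: 30}
    nsaid_non_aspirin:
      daily_cost: 0.10
      em: {rate: 0.311, mean: 4.7, sd: 5.8, median: 3.0, min: 1, max: 30}
      cm: {rate: 0.387, mean: 6.2, sd: 7.2, median: 3.0, min: 1, max: 30}
    acetaminophen:
      daily_cost: 0.06
      em: {rate: 0.096, mean: 7.4, sd: 9.4, median: 3.0, min: 1, max: 30}
      cm: {rate: 0.122, mean: 11.9, sd: 11.8, median: 9.4, min: 1, max: 30}
    triptans:
      daily_cost: 10.0
      em: {rate: 0.011, mean: 7.5, sd: 10.0, median: 3.9, min: 2, max: 30}
      cm: {rate: 0.037, mean: 5.0, sd: 1.3, median: 5.0, min: 4, max: 6}
    ergot_alkaloids:
      daily_cost: 1.50
      em: {rate: 0.009, mean: 4.7, sd: 1.4, median: 5.0, min: 3, max: 6}
      cm: {rate: 0.0, mean: 0, sd: 0, median: 0, min: 0, max: 0}
  preventive:
    calcium_antagonists:
      daily_cost: 0.15
      em: {rate: 0.104, mean: 14.7, sd: 40.6, median: 7.0, min: 7, max: 360}
      cm: {rate: 0.054, mean: 35.8, sd: 69.9, median: 7.6, min: 7, max: 154}
    beta1_antagonists:
      daily_cost: 0.10
      em: {rate: 0.011, mean: 9.1, sd: 6.4, median: 7.0, min: 7, max: 25}
      cm: {rate: 0.019, mean: 220.0, sd: 0.0, median: 220.0, min: 220, max: 220}
    antiepileptics:
      daily_cost: 0.45
      em: {rate: 0.041, mean: 14.8, sd: 14.9, median: 8.1, min: 7, max: 66}
      cm: {rate: 0.010, mean: 78.0, sd: 0.0, median: 78.0, min: 78, max: 78}
    vitamin_b2:
      daily_cost: 0.03
      em: {rate: 0.037, mean: 33.0, sd: 88.6, median: 7.0, min: 7, max: 360}
      cm: {rate: 0.044, mean: 24.3, sd: 24.0, median: 21.5, min: 7, max: 45}
    candesartan:
      daily_cost: 0.35
      em: {rate: 0.016, mean: 10.4, sd: 6.8, median: 7.0, min: 7, max: 30}
      cm: {rate: 0.010, mean: 85.0, sd: 0.0, median: 85.0, min: 85, max: 85}

# Complementary therapies in the preceding year, by therapy and facility class
# (public vs informal). spend = annual per-patient out-of-pocket spend (USD);
# cv_spend parameterises the gamma used by the synthetic generator.
therapies:
  acupuncture_public:    {rate_em: 0.060, rate_cm: 0.150, spend: 300, cv_spend: 0.8}
  tuina_public:          {rate_em: 0.031, rate_cm: 0.101, spend: 200, cv_spend: 0.8}
  moxibustion_public:    {rate_em: 0.020, rate_cm: 0.050, spend: 150, cv_spend: 0.8}
  acupuncture_informal:  {rate_em: 0.030, rate_cm: 0.070, spend: 150, cv_spend: 0.8}
  tuina_informal:        {rate_em: 0.040, rate_cm: 0.080, spend: 100, cv_spend: 0.8}
  moxibustion_informal:  {rate_em: 0.051, rate_cm: 0.120, spend: 120, cv_spend: 0.8}
  cupping_informal:      {rate_em: 0.040, rate_cm: 0.080, spend:  80, cv_spend: 0.8}

# Probabilistic sensitivity analysis: distribution families are assigned by
# parameter type (beta for proportions, gamma for unit costs and quantities,
# lognormal for lost workdays); spreads below are assumed coefficients of
# variation / log-sd.
psa:
  n_draws: 10000
  cv_proportion: 0.10
  cv_unit_cost: 0.30
  cv_quantity: 0.30
  sdlog_lost_workdays: 0.75

tornado:
  delta: 0.20

currency:
  base_year: 2022
  ppp: 4.19                       # CNY per USD, 2022
  gdp_deflator:                   # index, 2020 = 100
    2020: 100.0
    2021: 104.6
    2022: 108.3
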