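test_that("sufferer counts follow population x gender share x prevalence", {
  p <- cost_parameters(141800, 0.504, 0.250, 0.292)
  ns <- n_sufferers(p)
  expect_equal(ns$male, 17866.8)
  expect_equal(ns$female, 20537.1776)
  expect_equal(ns$total, ns$male + ns$female)

  p0 <- cost_parameters(141800, 0.504, 0, 0)
  expect_equal(n_sufferers(p0)$total, 0)
})

test_that("outpatient costs sum facility consultations, tests, and the bundled private fee", {
  p <- one_patient_params(
    unit_cost_consultation = c(a = 10, b = 20),
    consultations_per_patient = c(a = 3, b = 1),
    unit_cost_test = c(t = 5), tests_per_patient = c(t = 2)
  )
  op <- outpatient_costs(p)
  expect_equal(op$public, 60)  # 10*3 + 20*1 + 5*2
  expect_equal(op$private, 0)

  p2 <- one_patient_params(
    avg_fee_private_visit = 81.8,
    consultations_per_patient = c(private_facility = 5)
  )
  expect_equal(outpatient_costs(p2)$private, 81.8 * 5)
  expect_equal(outpatient_costs(p2)$public, 0)

  p3 <- one_patient_params(unit_cost_consultation = c(a = 7),
                           consultations_per_patient = c(a = 1))
  expect_equal(outpatient_costs(p3)$public, 7)
})

test_that("medicine costs are the sum of daily cost times annual days", {
  p <- one_patient_params(
    daily_cost_medicine = c(x = 0.5, y = 2.0),
    annual_medication_days_per_patient = c(x = 24, y = 12)
  )
  expect_equal(medicine_costs(p), 36.0)
  expect_equal(medicine_costs(one_patient_params()), 0)
  p1 <- one_patient_params(daily_cost_medicine = c(x = 1.0),
                           annual_medication_days_per_patient = c(x = 36))
  expect_equal(medicine_costs(p1), 36.0)
})

test_that("therapy costs are per-patient cost times receiving patients", {
  p <- cost_parameters(
    5, 1, 1, 0,
    therapy_cost_per_patient = c(a = 100, b = 50),
    therapy_users_per_patient = c(a = 0.6, b = 0.4)
  )
  expect_equal(therapy_costs(p), 100 * 3 + 50 * 2)
  expect_equal(therapy_costs(one_patient_params(
    therapy_cost_per_patient = c(a = 100),
    therapy_users_per_patient = c(a = 0))), 0)
})

test_that("indirect costs value lost workdays at the daily wage, annualised by 4", {
  p <- one_patient_params(daily_wage_male = 83.9, lost_workdays_3mo_male = 5)
  ind <- indirect_costs(p)
  expect_equal(ind$male, 1678)  # 83.9 * 5 * 4
  expect_equal(ind$total, 1678)

  p0 <- one_patient_params(daily_wage_male = 83.9, lost_workdays_3mo_male = 0)
  expect_equal(indirect_costs(p0)$total, 0)

  # homogeneity: doubling prevalence doubles indirect costs
  base <- cost_parameters(1000, 0.5, 0.2, 0.3,
                          daily_wage_male = 80, daily_wage_female = 90,
                          lost_workdays_3mo_male = 3, lost_workdays_3mo_female = 4)
  doubled <- base
  doubled$prevalence_male <- 0.4
  doubled$prevalence_female <- 0.6
  expect_equal(indirect_costs(doubled)$total, 2 * indirect_costs(base)$total)
})

test_that("the point estimate satisfies the accounting identities exactly", {
  p <- cost_parameters_from_config(default_cfg(), "median")
  bd <- point_estimate(p)
  expect_identical(
    bd$direct_total,
    bd$cost_outpatient_public + bd$cost_outpatient_private +
      bd$cost_medicines + bd$cost_therapies
  )
  expect_identical(bd$societal_total, bd$direct_total + bd$indirect_total)
  expect_equal(bd$per_patient_societal,
               bd$societal_total / (bd$n_sufferers_male + bd$n_sufferers_female))
  expect_equal(sum(bd$cost_medicines_by_type), bd$cost_medicines)
  comps <- unlist(bd[c("cost_outpatient_public", "cost_outpatient_private",
                       "cost_medicines", "cost_therapies", "indirect_male",
                       "indirect_female")])
  expect_true(all(comps >= 0))
})

test_that("zero utilisation and zero lost workdays give zero cost with defined per-patient value", {
  p <- cost_parameters(141800, 0.504, 0.25, 0.292)
  bd <- point_estimate(p)
  expect_equal(bd$societal_total, 0)
  expect_equal(bd$per_patient_societal, 0)
  expect_gt(bd$n_sufferers_male + bd$n_sufferers_female, 0)
})

test_that("every cost component is homogeneous of degree 1 in its unit cost", {
  p <- cost_parameters_from_config(default_cfg(), "median")
  bd <- point_estimate(p)
  # doubling one unit cost raises the total by exactly that component's value
  p2 <- set_param(p, "unit_cost_test.ct", 2 * get_param(p, "unit_cost_test.ct"))
  bd2 <- point_estimate(p2)
  ct_component <- get_param(p, "unit_cost_test.ct") *
    get_param(p, "tests_per_patient.ct") * n_sufferers(p)$total
  expect_equal(bd2$societal_total - bd$societal_total, ct_component)

  # scaling a quantity scales its component identically
  p3 <- set_param(p, "tests_per_patient.ct", 2 * get_param(p, "tests_per_patient.ct"))
  expect_equal(point_estimate(p3)$societal_total, bd2$societal_total)
})

test_that("a used item without a unit cost is a configuration error naming the key", {
  expect_error(
    point_estimate(one_patient_params(
      consultations_per_patient = c(mystery_clinic = 2))),
    "mystery_clinic")
  expect_error(
    point_estimate(one_patient_params(
      daily_cost_medicine = c(a = 1),
      annual_medication_days_per_patient = c(a = 3, orphan_drug = 2))),
    "orphan_drug")
  expect_error(cost_parameters(100, 0.5, 1.2, 0.3), "prevalence_male")
})

test_that("survey-derived parameters feed the same engine", {
  cfg <- default_cfg()
  s <- generate_survey(cfg, seed = 31, n_respondents = 4000)
  p <- cost_parameters_from_survey(s, cfg, "median")
  bd <- point_estimate(p)
  expect_gt(bd$direct_total, 0)
  expect_identical(bd$societal_total, bd$direct_total + bd$indirect_total)
  # consultations are annual already: per-patient quantity equals the sample mean
  pos <- s[s$has_migraine, ]
  expect_equal(p$consultations_per_patient[["public_clinic"]],
               mean(pos$consult_public_clinic))
})
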