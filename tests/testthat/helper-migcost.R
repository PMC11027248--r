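# Shared fixtures, built in code.

default_cfg <- function() load_config()

# Minimal parameter set with exactly one sufferer, for hand-summed oracles.
one_patient_params <- function(...) {
  cost_parameters(
    population_size = 1, prop_male = 1,
    prevalence_male = 1, prevalence_female = 0,
    ...
  )
}

# A tiny hand-built survey (<= 30 records) for brute-force recount checks.
tiny_survey <- function() {
  tab <- tibble::tibble(
    respondent_id = 1:12,
    gender = rep(c("male", "female"), 6),
    has_migraine = c(rep(TRUE, 9), rep(FALSE, 3)),
    migraine_days_per_month = c(20, 16, 15, 5, 3, 8, 2, 14, 1, 0, 0, 0),
    consult_public_clinic = c(2, 0, 1, 3, 0, 0, 1, 0, 0, 0, 0, 0),
    consult_private_facility = c(0, 5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    test_ct = c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
    acute_aspirin = c(10, 0, 4, 2, 0, 3, 0, 0, 0, 0, 0, 0),
    prev_vitamin_b2 = c(0, 30, 0, 0, 0, 0, 7, 0, 0, 0, 0, 0),
    therapy_acupuncture_public = c(250, 0, 0, 0, 120, 0, 0, 0, 0, 0, 0, 0),
    lost_workdays_3mo = c(9, 12, 6, 2, 0, 1, 0, 3, 0, 0, 0, 0),
    monthly_wage = rep(1845.8, 12)
  )
  tab$migraine_class <- classify_migraine(tab$migraine_days_per_month,
                                          tab$has_migraine)
  class(tab) <- c("migcost_survey", class(tab))
  tab
}
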