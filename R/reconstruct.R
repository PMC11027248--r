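#' Reconstruct a record-level survey from published marginal counts
#'
#' Builds a minimal respondent-level table consistent with a set of published
#' marginal counts: total respondents, migraine positives, chronic-migraine
#' cases, respondents with at least one outpatient consultation, at least one
#' diagnostic test, at least one medicine, and respondents using no resources
#' at all. Useful for recomputing published percentages from record-level
#' data with the same summarisation code used for real or synthetic surveys.
#' The arrangement places the no-resource respondents last and overlaps
#' consultation, test and medicine users within the remaining block, which is
#' always feasible when each user count is at most `n_migraine -
#' n_no_resources`.
#'
#' @param n_respondents,n_migraine,n_cm,n_any_consultation,n_any_test,n_any_medicine,n_no_resources
#'   Non-negative integers; defaults encode the baseline survey margins
#'   (1,929 respondents, 525 migraine positives, 59 CM, 114 consulters, 91
#'   tested, 276 medicine users, 227 using nothing).
#' @return A `migcost_survey` tibble with one consultation, one test, one
#'   acute-medicine and one therapy column.
#' @export
survey_from_counts <- function(n_respondents = 1929, n_migraine = 525,
                               n_cm = 59, n_any_consultation = 114,
                               n_any_test = 91, n_any_medicine = 276,
                               n_no_resources = 227) {
  active <- n_migraine - n_no_resources
  if (n_migraine > n_respondents || n_cm > n_migraine ||
      max(n_any_consultation, n_any_test, n_any_medicine) > active) {
    stop("inconsistent marginal counts", call. = FALSE)
  }
  has_mig <- seq_len(n_respondents) <= n_migraine
  is_cm <- seq_len(n_respondents) <= n_cm
  days <- ifelse(!has_mig, 0L, ifelse(is_cm, 15L, 5L))
  consult <- as.numeric(seq_len(n_respondents) <= n_any_consultation)
  test <- as.numeric(seq_len(n_respondents) <= n_any_test)
  med_rows <- seq(active - n_any_medicine + 1, length.out = n_any_medicine)
  med <- as.numeric(seq_len(n_respondents) %in% med_rows)
  tab <- tibble::tibble(
    respondent_id = seq_len(n_respondents),
    gender = rep(c("male", "female"), length.out = n_respondents),
    has_migraine = has_mig,
    migraine_days_per_month = days,
    migraine_class = classify_migraine(days, has_mig),
    consult_public_clinic = consult,
    test_ct = test,
    acute_aspirin = med,
    therapy_acupuncture_public = 0,
    lost_workdays_3mo = 0,
    monthly_wage = 0
  )
  class(tab) <- c("migcost_survey", class(tab))
  tab
}
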