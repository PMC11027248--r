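# Build a survey of n_em EM and n_cm CM patients with one utilisation column
# holding the given user quantities (zeros are non-users).
two_class_survey <- function(em_values, cm_values, col = "test_ct") {
  n <- length(em_values) + length(cm_values)
  tab <- tibble::tibble(
    respondent_id = seq_len(n),
    gender = rep("female", n),
    has_migraine = TRUE,
    migraine_days_per_month = c(rep(5, length(em_values)), rep(20, length(cm_values))),
    lost_workdays_3mo = 0,
    monthly_wage = 0
  )
  tab$migraine_class <- classify_migraine(tab$migraine_days_per_month, TRUE)
  tab[[col]] <- c(em_values, cm_values)
  class(tab) <- c("migcost_survey", class(tab))
  tab
}

test_that("summaries match a brute-force recount on a small survey", {
  s <- tiny_survey()
  summ <- summarise_utilisation(s)

  # independent recount by direct loops
  pos <- s[s$has_migraine, ]
  n_pos <- nrow(pos)
  for (col in c("consult_public_clinic", "test_ct", "acute_aspirin",
                "prev_vitamin_b2", "therapy_acupuncture_public")) {
    users <- which(pos[[col]] > 0)
    row <- summ[summ$item == sub("^[a-z]+_", "", col) &
                  summ$group != "aggregate", ]
    expect_equal(row$n_users, length(users))
    expect_equal(row$pct_all, 100 * length(users) / n_pos)
    for (cls in c("EM", "CM")) {
      idx <- which(pos$migraine_class == cls)
      u <- intersect(users, idx)
      pct <- 100 * length(u) / length(idx)
      expect_equal(row[[paste0("pct_", tolower(cls))]], pct)
      vals <- pos[[col]][u]
      if (length(vals) > 0) {
        expect_equal(row[[paste0("median_", tolower(cls))]], median(vals))
        expect_equal(row[[paste0("mean_", tolower(cls))]], mean(vals))
        expect_equal(row[[paste0("min_", tolower(cls))]], min(vals))
        expect_equal(row[[paste0("max_", tolower(cls))]], max(vals))
      }
    }
  }
  # aggregates recounted independently
  any_cons <- sum(pos$consult_public_clinic > 0 | pos$consult_private_facility > 0)
  expect_equal(summ$n_users[summ$item == "any_facility"], any_cons)
  none <- sum(rowSums(as.matrix(
    pos[grep("^(consult|test|acute|prev|therapy)_", names(pos))])) == 0)
  expect_equal(summ$n_users[summ$item == "no_resources"], none)
})

test_that("a single user of an item yields median = value and an absent SD", {
  s <- tiny_survey()
  summ <- summarise_utilisation(s)
  row <- summ[summ$item == "vitamin_b2", ]
  expect_equal(row$mean_cm, 30)
  expect_true(is.na(row$sd_cm))
  expect_equal(row$median_cm, 30)
  expect_equal(row$min_cm, 30)
  expect_equal(row$max_cm, 30)
})

test_that("overall percentage is the class-size-weighted mixture of EM and CM percentages", {
  s <- generate_survey(default_cfg(), seed = 17, n_respondents = 3000)
  summ <- summarise_utilisation(s)
  n_em <- attr(summ, "n_em"); n_cm <- attr(summ, "n_cm")
  n_pos <- attr(summ, "n_migraine")
  mix <- (summ$pct_em * n_em + summ$pct_cm * n_cm) / n_pos
  expect_equal(summ$pct_all, mix, tolerance = 1e-12)
})

test_that("empty migraine-positive input is an error", {
  s <- tiny_survey()
  s$has_migraine <- FALSE
  expect_error(summarise_utilisation(s), "migraine-positive")
})

test_that("rate comparison switches to Fisher's exact test for sparse tables", {
  # 18 of 466 EM vs 7 of 59 CM users: smallest expected cell 2.81 < 5
  s <- two_class_survey(c(rep(1, 18), rep(0, 448)), c(rep(1, 7), rep(0, 52)))
  cmp <- compare_groups(s, "test_ct")
  expect_equal(cmp$rate_method, "fisher")
  expect_equal(cmp$rate_p, 0.01496572, tolerance = 1e-6)
  expect_lt(cmp$rate_p, 0.05)
})

test_that("rate comparison uses the chi-square test when all expected cells are >= 5", {
  s <- two_class_survey(c(rep(1, 50), rep(0, 150)), c(rep(1, 30), rep(0, 70)))
  cmp <- compare_groups(s, "test_ct")
  expect_equal(cmp$rate_method, "chisq")
  tab <- matrix(c(50, 150, 30, 70), 2, byrow = TRUE)
  expect_equal(cmp$rate_p, chisq.test(tab, correct = FALSE)$p.value)
})

test_that("identical EM and CM distributions are not declared different", {
  s <- two_class_survey(c(rep(2, 10), rep(0, 30)), c(rep(2, 10), rep(0, 30)))
  cmp <- compare_groups(s, "test_ct")
  expect_gt(cmp$rate_p, 0.05)
  expect_gt(cmp$quantity_p, 0.05)
})

test_that("complete separation yields the exact Mann-Whitney tail probability", {
  # all CM counts exceed all EM counts; 3 vs 3 users: p = 2 / choose(6, 3)
  s <- two_class_survey(c(1, 2, 3, 0, 0), c(10, 11, 12, 0))
  cmp <- compare_groups(s, "test_ct")
  expect_equal(cmp$quantity_p, 0.1)
})

test_that("swapping EM and CM labels leaves two-sided p-values unchanged", {
  s <- generate_survey(default_cfg(), seed = 23, n_respondents = 3000)
  swapped <- s
  swapped$migraine_class[s$migraine_class == "EM"] <- "CM"
  swapped$migraine_class[s$migraine_class == "CM"] <- "EM"
  for (item in c("test_ct", "acute_aspirin", "any_facility")) {
    a <- compare_groups(s, item)
    b <- compare_groups(swapped, item)
    expect_equal(a$rate_p, b$rate_p, tolerance = 1e-12)
    expect_equal(a$quantity_p, b$quantity_p, tolerance = 1e-12)
  }
})

test_that("an item used by nobody gets a no-data flag, not an error", {
  s <- two_class_survey(rep(0, 5), rep(0, 4))
  cmp <- compare_groups(s, "test_ct")
  expect_true(cmp$no_data)
  expect_true(is.na(cmp$rate_p))
  expect_error(compare_groups(s, "not_a_column"), "unknown item")
})

test_that("annual quantities annualise the acute one-month recall by 12", {
  tab <- tibble::tibble(
    respondent_id = 1:2, gender = c("male", "female"),
    has_migraine = TRUE, migraine_days_per_month = c(5, 20),
    acute_aspirin = c(3, 0), prev_vitamin_b2 = c(0, 30),
    therapy_acupuncture_public = 0,
    lost_workdays_3mo = c(4, 8), monthly_wage = c(2200, 1100)
  )
  tab$migraine_class <- classify_migraine(tab$migraine_days_per_month, TRUE)
  class(tab) <- c("migcost_survey", class(tab))
  aq <- derive_annual_quantities(tab)
  expect_equal(aq$medication_days_per_patient[["aspirin"]], mean(c(3, 0)) * 12)
  expect_equal(aq$medication_days_per_patient[["vitamin_b2"]], mean(c(0, 30)))
  expect_equal(aq$therapy_users_share[["acupuncture_public"]], 0)
  expect_equal(aq$therapy_spend_per_user[["acupuncture_public"]], 0)
  expect_equal(aq$lost_workdays_3mo_median[["male"]], 4)
  expect_equal(aq$monthly_wage_median[["female"]], 1100)
})
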