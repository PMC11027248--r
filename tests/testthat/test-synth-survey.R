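test_that("chronic migraine classification uses the 15-day threshold", {
  expect_equal(classify_migraine(15, TRUE), "CM")
  expect_equal(classify_migraine(14, TRUE), "EM")
  expect_equal(classify_migraine(20, FALSE), "none")
  expect_equal(classify_migraine(c(0, 14.9, 15, 30), c(TRUE, TRUE, TRUE, TRUE)),
               c("EM", "EM", "CM", "CM"))
  expect_error(classify_migraine(-1, TRUE), "non-negative")
})

test_that("identical configuration and seed reproduce the survey exactly", {
  cfg <- default_cfg()
  s1 <- generate_survey(cfg, seed = 42, n_respondents = 400)
  s2 <- generate_survey(cfg, seed = 42, n_respondents = 400)
  expect_identical(s1, s2)
  s3 <- generate_survey(cfg, seed = 43, n_respondents = 400)
  expect_false(identical(s1, s3))
})

test_that("zero prevalence yields a survey with no migraine and no utilisation", {
  cfg <- default_cfg()
  cfg$survey$prevalence_male <- 0
  cfg$survey$prevalence_female <- 0
  s <- generate_survey(cfg, seed = 7, n_respondents = 300)
  expect_false(any(s$has_migraine))
  expect_true(all(s$migraine_class == "none"))
  util <- as.matrix(s[grep("^(consult|test|acute|prev|therapy)_", names(s))])
  expect_equal(sum(util), 0)
  expect_equal(sum(s$lost_workdays_3mo), 0)
})

test_that("non-migraine records carry structurally zero utilisation", {
  s <- generate_survey(default_cfg(), seed = 11, n_respondents = 2000)
  neg <- s[!s$has_migraine, ]
  util <- as.matrix(neg[grep("^(consult|test|acute|prev|therapy)_", names(neg))])
  expect_equal(sum(util), 0)
  expect_equal(sum(neg$lost_workdays_3mo), 0)
})

test_that("degenerate chronic assignment puts every case at >= 15 days", {
  cfg <- default_cfg()
  cfg$survey$prob_cm_given_migraine <- 1
  s <- generate_survey(cfg, seed = 5, n_respondents = 500)
  pos <- s[s$has_migraine, ]
  expect_gt(nrow(pos), 0)
  expect_true(all(pos$migraine_days_per_month >= 15))
  expect_true(all(pos$migraine_class == "CM"))
  expect_true(all(pos$migraine_days_per_month <= 30))
})

test_that("migraine-positive count at the survey scale falls in its binomial 99% interval", {
  # n = 1929, gender-weighted prevalence 0.270832: 99% interval [473, 573]
  s <- generate_survey(default_cfg(), seed = 20220501)
  expect_equal(nrow(s), 1929)
  n_mig <- sum(s$has_migraine)
  expect_gte(n_mig, 473)
  expect_lte(n_mig, 573)
})

test_that("configured utilisation rates are recovered at n = 10,000", {
  cfg <- default_cfg()
  s <- generate_survey(cfg, seed = 99, n_respondents = 10000)
  pos <- s[s$has_migraine, ]
  em <- pos[pos$migraine_class == "EM", ]
  cm <- pos[pos$migraine_class == "CM", ]
  checks <- list(
    list(col = "consult_public_clinic", em = 0.086, cm = 0.096),
    list(col = "test_ct", em = 0.096, cm = 0.216),
    list(col = "acute_nsaid_non_aspirin", em = 0.311, cm = 0.387),
    list(col = "prev_calcium_antagonists", em = 0.104, cm = 0.054),
    list(col = "therapy_acupuncture_public", em = 0.060, cm = 0.150)
  )
  for (ck in checks) {
    for (cls in c("em", "cm")) {
      tab <- if (cls == "em") em else cm
      k <- sum(tab[[ck$col]] > 0)
      n <- nrow(tab)
      expect_gte(k, qbinom(0.005, n, ck[[cls]]))
      expect_lte(k, qbinom(0.995, n, ck[[cls]]))
    }
  }
  # EM/CM split recovery
  expect_gte(nrow(cm), qbinom(0.005, nrow(pos), 0.112))
  expect_lte(nrow(cm), qbinom(0.995, nrow(pos), 0.112))
})

test_that("user counts respect the configured ranges and lost workdays the 66-day cap", {
  s <- generate_survey(default_cfg(), seed = 3, n_respondents = 8000)
  pos <- s[s$has_migraine, ]
  items <- config_items(default_cfg())
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    pfx <- c(consultation = "consult_", test = "test_",
             acute_medicine = "acute_", preventive_medicine = "prev_")[[it$group]]
    for (cls in c("EM", "CM")) {
      rate <- if (cls == "EM") it$rate_em else it$rate_cm
      if (rate == 0) next
      x <- pos[[paste0(pfx, it$item)]][pos$migraine_class == cls]
      x <- x[x > 0]
      lo <- if (cls == "EM") it$min_em else it$min_cm
      hi <- if (cls == "EM") it$max_em else it$max_cm
      if (length(x) > 0) {
        expect_gte(min(x), lo)
        expect_lte(max(x), hi)
      }
    }
  }
  expect_true(all(pos$lost_workdays_3mo <= 66))
  expect_true(all(s$lost_workdays_3mo >= 0))
})

test_that("invalid generator configuration raises a configuration error", {
  cfg <- default_cfg()
  cfg$survey$prevalence_female <- 1.3
  expect_error(generate_survey(cfg, seed = 1), "prevalence_female")
  expect_error(generate_survey(default_cfg(), seed = 1, n_respondents = 0),
               "n_respondents")
})
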