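#' Construct the cost-model parameter set
#'
#' Houses every input of the decision-analytic model: the target population
#' and its gender split, gender-specific migraine prevalence, unit costs for
#' public-facility consultations (tariff-based, per facility level) and
#' diagnostic tests, the bundled all-cause average fee per private outpatient
#' visit (consultations and tests jointly), daily medicine costs, per-patient
#' annual complementary-therapy costs, per-patient annual utilisation
#' quantities, daily wages by gender, and 3-month lost workdays per patient by
#' gender. All monetary values are unscaled 2022 USD; "thousand USD" appears
#' only at the reporting layer. Quantities are per migraine patient and are
#' scaled by the prevalence-weighted sufferer count, so the same engine runs
#' on survey-derived or configuration-supplied inputs.
#'
#' @param population_size Persons in the target workforce.
#' @param prop_male Male share of the workforce, in \[0, 1\].
#' @param prevalence_male,prevalence_female Migraine prevalence by gender.
#' @param unit_cost_consultation Named vector: 2022 USD per consultation, per
#'   public facility level.
#' @param avg_fee_private_visit Bundled average fee per private outpatient
#'   visit (2022 USD).
#' @param consultations_per_patient Named vector of annual visits per patient,
#'   per facility level, including `private_facility`.
#' @param unit_cost_test,tests_per_patient Named vectors over test types.
#' @param daily_cost_medicine,annual_medication_days_per_patient Named vectors
#'   over medicines (days already annualised).
#' @param therapy_cost_per_patient,therapy_users_per_patient Named vectors
#'   over (therapy, facility class) cells: annual per-patient cost and the
#'   share of patients using the cell.
#' @param daily_wage_male,daily_wage_female 2022 USD per working day
#'   (monthly wage / working days per month).
#' @param lost_workdays_3mo_male,lost_workdays_3mo_female Lost workdays per
#'   patient over a 3-month recall.
#' @param working_days_per_month Working days per month (wage denominator).
#' @param lost_workdays_annualisation Factor extrapolating the 3-month recall
#'   to a full year.
#' @return A list of class `migcost_params`.
#' @export
cost_parameters <- function(population_size, prop_male,
                            prevalence_male, prevalence_female,
                            unit_cost_consultation = numeric(0),
                            avg_fee_private_visit = 0,
                            consultations_per_patient = numeric(0),
                            unit_cost_test = numeric(0),
                            tests_per_patient = numeric(0),
                            daily_cost_medicine = numeric(0),
                            annual_medication_days_per_patient = numeric(0),
                            therapy_cost_per_patient = numeric(0),
                            therapy_users_per_patient = numeric(0),
                            daily_wage_male = 0, daily_wage_female = 0,
                            lost_workdays_3mo_male = 0,
                            lost_workdays_3mo_female = 0,
                            working_days_per_month = 22,
                            lost_workdays_annualisation = 4) {
  p <- list(
    population_size = population_size,
    prop_male = prop_male,
    prevalence_male = prevalence_male,
    prevalence_female = prevalence_female,
    unit_cost_consultation = unit_cost_consultation,
    avg_fee_private_visit = avg_fee_private_visit,
    consultations_per_patient = consultations_per_patient,
    unit_cost_test = unit_cost_test,
    tests_per_patient = tests_per_patient,
    daily_cost_medicine = daily_cost_medicine,
    annual_medication_days_per_patient = annual_medication_days_per_patient,
    therapy_cost_per_patient = therapy_cost_per_patient,
    therapy_users_per_patient = therapy_users_per_patient,
    daily_wage_male = daily_wage_male,
    daily_wage_female = daily_wage_female,
    lost_workdays_3mo_male = lost_workdays_3mo_male,
    lost_workdays_3mo_female = lost_workdays_3mo_female,
    working_days_per_month = working_days_per_month,
    lost_workdays_annualisation = lost_workdays_annualisation
  )
  validate_params(p)
  structure(p, class = c("migcost_params", "list"))
}

validate_params <- function(p) {
  props <- c("prop_male", "prevalence_male", "prevalence_female")
  for (nm in props) {
    if (any(p[[nm]] < 0 | p[[nm]] > 1)) {
      stop("parameter ", nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  nonneg <- setdiff(names(p), props)
  for (nm in nonneg) {
    if (any(p[[nm]] < 0)) stop("parameter ", nm, " must be non-negative", call. = FALSE)
  }
  used <- function(q) names(q)[vapply(seq_along(q), function(i) any(q[[i]] > 0), logical(1))]
  need <- setdiff(setdiff(used(p$consultations_per_patient), "private_facility"),
                  names(p$unit_cost_consultation))
  if (length(need) > 0) {
    stop("missing unit_cost_consultation for: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  need <- setdiff(used(p$tests_per_patient), names(p$unit_cost_test))
  if (length(need) > 0) {
    stop("missing unit_cost_test for: ", paste(need, collapse = ", "), call. = FALSE)
  }
  need <- setdiff(used(p$annual_medication_days_per_patient),
                  names(p$daily_cost_medicine))
  if (length(need) > 0) {
    stop("missing daily_cost_medicine for: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  need <- setdiff(used(p$therapy_users_per_patient),
                  names(p$therapy_cost_per_patient))
  if (length(need) > 0) {
    stop("missing therapy_cost_per_patient for: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  invisible(p)
}

#' Build cost parameters from a configuration
#'
#' Per-patient annual quantities are class-mixture expectations over the item
#' tables: for each item, `(1 - p_CM) * rate_EM * stat_EM + p_CM * rate_CM *
#' stat_CM`, where `stat` is the median (`statistic = "median"`, the point
#' estimation convention for skewed inputs) or the mean (`statistic = "mean"`,
#' the centring convention for PSA distributions). Acute medicine days are
#' annualised by the configured factor; preventive days are annual already.
#'
#' @param cfg A `migcost_config`.
#' @param statistic `"median"` or `"mean"`; summary statistic used for
#'   skewed quantity and lost-workday inputs.
#' @return A `migcost_params` object.
#' @export
cost_parameters_from_config <- function(cfg, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  validate_config(cfg)
  w_cm <- cfg$survey$prob_cm_given_migraine
  w_em <- 1 - w_cm
  items <- config_items(cfg)

  stat_col <- function(cls) paste0(statistic, "_", cls)
  qty <- function(tab) {
    q <- w_em * tab$rate_em * ifelse(tab$rate_em > 0, tab[[stat_col("em")]], 0) +
      w_cm * tab$rate_cm * ifelse(tab$rate_cm > 0, tab[[stat_col("cm")]], 0)
    stats::setNames(q, tab$item)
  }

  cons <- items[items$group == "consultation", ]
  tst <- items[items$group == "test", ]
  acu <- items[items$group == "acute_medicine", ]
  prv <- items[items$group == "preventive_medicine", ]
  ther <- config_therapies(cfg)

  acute_factor <- cfg$annualisation$acute_medicine_factor %||% 12
  med_days <- c(qty(acu) * acute_factor, qty(prv))
  med_cost <- stats::setNames(c(acu$unit_cost, prv$unit_cost), c(acu$item, prv$item))

  pub <- cons[cons$item != "private_facility", ]
  priv <- cons[cons$item == "private_facility", ]
  wd <- cfg$wages$working_days_per_month

  lw <- vapply(c("male", "female"), function(g) {
    v <- cfg$lost_workdays_3mo[[g]]
    if (statistic == "median") v$median else v$mean
  }, numeric(1))

  cost_parameters(
    population_size = cfg$population$size,
    prop_male = cfg$population$prop_male,
    prevalence_male = cfg$survey$prevalence_male,
    prevalence_female = cfg$survey$prevalence_female,
    unit_cost_consultation = stats::setNames(pub$unit_cost, pub$item),
    avg_fee_private_visit = if (nrow(priv) > 0) priv$unit_cost else 0,
    consultations_per_patient = qty(cons),
    unit_cost_test = stats::setNames(tst$unit_cost, tst$item),
    tests_per_patient = qty(tst),
    daily_cost_medicine = med_cost,
    annual_medication_days_per_patient = med_days,
    therapy_cost_per_patient = stats::setNames(ther$spend, ther$item),
    therapy_users_per_patient = stats::setNames(
      w_em * ther$rate_em + w_cm * ther$rate_cm, ther$item),
    daily_wage_male = cfg$wages$monthly_wage_male / wd,
    daily_wage_female = cfg$wages$monthly_wage_female / wd,
    lost_workdays_3mo_male = lw[["male"]],
    lost_workdays_3mo_female = lw[["female"]],
    working_days_per_month = wd,
    lost_workdays_annualisation = cfg$annualisation$lost_workdays_factor %||% 4
  )
}

#' Build cost parameters from a respondent-level survey
#'
#' Unit costs and the target population come from the configuration;
#' per-patient annual quantities, therapy user shares and spends, lost
#' workdays and wages come from the survey via
#' [derive_annual_quantities()].
#'
#' @param survey A `migcost_survey`.
#' @param cfg A `migcost_config` supplying unit costs and population.
#' @param statistic Summary statistic for lost workdays (`"median"` for point
#'   estimation, `"mean"` for PSA centring).
#' @return A `migcost_params` object.
#' @export
cost_parameters_from_survey <- function(survey, cfg,
                                        statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  validate_config(cfg)
  aq <- derive_annual_quantities(
    survey, acute_factor = cfg$annualisation$acute_medicine_factor %||% 12)
  items <- config_items(cfg)
  cons <- items[items$group == "consultation", ]
  tst <- items[items$group == "test", ]
  med <- items[items$group %in% c("acute_medicine", "preventive_medicine"), ]
  ther <- config_therapies(cfg)
  wd <- cfg$wages$working_days_per_month
  lw <- if (statistic == "median") aq$lost_workdays_3mo_median else aq$lost_workdays_3mo_mean
  lw[is.na(lw)] <- 0
  wage <- aq$monthly_wage_median
  wage[is.na(wage)] <- 0

  pub <- cons[cons$item != "private_facility", ]
  priv <- cons[cons$item == "private_facility", ]

  cost_parameters(
    population_size = cfg$population$size,
    prop_male = cfg$population$prop_male,
    prevalence_male = cfg$survey$prevalence_male,
    prevalence_female = cfg$survey$prevalence_female,
    unit_cost_consultation = stats::setNames(pub$unit_cost, pub$item),
    avg_fee_private_visit = if (nrow(priv) > 0) priv$unit_cost else 0,
    consultations_per_patient = aq$consultations_per_patient,
    unit_cost_test = stats::setNames(tst$unit_cost, tst$item),
    tests_per_patient = aq$tests_per_patient,
    daily_cost_medicine = stats::setNames(med$unit_cost, med$item),
    annual_medication_days_per_patient = aq$medication_days_per_patient,
    therapy_cost_per_patient = aq$therapy_spend_per_user,
    therapy_users_per_patient = aq$therapy_users_share,
    daily_wage_male = wage[["male"]] / wd,
    daily_wage_female = wage[["female"]] / wd,
    lost_workdays_3mo_male = lw[["male"]],
    lost_workdays_3mo_female = lw[["female"]],
    working_days_per_month = wd,
    lost_workdays_annualisation = cfg$annualisation$lost_workdays_factor %||% 4
  )
}

# Row-wise dot product supporting scalar parameters (named vectors) and
# per-draw parameters (n x k matrices), recycling as needed.
dot_rows <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    n <- if (is.matrix(a)) nrow(a) else nrow(b)
    A <- if (is.matrix(a)) a else matrix(a, n, length(a), byrow = TRUE)
    B <- if (is.matrix(b)) b else matrix(b, n, length(b), byrow = TRUE)
    rowSums(A * B)
  } else {
    sum(a * b)
  }
}

#' Number of migraine sufferers by gender
#'
#' Population size times the gender share times the gender-specific
#' prevalence; fractional persons are retained until reporting.
#'
#' @param params A `migcost_params` object.
#' @return List with elements `male`, `female` and `total`.
#' @export
#' @examples
#' p <- cost_parameters(141800, 0.504, 0.250, 0.292)
#' n_sufferers(p)$male  # 17866.8
n_sufferers <- function(params) {
  male <- params$population_size * params$prop_male * params$prevalence_male
  female <- params$population_size * (1 - params$prop_male) * params$prevalence_female
  list(male = male, female = female, total = male + female)
}

#' Outpatient visit costs (public and private pathways)
#'
#' Public pathway: consultations priced per facility level plus diagnostic
#' tests priced per type (the tariff covers public facilities only). Private
#' pathway: the bundled all-cause average fee per outpatient visit covers
#' consultations and tests jointly. Per-patient quantities are scaled by the
#' total sufferer count.
#'
#' @param params A `migcost_params` object.
#' @return List with elements `public` and `private` (2022 USD).
#' @export
outpatient_costs <- function(params) {
  N <- n_sufferers(params)$total
  q <- params$consultations_per_patient
  nm <- if (is.matrix(q)) colnames(q) else names(q)
  pub_keys <- setdiff(nm, "private_facility")

  pick <- function(x, keys) if (is.matrix(x)) x[, keys, drop = FALSE] else x[keys]
  pub_q <- pick(q, pub_keys)
  if (length(pub_keys) > 0) {
    uc <- align_names_safe(params$unit_cost_consultation, pub_keys, "unit_cost_consultation")
    public <- N * dot_rows(uc, pub_q)
  } else {
    public <- N * 0
  }
  tq <- params$tests_per_patient
  tnm <- if (is.matrix(tq)) colnames(tq) else names(tq)
  if (length(tnm) > 0) {
    ut <- align_names_safe(params$unit_cost_test, tnm, "unit_cost_test")
    public <- public + N * dot_rows(ut, tq)
  }

  if ("private_facility" %in% nm) {
    priv_q <- if (is.matrix(q)) q[, "private_facility"] else q[["private_facility"]]
    private <- N * params$avg_fee_private_visit * priv_q
  } else {
    private <- N * 0
  }
  list(public = public, private = private)
}

align_names_safe <- function(costs, keys, what) {
  have <- if (is.matrix(costs)) colnames(costs) else names(costs)
  missing <- setdiff(keys, have)
  if (length(missing) > 0) {
    stop("missing ", what, " for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.matrix(costs)) costs[, keys, drop = FALSE] else costs[keys]
}

#' Medicine costs
#'
#' Sum over medicines of daily cost times annual medication days, scaled by
#' the sufferer count.
#'
#' @param params A `migcost_params` object.
#' @return Total medicine cost (2022 USD).
#' @export
medicine_costs <- function(params) {
  N <- n_sufferers(params)$total
  d <- params$annual_medication_days_per_patient
  nm <- if (is.matrix(d)) colnames(d) else names(d)
  if (length(nm) == 0) return(N * 0)
  dc <- align_names_safe(params$daily_cost_medicine, nm, "daily_cost_medicine")
  N * dot_rows(dc, d)
}

#' Complementary therapy costs
#'
#' Sum over (therapy, facility class) cells of the annual per-patient cost
#' times the annual number of patients receiving the therapy (user share
#' times sufferer count).
#'
#' @param params A `migcost_params` object.
#' @return Total therapy cost (2022 USD).
#' @export
therapy_costs <- function(params) {
  N <- n_sufferers(params)$total
  u <- params$therapy_users_per_patient
  nm <- if (is.matrix(u)) colnames(u) else names(u)
  if (length(nm) == 0) return(N * 0)
  tc <- align_names_safe(params$therapy_cost_per_patient, nm, "therapy_cost_per_patient")
  N * dot_rows(tc, u)
}

#' Indirect (productivity) costs by gender
#'
#' Human-capital valuation: sufferers times daily wage times annual lost
#' workdays, where annual lost workdays extrapolate the 3-month recall by the
#' configured factor (default 4).
#'
#' @param params A `migcost_params` object.
#' @return List with elements `male`, `female` and `total` (2022 USD).
#' @export
indirect_costs <- function(params) {
  ns <- n_sufferers(params)
  f <- params$lost_workdays_annualisation
  male <- ns$male * params$daily_wage_male * params$lost_workdays_3mo_male * f
  female <- ns$female * params$daily_wage_female * params$lost_workdays_3mo_female * f
  list(male = male, female = female, total = male + female)
}

# Vectorised engine shared by the point estimate and the PSA: every parameter
# leaf may be a scalar/named vector or an n-draw vector/matrix.
evaluate_costs <- function(params) {
  ns <- n_sufferers(params)
  op <- outpatient_costs(params)
  med <- medicine_costs(params)
  ther <- therapy_costs(params)
  ind <- indirect_costs(params)
  direct <- op$public + op$private + med + ther
  total <- direct + ind$total
  per_patient <- ifelse(ns$total > 0, total / ns$total, 0)
  list(
    n_sufferers_male = ns$male, n_sufferers_female = ns$female,
    cost_outpatient_public = op$public, cost_outpatient_private = op$private,
    cost_medicines = med, cost_therapies = ther,
    direct_total = direct,
    indirect_male = ind$male, indirect_female = ind$female,
    indirect_total = ind$total,
    societal_total = total,
    per_patient_societal = per_patient
  )
}

#' Deterministic point estimate of the annual cost of illness
#'
#' Composes the sufferer, outpatient, medicine, therapy and indirect cost
#' operations into the full cost breakdown: direct costs (healthcare-system
#' perspective), indirect costs (employer perspective), their sum (societal
#' perspective) and the societal cost per patient-year. Exact identities hold
#' to full precision: direct = public outpatient + private outpatient +
#' medicines + therapies, and societal = direct + indirect. No discounting is
#' applied (annual time horizon).
#'
#' @param params A `migcost_params` object with scalar leaves.
#' @return A list of class `migcost_breakdown`, including a per-medicine cost
#'   map (`cost_medicines_by_type`).
#' @export
point_estimate <- function(params) {
  validate_params(params)
  out <- evaluate_costs(params)
  d <- params$annual_medication_days_per_patient
  if (length(d) > 0) {
    dc <- align_names_safe(params$daily_cost_medicine, names(d), "daily_cost_medicine")
    out$cost_medicines_by_type <- dc * d * n_sufferers(params)$total
  } else {
    out$cost_medicines_by_type <- numeric(0)
  }
  structure(out, class = c("migcost_breakdown", "list"))
}

#' @export
print.migcost_breakdown <- function(x, ...) {
  k <- function(v) formatC(v / 1000, format = "f", digits = 1, big.mark = ",")
  cat("Annual cost of illness (thousand 2022 USD)\n")
  cat("  Sufferers:          ",
      formatC(x$n_sufferers_male + x$n_sufferers_female, format = "f", digits = 1,
              big.mark = ","), "\n")
  cat("  Outpatient, public: ", k(x$cost_outpatient_public), "\n")
  cat("  Outpatient, private:", k(x$cost_outpatient_private), "\n")
  cat("  Medicines:          ", k(x$cost_medicines), "\n")
  cat("  Therapies:          ", k(x$cost_therapies), "\n")
  cat("  Direct total:       ", k(x$direct_total), "\n")
  cat("  Indirect total:     ", k(x$indirect_total), "\n")
  cat("  Societal total:     ", k(x$societal_total), "\n")
  cat("  Per patient (USD):  ",
      formatC(x$per_patient_societal, format = "f", digits = 1), "\n")
  invisible(x)
}

#' Flatten cost parameters to a named numeric vector
#'
#' Map-valued leaves are flattened to `leaf.key` entries (e.g.
#' `unit_cost_test.ct`). Used by the tornado and PSA machinery.
#'
#' @param params A `migcost_params` object.
#' @return A named numeric vector.
#' @export
flatten_params <- function(params) {
  out <- numeric(0)
  for (nm in names(params)) {
    v <- params[[nm]]
    if (length(v) == 1 && is.null(names(v))) {
      out[nm] <- v
    } else if (length(v) >= 1) {
      out[paste0(nm, ".", names(v))] <- unname(v)
    }
  }
  out
}

#' Set one flattened parameter
#'
#' @param params A `migcost_params` object.
#' @param key A flattened name as produced by [flatten_params()].
#' @param value Replacement value (scalar or per-draw vector).
#' @return The modified parameter object.
#' @export
set_param <- function(params, key, value) {
  if (key %in% names(params)) {
    params[[key]] <- value
    return(params)
  }
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  leaf <- parts[1]
  sub <- paste(parts[-1], collapse = ".")
  if (!leaf %in% names(params) || !sub %in% names(params[[leaf]])) {
    stop("unknown parameter: ", key, call. = FALSE)
  }
  params[[leaf]][[sub]] <- value
  params
}

#' @rdname set_param
#' @export
get_param <- function(params, key) {
  fp <- flatten_params(params)
  if (!key %in% names(fp)) stop("unknown parameter: ", key, call. = FALSE)
  fp[[key]]
}

#' Write a cost breakdown to JSON and CSV
#'
#' JSON keeps raw 2022 USD; the CSV adds a thousand-USD column rounded to one
#' decimal for table-style reporting.
#'
#' @param breakdown A `migcost_breakdown`.
#' @param json_path,csv_path Output paths (`NULL` to skip one format).
#' @return Invisibly, the breakdown.
#' @export
write_breakdown <- function(breakdown, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(breakdown), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    scalar <- breakdown[vapply(breakdown, length, integer(1)) == 1]
    tab <- tibble::tibble(
      component = names(scalar),
      usd = unlist(scalar, use.names = FALSE)
    )
    tab$thousand_usd <- round(tab$usd / 1000, 1)
    readr::write_csv(tab, csv_path)
  }
  invisible(breakdown)
}
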