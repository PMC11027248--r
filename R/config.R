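#' Load a model configuration
#'
#' Reads a structured YAML configuration holding every model input: the survey
#' block (sample size, gender split, prevalence, episodic/chronic split), the
#' target population, wages, lost workdays, the utilisation item tables
#' (consultation facilities, diagnostic tests, acute and preventive medicines,
#' complementary therapies), annualisation factors, PSA spread settings and
#' currency factors. The packaged default encodes the baseline study
#' conditions: a financial-sector workforce of 141,800 (50.4% male), migraine
#' prevalence of 25.0% (males) and 29.2% (females), a daily wage of $83.9 for
#' both genders, and utilisation rates and visit/day summaries from a
#' 1,929-respondent headache survey. All monetary values are 2022 USD.
#'
#' @param path Path to a YAML configuration file, or `NULL` for the packaged
#'   default (`inst/extdata/default_config.yaml`).
#' @return A named list of class `migcost_config`.
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$population$size
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml", package = "migcost")
  }
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  structure(cfg, class = c("migcost_config", "list"))
}

#' Validate a model configuration
#'
#' Checks structural completeness (required sections and keys) and domain
#' constraints (proportions in \[0, 1\], non-negative costs and quantities,
#' positive sample sizes). Errors name the offending keys.
#'
#' @param cfg A configuration list as returned by [load_config()].
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  required <- c(
    "survey", "population", "wages", "lost_workdays_3mo", "annualisation",
    "consultations", "tests", "medicines", "therapies", "psa", "tornado",
    "currency"
  )
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("configuration is missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  bad <- character(0)
  chk_prop <- function(x, key) {
    if (is.null(x) || !is.numeric(x) || is.na(x) || x < 0 || x > 1) bad <<- c(bad, key)
  }
  chk_pos <- function(x, key) {
    if (is.null(x) || !is.numeric(x) || is.na(x) || x < 0) bad <<- c(bad, key)
  }

  s <- cfg$survey
  if (is.null(s$n_respondents) || s$n_respondents < 1) bad <- c(bad, "survey.n_respondents")
  chk_prop(s$prop_male, "survey.prop_male")
  chk_prop(s$prevalence_male, "survey.prevalence_male")
  chk_prop(s$prevalence_female, "survey.prevalence_female")
  chk_prop(s$prob_cm_given_migraine, "survey.prob_cm_given_migraine")
  chk_pos(cfg$population$size, "population.size")
  chk_prop(cfg$population$prop_male, "population.prop_male")
  chk_pos(cfg$wages$monthly_wage_male, "wages.monthly_wage_male")
  chk_pos(cfg$wages$monthly_wage_female, "wages.monthly_wage_female")
  if (is.null(cfg$wages$working_days_per_month) || cfg$wages$working_days_per_month <= 0) {
    bad <- c(bad, "wages.working_days_per_month")
  }
  for (g in c("male", "female")) {
    lw <- cfg$lost_workdays_3mo[[g]]
    chk_pos(lw$median, paste0("lost_workdays_3mo.", g, ".median"))
    chk_pos(lw$mean, paste0("lost_workdays_3mo.", g, ".mean"))
  }

  chk_item <- function(entry, key, needs_cost = TRUE) {
    if (needs_cost) chk_pos(entry$unit_cost %||% entry$daily_cost, paste0(key, ".unit_cost"))
    for (cls in c("em", "cm")) {
      e <- entry[[cls]]
      if (is.null(e)) { bad <<- c(bad, paste0(key, ".", cls)); next }
      chk_prop(e$rate, paste0(key, ".", cls, ".rate"))
      if (isTRUE(e$rate > 0)) {
        if (is.null(e$min) || is.null(e$max) || e$min < 1 || e$max < e$min) {
          bad <<- c(bad, paste0(key, ".", cls, ".range"))
        }
      }
    }
  }
  for (nm in names(cfg$consultations)) chk_item(cfg$consultations[[nm]], paste0("consultations.", nm))
  for (nm in names(cfg$tests)) chk_item(cfg$tests[[nm]], paste0("tests.", nm))
  for (grp in c("acute", "preventive")) {
    for (nm in names(cfg$medicines[[grp]])) {
      chk_item(cfg$medicines[[grp]][[nm]], paste0("medicines.", grp, ".", nm))
    }
  }
  for (nm in names(cfg$therapies)) {
    th <- cfg$therapies[[nm]]
    chk_prop(th$rate_em, paste0("therapies.", nm, ".rate_em"))
    chk_prop(th$rate_cm, paste0("therapies.", nm, ".rate_cm"))
    chk_pos(th$spend, paste0("therapies.", nm, ".spend"))
  }
  chk_pos(cfg$currency$ppp, "currency.ppp")

  if (length(bad) > 0) {
    stop("invalid configuration value(s) for: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy utilisation item table from a configuration
#'
#' Flattens the consultation, test and medicine blocks of a configuration into
#' one tibble with a row per item: unit cost and, per EM/CM class, the use
#' rate and the visit/day summaries (mean, SD, median, range) among users.
#'
#' @param cfg A `migcost_config`.
#' @return A tibble with columns `group`, `item`, `unit_cost`, and
#'   `rate_em` ... `max_cm`.
#' @export
config_items <- function(cfg) {
  one <- function(entry, group, item) {
    cost <- entry$unit_cost %||% entry$daily_cost
    row <- list(group = group, item = item, unit_cost = cost)
    for (cls in c("em", "cm")) {
      e <- entry[[cls]]
      row[[paste0("rate_", cls)]]   <- e$rate
      row[[paste0("mean_", cls)]]   <- e$mean %||% NA_real_
      row[[paste0("sd_", cls)]]     <- e$sd %||% NA_real_
      row[[paste0("median_", cls)]] <- e$median %||% NA_real_
      row[[paste0("min_", cls)]]    <- e$min %||% NA_real_
      row[[paste0("max_", cls)]]    <- e$max %||% NA_real_
    }
    tibble::as_tibble(row)
  }
  rows <- c(
    lapply(names(cfg$consultations), function(nm)
      one(cfg$consultations[[nm]], "consultation", nm)),
    lapply(names(cfg$tests), function(nm)
      one(cfg$tests[[nm]], "test", nm)),
    lapply(names(cfg$medicines$acute), function(nm)
      one(cfg$medicines$acute[[nm]], "acute_medicine", nm)),
    lapply(names(cfg$medicines$preventive), function(nm)
      one(cfg$medicines$preventive[[nm]], "preventive_medicine", nm))
  )
  dplyr::bind_rows(rows)
}

#' Tidy therapy table from a configuration
#'
#' @param cfg A `migcost_config`.
#' @return A tibble with one row per (therapy, facility class) cell: use rates
#'   by EM/CM class and the annual per-patient spend (2022 USD).
#' @export
config_therapies <- function(cfg) {
  dplyr::bind_rows(lapply(names(cfg$therapies), function(nm) {
    th <- cfg$therapies[[nm]]
    tibble::tibble(
      item = nm,
      facility_class = if (grepl("_informal$", nm)) "informal" else "public",
      rate_em = th$rate_em, rate_cm = th$rate_cm,
      spend = th$spend, cv_spend = th$cv_spend %||% 0.8
    )
  }))
}

#' Convert an amount in local currency to 2022 USD
#'
#' Inflates (or deflates) an amount expressed in `year` prices to 2022 prices
#' using the ratio of GDP deflator indexes, then converts to USD with the
#' 2022 purchasing power parity factor (local currency units per USD).
#'
#' @param amount Non-negative amount in local currency, `year` prices.
#' @param year Price year of `amount`.
#' @param factors A list with `gdp_deflator` (named index vector or list keyed
#'   by year), `ppp` (> 0), and `base_year` (2022); the `currency` block of a
#'   configuration fits directly.
#' @return The amount in 2022 USD.
#' @export
#' @examples
#' fac <- list(base_year = 2022, ppp = 5, gdp_deflator = list(`2021` = 100, `2022` = 110))
#' convert_to_usd_2022(100, 2021, fac)  # 100 * 1.1 / 5 = 22
convert_to_usd_2022 <- function(amount, year, factors) {
  if (any(amount < 0)) stop("amount must be non-negative", call. = FALSE)
  defl <- factors$gdp_deflator
  base_year <- as.character(factors$base_year %||% 2022)
  yr <- as.character(year)
  if (is.null(defl[[yr]]) || is.null(defl[[base_year]])) {
    stop("no GDP deflator index for year ", yr, " or base year ", base_year,
         call. = FALSE)
  }
  if (is.null(factors$ppp) || factors$ppp <= 0) {
    stop("ppp factor must be positive", call. = FALSE)
  }
  amount * (defl[[base_year]] / defl[[yr]]) / factors$ppp
}
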