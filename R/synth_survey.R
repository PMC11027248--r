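#' Classify migraine as episodic, chronic, or absent
#'
#' Chronic migraine (CM) is defined as migraine on 15 or more days per month;
#' fewer than 15 days is episodic migraine (EM). Non-migraineurs are `"none"`
#' regardless of headache days.
#'
#' @param days_per_month Non-negative headache days per month (vectorised).
#' @param has_migraine Logical, migraine-positive status (vectorised).
#' @return Character vector in `c("EM", "CM", "none")`.
#' @export
#' @examples
#' classify_migraine(c(15, 14, 20), c(TRUE, TRUE, FALSE))
classify_migraine <- function(days_per_month, has_migraine) {
  if (any(days_per_month < 0)) {
    stop("days_per_month must be non-negative", call. = FALSE)
  }
  n <- max(length(days_per_month), length(has_migraine))
  d <- rep_len(days_per_month, n)
  h <- rep_len(has_migraine, n)
  as.character(ifelse(!h, "none", ifelse(d >= 15, "CM", "EM")))
}

# Shifted, range-truncated negative-binomial count sampler for visit/test/day
# counts among users. The survey tables publish medians and ranges, not
# distributions; an over-dispersed count family truncated to the printed range
# and centred near the printed mean is used. Degenerate ranges collapse to a
# point mass.
draw_counts <- function(n, min, max, mean, size = 1.5) {
  if (n == 0) return(numeric(0))
  if (max <= min) return(rep(min, n))
  mu <- max(mean - min, 0.05)
  out <- min + stats::rnbinom(n, size = size, mu = mu)
  while (any(out > max)) {
    k <- which(out > max)
    out[k] <- min + stats::rnbinom(length(k), size = size, mu = mu)
  }
  out
}

# Truncated geometric on {lo, ..., hi}, used for monthly migraine-day counts.
draw_days <- function(n, lo, hi, p = 0.25) {
  if (n == 0) return(integer(0))
  lo + pmin(stats::rgeom(n, prob = p), hi - lo)
}

draw_spend <- function(n, mean, cv) {
  if (n == 0) return(numeric(0))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean * cv^2)
}

#' Generate a synthetic HARDSHIP-style migraine survey
#'
#' Draws one row per respondent: gender (per the configured male share),
#' migraine status (per gender-specific prevalence), EM/CM class (with monthly
#' migraine days consistent with the class: CM 15--30, EM 1--14), and -- for
#' migraine-positive respondents only -- annual consultation counts per
#' facility level, annual diagnostic-test counts per type, acute medication
#' days (preceding-month recall), preventive medication days (preceding-year
#' recall), annual complementary-therapy spending per (therapy, facility
#' class) cell, 3-month lost workdays (capped at 66 = 3 months of 22 working
#' days), and monthly wage. Utilisation categories are sampled independently
#' given EM/CM class; the published tables report only marginal rates, so no
#' joint structure is imposed. All draws come from one RNG stream seeded by
#' `seed`, so identical configuration and seed reproduce the table exactly.
#'
#' @param config A `migcost_config` (see [load_config()]).
#' @param seed Integer seed; defaults to `config$survey$rng_seed`.
#' @param n_respondents Optional override of the configured sample size.
#' @return A tibble of class `migcost_survey`, one row per respondent, with
#'   map-valued fields flattened to `consult_*`, `test_*`, `acute_*`, `prev_*`
#'   and `therapy_*` columns.
#' @export
generate_survey <- function(config, seed = NULL,
                            n_respondents = NULL) {
  validate_config(config)
  n <- as.integer(n_respondents %||% config$survey$n_respondents)
  if (is.na(n) || n < 1) stop("n_respondents must be >= 1", call. = FALSE)
  seed <- as.integer(seed %||% config$survey$rng_seed %||% 1L)

  items <- config_items(config)
  ther <- config_therapies(config)
  s <- config$survey

  withr::with_seed(seed, {
    gender <- ifelse(stats::runif(n) < s$prop_male, "male", "female")
    prev <- ifelse(gender == "male", s$prevalence_male, s$prevalence_female)
    has_mig <- stats::runif(n) < prev

    is_cm <- has_mig & (stats::runif(n) < s$prob_cm_given_migraine)
    days <- integer(n)
    n_cm <- sum(is_cm)
    n_em <- sum(has_mig & !is_cm)
    days[is_cm] <- draw_days(n_cm, 15L, 30L)
    days[has_mig & !is_cm] <- draw_days(n_em, 1L, 14L)
    cls <- classify_migraine(days, has_mig)

    tab <- tibble::tibble(
      respondent_id = seq_len(n),
      gender = gender,
      has_migraine = has_mig,
      migraine_days_per_month = days,
      migraine_class = cls
    )

    prefix <- c(consultation = "consult_", test = "test_",
                acute_medicine = "acute_", preventive_medicine = "prev_")
    for (i in seq_len(nrow(items))) {
      it <- items[i, ]
      col <- paste0(prefix[[it$group]], it$item)
      x <- numeric(n)
      for (cc in c("EM", "CM")) {
        rate <- if (cc == "EM") it$rate_em else it$rate_cm
        idx <- which(cls == cc)
        if (length(idx) == 0 || rate == 0) next
        user <- idx[stats::runif(length(idx)) < rate]
        lo <- if (cc == "EM") it$min_em else it$min_cm
        hi <- if (cc == "EM") it$max_em else it$max_cm
        mn <- if (cc == "EM") it$mean_em else it$mean_cm
        x[user] <- draw_counts(length(user), lo, hi, mn)
      }
      tab[[col]] <- x
    }

    for (i in seq_len(nrow(ther))) {
      th <- ther[i, ]
      col <- paste0("therapy_", th$item)
      x <- numeric(n)
      for (cc in c("EM", "CM")) {
        rate <- if (cc == "EM") th$rate_em else th$rate_cm
        idx <- which(cls == cc)
        if (length(idx) == 0 || rate == 0) next
        user <- idx[stats::runif(length(idx)) < rate]
        x[user] <- draw_spend(length(user), th$spend, th$cv_spend)
      }
      tab[[col]] <- x
    }

    lw <- numeric(n)
    for (g in c("male", "female")) {
      idx <- which(has_mig & gender == g)
      par <- config$lost_workdays_3mo[[g]]
      shape <- par$gen_shape %||% 0.6
      if (length(idx) > 0) {
        lw[idx] <- pmin(stats::rgamma(length(idx), shape = shape,
                                      scale = par$mean / shape), 66)
      }
    }
    tab$lost_workdays_3mo <- lw
    tab$monthly_wage <- ifelse(gender == "male",
                               config$wages$monthly_wage_male,
                               config$wages$monthly_wage_female)
    class(tab) <- c("migcost_survey", class(tab))
    tab
  })
}

#' Write / read a survey table as CSV
#'
#' One row per respondent; map-valued fields are one column per key
#' (`consult_*`, `test_*`, `acute_*`, `prev_*`, `therapy_*`). A written table
#' re-read with [read_survey()] yields identical utilisation summaries.
#'
#' @param survey A `migcost_survey` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly (for `write_survey`); the survey tibble (for
#'   `read_survey`).
#' @export
write_survey <- function(survey, path) {
  readr::write_csv(survey, path)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tab$gender <- as.character(tab$gender)
  tab$migraine_class <- as.character(tab$migraine_class)
  tab$has_migraine <- as.logical(tab$has_migraine)
  class(tab) <- c("migcost_survey", class(tab))
  tab
}

# Column names of the flattened utilisation fields of a survey table.
utilisation_columns <- function(survey) {
  grep("^(consult|test|acute|prev|therapy)_", names(survey), value = TRUE)
}
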