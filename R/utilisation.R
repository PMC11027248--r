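#' Prevalence and EM/CM composition of a survey
#'
#' @param survey A `migcost_survey` tibble.
#' @return A one-row tibble: respondent count, migraine-positive count and
#'   percentage, EM and CM counts and percentages (denominator: migraine
#'   positives). Percentages are exact; round at reporting time.
#' @export
survey_prevalence <- function(survey) {
  n <- nrow(survey)
  n_mig <- sum(survey$has_migraine)
  n_cm <- sum(survey$migraine_class == "CM")
  n_em <- sum(survey$migraine_class == "EM")
  tibble::tibble(
    n_respondents = n,
    n_migraine = n_mig,
    pct_migraine = 100 * n_mig / n,
    n_em = n_em, n_cm = n_cm,
    pct_em = if (n_mig > 0) 100 * n_em / n_mig else NA_real_,
    pct_cm = if (n_mig > 0) 100 * n_cm / n_mig else NA_real_
  )
}

# Aggregate user-flag definitions over flattened survey columns.
aggregate_flags <- function(survey) {
  cols <- utilisation_columns(survey)
  pick <- function(re) {
    sel <- grep(re, cols, value = TRUE)
    if (length(sel) == 0) return(rep(FALSE, nrow(survey)))
    rowSums(as.matrix(survey[sel])) > 0
  }
  list(
    any_facility = pick("^consult_"),
    any_tests = pick("^test_"),
    any_acute_medicines = pick("^acute_"),
    any_preventive_medicines = pick("^prev_"),
    any_medicines = pick("^(acute|prev)_"),
    any_therapies = pick("^therapy_"),
    no_resources = !pick("^(consult|test|acute|prev|therapy)_")
  )
}

#' Summarise healthcare utilisation with EM-vs-CM comparisons
#'
#' Reproduces the structure of the published utilisation tables: for every
#' item (consultation facility, diagnostic test, acute or preventive medicine,
#' complementary therapy) the number and percentage of users overall and by
#' EM/CM class, visit/test/day summaries among users (mean, SD, median,
#' range), and EM-vs-CM comparison p-values (chi-square or Fisher for the use
#' rate, Mann--Whitney U for the quantity). Aggregate rows (`any_facility`,
#' `any_tests`, `any_acute_medicines`, `any_preventive_medicines`,
#' `any_medicines`, `any_therapies`, `no_resources`) count respondents with at
#' least one item in the group (or none anywhere). Denominators: all
#' percentages use the migraine-positive count overall and the class sizes for
#' the EM/CM columns; quantity summaries are over users of the item only.
#'
#' @param survey A `migcost_survey` tibble with at least one migraine-positive
#'   record.
#' @return A tibble of class `migcost_utilisation`, one row per item plus the
#'   aggregate rows; attributes `n_migraine`, `n_em`, `n_cm`. Percentages are
#'   exact; round to one decimal at reporting time.
#' @export
summarise_utilisation <- function(survey) {
  pos <- survey[survey$has_migraine, , drop = FALSE]
  if (nrow(pos) == 0) {
    stop("no migraine-positive records to summarise", call. = FALSE)
  }
  n_pos <- nrow(pos)
  n_em <- sum(pos$migraine_class == "EM")
  n_cm <- sum(pos$migraine_class == "CM")
  em <- pos$migraine_class == "EM"
  cm <- pos$migraine_class == "CM"

  cols <- utilisation_columns(survey)
  groups <- c(consult = "consultation", test = "test", acute = "acute_medicine",
              prev = "preventive_medicine", therapy = "therapy")

  qsum <- function(x) {
    if (length(x) == 0) {
      return(list(mean = NA_real_, sd = NA_real_, median = NA_real_,
                  min = NA_real_, max = NA_real_))
    }
    list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
         median = stats::median(x), min = min(x), max = max(x))
  }

  rows <- lapply(cols, function(col) {
    pfx <- sub("_.*$", "", col)
    x <- pos[[col]]
    users <- x > 0
    cmp <- compare_groups(survey, col)
    qe <- qsum(x[users & em]); qc <- qsum(x[users & cm])
    tibble::tibble(
      group = groups[[pfx]],
      item = sub("^[a-z]+_", "", col),
      n_users = sum(users),
      pct_all = 100 * sum(users) / n_pos,
      pct_em = if (n_em > 0) 100 * sum(users & em) / n_em else NA_real_,
      pct_cm = if (n_cm > 0) 100 * sum(users & cm) / n_cm else NA_real_,
      mean_em = qe$mean, sd_em = qe$sd, median_em = qe$median,
      min_em = qe$min, max_em = qe$max,
      mean_cm = qc$mean, sd_cm = qc$sd, median_cm = qc$median,
      min_cm = qc$min, max_cm = qc$max,
      rate_p = cmp$rate_p, quantity_p = cmp$quantity_p
    )
  })

  flags <- aggregate_flags(pos)
  agg <- lapply(names(flags), function(nm) {
    f <- flags[[nm]]
    cmp <- compare_groups(survey, nm)
    tibble::tibble(
      group = "aggregate", item = nm,
      n_users = sum(f),
      pct_all = 100 * sum(f) / n_pos,
      pct_em = if (n_em > 0) 100 * sum(f & em) / n_em else NA_real_,
      pct_cm = if (n_cm > 0) 100 * sum(f & cm) / n_cm else NA_real_,
      mean_em = NA_real_, sd_em = NA_real_, median_em = NA_real_,
      min_em = NA_real_, max_em = NA_real_,
      mean_cm = NA_real_, sd_cm = NA_real_, median_cm = NA_real_,
      min_cm = NA_real_, max_cm = NA_real_,
      rate_p = cmp$rate_p, quantity_p = NA_real_
    )
  })

  out <- dplyr::bind_rows(c(rows, agg))
  attr(out, "n_migraine") <- n_pos
  attr(out, "n_em") <- n_em
  attr(out, "n_cm") <- n_cm
  class(out) <- c("migcost_utilisation", class(out))
  out
}

#' Compare EM and CM utilisation of one item
#'
#' Use rates are compared on the 2x2 user-by-class table with the Pearson
#' chi-square test, switching to Fisher's exact test when any expected cell
#' count is below 5. Quantities among users are compared with a two-sided
#' Mann--Whitney U test: exact enumeration when both user groups have at most
#' 8 members (and no ties), normal approximation with tie correction
#' otherwise.
#'
#' @param survey A `migcost_survey` tibble.
#' @param item A flattened utilisation column name (e.g. `"test_ct"`) or an
#'   aggregate name (e.g. `"any_facility"`).
#' @return A list: `rate_p`, `quantity_p`, `rate_method` (`"chisq"` or
#'   `"fisher"`), and `no_data` (`TRUE` when no migraine-positive respondent
#'   uses the item; the p-values are then `NA`, not an error).
#' @export
compare_groups <- function(survey, item) {
  pos <- survey[survey$has_migraine, , drop = FALSE]
  if (nrow(pos) == 0) stop("no migraine-positive records", call. = FALSE)
  em <- pos$migraine_class == "EM"
  cm <- pos$migraine_class == "CM"
  if (sum(em) == 0 || sum(cm) == 0) {
    stop("both EM and CM classes must be non-empty", call. = FALSE)
  }

  flags <- aggregate_flags(pos)
  if (item %in% names(flags)) {
    users <- flags[[item]]
    x <- NULL
  } else if (item %in% names(pos)) {
    x <- pos[[item]]
    users <- x > 0
  } else {
    stop("unknown item: ", item, call. = FALSE)
  }

  if (sum(users) == 0) {
    return(list(rate_p = NA_real_, quantity_p = NA_real_,
                rate_method = NA_character_, no_data = TRUE))
  }

  tab <- rbind(EM = c(sum(users & em), sum(!users & em)),
               CM = c(sum(users & cm), sum(!users & cm)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    rate_p <- stats::fisher.test(tab)$p.value
    rate_method <- "fisher"
  } else {
    rate_p <- stats::chisq.test(tab, correct = FALSE)$p.value
    rate_method <- "chisq"
  }

  quantity_p <- NA_real_
  if (!is.null(x)) {
    xe <- x[users & em]
    xc <- x[users & cm]
    if (length(xe) > 0 && length(xc) > 0) {
      exact <- length(xe) <= 8 && length(xc) <= 8
      quantity_p <- suppressWarnings(
        stats::wilcox.test(xc, xe, exact = exact)$p.value
      )
      # fully tied samples degenerate the normal approximation; no evidence
      # of a difference
      if (is.nan(quantity_p)) quantity_p <- 1
    }
  }
  list(rate_p = rate_p, quantity_p = quantity_p, rate_method = rate_method,
       no_data = FALSE)
}

#' Derive per-patient annual utilisation quantities from a survey
#'
#' Converts record-level recall data into the annual, per-patient inputs the
#' cost model consumes. Consultation and test counts are annual already
#' (one-year recall). Acute medication days use a one-month recall and are
#' annualised by `acute_factor` (default 12); preventive medication days use a
#' one-year recall and are taken as-is. Therapy use is expressed as the share
#' of patients using each (therapy, facility class) cell, with the mean annual
#' spend among users. Lost workdays and wages are summarised by gender
#' (median and mean; point estimation uses medians for these skewed inputs,
#' PSA is centred on means). All quantities are per migraine patient and scale
#' to a target population via the prevalence-weighted sufferer count.
#'
#' @param survey A `migcost_survey` with at least one migraine-positive record.
#' @param acute_factor Annualisation factor for the acute-medicine one-month
#'   recall window.
#' @return A list of named numeric vectors: `consultations_per_patient`,
#'   `tests_per_patient`, `medication_days_per_patient`,
#'   `therapy_users_share`, `therapy_spend_per_user`, plus gender-level
#'   `lost_workdays_3mo` (median/mean) and `monthly_wage` summaries and the
#'   positive-record count `n_patients`.
#' @export
derive_annual_quantities <- function(survey, acute_factor = 12) {
  pos <- survey[survey$has_migraine, , drop = FALSE]
  if (nrow(pos) == 0) {
    stop("no migraine-positive records", call. = FALSE)
  }
  grab <- function(re) {
    sel <- grep(re, names(pos), value = TRUE)
    stats::setNames(
      vapply(sel, function(cl) mean(pos[[cl]]), numeric(1)),
      sub("^[a-z]+_", "", sel)
    )
  }
  acute <- grab("^acute_") * acute_factor
  prev <- grab("^prev_")

  ther_cols <- grep("^therapy_", names(pos), value = TRUE)
  share <- stats::setNames(
    vapply(ther_cols, function(cl) mean(pos[[cl]] > 0), numeric(1)),
    sub("^therapy_", "", ther_cols)
  )
  spend <- stats::setNames(
    vapply(ther_cols, function(cl) {
      u <- pos[[cl]][pos[[cl]] > 0]
      if (length(u) == 0) 0 else mean(u)
    }, numeric(1)),
    sub("^therapy_", "", ther_cols)
  )

  by_gender <- function(col, fun) {
    vapply(c(male = "male", female = "female"),
           function(g) {
             v <- pos[[col]][pos$gender == g]
             if (length(v) == 0) NA_real_ else fun(v)
           }, numeric(1))
  }

  list(
    consultations_per_patient = grab("^consult_"),
    tests_per_patient = grab("^test_"),
    medication_days_per_patient = c(acute, prev),
    therapy_users_share = share,
    therapy_spend_per_user = spend,
    lost_workdays_3mo_median = by_gender("lost_workdays_3mo", stats::median),
    lost_workdays_3mo_mean = by_gender("lost_workdays_3mo", mean),
    monthly_wage_median = by_gender("monthly_wage", stats::median),
    n_patients = nrow(pos)
  )
}

#' Write a utilisation summary as CSV
#'
#' Percentages and quantity summaries are rounded to one decimal, matching
#' the published table layout; p-values keep four decimals.
#'
#' @param summary A `migcost_utilisation` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_utilisation_csv <- function(summary, path) {
  out <- summary
  pct_cols <- c("pct_all", "pct_em", "pct_cm", "mean_em", "sd_em", "median_em",
                "min_em", "max_em", "mean_cm", "sd_cm", "median_cm", "min_cm",
                "max_cm")
  for (cl in pct_cols) out[[cl]] <- round(out[[cl]], 1)
  for (cl in c("rate_p", "quantity_p")) out[[cl]] <- round(out[[cl]], 4)
  readr::write_csv(out, path)
  invisible(path)
}
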