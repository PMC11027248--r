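#' Define a sampling distribution for one model parameter
#'
#' @param name Flattened parameter name (see [flatten_params()]).
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"uniform"`,
#'   `"fixed"`.
#' @param parameters Named list of family parameters: beta `shape1`/`shape2`;
#'   gamma `shape`/`scale`; lognormal `meanlog`/`sdlog`; uniform `min`/`max`;
#'   fixed none.
#' @param point_value The deterministic point value (tornado baseline and the
#'   value used when the parameter is held fixed).
#' @return A list of class `migcost_dist`.
#' @export
param_distribution <- function(name, family, parameters = list(), point_value) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "uniform", "fixed"))
  structure(list(name = name, family = family, parameters = parameters,
                 point_value = point_value),
            class = c("migcost_dist", "list"))
}

# Method-of-moments helpers.
beta_from_mean_cv <- function(mean, cv) {
  v <- (cv * mean)^2
  v <- min(v, 0.95 * mean * (1 - mean)) # keep shapes positive near the bounds
  s <- mean * (1 - mean) / v - 1
  list(shape1 = mean * s, shape2 = (1 - mean) * s)
}
gamma_from_mean_cv <- function(mean, cv) {
  shape <- 1 / cv^2
  list(shape = shape, scale = mean / shape)
}

is_proportion_key <- function(key) {
  grepl("^(prevalence_|prop_male$|therapy_users_per_patient\\.)", key)
}

param_domain <- function(key) {
  if (is_proportion_key(key)) c(0, 1) else c(0, Inf)
}

#' Default PSA distributions for a configuration
#'
#' Assigns families by parameter type: beta for proportions (prevalence,
#' therapy user shares; method of moments from the point value and the
#' configured coefficient of variation), gamma for unit costs and per-patient
#' quantities (quantities centred on the mean-based class-mixture values,
#' since PSA distributions are centred on means while point estimation uses
#' medians for skewed inputs), and lognormal for 3-month lost workdays
#' (median at the survey mean, configured log-SD). Wages and structural
#' parameters are held fixed at point values. Parameters with a zero centre
#' are fixed at zero.
#'
#' @param cfg A `migcost_config`.
#' @return A named list of `migcost_dist` objects keyed by flattened
#'   parameter name.
#' @export
default_distributions <- function(cfg) {
  point <- flatten_params(cost_parameters_from_config(cfg, "median"))
  centre <- flatten_params(cost_parameters_from_config(cfg, "mean"))
  psa <- cfg$psa
  dists <- list()

  add <- function(key, family, pars, pv) {
    dists[[key]] <<- param_distribution(key, family, pars, pv)
  }

  for (key in c("prevalence_male", "prevalence_female")) {
    add(key, "beta", beta_from_mean_cv(point[[key]], psa$cv_proportion), point[[key]])
  }
  cost_keys <- grep(
    "^(unit_cost_consultation\\.|unit_cost_test\\.|daily_cost_medicine\\.|therapy_cost_per_patient\\.|avg_fee_private_visit$)",
    names(point), value = TRUE)
  for (key in cost_keys) {
    if (point[[key]] <= 0) add(key, "fixed", list(), point[[key]])
    else add(key, "gamma", gamma_from_mean_cv(point[[key]], psa$cv_unit_cost), point[[key]])
  }
  qty_keys <- grep(
    "^(consultations_per_patient\\.|tests_per_patient\\.|annual_medication_days_per_patient\\.)",
    names(point), value = TRUE)
  for (key in qty_keys) {
    if (centre[[key]] <= 0) add(key, "fixed", list(), point[[key]])
    else add(key, "gamma", gamma_from_mean_cv(centre[[key]], psa$cv_quantity), point[[key]])
  }
  share_keys <- grep("^therapy_users_per_patient\\.", names(point), value = TRUE)
  for (key in share_keys) {
    if (point[[key]] <= 0) add(key, "fixed", list(), point[[key]])
    else add(key, "beta", beta_from_mean_cv(point[[key]], psa$cv_quantity), point[[key]])
  }
  for (key in c("lost_workdays_3mo_male", "lost_workdays_3mo_female")) {
    add(key, "lognormal",
        list(meanlog = log(centre[[key]]), sdlog = psa$sdlog_lost_workdays),
        point[[key]])
  }
  dists
}

# Draw n values from one distribution, rejecting draws outside the target
# parameter's domain. Returns the values and the rejection count.
sample_distribution <- function(dist, n) {
  pars <- dist$parameters
  draw <- switch(dist$family,
    fixed = function(m) rep(dist$point_value, m),
    beta = function(m) stats::rbeta(m, pars$shape1, pars$shape2),
    gamma = function(m) stats::rgamma(m, shape = pars$shape, scale = pars$scale),
    lognormal = function(m) stats::rlnorm(m, pars$meanlog, pars$sdlog),
    uniform = function(m) stats::runif(m, pars$min, pars$max)
  )
  dom <- param_domain(dist$name)
  x <- draw(n)
  rejected <- 0L
  bad <- which(x < dom[1] | x > dom[2])
  while (length(bad) > 0) {
    rejected <- rejected + length(bad)
    x[bad] <- draw(length(bad))
    bad <- bad[x[bad] < dom[1] | x[bad] > dom[2]]
    if (rejected > 1000 * n) {
      stop("distribution for ", dist$name, " cannot satisfy its domain", call. = FALSE)
    }
  }
  list(values = x, rejected = rejected)
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the societal total with each key parameter scaled to
#' `(1 - delta)` and `(1 + delta)` times its point value, all other
#' parameters held at point values. Proportions are capped at 1 after
#' scaling. Entries are sorted by descending swing (absolute difference
#' between the high and low totals), ties broken alphabetically.
#'
#' @param params A `migcost_params` object (the point-input set; its societal
#'   total is the tornado baseline).
#' @param keys Flattened parameter names to vary; defaults to the key cost
#'   drivers (prevalence, lost workdays, wages, private fee, the main unit
#'   costs).
#' @param delta Relative variation (default 0.20).
#' @return A tibble of class `migcost_tornado`: `name`, `total_low`,
#'   `total_high`, `swing`, `pct_change_low`, `pct_change_high`; attribute
#'   `baseline` holds the point societal total.
#' @export
one_way <- function(params, keys = default_tornado_keys(params), delta = 0.20) {
  validate_params(params)
  flat <- flatten_params(params)
  unknown <- setdiff(keys, names(flat))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  baseline <- evaluate_costs(params)$societal_total

  rows <- lapply(keys, function(key) {
    pv <- flat[[key]]
    scale_to <- function(f) {
      v <- pv * f
      if (is_proportion_key(key)) v <- min(v, 1)
      evaluate_costs(set_param(params, key, v))$societal_total
    }
    lo <- scale_to(1 - delta)
    hi <- scale_to(1 + delta)
    tibble::tibble(
      name = key, total_low = lo, total_high = hi, swing = abs(hi - lo),
      pct_change_low = 100 * (lo - baseline) / baseline,
      pct_change_high = 100 * (hi - baseline) / baseline
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$swing, out$name), ]
  attr(out, "baseline") <- baseline
  attr(out, "delta") <- delta
  class(out) <- c("migcost_tornado", class(out))
  out
}

#' @rdname one_way
#' @export
default_tornado_keys <- function(params) {
  cand <- c(
    "prevalence_female", "prevalence_male",
    "lost_workdays_3mo_female", "lost_workdays_3mo_male",
    "daily_wage_female", "daily_wage_male",
    "avg_fee_private_visit",
    "unit_cost_test.ct", "unit_cost_test.mri",
    "unit_cost_consultation.public_tertiary",
    "daily_cost_medicine.triptans",
    "therapy_cost_per_patient.acupuncture_public"
  )
  intersect(cand, names(flatten_params(params)))
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Samples every listed parameter independently from its distribution,
#' evaluates the full cost model per draw, and summarises direct, indirect,
#' total, and per-patient societal costs by median and 25th/75th percentiles
#' (linear-interpolation quantiles). Parameters without a distribution are
#' held at their point values. Draws falling outside a parameter's domain are
#' rejected and resampled; a warning is issued when more than 1% of draws had
#' to be rejected. Identical `(dists, n_draws, seed)` reproduce the result
#' exactly.
#'
#' @param params A `migcost_params` point-input set.
#' @param dists Named list of `migcost_dist` objects (see
#'   [default_distributions()]).
#' @param n_draws Number of Monte Carlo draws (default 10000).
#' @param seed Integer RNG seed.
#' @return A list of class `migcost_psa`: `n_draws`, `seed`, `n_rejected`,
#'   `draws` (tibble with one row per draw: `direct`, `indirect`, `total`,
#'   `per_patient`, in USD) and `summary` (tibble of median/p25/p75 per
#'   quantity).
#' @export
run_psa <- function(params, dists, n_draws = 10000, seed = 1L) {
  validate_params(params)
  if (is.null(names(dists))) {
    names(dists) <- vapply(dists, function(d) d$name, character(1))
  }
  flat <- flatten_params(params)
  unknown <- setdiff(names(dists), names(flat))
  if (length(unknown) > 0) {
    stop("distribution(s) for unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  n_rejected <- 0L
  draws_by_key <- withr::with_seed(as.integer(seed), {
    lapply(dists, function(d) {
      s <- sample_distribution(d, n_draws)
      n_rejected <<- n_rejected + s$rejected
      s$values
    })
  })
  if (n_rejected > 0.01 * n_draws * length(dists)) {
    warning(n_rejected, " out-of-domain draws were rejected and resampled")
  }

  # Assemble the vectorised parameter object: sampled scalar leaves become
  # n-draw vectors; map leaves with any sampled entry become n x k matrices.
  vp <- params
  leaves <- unique(sub("\\..*$", "", names(draws_by_key)))
  for (leaf in leaves) {
    sampled <- names(draws_by_key)[sub("\\..*$", "", names(draws_by_key)) == leaf]
    if (leaf %in% sampled && !grepl("\\.", sampled[1]) &&
        length(params[[leaf]]) == 1 && is.null(names(params[[leaf]]))) {
      vp[[leaf]] <- draws_by_key[[leaf]]
    } else {
      base <- params[[leaf]]
      m <- matrix(base, n_draws, length(base), byrow = TRUE,
                  dimnames = list(NULL, names(base)))
      for (key in sampled) {
        sub <- sub("^[^.]*\\.", "", key)
        m[, sub] <- draws_by_key[[key]]
      }
      vp[[leaf]] <- m
    }
  }

  res <- evaluate_costs(vp)
  draws <- tibble::tibble(
    direct = res$direct_total,
    indirect = res$indirect_total,
    total = res$societal_total,
    per_patient = res$per_patient_societal
  )
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  summary <- dplyr::bind_rows(lapply(names(draws), function(nm) {
    q <- qs(draws[[nm]])
    tibble::tibble(quantity = nm, p25 = q[1], median = q[2], p75 = q[3])
  }))
  structure(list(n_draws = n_draws, seed = as.integer(seed),
                 n_rejected = n_rejected, draws = draws, summary = summary),
            class = c("migcost_psa", "list"))
}

#' @export
print.migcost_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_draws, "draws (seed",
      paste0(x$seed, ")\n"))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s median %12.1f  [p25 %12.1f, p75 %12.1f] USD\n",
                s$quantity[i], s$median[i], s$p25[i], s$p75[i]))
  }
  invisible(x)
}

#' Write tornado entries as CSV
#'
#' @param tornado A `migcost_tornado` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(tornado, path) {
  out <- tibble::as_tibble(tornado)
  out$baseline <- attr(tornado, "baseline")
  readr::write_csv(out, path)
  invisible(path)
}
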