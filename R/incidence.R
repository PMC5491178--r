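age_band_labels <- function(breaks) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1] - 1
  ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi))
}

#' Exact person-years at risk by calendar year, age band and sex
#'
#' Sums each person's eligible fraction of every calendar year, split at the
#' birthday when it crosses an age-band boundary, so total person-years
#' equal the summed eligible durations. A full calendar year of eligibility
#' contributes exactly 1.0 PY. Ages at or above the top break are outside
#' the population of interest and contribute nothing.
#'
#' @param registry Registry tibble (`person_id`, `birth_date`, `sex`).
#' @param eligibility Eligibility tibble (`person_id`, `start_date`,
#'   `end_date`, half-open).
#' @param window Length-2 `Date`, inclusive study window.
#' @param age_breaks Increasing integer ages delimiting half-open bands
#'   `[lo, hi)`; default 5-year pediatric bands `c(0, 5, 10, 15)`. Use
#'   `0:15` for single-year ages (trend-model denominators).
#' @return Tibble `year`, `age_band`, `sex`, `py`, complete over the
#'   year x band x sex grid (zero rows included).
#' @export
person_years <- function(registry, eligibility, window,
                         age_breaks = c(0, 5, 10, 15)) {
  stopifnot(length(window) == 2, window[1] <= window[2],
            length(age_breaks) >= 2, !is.unsorted(age_breaks))
  labs <- age_band_labels(age_breaks)
  grid <- tidyr::expand_grid(
    year = seq(lubridate::year(window[1]), lubridate::year(window[2])),
    age_band = labs, sex = c("female", "male"))

  el <- eligibility |>
    mutate(start_date = pmax(.data$start_date, window[1]),
           end_date = pmin(.data$end_date, window[2] + 1)) |>
    filter(.data$end_date > .data$start_date) |>
    inner_join(registry[c("person_id", "birth_date", "sex")],
               by = "person_id")
  if (!nrow(el)) {
    return(grid |> mutate(py = 0) |> arrange(.data$year, .data$sex))
  }
  seg <- el |>
    mutate(y_from = lubridate::year(.data$start_date),
           y_to = lubridate::year(.data$end_date - 1)) |>
    mutate(year = map2(.data$y_from, .data$y_to, seq)) |>
    tidyr::unnest_longer("year") |>
    mutate(
      ys = as.Date(paste0(.data$year, "-01-01")),
      ye = as.Date(paste0(.data$year + 1, "-01-01")),
      seg_start = pmax(.data$start_date, .data$ys),
      seg_end = pmin(.data$end_date, .data$ye),
      year_days = as.numeric(.data$ye - .data$ys),
      # birthday anniversary falling in this calendar year
      bday = .data$birth_date %m+%
        lubridate::years(.data$year - lubridate::year(.data$birth_date)),
      age_after = .data$year - lubridate::year(.data$birth_date),
      split = pmin(pmax(.data$bday, .data$seg_start), .data$seg_end),
      days_before = as.numeric(.data$split - .data$seg_start),
      days_after = as.numeric(.data$seg_end - .data$split)
    )
  halves <- bind_rows(
    seg |> transmute(.data$year, .data$sex, .data$year_days,
                     age = .data$age_after - 1L, days = .data$days_before),
    seg |> transmute(.data$year, .data$sex, .data$year_days,
                     age = .data$age_after, days = .data$days_after)
  ) |>
    filter(.data$days > 0, .data$age >= age_breaks[1],
           .data$age < age_breaks[length(age_breaks)]) |>
    mutate(age_band = as.character(
      cut(.data$age, breaks = age_breaks, labels = labs, right = FALSE)))
  out <- halves |>
    group_by(.data$year, .data$age_band, .data$sex) |>
    summarise(py = sum(.data$days / .data$year_days), .groups = "drop")
  grid |>
    left_join(out, by = c("year", "age_band", "sex")) |>
    mutate(py = dplyr::coalesce(.data$py, 0)) |>
    arrange(.data$year, .data$sex)
}

#' A synthetic standard population
#'
#' Uniform stand-in for a census standard population (the real reference is
#' a census age-sex profile, not redistributable): weight proportional to
#' band width, split equally by sex.
#'
#' @param age_breaks As in [person_years()].
#' @return Tibble `age_band`, `sex`, `weight` with weights summing to 1.
#' @export
synthetic_standard_population <- function(age_breaks = c(0, 5, 10, 15)) {
  labs <- age_band_labels(age_breaks)
  widths <- diff(age_breaks)
  tidyr::expand_grid(age_band = labs, sex = c("female", "male")) |>
    left_join(tibble(age_band = labs, width = widths), by = "age_band") |>
    mutate(weight = .data$width / sum(.data$width)) |>
    select("age_band", "sex", "weight")
}

#' Directly standardized incidence rate with a Gamma-method interval
#'
#' Direct standardization of stratum rates to a fixed standard population:
#' `dsr = sum_i w_i d_i/n_i * per`, with variance
#' `v = sum_i w_i^2 d_i/n_i^2 * per^2`. The confidence interval is the
#' gamma-distribution method of Fay and Feuer, valid at low event counts:
#' the lower bound is `v/(2 dsr) * qchisq(alpha/2, 2 dsr^2/v)` (zero when no
#' events), and the upper bound augments the rate by the largest
#' weight-per-person-year, `w_M = max_i w_i/n_i * per`: with
#' `y+ = dsr + w_M` and `v+ = v + w_M^2`, the bound is
#' `v+/(2 y+) * qchisq(1 - alpha/2, 2 y+^2/v+)`. In the single-stratum case
#' this reduces to the exact Poisson chi-square interval.
#'
#' @param counts Tibble with `age_band`, `sex`, `d` (events), `py`
#'   (person-years) for one period; every standard stratum must be present.
#' @param std Standard population tibble (`age_band`, `sex`, `weight`
#'   summing to 1).
#' @param alpha Interval level complement.
#' @param per Rate multiplier (default per 100,000).
#' @return One-row tibble `dsr`, `variance`, `conf.low`, `conf.high`,
#'   `events`, `method = "gamma"`.
#' @export
direct_standardize <- function(counts, std, alpha = 0.05, per = 1e5) {
  if (abs(sum(std$weight) - 1) > 1e-9)
    abort("standard population weights must sum to 1",
          class = "claims_domain_error")
  j <- std |>
    select("age_band", "sex", "weight") |>
    left_join(counts |> select("age_band", "sex", "d", "py"),
              by = c("age_band", "sex"))
  if (anyNA(j$py)) {
    miss <- j |> filter(is.na(.data$py))
    abort(sprintf("missing count strata: %s",
                  paste(paste0(miss$age_band, "/", miss$sex), collapse = ", ")),
          class = "claims_domain_error")
  }
  if (any(j$py <= 0))
    abort("all strata need positive person-years",
          class = "claims_domain_error")
  y <- sum(j$weight * j$d / j$py) * per
  v <- sum(j$weight^2 * j$d / j$py^2) * per^2
  wm <- max(j$weight / j$py) * per
  lo <- if (y == 0) 0 else v / (2 * y) * qchisq(alpha / 2, 2 * y^2 / v)
  yu <- y + wm
  vu <- v + wm^2
  hi <- vu / (2 * yu) * qchisq(1 - alpha / 2, 2 * yu^2 / vu)
  tibble(dsr = y, variance = v, conf.low = lo, conf.high = hi,
         events = sum(j$d), method = "gamma")
}

#' Annual standardized incidence series from ascertained cases
#'
#' Buckets case records by calendar year of index date and by the (age at
#' index, sex) stratum, then directly standardizes each year.
#'
#' @param cases `cd_cases` tibble from [apply_algorithm()].
#' @param registry Registry tibble supplying birth dates and sex.
#' @param denominators Person-year denominators from [person_years()]
#'   (complete grid).
#' @param std Standard population over the same bands.
#' @param age_breaks Band definition used for the denominators.
#' @param alpha Interval level complement.
#' @return Tibble with one row per denominator year (`year`, `dsr`,
#'   `conf.low`, `conf.high`, `variance`, `events`), class
#'   `"cd_rate_series"`.
#' @export
incidence_series <- function(cases, registry, denominators, std,
                             age_breaks = c(0, 5, 10, 15), alpha = 0.05) {
  labs <- age_band_labels(age_breaks)
  ev <- cases |>
    inner_join(registry[c("person_id", "birth_date", "sex")],
               by = "person_id") |>
    mutate(year = lubridate::year(.data$index_date),
           age = age_at(.data$birth_date, .data$index_date),
           age_band = as.character(
             cut(.data$age, breaks = age_breaks, labels = labs,
                 right = FALSE)))
  bad <- ev |>
    anti_join(denominators |> filter(.data$py > 0),
              by = c("year", "age_band", "sex"))
  if (nrow(bad))
    abort(sprintf("case outside denominator coverage: person %s (%d, %s, %s)",
                  bad$person_id[1], bad$year[1], bad$age_band[1], bad$sex[1]),
          class = "claims_domain_error")
  counts <- denominators |>
    left_join(ev |> count(.data$year, .data$age_band, .data$sex, name = "d"),
              by = c("year", "age_band", "sex")) |>
    mutate(d = dplyr::coalesce(.data$d, 0L))
  out <- counts |>
    group_by(.data$year) |>
    group_modify(function(g, key) {
      # a stratum with zero PY in a year cannot host events; drop it and
      # renormalize would bias; instead require positive PY everywhere
      direct_standardize(g, std, alpha = alpha)
    }) |>
    ungroup()
  class(out) <- c("cd_rate_series", class(out))
  out
}

#' Poisson trend model for annual percent change in incidence
#'
#' Log-linear Poisson model for stratum event counts with a person-years
#' offset: `log E[d] = log(py) + b0 + b1 year + b2 male + b3 age`, with
#' optional `year x age` interaction and quadratic year term (the linearity
#' check). Year is continuous, centered at `year_center` so the intercept
#' rate is interpretable; age is age at diagnosis in completed years. The
#' annual percent change is `(exp(b1) - 1) * 100`; rate ratios are
#' exponentiated coefficients with Wald intervals.
#'
#' @param cases `cd_cases` tibble.
#' @param registry Registry tibble for birth dates and sex.
#' @param denominators Single-year-age person-year denominators
#'   (`person_years(..., age_breaks = 0:15)`), columns `year`, `age_band`,
#'   `sex`, `py`.
#' @param interaction_year_age Add a `year x age` term.
#' @param quadratic_year Add a squared-year term.
#' @param year_center Year subtracted from calendar year; defaults to the
#'   first denominator year.
#' @param alpha Wald interval level complement.
#' @return Object of class `"cd_trend"`: use [tidy()] for the coefficient
#'   and rate-ratio table, [glance()] for APC and fit diagnostics.
#' @export
fit_poisson_trend <- function(cases, registry, denominators,
                              interaction_year_age = FALSE,
                              quadratic_year = FALSE,
                              year_center = NULL, alpha = 0.05) {
  stopifnot(length(unique(denominators$year)) >= 2)
  den <- denominators |>
    filter(.data$py > 0) |>
    mutate(age = suppressWarnings(as.integer(.data$age_band)))
  if (anyNA(den$age))
    abort("trend denominators need single-year age bands (age_breaks = 0:15)",
          class = "claims_domain_error")
  year_center <- year_center %||% min(den$year)
  ev <- cases |>
    inner_join(registry[c("person_id", "birth_date", "sex")],
               by = "person_id") |>
    mutate(year = lubridate::year(.data$index_date),
           age = age_at(.data$birth_date, .data$index_date)) |>
    count(.data$year, .data$age, .data$sex, name = "d")
  dat <- den |>
    left_join(ev, by = c("year", "age", "sex")) |>
    mutate(d = dplyr::coalesce(.data$d, 0L),
           year_c = .data$year - year_center,
           sex_male = as.integer(.data$sex == "male"))
  rhs <- c("year_c", "sex_male", "age")
  if (interaction_year_age) rhs <- c(rhs, "year_c:age")
  if (quadratic_year) rhs <- c(rhs, "I(year_c^2)")
  fml <- as.formula(paste("d ~", paste(rhs, collapse = " + "),
                          "+ offset(log(py))"))
  fit <- glm(fml, family = poisson(), data = dat)
  z <- stats::qnorm(1 - alpha / 2)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  coefs <- tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    rate.ratio = exp(unname(est)),
    conf.low = exp(unname(est - z * se)),
    conf.high = exp(unname(est + z * se)))
  b1 <- est[["year_c"]]
  s1 <- se[names(est) == "year_c"]
  structure(
    list(coefficients = coefs,
         apc = (exp(b1) - 1) * 100,
         apc_ci = (exp(b1 + c(-z, z) * s1) - 1) * 100,
         deviance = fit$deviance, df.residual = fit$df.residual,
         converged = fit$converged, nobs = nrow(dat),
         year_center = year_center, fit = fit),
    class = "cd_trend")
}

#' @export
print.cd_trend <- function(x, ...) {
  cat(sprintf("Poisson incidence trend (year centered at %d)\n",
              x$year_center))
  cat(sprintf("APC: %.2f%% (95%% CI %.2f to %.2f)%s\n",
              x$apc, x$apc_ci[1], x$apc_ci[2],
              if (!x$converged) "  [did not converge]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_poisson_trend
#' @param x A `cd_trend` object.
#' @param ... Unused.
#' @method tidy cd_trend
#' @export
tidy.cd_trend <- function(x, ...) x$coefficients

#' @rdname fit_poisson_trend
#' @method glance cd_trend
#' @export
glance.cd_trend <- function(x, ...) {
  tibble(apc = x$apc, apc.conf.low = x$apc_ci[1],
         apc.conf.high = x$apc_ci[2], deviance = x$deviance,
         df.residual = x$df.residual, converged = x$converged,
         nobs = x$nobs)
}
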