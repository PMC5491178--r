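win <- as.Date(c("2005-01-01", "2011-12-31"))

test_that("person-years conserve eligible time and split at birthdays", {
  # one child, age 7 all of 2005, male
  reg <- tibble::tibble(person_id = "a", birth_date = as.Date("1997-06-15"),
                        sex = "male", region_flag = TRUE)
  el <- tibble::tibble(person_id = "a", start_date = as.Date("2005-01-01"),
                       end_date = as.Date("2006-01-01"))
  py <- person_years(reg, el, as.Date(c("2005-01-01", "2005-12-31")))
  expect_equal(sum(py$py), 1)
  expect_equal(py$py[py$age_band == "5-9" & py$sex == "male"], 1)
  # eligible half the year -> 0.5 PY (non-leap 2005: 182.5 days is not
  # attainable; use July 2 to get exactly half)
  el2 <- tibble::tibble(person_id = "a", start_date = as.Date("2005-01-01"),
                        end_date = as.Date("2005-01-01") + 182)
  py2 <- person_years(reg, el2, as.Date(c("2005-01-01", "2005-12-31")))
  expect_equal(sum(py2$py), 182 / 365)
  # 1000 children fully eligible three years: total PY = 3000
  reg3 <- tibble::tibble(person_id = sprintf("c%04d", 1:1000),
                         birth_date = as.Date("2001-03-10"),
                         sex = rep(c("male", "female"), 500),
                         region_flag = TRUE)
  el3 <- tibble::tibble(person_id = reg3$person_id,
                        start_date = as.Date("2005-01-01"),
                        end_date = as.Date("2008-01-01"))
  py3 <- person_years(reg3, el3, as.Date(c("2005-01-01", "2007-12-31")))
  expect_equal(sum(py3$py), 3000)
  # birthday split: a child turning 5 on 2005-07-01 contributes to both bands
  reg4 <- tibble::tibble(person_id = "b", birth_date = as.Date("2000-07-01"),
                         sex = "female", region_flag = TRUE)
  py4 <- person_years(reg4,
                      tibble::tibble(person_id = "b",
                                     start_date = as.Date("2005-01-01"),
                                     end_date = as.Date("2006-01-01")),
                      as.Date(c("2005-01-01", "2005-12-31")))
  expect_equal(py4$py[py4$age_band == "0-4" & py4$sex == "female"],
               181 / 365)
  expect_equal(py4$py[py4$age_band == "5-9" & py4$sex == "female"],
               184 / 365)
  # person with no eligibility contributes zero, not an error
  py5 <- person_years(reg, el[0, ], as.Date(c("2005-01-01", "2005-12-31")))
  expect_equal(sum(py5$py), 0)
})

test_that("direct standardization is exact in degenerate cases and errors on missing strata", {
  std <- synthetic_standard_population()
  # identical stratum rates: dsr equals the shared rate for any weights
  counts <- std |>
    dplyr::mutate(py = c(1000, 2000, 1500, 800, 1200, 900),
                  d = py * 0.002)
  expect_equal(direct_standardize(counts, std)$dsr, 0.002 * 1e5)
  skewed <- std |> dplyr::mutate(weight = c(.4, .2, .1, .1, .1, .1))
  expect_equal(direct_standardize(counts, skewed)$dsr, 0.002 * 1e5)
  # zero events: rate 0 with lower bound exactly 0
  z <- direct_standardize(counts |> dplyr::mutate(d = 0), std)
  expect_equal(z$dsr, 0)
  expect_equal(z$conf.low, 0)
  expect_gt(z$conf.high, 0)
  expect_error(direct_standardize(counts[-1, ], std), "0-4",
               class = "claims_domain_error")
})

test_that("gamma interval equals the exact Poisson chi-square interval for a single stratum", {
  std1 <- tibble::tibble(age_band = "0-14", sex = "female", weight = 1)
  for (d in c(1, 4, 17, 120)) {
    n <- 5000
    got <- direct_standardize(
      tibble::tibble(age_band = "0-14", sex = "female", d = d, py = n), std1)
    lo <- qchisq(0.025, 2 * d) / (2 * n) * 1e5
    hi <- qchisq(0.975, 2 * d + 2) / (2 * n) * 1e5
    expect_equal(got$conf.low, lo, tolerance = 1e-9)
    expect_equal(got$conf.high, hi, tolerance = 1e-9)
  }
})

test_that("gamma interval coverage is conservative (93-99%) across replicates", {
  withr::local_seed(1234)
  std <- synthetic_standard_population()
  py <- c(4000, 4100, 3900, 4200, 4000, 3800)
  rates <- c(10, 15, 25, 30, 45, 60) / 1e5
  true_dsr <- sum(std$weight * rates) * 1e5
  hits <- vapply(seq_len(500), function(i) {
    counts <- std |>
      dplyr::mutate(py = py, d = rpois(6, py * rates))
    ci <- direct_standardize(counts, std)
    ci$conf.low <= true_dsr && true_dsr <= ci$conf.high
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.99)
})

test_that("annual series is linear in events and zero without cases", {
  # birth cohorts chosen so every 5-year band has person-time every year
  reg <- tibble::tibble(person_id = sprintf("k%03d", 1:200),
                        birth_date = rep(as.Date(c("1995-03-01", "1997-02-01",
                                                   "2001-08-15", "2003-05-01",
                                                   "2006-11-20")), 40),
                        sex = rep(c("male", "female"), 100),
                        region_flag = TRUE)
  el <- tibble::tibble(person_id = reg$person_id,
                       start_date = pmax(as.Date("2004-01-01"),
                                         reg$birth_date),
                       end_date = as.Date("2013-01-01"))
  den <- person_years(reg, el, win)
  std <- synthetic_standard_population()
  empty <- tibble::tibble(person_id = character(),
                          index_date = as.Date(character()))
  s0 <- incidence_series(empty, reg, den, std)
  expect_equal(nrow(s0), 7)
  expect_true(all(s0$dsr == 0))
  cases <- tibble::tibble(person_id = c("k001", "k002", "k003", "k004"),
                          index_date = as.Date(c("2006-03-01", "2006-07-01",
                                                 "2008-01-15", "2010-06-30")))
  s1 <- incidence_series(cases, reg, den, std)
  doubled <- incidence_series(
    dplyr::bind_rows(cases,
                     cases |> dplyr::mutate(person_id = paste0(person_id, "b"))),
    reg |> dplyr::bind_rows(reg |> dplyr::mutate(person_id = paste0(person_id, "b"))),
    person_years(dplyr::bind_rows(reg, reg |>
                                    dplyr::mutate(person_id = paste0(person_id, "b"))),
                 dplyr::bind_rows(el, el |>
                                    dplyr::mutate(person_id = paste0(person_id, "b"))),
                 win),
    std)
  expect_equal(doubled$dsr, s1$dsr)  # same rate when cases and PY both double
  # a case aged out of every band is outside denominator coverage
  bad <- tibble::tibble(person_id = "k001",                  # born 1995-03-01
                        index_date = as.Date("2011-06-01"))  # aged 16
  expect_error(incidence_series(bad, reg, den, std),
               class = "claims_domain_error")
})

test_that("poisson trend fit matches an independent likelihood optimizer", {
  withr::local_seed(99)
  grid <- tidyr::expand_grid(year = 2005:2011, age = 0:14,
                             sex = c("female", "male")) |>
    dplyr::mutate(py = runif(dplyr::n(), 500, 1500))
  b <- c(b0 = log(3e-4), b1 = 0.06, b2 = -0.3, b3 = -0.05)
  mu <- with(grid, py * exp(b["b0"] + b["b1"] * (year - 2005) +
                              b["b2"] * (sex == "male") + b["b3"] * age))
  grid$d <- rpois(nrow(grid), mu)
  # expand to case records with synthetic persons matching each stratum
  ev <- grid[rep(seq_len(nrow(grid)), grid$d), ]
  ids <- sprintf("s%05d", seq_len(nrow(ev)))
  reg <- tibble::tibble(person_id = ids,
                        birth_date = as.Date(sprintf("%d-01-01",
                                                     ev$year - ev$age)),
                        sex = ev$sex, region_flag = TRUE)
  cases <- tibble::tibble(person_id = ids,
                          index_date = as.Date(sprintf("%d-07-01", ev$year)))
  den <- grid |>
    dplyr::transmute(year, age_band = as.character(age), sex, py)
  fit <- fit_poisson_trend(cases, reg, den)
  # independent oracle: minimize the same Poisson likelihood numerically
  X <- cbind(1, grid$year - 2005, as.integer(grid$sex == "male"), grid$age)
  nll <- function(beta) {
    eta <- X %*% beta + log(grid$py)
    sum(exp(eta)) - sum(grid$d * eta)
  }
  gr <- function(beta) {
    eta <- X %*% beta + log(grid$py)
    drop(t(X) %*% (exp(eta) - grid$d))
  }
  opt <- optim(c(-8, 0, 0, 0), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  expect_equal(unname(tidy(fit)$estimate), unname(opt$par), tolerance = 1e-6)
  # recovery of the generating coefficients within 3 SE
  co <- tidy(fit)
  expect_lt(abs(co$estimate[co$term == "year_c"] - b["b1"]),
            3 * co$std.error[co$term == "year_c"])
  # rate ratios are exponentiated coefficients
  expect_equal(co$rate.ratio, exp(co$estimate))
})

test_that("constant incidence yields a null trend and RR near one", {
  withr::local_seed(7)
  grid <- tidyr::expand_grid(year = 2005:2011, age = 0:14,
                             sex = c("female", "male")) |>
    dplyr::mutate(py = 3000, d = rpois(dplyr::n(), 3000 * 2e-4))
  ev <- grid[rep(seq_len(nrow(grid)), grid$d), ]
  ids <- sprintf("n%05d", seq_len(nrow(ev)))
  reg <- tibble::tibble(person_id = ids,
                        birth_date = as.Date(sprintf("%d-01-01",
                                                     ev$year - ev$age)),
                        sex = ev$sex, region_flag = TRUE)
  cases <- tibble::tibble(person_id = ids,
                          index_date = as.Date(sprintf("%d-07-01", ev$year)))
  den <- grid |> dplyr::transmute(year, age_band = as.character(age), sex, py)
  fit <- fit_poisson_trend(cases, reg, den)
  co <- tidy(fit)
  b1 <- co[co$term == "year_c", ]
  expect_lt(abs(b1$estimate), 3 * b1$std.error)
  expect_equal(b1$rate.ratio, 1, tolerance = 0.1)
  g <- glance(fit)
  expect_true(g$converged)
  expect_true(g$apc.conf.low < 0 && g$apc.conf.high > 0)
  # optional model terms are present when requested
  fit2 <- fit_poisson_trend(cases, reg, den, interaction_year_age = TRUE,
                            quadratic_year = TRUE)
  expect_true(all(c("year_c:age", "I(year_c^2)") %in% tidy(fit2)$term))
})
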