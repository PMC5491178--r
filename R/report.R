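#' Round half away from zero
#'
#' Reporting convention for printed percentages (IEEE round-half-even would
#' print 0.125 as 0.12; published tables round 5 up).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Privacy-style small-cell suppression for displayed counts
#'
#' Counts of 1–5 display as `"<6"`. Counts outside the union of identified
#' cases are additionally rounded to the nearest 10 (half up). Zero and
#' in-union counts of 6 or more display as-is. Suppression applies to
#' rendering only, never to the statistics themselves.
#'
#' @param raw Non-negative integer counts (vectorised).
#' @param context `"in_union"` or `"outside_union"`, recycled.
#' @return Tibble `raw`, `display`.
#' @examples
#' suppress_count(c(3, 0, 235249), c("in_union", "in_union", "outside_union"))
#' @export
suppress_count <- function(raw, context = "in_union") {
  stopifnot(all(raw >= 0), all(context %in% c("in_union", "outside_union")))
  ctx <- rep_len(context, length(raw))
  display <- ifelse(
    raw >= 1 & raw <= 5, "<6",
    ifelse(ctx == "outside_union",
           format(round_half_up(raw / 10) * 10, scientific = FALSE,
                  trim = TRUE),
           format(raw, scientific = FALSE, trim = TRUE)))
  tibble(raw = raw, display = display)
}

fmt_cell <- function(est, lo, hi, digits = 2) {
  ifelse(is.na(est), "NA",
         sprintf("%.*f (%.*f–%.*f)", digits, round_half_up(est * 100, digits),
                 digits, round_half_up(lo * 100, digits),
                 digits, round_half_up(hi * 100, digits)))
}

#' Render operating characteristics as a publication-style table
#'
#' One row per algorithm, the four measures as `"estimate (lower-upper)"`
#' percentage cells.
#'
#' @param chars A `cd_accuracy` tibble (long form, as returned by
#'   [operating_characteristics()] or [subgroup_validation()]).
#' @param digits Decimal places (2 for full tables, 1 for abstract-style
#'   reporting).
#' @return A tibble with columns `algorithm_id` (and `age_cutoff` when
#'   present), `sensitivity`, `specificity`, `ppv`, `npv`; write with
#'   `readr::write_csv()`.
#' @export
render_table1 <- function(chars, digits = 2) {
  stopifnot(nrow(chars) > 0)
  keys <- intersect(c("algorithm_id", "age_cutoff"), names(chars))
  if (!length(keys)) {
    chars$algorithm_id <- "(unnamed)"
    keys <- "algorithm_id"
  }
  chars |>
    mutate(cell = fmt_cell(.data$estimate, .data$conf.low, .data$conf.high,
                           digits)) |>
    select(dplyr::all_of(keys), "measure", "cell") |>
    tidyr::pivot_wider(names_from = "measure", values_from = "cell") |>
    select(dplyr::all_of(c(keys, "sensitivity", "specificity", "ppv", "npv")))
}

#' Run the full synthetic pipeline: simulate, ascertain, validate, estimate
#'
#' Orchestrates simulation, case ascertainment for the configured
#' algorithms, validation against the emitted reference labels, the
#' channel-overlap partition, annual standardized incidence, and the
#' Poisson trend fit; writes `table1.csv`, `venn.csv`, `rates.csv`,
#' `fit.json` and `run.log` to `out_dir`. Deterministic for a fixed seed;
#' the log records the seed, a configuration hash and row counts at every
#' stage, so a run is reproducible from its log alone.
#'
#' @param config A list (or path to a YAML file) with any of: `seed`,
#'   `out_dir`, `simulation` (arguments to [sim_params()]), `algorithms`
#'   (ids, default `c("13-OHIP", "1-SDS")`), `alpha`, `age_breaks`,
#'   `digits`.
#' @return Invisibly, a list with the bundle, results, characteristics,
#'   rate series and trend fit.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 20110629L
  out_dir <- config$out_dir %||% tempfile("cdrun")
  algorithms <- config$algorithms %||% c("13-OHIP", "1-SDS")
  alpha <- config$alpha %||% 0.05
  age_breaks <- config$age_breaks %||% c(0, 5, 10, 15)
  digits <- config$digits %||% 2
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- claims_config(alpha = alpha)
  grid <- build_algorithm_grid()
  unknown <- setdiff(algorithms, grid$algorithm_id)
  if (length(unknown))
    abort(sprintf("pipeline stage 'ascertain' failed: unknown algorithm id '%s'",
                  unknown[1]), class = "claims_schema_error")

  log_lines <- c(
    sprintf("seed: %d", seed),
    sprintf("config_hash: %s", rlang::hash(config[sort(names(config))])),
    sprintf("algorithms: %s", paste(algorithms, collapse = ", ")))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  sim_args <- config$simulation %||% list()
  sim_args$seed <- seed
  params <- do.call(sim_params, sim_args)
  sim <- simulate_population(params, cfg)
  bundle <- sim$bundle
  note("simulate: %d persons, %d claims, %d procedures",
       nrow(bundle$registry), nrow(bundle$claims), nrow(bundle$procedures))

  results <- map(algorithms, function(id)
    apply_algorithm(bundle, id, cfg))
  names(results) <- algorithms
  for (id in algorithms)
    note("ascertain %s: %d cases", id, nrow(results[[id]]))

  chars <- map(results, function(r)
    operating_characteristics(confusion_table(r, bundle$labels), alpha)) |>
    list_rbind()
  tab1 <- render_table1(chars, digits)
  readr::write_csv(tab1, file.path(out_dir, "table1.csv"), progress = FALSE)
  note("validate: %d algorithms -> table1.csv", length(algorithms))

  if (length(results) >= 2) {
    ov <- overlap(results[[1]], results[[2]])
    venn <- tibble(
      region = c(paste0("only_", algorithms[1]), "both",
                 paste0("only_", algorithms[2])),
      count = suppress_count(c(ov$only_a, ov$both, ov$only_b),
                             "in_union")$display)
    readr::write_csv(venn, file.path(out_dir, "venn.csv"), progress = FALSE)
    note("overlap %s vs %s: %d / %d / %d", algorithms[1], algorithms[2],
         ov$only_a, ov$both, ov$only_b)
  }

  den <- person_years(bundle$registry, bundle$eligibility,
                      params$study_window, age_breaks)
  std <- synthetic_standard_population(age_breaks)
  cases1 <- results[[1]]
  keep <- in_band(cases1, bundle$registry, age_breaks)
  if (sum(!keep))
    note("incidence: dropped %d case(s) outside the age bands", sum(!keep))
  series <- incidence_series(cases1[keep, ], bundle$registry, den, std,
                             age_breaks, alpha)
  readr::write_csv(
    series |> select("year", "dsr", "conf.low", "conf.high", "events"),
    file.path(out_dir, "rates.csv"), progress = FALSE)
  note("incidence: %d years -> rates.csv", nrow(series))

  den1 <- person_years(bundle$registry, bundle$eligibility,
                       params$study_window, seq(0, 15))
  trend <- fit_poisson_trend(cases1[keep, ], bundle$registry, den1,
                             alpha = alpha)
  jsonlite::write_json(
    list(apc = trend$apc, apc_ci = trend$apc_ci,
         coefficients = tidy(trend), converged = trend$converged),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  note("trend: APC %.2f%% -> fit.json", trend$apc)

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(bundle = bundle, truth = sim$truth, results = results,
                 characteristics = chars, table1 = tab1, series = series,
                 trend = trend, out_dir = out_dir))
}

in_band <- function(cases, registry, age_breaks) {
  if (!nrow(cases)) return(logical(0))
  age <- cases |>
    inner_join(registry[c("person_id", "birth_date")], by = "person_id") |>
    mutate(a = age_at(.data$birth_date, .data$index_date)) |>
    pull("a")
  age >= age_breaks[1] & age < age_breaks[length(age_breaks)]
}
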