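#' Linked claims bundle: construct and validate
#'
#' A `claims_bundle` holds the five linked administrative tables plus an
#' optional reference-standard label table, pre-linked on `person_id`:
#'
#' * `registry` — one row per child: `person_id`, `birth_date`, `sex`
#'   (`"male"`/`"female"`), `region_flag`.
#' * `eligibility` — health-insurance coverage intervals, half-open
#'   `[start_date, end_date)`: `person_id`, `start_date`, `end_date`.
#' * `claims` — outpatient physician billing claims: `person_id`,
#'   `service_date`, `physician_id`, `diagnostic_code` (exactly one per
#'   claim), `fee_code`.
#' * `procedures` — same-day-surgery records: `person_id`, `procedure_date`,
#'   `facility_id`, `intervention_codes` (list-column), `diagnostic_codes`
#'   (list-column, 1–20 codes).
#' * `hospitalizations` — `person_id`, `admission_date`, `discharge_date`,
#'   `diagnostic_codes` (list-column).
#' * `physicians` — `physician_id`, `specialty`.
#' * `labels` (optional) — `person_id`, `status`
#'   (`"true_positive"`/`"true_negative"`), `diagnosis_date`, `marsh_class`
#'   (`"3a"`/`"3b"`/`"3c"`/`"none"`). A true positive is biopsy-proven:
#'   Marsh grade IIIa or above with a diagnosis date.
#'
#' @param registry,eligibility,claims,procedures,hospitalizations,physicians
#'   Data frames with the columns above.
#' @param labels Optional label data frame.
#' @param validate Run invariant checks (default `TRUE`).
#' @return A list of tibbles with class `"claims_bundle"`.
#' @export
claims_bundle <- function(registry, eligibility, claims, procedures,
                          hospitalizations, physicians, labels = NULL,
                          validate = TRUE) {
  b <- structure(
    list(
      registry = as_tibble(registry),
      eligibility = as_tibble(eligibility),
      claims = as_tibble(claims),
      procedures = as_tibble(procedures),
      hospitalizations = as_tibble(hospitalizations),
      physicians = as_tibble(physicians),
      labels = if (!is.null(labels)) as_tibble(labels)
    ),
    class = "claims_bundle"
  )
  if (validate) validate_bundle(b)
  b
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) cat(sprintf("  %-16s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

stop_schema <- function(table, row, field, msg) {
  abort(sprintf("schema violation in `%s` (row %s, field `%s`): %s",
                table, paste(row, collapse = ","), field, msg),
        class = "claims_schema_error")
}

stop_linkage <- function(table, row, msg) {
  abort(sprintf("linkage error in `%s` (row %s): %s",
                table, paste(row, collapse = ","), msg),
        class = "claims_linkage_error")
}

#' Validate all bundle invariants
#'
#' Checks uniqueness of identifiers, referential integrity of every
#' `person_id`/`physician_id`, the single-diagnostic-code constraint on
#' outpatient claims, the 1–20 diagnostic-code bound on procedure records,
#' non-overlapping sorted eligibility intervals that start after birth, date
#' ordering of hospitalizations, binary sex, and label consistency
#' (true positives have a Marsh III grade and a diagnosis date).
#'
#' @param bundle A `claims_bundle`.
#' @return The bundle, invisibly; errors name the offending table, row and
#'   field.
#' @export
validate_bundle <- function(bundle) {
  reg <- bundle$registry
  if (anyDuplicated(reg$person_id))
    stop_schema("registry", which(duplicated(reg$person_id))[1], "person_id",
                "duplicate person_id")
  bad_sex <- which(!reg$sex %in% c("male", "female"))
  if (length(bad_sex))
    stop_schema("registry", bad_sex[1], "sex",
                "sex must be 'male' or 'female'")

  el <- bundle$eligibility
  if (nrow(el)) {
    bad <- which(el$end_date <= el$start_date)
    if (length(bad))
      stop_schema("eligibility", bad[1], "end_date",
                  "intervals must satisfy start_date < end_date")
    el2 <- el |>
      left_join(reg[c("person_id", "birth_date")], by = "person_id") |>
      arrange(.data$person_id, .data$start_date)
    bad <- which(el2$start_date < el2$birth_date)
    if (length(bad))
      stop_schema("eligibility", bad[1], "start_date",
                  "interval starts before birth_date")
    ovl <- el2 |>
      group_by(.data$person_id) |>
      summarise(ok = all(diff_ok(.data$start_date, .data$end_date)),
                .groups = "drop")
    if (any(!ovl$ok))
      stop_schema("eligibility", NA, "start_date",
                  sprintf("overlapping intervals for person %s",
                          ovl$person_id[!ovl$ok][1]))
  }

  known <- reg$person_id
  for (tab in c("eligibility", "claims", "procedures", "hospitalizations",
                "labels")) {
    t <- bundle[[tab]]
    if (is.null(t) || !nrow(t)) next
    orphan <- which(!t$person_id %in% known)
    if (length(orphan))
      stop_linkage(tab, orphan[1],
                   sprintf("person_id '%s' not in registry",
                           t$person_id[orphan[1]]))
  }

  cl <- bundle$claims
  if (nrow(cl)) {
    orphan <- which(!cl$physician_id %in% bundle$physicians$physician_id)
    if (length(orphan))
      stop_linkage("claims", orphan[1],
                   sprintf("physician_id '%s' not in physicians",
                           cl$physician_id[orphan[1]]))
    bad <- which(is.na(cl$diagnostic_code) | cl$diagnostic_code == "" |
                   grepl(";", cl$diagnostic_code, fixed = TRUE))
    if (length(bad))
      stop_schema("claims", bad[1], "diagnostic_code",
                  "exactly one non-empty diagnostic code per claim")
  }

  pr <- bundle$procedures
  if (nrow(pr)) {
    n_dx <- lengths(pr$diagnostic_codes)
    bad <- which(n_dx < 1 | n_dx > 20)
    if (length(bad))
      stop_schema("procedures", bad[1], "diagnostic_codes",
                  sprintf("record carries %d diagnostic codes; 1-20 allowed",
                          n_dx[bad[1]]))
  }

  ho <- bundle$hospitalizations
  if (nrow(ho)) {
    bad <- which(ho$discharge_date < ho$admission_date)
    if (length(bad))
      stop_schema("hospitalizations", bad[1], "discharge_date",
                  "discharge precedes admission")
  }

  ph <- bundle$physicians
  if (anyDuplicated(ph$physician_id))
    stop_schema("physicians", which(duplicated(ph$physician_id))[1],
                "physician_id", "duplicate physician_id")

  lb <- bundle$labels
  if (!is.null(lb) && nrow(lb)) {
    pos <- lb$status == "true_positive"
    bad <- which(pos & (is.na(lb$diagnosis_date) |
                          !lb$marsh_class %in% c("3a", "3b", "3c")))
    if (length(bad))
      stop_schema("labels", bad[1], "marsh_class",
                  "true positives require Marsh 3a/3b/3c and a diagnosis date")
    bad <- which(!pos & lb$marsh_class %in% c("3a", "3b", "3c"))
    if (length(bad))
      stop_schema("labels", bad[1], "marsh_class",
                  "true negatives must not carry a Marsh III grade")
  }
  invisible(bundle)
}

# TRUE iff sorted half-open intervals do not overlap
diff_ok <- function(start, end) {
  if (length(start) <= 1) return(TRUE)
  all(start[-1] >= end[-length(end)])
}

bundle_tables <- c("registry", "claims", "procedures", "hospitalizations",
                   "physicians", "labels")

join_codes <- function(x) map_chr(x, paste, collapse = ";")
split_codes <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  map(out, function(v) v[v != ""])
}

#' Read a linked claims bundle from CSV files
#'
#' Expects `registry.csv`, `claims.csv`, `procedures.csv`,
#' `hospitalizations.csv`, `physicians.csv` and optionally `labels.csv` in
#' `dir` (individual paths can be overridden through `paths`). All dates are
#' ISO-8601. Eligibility intervals travel inside `registry.csv` as a
#' `;`-separated list of `start/end` half-open spans; multi-code fields use
#' `;`-separated code lists.
#'
#' @param dir Directory containing the CSV tables.
#' @param paths Optional named list overriding individual table paths.
#' @param validate Check invariants after loading (default `TRUE`).
#' @return A `claims_bundle`.
#' @examples
#' demo <- system.file("extdata", "demo_bundle", package = "celiacclaims")
#' bundle <- load_bundle(demo)
#' bundle
#' @export
load_bundle <- function(dir = ".", paths = list(), validate = TRUE) {
  path_of <- function(tab) {
    paths[[tab]] %||% file.path(dir, paste0(tab, ".csv"))
  }
  need <- setdiff(bundle_tables, "labels")
  for (tab in need) {
    if (!file.exists(path_of(tab)))
      abort(sprintf("missing table file: %s", path_of(tab)),
            class = "claims_schema_error")
  }
  rd <- function(tab, col_types) {
    readr::read_csv(path_of(tab), col_types = col_types, progress = FALSE)
  }
  reg_raw <- rd("registry", readr::cols(
    person_id = "c", birth_date = "D", sex = "c", region_flag = "l",
    eligibility_intervals = "c"))
  registry <- reg_raw |> select(!"eligibility_intervals")
  eligibility <- reg_raw |>
    select("person_id", "eligibility_intervals") |>
    mutate(span = split_codes(.data$eligibility_intervals)) |>
    select("person_id", "span") |>
    tidyr::unnest_longer("span") |>
    tidyr::separate_wider_delim("span", "/",
                                names = c("start_date", "end_date")) |>
    mutate(start_date = as.Date(.data$start_date),
           end_date = as.Date(.data$end_date))

  claims <- rd("claims", readr::cols(
    person_id = "c", service_date = "D", physician_id = "c",
    diagnostic_code = "c", fee_code = "c"))
  procedures <- rd("procedures", readr::cols(
    person_id = "c", procedure_date = "D", facility_id = "c",
    intervention_codes = "c", diagnostic_codes = "c")) |>
    mutate(intervention_codes = split_codes(.data$intervention_codes),
           diagnostic_codes = split_codes(.data$diagnostic_codes))
  hospitalizations <- rd("hospitalizations", readr::cols(
    person_id = "c", admission_date = "D", discharge_date = "D",
    diagnostic_codes = "c")) |>
    mutate(diagnostic_codes = split_codes(.data$diagnostic_codes))
  physicians <- rd("physicians", readr::cols(
    physician_id = "c", specialty = "c"))
  labels <- NULL
  if (file.exists(path_of("labels"))) {
    labels <- rd("labels", readr::cols(
      person_id = "c", status = "c", diagnosis_date = "D", marsh_class = "c"))
  }
  claims_bundle(registry, eligibility, claims, procedures, hospitalizations,
                physicians, labels, validate = validate)
}

#' Write a claims bundle to CSV files
#'
#' Inverse of [load_bundle()]: emits the canonical column order so a
#' load/write round trip reproduces the files.
#'
#' @param bundle A `claims_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spans <- bundle$eligibility |>
    arrange(.data$person_id, .data$start_date) |>
    mutate(span = paste0(.data$start_date, "/", .data$end_date)) |>
    group_by(.data$person_id) |>
    summarise(eligibility_intervals = paste(.data$span, collapse = ";"),
              .groups = "drop")
  reg <- bundle$registry |>
    left_join(spans, by = "person_id") |>
    mutate(eligibility_intervals =
             ifelse(is.na(.data$eligibility_intervals), "",
                    .data$eligibility_intervals)) |>
    select("person_id", "birth_date", "sex", "region_flag",
           "eligibility_intervals")
  readr::write_csv(reg, file.path(dir, "registry.csv"), progress = FALSE)
  readr::write_csv(
    bundle$claims |> select("person_id", "service_date", "physician_id",
                            "diagnostic_code", "fee_code"),
    file.path(dir, "claims.csv"), progress = FALSE)
  readr::write_csv(
    bundle$procedures |>
      mutate(intervention_codes = join_codes(.data$intervention_codes),
             diagnostic_codes = join_codes(.data$diagnostic_codes)) |>
      select("person_id", "procedure_date", "facility_id",
             "intervention_codes", "diagnostic_codes"),
    file.path(dir, "procedures.csv"), progress = FALSE)
  readr::write_csv(
    bundle$hospitalizations |>
      mutate(diagnostic_codes = join_codes(.data$diagnostic_codes)) |>
      select("person_id", "admission_date", "discharge_date",
             "diagnostic_codes"),
    file.path(dir, "hospitalizations.csv"), progress = FALSE)
  readr::write_csv(
    bundle$physicians |> select("physician_id", "specialty"),
    file.path(dir, "physicians.csv"), progress = FALSE)
  if (!is.null(bundle$labels)) {
    readr::write_csv(
      bundle$labels |> select("person_id", "status", "diagnosis_date",
                              "marsh_class"),
      file.path(dir, "labels.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' Age at a date, in completed years or months
#'
#' Vectorised over both date arguments.
#'
#' @param birth_date,on `Date` vectors.
#' @param unit `"years"` (completed years, floor) or `"months"` (completed
#'   months, for the 6-month lower eligibility bound).
#' @return Integer vector of completed units.
#' @examples
#' age_at(as.Date("2000-03-15"), as.Date("2007-03-14"))  # 6
#' age_at(as.Date("2000-03-15"), as.Date("2007-03-15"))  # 7
#' age_at(as.Date("2000-03-15"), as.Date("2000-09-15"), unit = "months")  # 6
#' @export
age_at <- function(birth_date, on, unit = c("years", "months")) {
  unit <- match.arg(unit)
  if (any(on < birth_date, na.rm = TRUE))
    abort("`on` precedes `birth_date`", class = "claims_domain_error")
  iv <- lubridate::interval(birth_date, on)
  per <- lubridate::as.period(iv, unit = "months")
  months <- per@year * 12L + per@month
  if (unit == "months") as.integer(months) else as.integer(months %/% 12L)
}

#' Continuous coverage over a window
#'
#' A person is continuously eligible over `window` when the union of their
#' half-open coverage intervals contains every day of the closed window.
#'
#' @param eligibility Tibble with `person_id`, `start_date`, `end_date`
#'   (half-open intervals), e.g. `bundle$eligibility`.
#' @param window Length-2 `Date` vector, inclusive.
#' @return Tibble with `person_id` and logical `eligible`; persons absent
#'   from `eligibility` are absent here (no coverage at all).
#' @export
continuously_eligible <- function(eligibility, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  eligibility |>
    arrange(.data$person_id, .data$start_date) |>
    group_by(.data$person_id) |>
    summarise(eligible = covers_window(.data$start_date, .data$end_date,
                                       window[1], window[2]),
              .groups = "drop")
}

# union of sorted half-open intervals covers the closed window [lo, hi]?
covers_window <- function(start, end, lo, hi) {
  need <- lo
  for (i in seq_along(start)) {
    if (start[i] > need) return(FALSE)
    if (end[i] > need) need <- end[i]
    # half-open: end itself is not covered, so need is next uncovered day
    if (need > hi) return(TRUE)
  }
  need > hi
}
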