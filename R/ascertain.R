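#' The grid of 26 case-identifying algorithms
#'
#' Every algorithm has the same two-step clinical structure: a dated
#' endoscopy ("scope") plus a required number of celiac-coded health-system
#' contacts. Thirteen rule variants are crossed with the two endoscopy
#' recording channels:
#'
#' * `ohip_any_indication` — an outpatient fee-schedule claim for endoscopy,
#'   regardless of its single diagnostic code (billed at procedure time,
#'   before histology is available);
#' * `sds_cd_coded` — a same-day-surgery procedure record carrying both an
#'   endoscopy intervention code and a celiac diagnostic code (abstracted by
#'   hospital coders who may already have the biopsy result).
#'
#' Variants 1–13 per channel: (1) scope plus >=1 gastroenterologist
#' celiac-coded outpatient contact anywhere in the study window; (2–6) scope
#' plus >=2 such contacts within 1–5 years of the scope; (7) scope plus >=1
#' contact or celiac-coded hospitalization; (8–12) scope plus >=2 contacts
#' or hospitalizations within 1–5 years; (13) scope plus >=1 contact
#' strictly after the scope.
#'
#' @return Tibble with one row per algorithm: `algorithm_id`,
#'   `endoscopy_source`, `min_contacts`, `contact_types` (list-column),
#'   `window_years` (`NA` when unwindowed), `require_contacts_after_scope`.
#' @examples
#' grid <- build_algorithm_grid()
#' nrow(grid)  # 26
#' @export
build_algorithm_grid <- function() {
  rows <- tibble(
    variant = 1:13,
    min_contacts = c(1L, rep(2L, 5), 1L, rep(2L, 5), 1L),
    window_years = c(NA, 1:5, NA, 1:5, NA),
    with_hosp = c(rep(FALSE, 6), rep(TRUE, 6), FALSE),
    require_contacts_after_scope = c(rep(FALSE, 12), TRUE)
  )
  tidyr::expand_grid(
    source = c("OHIP", "SDS"),
    rows
  ) |>
    mutate(
      algorithm_id = paste0(.data$variant, "-", .data$source),
      endoscopy_source = ifelse(.data$source == "OHIP",
                                "ohip_any_indication", "sds_cd_coded"),
      contact_types = map(.data$with_hosp, function(h) {
        if (h) c("gi_outpatient_cd_visit", "cd_hospitalization")
        else "gi_outpatient_cd_visit"
      })
    ) |>
    select("algorithm_id", "endoscopy_source", "min_contacts",
           "contact_types", "window_years", "require_contacts_after_scope")
}

#' Look up one algorithm specification
#'
#' @param algorithm_id Id such as `"13-OHIP"` or `"1-SDS"`.
#' @param grid Algorithm grid (defaults to [build_algorithm_grid()]).
#' @return One-row tibble.
#' @export
algorithm_spec <- function(algorithm_id, grid = build_algorithm_grid()) {
  out <- grid |> filter(.data$algorithm_id == .env$algorithm_id)
  if (nrow(out) != 1)
    abort(sprintf("unknown algorithm id '%s'", algorithm_id),
          class = "claims_schema_error")
  out
}

#' Dated endoscopy events under a recording channel
#'
#' @param bundle A `claims_bundle`.
#' @param source `"ohip_any_indication"` (outpatient claim with an endoscopy
#'   fee code, any diagnostic code) or `"sds_cd_coded"` (procedure record
#'   with an endoscopy intervention code and a celiac diagnostic code).
#' @param config A [claims_config()].
#' @return Tibble `person_id`, `scope_date`, sorted.
#' @export
find_endoscopies <- function(bundle, source = c("ohip_any_indication",
                                                "sds_cd_coded"),
                             config = claims_config()) {
  source <- match.arg(source)
  if (source == "ohip_any_indication") {
    out <- bundle$claims |>
      filter(.data$fee_code %in% config$endoscopy_fee_codes) |>
      transmute(person_id = .data$person_id, scope_date = .data$service_date)
  } else {
    pr <- bundle$procedures
    keep <- map_lgl(pr$intervention_codes, function(ic)
      any(ic %in% config$endoscopy_intervention_codes)) &
      any_celiac(pr$diagnostic_codes, config)
    out <- pr[keep, ] |>
      transmute(person_id = .data$person_id,
                scope_date = .data$procedure_date)
  }
  out |> distinct() |> arrange(.data$person_id, .data$scope_date)
}

#' Qualifying celiac-coded contacts
#'
#' `gi_outpatient_cd_visit`: an outpatient claim with a celiac diagnostic
#' code billed by an adult or pediatric gastroenterologist (family-physician
#' and other-specialty claims are excluded). `cd_hospitalization`: a hospital
#' discharge record carrying a celiac code in any diagnosis position (dated
#' by admission). Duplicate claims (same person, physician, date, code) are
#' collapsed first; distinct claims on one day count separately.
#'
#' @param bundle A `claims_bundle`.
#' @param types Subset of `c("gi_outpatient_cd_visit", "cd_hospitalization")`.
#' @param config A [claims_config()].
#' @return Tibble `person_id`, `contact_date`, `type`.
#' @export
find_contacts <- function(bundle, types = "gi_outpatient_cd_visit",
                          config = claims_config()) {
  stopifnot(all(types %in% c("gi_outpatient_cd_visit", "cd_hospitalization")))
  out <- list()
  if ("gi_outpatient_cd_visit" %in% types) {
    cl <- bundle$claims |> filter(is_celiac(.data$diagnostic_code, config))
    if (nrow(cl)) {
      unknown <- setdiff(cl$physician_id, bundle$physicians$physician_id)
      if (length(unknown))
        stop_linkage("claims", NA,
                     sprintf("physician_id '%s' not in physicians",
                             unknown[1]))
    }
    out$gi <- cl |>
      inner_join(bundle$physicians, by = "physician_id") |>
      filter(.data$specialty %in% config$gi_specialties) |>
      distinct(.data$person_id, .data$physician_id, .data$service_date,
               .data$diagnostic_code) |>
      transmute(person_id = .data$person_id,
                contact_date = .data$service_date,
                type = "gi_outpatient_cd_visit")
  }
  if ("cd_hospitalization" %in% types) {
    ho <- bundle$hospitalizations
    out$hosp <- ho[any_celiac(ho$diagnostic_codes, config), ] |>
      transmute(person_id = .data$person_id,
                contact_date = .data$admission_date,
                type = "cd_hospitalization")
  }
  bind_rows(out) |> arrange(.data$person_id, .data$contact_date)
}

#' Apply one case-ascertainment algorithm to a bundle
#'
#' A person is flagged when some scope event anchors a qualifying pattern:
#' at least `min_contacts` qualifying contacts that (a) fall in the
#' scope-anchored half-open window `[scope, scope + window_years)` when a
#' window is set, (b) fall strictly after the scope when
#' `require_contacts_after_scope`, and (c) may fall anywhere in the study
#' window otherwise. The assigned index (diagnosis) date is the earliest
#' scope participating in a qualifying pattern, reflecting that biopsy
#' defines the diagnosis. All events are restricted to the study window
#' first.
#'
#' @param bundle A `claims_bundle`.
#' @param spec One-row tibble from [build_algorithm_grid()] or an id string.
#' @param config A [claims_config()].
#' @param study_window Length-2 `Date`; defaults to `config$study_window`.
#' @return Tibble of case records (`person_id`, `index_date`, `scope_date`,
#'   `n_qualifying_contacts`, `algorithm_id`) with class `"cd_cases"`; the
#'   flagged id set is `unique(result$person_id)`.
#' @export
apply_algorithm <- function(bundle, spec, config = claims_config(),
                            study_window = config$study_window) {
  if (is.character(spec)) spec <- algorithm_spec(spec)
  stopifnot(nrow(spec) == 1)
  scopes <- find_endoscopies(bundle, spec$endoscopy_source, config) |>
    filter(.data$scope_date >= study_window[1],
           .data$scope_date <= study_window[2])
  contacts <- find_contacts(bundle, spec$contact_types[[1]], config) |>
    filter(.data$contact_date >= study_window[1],
           .data$contact_date <= study_window[2])
  cases <- eval_patterns(scopes, contacts,
                         min_contacts = spec$min_contacts,
                         window_years = spec$window_years,
                         after_scope = spec$require_contacts_after_scope)
  cases$algorithm_id <- rep(spec$algorithm_id, nrow(cases))
  class(cases) <- c("cd_cases", class(cases))
  attr(cases, "algorithm_id") <- spec$algorithm_id
  cases
}

# scope-anchored pattern evaluation, one row per flagged person
eval_patterns <- function(scopes, contacts, min_contacts, window_years,
                          after_scope) {
  empty <- tibble(person_id = character(), index_date = as.Date(character()),
                  scope_date = as.Date(character()),
                  n_qualifying_contacts = integer())
  if (!nrow(scopes)) return(empty)
  cnt <- split(contacts$contact_date, contacts$person_id)
  per <- scopes |>
    group_by(.data$person_id) |>
    summarise(scope_dates = list(.data$scope_date), .groups = "drop")
  rows <- pmap(list(per$person_id, per$scope_dates), function(pid, sd) {
    cd <- cnt[[pid]]
    if (is.null(cd)) cd <- as.Date(character())
    for (s in sort(sd)) {
      s <- as.Date(s, origin = "1970-01-01")
      q <- if (!is.na(window_years)) {
        cd[cd >= s & cd < add_years(s, window_years)]
      } else if (after_scope) {
        cd[cd > s]
      } else {
        cd
      }
      if (length(q) >= min_contacts) {
        return(tibble(person_id = pid, index_date = s, scope_date = s,
                      n_qualifying_contacts = length(q)))
      }
    }
    NULL
  })
  out <- list_rbind(rows[!map_lgl(rows, is.null)])
  if (!nrow(out)) return(empty)
  arrange(out, .data$person_id)
}

# calendar-aware "+ k years" (Feb 29 rolls back to Feb 28)
add_years <- function(d, k) {
  out <- d %m+% lubridate::years(k)
  out
}

#' @importFrom lubridate %m+%
NULL

#' Overlap between two flagged-case sets
#'
#' Partition of the union of persons flagged by two algorithms, the
#' Venn-diagram comparison of the recording channels.
#'
#' @param result_a,result_b `cd_cases` tibbles from [apply_algorithm()] (or
#'   character vectors of person ids).
#' @return One-row tibble `only_a`, `both`, `only_b`.
#' @export
overlap <- function(result_a, result_b) {
  ids <- function(r) if (is.character(r)) unique(r) else unique(r$person_id)
  a <- ids(result_a); b <- ids(result_b)
  tibble(only_a = length(setdiff(a, b)),
         both = length(intersect(a, b)),
         only_b = length(setdiff(b, a)))
}
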