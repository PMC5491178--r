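# Shared builders: tiny hand-laid bundles, random event bundles, and an
# independent brute-force ascertainment oracle.

test_config <- claims_config()
W0 <- test_config$study_window[1]
W1 <- test_config$study_window[2]

# A bundle from per-person event offsets (days relative to a reference day
# well inside the study window). `ohip_scopes`, `sds_scopes_cd`,
# `sds_scopes_plain`, `gi_visits`, `fm_visits`, `hosps` are lists mapping
# person_id -> integer day offsets.
toy_bundle <- function(persons,
                       ohip_scopes = list(), sds_scopes_cd = list(),
                       sds_scopes_plain = list(), gi_visits = list(),
                       fm_visits = list(), hosps = list(),
                       labels_status = NULL, ref_day = W0 + 1200) {
  cfg <- test_config
  registry <- tibble::tibble(person_id = persons,
                             birth_date = as.Date("1999-03-01"),
                             sex = rep_len(c("female", "male"),
                                           length(persons)),
                             region_flag = TRUE)
  eligibility <- tibble::tibble(person_id = persons,
                                start_date = as.Date("1999-03-01"),
                                end_date = W1 + 366)
  physicians <- tibble::tibble(
    physician_id = c("GI1", "GI2", "FM1"),
    specialty = c("gastroenterology_pediatric", "gastroenterology_adult",
                  "family_medicine"))
  claim_rows <- function(ev, dx, fee, doc) {
    purrr::imap(ev, function(offs, pid) {
      tibble::tibble(person_id = pid, service_date = ref_day + offs,
                     physician_id = doc, diagnostic_code = dx,
                     fee_code = fee)
    }) |> purrr::list_rbind()
  }
  claims <- dplyr::bind_rows(
    claim_rows(ohip_scopes, "787", cfg$endoscopy_fee_codes[1], "GI1"),
    claim_rows(gi_visits, "5790", "A005", "GI1"),
    claim_rows(fm_visits, "5790", "A005", "FM1"))
  if (is.null(claims) || !nrow(claims))
    claims <- tibble::tibble(person_id = character(),
                             service_date = as.Date(character()),
                             physician_id = character(),
                             diagnostic_code = character(),
                             fee_code = character())
  proc_rows <- function(ev, dx) {
    purrr::imap(ev, function(offs, pid) {
      tibble::tibble(person_id = pid, procedure_date = ref_day + offs,
                     facility_id = "F1",
                     intervention_codes =
                       rep(list(cfg$endoscopy_intervention_codes[1]),
                           length(offs)),
                     diagnostic_codes = rep(list(dx), length(offs)))
    }) |> purrr::list_rbind()
  }
  procedures <- dplyr::bind_rows(proc_rows(sds_scopes_cd, c("5790", "787")),
                                 proc_rows(sds_scopes_plain, "787"))
  if (is.null(procedures) || !nrow(procedures))
    procedures <- tibble::tibble(person_id = character(),
                                 procedure_date = as.Date(character()),
                                 facility_id = character(),
                                 intervention_codes = list(),
                                 diagnostic_codes = list())
  hospitalizations <- purrr::imap(hosps, function(offs, pid) {
    tibble::tibble(person_id = pid, admission_date = ref_day + offs,
                   discharge_date = ref_day + offs + 2,
                   diagnostic_codes = rep(list("5790"), length(offs)))
  }) |> purrr::list_rbind()
  if (is.null(hospitalizations) || !nrow(hospitalizations))
    hospitalizations <- tibble::tibble(person_id = character(),
                                       admission_date = as.Date(character()),
                                       discharge_date = as.Date(character()),
                                       diagnostic_codes = list())
  labels <- NULL
  if (!is.null(labels_status)) {
    pos <- labels_status == "true_positive"
    labels <- tibble::tibble(
      person_id = persons, status = labels_status,
      diagnosis_date = as.Date(ifelse(pos, ref_day, NA),
                               origin = "1970-01-01"),
      marsh_class = ifelse(pos, "3b", "none"))
  }
  claims_bundle(registry, eligibility, claims, procedures, hospitalizations,
                physicians, labels, validate = FALSE)
}

# random small bundle for property tests
random_bundle <- function(seed, n = 30) {
  withr::local_seed(seed)
  persons <- sprintf("R%03d", seq_len(n))
  span <- as.integer(W1 - W0) - 10
  rand_days <- function(lambda) {
    out <- lapply(persons, function(p) sort(sample.int(span, rpois(1, lambda))))
    names(out) <- persons
    out[lengths(out) > 0]
  }
  toy_bundle(persons,
             ohip_scopes = rand_days(0.7),
             sds_scopes_cd = rand_days(0.4),
             sds_scopes_plain = rand_days(0.3),
             gi_visits = rand_days(1.1),
             fm_visits = rand_days(0.5),
             hosps = rand_days(0.25),
             ref_day = W0 + 5)
}

flagged_ids <- function(bundle, id_or_spec) {
  unique(apply_algorithm(bundle, id_or_spec, test_config)$person_id)
}

# Independent oracle: enumerate every (scope, contact-subset) combination
# and test the rule literally on each subset.
oracle_flagged <- function(bundle, spec, config = test_config) {
  if (is.character(spec)) spec <- algorithm_spec(spec)
  sc <- find_endoscopies(bundle, spec$endoscopy_source, config) |>
    dplyr::filter(scope_date >= config$study_window[1],
                  scope_date <= config$study_window[2])
  ct <- find_contacts(bundle, spec$contact_types[[1]], config) |>
    dplyr::filter(contact_date >= config$study_window[1],
                  contact_date <= config$study_window[2])
  m <- spec$min_contacts
  qualifies <- function(s, subset) {
    if (!is.na(spec$window_years)) {
      all(subset >= s) &&
        all(subset < s %m+% lubridate::years(spec$window_years))
    } else if (spec$require_contacts_after_scope) {
      all(subset > s)
    } else TRUE
  }
  flagged <- character()
  for (pid in unique(sc$person_id)) {
    scopes <- sc$scope_date[sc$person_id == pid]
    contacts <- ct$contact_date[ct$person_id == pid]
    if (length(contacts) < m) next
    hit <- FALSE
    for (s in scopes) {
      s <- as.Date(s, origin = "1970-01-01")
      idx <- utils::combn(seq_along(contacts), m)
      for (k in seq_len(ncol(idx))) {
        if (qualifies(s, contacts[idx[, k]])) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) flagged <- c(flagged, pid)
  }
  sort(flagged)
}

`%m+%` <- lubridate::`%m+%`
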