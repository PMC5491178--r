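#' Simulation parameters for the synthetic linked cohort
#'
#' Defaults describe a population the size of the validation region cohort
#' (235,320 children ever resident during the window) followed 2005–2011 as
#' an open cohort (children age in by birth and out at 15). The default
#' annual incidence of biopsy-proven celiac disease, 10 per 100,000
#' at-risk person-years, yields an expected reference-positive cohort of
#' roughly 110–115 children over the window. The two endoscopy recording channels
#' are modeled independently, which is the crux of the validation problem:
#' the outpatient fee claim is billed at procedure time with a single,
#' often non-specific diagnostic code, while the same-day-surgery record is
#' abstracted later by coders who may already know the biopsy result
#' (`p_sds_record_cd_coded`). `background_cd_code_noise` models non-cases
#' accruing celiac-coded visits (e.g. gluten sensitivity without biopsy
#' confirmation, which has no diagnostic code of its own).
#'
#' @param n_children Cohort size.
#' @param study_window Length-2 `Date`.
#' @param annual_incidence_per_100k True incidence rate of biopsy-proven
#'   disease per 100,000 person-years.
#' @param age_distribution Weights over integer ages 0–14 at window start.
#' @param sex_ratio Proportion male.
#' @param p_biopsy_if_cd Probability a true case undergoes endoscopy (a
#'   non-biopsied case is not biopsy-proven and labels as reference
#'   negative).
#' @param p_ohip_endoscopy_billed Probability the endoscopy generates an
#'   outpatient fee claim.
#' @param p_sds_record_cd_coded Probability the procedure record carries a
#'   celiac diagnostic code.
#' @param p_outpatient_cd_visit_post_dx Per-year probability of a
#'   celiac-coded gastroenterologist visit after diagnosis; the first
#'   post-diagnosis year's visit is placed inside the study window so this
#'   is exactly the per-case probability of at least one qualifying contact.
#' @param background_endoscopy_rate Non-celiac endoscopies per 100,000
#'   person-years (recorded in both channels, without celiac codes).
#' @param background_cd_code_noise Probability a non-case acquires a
#'   celiac-coded gastroenterologist visit during the window.
#' @param p_eligibility_gap Probability of a mid-window coverage gap.
#' @param seed Integer seed; every simulation is reproducible given the
#'   seed.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_children = 235320,
                       study_window = as.Date(c("2005-01-01", "2011-12-31")),
                       annual_incidence_per_100k = 10,
                       age_distribution = rep(1 / 15, 15),
                       sex_ratio = 0.51,
                       p_biopsy_if_cd = 1,
                       p_ohip_endoscopy_billed = 0.95,
                       p_sds_record_cd_coded = 0.85,
                       p_outpatient_cd_visit_post_dx = 0.9,
                       background_endoscopy_rate = 300,
                       background_cd_code_noise = 0.001,
                       p_eligibility_gap = 0.02,
                       seed = 20110629) {
  probs <- c(sex_ratio, p_biopsy_if_cd, p_ohip_endoscopy_billed,
             p_sds_record_cd_coded, p_outpatient_cd_visit_post_dx,
             background_cd_code_noise, p_eligibility_gap)
  if (any(probs < 0 | probs > 1))
    abort("probabilities must lie in [0, 1]", class = "claims_domain_error")
  if (n_children <= 0 || annual_incidence_per_100k < 0 ||
      background_endoscopy_rate < 0)
    abort("counts and rates must be non-negative (n_children > 0)",
          class = "claims_domain_error")
  if (length(age_distribution) != 15 || any(age_distribution < 0))
    abort("age_distribution needs 15 non-negative weights (ages 0-14)",
          class = "claims_domain_error")
  structure(
    list(n_children = as.integer(n_children), study_window = study_window,
         annual_incidence_per_100k = annual_incidence_per_100k,
         age_distribution = age_distribution / sum(age_distribution),
         sex_ratio = sex_ratio, p_biopsy_if_cd = p_biopsy_if_cd,
         p_ohip_endoscopy_billed = p_ohip_endoscopy_billed,
         p_sds_record_cd_coded = p_sds_record_cd_coded,
         p_outpatient_cd_visit_post_dx = p_outpatient_cd_visit_post_dx,
         background_endoscopy_rate = background_endoscopy_rate,
         background_cd_code_noise = background_cd_code_noise,
         p_eligibility_gap = p_eligibility_gap, seed = as.integer(seed)),
    class = "sim_params")
}

sim_physicians <- function(n_children) {
  n_gi <- max(4L, n_children %/% 20000L)
  n_fm <- max(4L, n_children %/% 5000L)
  bind_rows(
    tibble(physician_id = sprintf("GI%04d", seq_len(n_gi)),
           specialty = rep_len(c("gastroenterology_pediatric",
                                 "gastroenterology_adult"), n_gi)),
    tibble(physician_id = sprintf("PD%04d", seq_len(n_fm %/% 2 + 1)),
           specialty = "pediatrics"),
    tibble(physician_id = sprintf("FM%04d", seq_len(n_fm)),
           specialty = "family_medicine"))
}

#' Simulate a linked claims cohort with known ground truth
#'
#' Draws a pediatric population, assigns incident biopsy-proven celiac
#' disease at the configured rate, and emits the event sequence of each
#' case: screening visit, endoscopy (recorded independently in the
#' fee-claim and procedure-record channels), then post-diagnosis
#' gastroenterology visits. Non-cases accrue background endoscopies and,
#' rarely, celiac-coded visits. Identical parameters and seed give
#' identical output.
#'
#' @param params A [sim_params()] object.
#' @param config A [claims_config()] supplying the code sets to emit.
#' @return List with `bundle` (a labeled `claims_bundle`) and `truth`
#'   (tibble `person_id`, `is_cd`, `onset_date`).
#' @export
simulate_population <- function(params, config = claims_config()) {
  stopifnot(inherits(params, "sim_params"))
  withr::local_seed(params$seed)
  w0 <- params$study_window[1]
  w1 <- params$study_window[2]
  years <- as.numeric(w1 - w0 + 1) / 365.25
  n <- params$n_children

  celiac_code <- paste0(config$celiac_codes[1], "0")  # e.g. "5790"
  other_code <- "787"
  fee_endo <- config$endoscopy_fee_codes[1]
  fee_visit <- "A005"
  interv_endo <- config$endoscopy_intervention_codes[1]

  physicians <- sim_physicians(n)
  gi_ids <- physicians$physician_id[startsWith(physicians$physician_id, "GI")]
  fm_ids <- physicians$physician_id[startsWith(physicians$physician_id, "FM")]

  # open cohort: ages 0-14 at window start follow age_distribution, plus
  # birth cohorts during the window (so every age stratum is populated in
  # every study year); a negative "age at start" means born mid-window
  n_birth_years <- ceiling(years)
  ext_w <- c(rep(mean(params$age_distribution), n_birth_years),
             params$age_distribution)
  age0 <- sample(seq(-n_birth_years, 14), n, replace = TRUE,
                 prob = ext_w / sum(ext_w)) + runif(n)
  registry <- tibble(
    person_id = sprintf("P%07d", seq_len(n)),
    birth_date = w0 - round(age0 * 365.25),
    sex = ifelse(runif(n) < params$sex_ratio, "male", "female"),
    region_flag = TRUE)

  # coverage: birth to past window end, occasionally with a mid-window gap
  gap <- runif(n) < params$p_eligibility_gap &
    registry$birth_date < w0 + 30
  gap_start <- w0 + round(runif(n, 60, as.numeric(w1 - w0) - 240))
  gap_len <- round(runif(n, 30, 180))
  eligibility <- bind_rows(
    tibble(person_id = registry$person_id[!gap],
           start_date = registry$birth_date[!gap],
           end_date = w1 + 366),
    tibble(person_id = registry$person_id[gap],
           start_date = registry$birth_date[gap],
           end_date = gap_start[gap]),
    tibble(person_id = registry$person_id[gap],
           start_date = gap_start[gap] + gap_len[gap],
           end_date = w1 + 366)) |>
    arrange(.data$person_id, .data$start_date)

  # ground truth: incident biopsy-proven disease while aged 6 months - 14 y;
  # each child's case risk is the rate times their at-risk person-time
  t_lo <- pmax(0, 0.5 - age0)
  t_hi <- pmin(years, 15 - age0 - 1 / 365.25)
  at_risk <- pmax(0, t_hi - t_lo)
  p_case <- pmin(1, params$annual_incidence_per_100k * at_risk / 1e5)
  is_cd <- runif(n) < p_case
  onset_t <- t_lo + runif(n) * at_risk
  onset <- pmin(w1, w0 + round(onset_t * 365.25))
  truth <- tibble(person_id = registry$person_id, is_cd = is_cd,
                  onset_date = as.Date(ifelse(is_cd, onset, NA),
                                       origin = "1970-01-01"))

  cases <- which(is_cd)
  biopsied <- cases[runif(length(cases)) < params$p_biopsy_if_cd]

  claims <- list()
  procedures <- list()

  if (length(biopsied)) {
    pid <- registry$person_id[biopsied]
    dx_date <- onset[biopsied]
    # pre-diagnosis screening visit at the family physician
    claims$screen <- tibble(
      person_id = pid,
      service_date = pmax(w0, dx_date - 30),
      physician_id = sample(fm_ids, length(pid), replace = TRUE),
      diagnostic_code = other_code, fee_code = fee_visit)
    # endoscopy: fee claim billed before histology, often without a
    # celiac code; procedure record abstracted later, often with one
    billed <- runif(length(pid)) < params$p_ohip_endoscopy_billed
    claims$scope <- tibble(
      person_id = pid[billed], service_date = dx_date[billed],
      physician_id = sample(gi_ids, sum(billed), replace = TRUE),
      diagnostic_code = other_code, fee_code = fee_endo)
    coded <- runif(length(pid)) < params$p_sds_record_cd_coded
    procedures$scope <- tibble(
      person_id = pid, procedure_date = dx_date,
      facility_id = "FAC001",
      intervention_codes = rep(list(interv_endo), length(pid)),
      diagnostic_codes = map(coded, function(cc)
        if (cc) c(celiac_code, other_code) else other_code))
    # post-diagnosis gastroenterology follow-up, celiac-coded; the first
    # year's visit is kept inside the study window
    p_fu <- params$p_outpatient_cd_visit_post_dx
    first <- runif(length(pid)) < p_fu
    max_off <- pmax(14, pmin(350, as.numeric(w1 - dx_date)))
    claims$fu1 <- tibble(
      person_id = pid[first],
      service_date = pmin(w1, dx_date[first] +
        round(14 + runif(sum(first)) * (max_off[first] - 14))),
      physician_id = sample(gi_ids, sum(first), replace = TRUE),
      diagnostic_code = celiac_code, fee_code = fee_visit)
    extra_years <- pmax(0, floor(as.numeric(w1 - dx_date) / 365.25) - 1)
    fu_more <- tibble(person_id = pid, dx = dx_date, k = extra_years) |>
      filter(.data$k > 0) |>
      mutate(yr = map(.data$k, seq_len)) |>
      tidyr::unnest_longer("yr") |>
      filter(runif(dplyr::n()) < p_fu) |>
      mutate(service_date = pmin(
        w1, .data$dx + .data$yr * 365 + round(runif(dplyr::n(), 14, 350))))
    if (nrow(fu_more)) {
      claims$fu_more <- fu_more |>
        transmute(.data$person_id, .data$service_date,
                  physician_id = sample(gi_ids, dplyr::n(), replace = TRUE),
                  diagnostic_code = celiac_code, fee_code = fee_visit)
    }
  }

  # background (non-celiac) endoscopies, recorded in both channels
  n_bg <- rpois(n, params$background_endoscopy_rate * years / 1e5)
  bg_idx <- rep(seq_len(n), n_bg)
  if (length(bg_idx)) {
    bg_date <- w0 + round(runif(length(bg_idx)) * as.numeric(w1 - w0))
    claims$bg_scope <- tibble(
      person_id = registry$person_id[bg_idx], service_date = bg_date,
      physician_id = sample(gi_ids, length(bg_idx), replace = TRUE),
      diagnostic_code = other_code, fee_code = fee_endo)
    procedures$bg <- tibble(
      person_id = registry$person_id[bg_idx], procedure_date = bg_date,
      facility_id = "FAC001",
      intervention_codes = rep(list(interv_endo), length(bg_idx)),
      diagnostic_codes = rep(list(other_code), length(bg_idx)))
  }

  # celiac-code noise on non-cases (no biopsy confirmation behind the code)
  noise <- which(!is_cd & runif(n) < params$background_cd_code_noise)
  if (length(noise)) {
    claims$noise <- tibble(
      person_id = registry$person_id[noise],
      service_date = w0 + round(runif(length(noise)) * as.numeric(w1 - w0)),
      physician_id = sample(gi_ids, length(noise), replace = TRUE),
      diagnostic_code = celiac_code, fee_code = fee_visit)
  }

  claims <- bind_rows(claims)
  if (!nrow(claims)) {
    claims <- tibble(person_id = character(),
                     service_date = as.Date(character()),
                     physician_id = character(),
                     diagnostic_code = character(), fee_code = character())
  }
  procedures <- bind_rows(procedures)
  if (!nrow(procedures)) {
    procedures <- tibble(person_id = character(),
                         procedure_date = as.Date(character()),
                         facility_id = character(),
                         intervention_codes = list(),
                         diagnostic_codes = list())
  }
  hospitalizations <- tibble(person_id = character(),
                             admission_date = as.Date(character()),
                             discharge_date = as.Date(character()),
                             diagnostic_codes = list())

  pos <- registry$person_id %in% registry$person_id[biopsied]
  labels <- tibble(
    person_id = registry$person_id,
    status = ifelse(pos, "true_positive", "true_negative"),
    diagnosis_date = as.Date(ifelse(pos, onset, NA), origin = "1970-01-01"),
    marsh_class = ifelse(
      pos, sample(c("3a", "3b", "3c"), n, replace = TRUE,
                  prob = c(0.157, 0.704, 0.139)), "none"))

  bundle <- claims_bundle(registry, eligibility, claims, procedures,
                          hospitalizations, physicians, labels,
                          validate = FALSE)
  list(bundle = bundle, truth = truth)
}

#' Construct a bundle realizing a requested confusion table
#'
#' Places qualifying and non-qualifying event patterns so that applying
#' `spec` to the emitted bundle reproduces the requested 2x2 table exactly
#' against the emitted labels. True positives counted as detected (`tp`)
#' and false positives receive a scope plus the required contacts after it;
#' missed true positives (`fn`) receive a scope with insufficient or
#' wrongly-ordered contacts; true negatives (`tn`) have no events. Used to
#' rebuild published validation tables from their printed statistics, which
#' uniquely determine the four cells.
#'
#' @param tp,fp,fn,tn Non-negative cell counts.
#' @param spec Algorithm specification row or id string.
#' @param config A [claims_config()].
#' @param seed Seed (kept for interface symmetry; construction is
#'   deterministic).
#' @return List with `bundle` and `truth` as in [simulate_population()].
#' @examples
#' fx <- build_validation_fixture(2, 1, 1, 10, "13-OHIP")
#' confusion_table(apply_algorithm(fx$bundle, "13-OHIP"), fx$bundle$labels)
#' @export
build_validation_fixture <- function(tp, fp, fn, tn, spec,
                                     config = claims_config(), seed = 1) {
  if (any(c(tp, fp, fn, tn) < 0))
    abort("cell counts must be non-negative", class = "claims_domain_error")
  if (is.character(spec)) spec <- algorithm_spec(spec)
  n <- tp + fp + fn + tn
  if (n == 0) abort("empty table", class = "claims_domain_error")
  w0 <- config$study_window[1]
  ids <- sprintf("V%07d", seq_len(n))
  role <- rep(c("tp", "fn", "fp", "tn"), times = c(tp, fn, fp, tn))
  registry <- tibble(person_id = ids,
                     birth_date = as.Date("1998-07-01"),
                     sex = rep_len(c("female", "male"), n),
                     region_flag = TRUE)
  eligibility <- tibble(person_id = ids,
                        start_date = as.Date("1998-07-01"),
                        end_date = config$study_window[2] + 366)
  physicians <- tibble(physician_id = c("GI0001", "FM0001"),
                       specialty = c("gastroenterology_pediatric",
                                     "family_medicine"))
  celiac_code <- paste0(config$celiac_codes[1], "0")
  scope_date <- w0 + 1200
  mk_contacts <- function(pid, dates) {
    tibble(person_id = rep(pid, each = length(dates)),
           service_date = rep(dates, length(pid)),
           physician_id = "GI0001",
           diagnostic_code = celiac_code, fee_code = "A005")
  }
  mk_scope_claims <- function(pid) {
    tibble(person_id = pid, service_date = scope_date,
           physician_id = "GI0001", diagnostic_code = "787",
           fee_code = config$endoscopy_fee_codes[1])
  }
  mk_scope_procs <- function(pid) {
    tibble(person_id = pid, procedure_date = scope_date,
           facility_id = "FAC001",
           intervention_codes = rep(list(config$endoscopy_intervention_codes[1]),
                                    length(pid)),
           diagnostic_codes = rep(list(celiac_code), length(pid)))
  }

  with_pattern <- ids[role %in% c("tp", "fp")]
  missed <- ids[role == "fn"]
  q_dates <- scope_date + 30 * seq_len(spec$min_contacts)

  claims <- list()
  procedures <- list()
  if (spec$endoscopy_source == "ohip_any_indication") {
    claims$scopes <- mk_scope_claims(c(with_pattern, missed))
  } else {
    procedures$scopes <- mk_scope_procs(c(with_pattern, missed))
  }
  if (length(with_pattern))
    claims$qualify <- mk_contacts(with_pattern, q_dates)
  if (length(missed)) {
    if (isTRUE(spec$require_contacts_after_scope)) {
      claims$near_miss <- mk_contacts(missed, scope_date - 30)
    } else if (spec$min_contacts > 1) {
      claims$near_miss <- mk_contacts(missed,
                                      q_dates[seq_len(spec$min_contacts - 1)])
    }
  }
  claims <- bind_rows(claims)
  if (is.null(claims) || !nrow(claims)) {
    claims <- tibble(person_id = character(),
                     service_date = as.Date(character()),
                     physician_id = character(),
                     diagnostic_code = character(), fee_code = character())
  }
  procedures <- bind_rows(procedures)
  if (is.null(procedures) || !nrow(procedures)) {
    procedures <- tibble(person_id = character(),
                         procedure_date = as.Date(character()),
                         facility_id = character(),
                         intervention_codes = list(),
                         diagnostic_codes = list())
  }
  hospitalizations <- tibble(person_id = character(),
                             admission_date = as.Date(character()),
                             discharge_date = as.Date(character()),
                             diagnostic_codes = list())
  pos <- role %in% c("tp", "fn")
  labels <- tibble(
    person_id = ids,
    status = ifelse(pos, "true_positive", "true_negative"),
    diagnosis_date = as.Date(ifelse(pos, scope_date, NA),
                             origin = "1970-01-01"),
    marsh_class = ifelse(pos, "3b", "none"))
  truth <- tibble(person_id = ids, is_cd = pos,
                  onset_date = labels$diagnosis_date)
  bundle <- claims_bundle(registry, eligibility, claims, procedures,
                          hospitalizations, physicians, labels,
                          validate = FALSE)
  list(bundle = bundle, truth = truth)
}
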