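#' Analysis configuration: code sets, specialties and study window
#'
#' Central configuration consumed by the ascertainment and validation
#' functions. The celiac diagnostic code set defaults to the ICD-9 family
#' rooted at `"579"`; outpatient claims carry 3-character codes while chart
#' abstractions cite `579.0`, so codes are matched by prefix by default
#' (`"579"` matches `"579"`, `"579.0"` and `"5790"`). The endoscopy fee-code
#' and intervention-code sets are synthetic placeholders standing in for the
#' jurisdiction-specific schedules; replace them with the local code lists
#' when working with real extracts.
#'
#' @param celiac_codes Character vector of celiac diagnostic codes (prefixes
#'   under the default match rule).
#' @param endoscopy_fee_codes Fee-schedule codes identifying an endoscopy
#'   billing claim in the outpatient claims table.
#' @param endoscopy_intervention_codes Intervention codes identifying an
#'   endoscopy in the same-day-surgery procedure table.
#' @param gi_specialties Physician specialties whose celiac-coded outpatient
#'   visits count as gastroenterology contacts.
#' @param code_match `"prefix"` (default) or `"exact"`.
#' @param study_window Length-2 `Date` vector, inclusive study window.
#' @param alpha Two-sided confidence level complement for all intervals.
#'
#' @return A list of class `"claims_config"`.
#' @examples
#' cfg <- claims_config()
#' cfg$celiac_codes
#' @export
claims_config <- function(celiac_codes = "579",
                          endoscopy_fee_codes = c("Z399", "Z499"),
                          endoscopy_intervention_codes = c("2OD70", "2NK70"),
                          gi_specialties = c("gastroenterology_adult",
                                             "gastroenterology_pediatric"),
                          code_match = c("prefix", "exact"),
                          study_window = as.Date(c("2005-01-01", "2011-12-31")),
                          alpha = 0.05) {
  code_match <- match.arg(code_match)
  stopifnot(length(study_window) == 2, inherits(study_window, "Date"),
            study_window[1] <= study_window[2],
            alpha > 0, alpha < 1)
  structure(
    list(
      celiac_codes = as.character(celiac_codes),
      endoscopy_fee_codes = as.character(endoscopy_fee_codes),
      endoscopy_intervention_codes = as.character(endoscopy_intervention_codes),
      gi_specialties = as.character(gi_specialties),
      code_match = code_match,
      study_window = study_window,
      alpha = alpha
    ),
    class = "claims_config"
  )
}

#' Match diagnostic codes against a configured code set
#'
#' @param codes Character vector of observed codes.
#' @param code_set Character vector of configured codes (prefixes under the
#'   prefix rule).
#' @param rule `"prefix"` or `"exact"`.
#' @return Logical vector, one element per observed code.
#' @examples
#' matches_code(c("579", "579.0", "5790", "009"), "579")
#' @export
matches_code <- function(codes, code_set, rule = c("prefix", "exact")) {
  rule <- match.arg(rule)
  if (length(codes) == 0) return(logical(0))
  if (rule == "exact") return(codes %in% code_set)
  out <- rep(FALSE, length(codes))
  for (p in code_set) out <- out | startsWith(codes, p)
  out
}

is_celiac <- function(codes, config) {
  matches_code(codes, config$celiac_codes, config$code_match)
}

# any() over a ";"-joinable character vector of codes
any_celiac <- function(code_list, config) {
  map_lgl(code_list, function(cc) any(is_celiac(cc, config)))
}
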