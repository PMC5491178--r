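#' Confusion table of a flagged-case set against the reference standard
#'
#' @param result A `cd_cases` tibble from [apply_algorithm()], or a character
#'   vector of flagged person ids.
#' @param labels Reference-standard label tibble (`person_id`, `status`).
#'   Every flagged id must be labeled.
#' @return One-row tibble `tp`, `fp`, `fn`, `tn` with class `"cd_confusion"`;
#'   the four cells always sum to `nrow(labels)`.
#' @export
confusion_table <- function(result, labels) {
  flagged <- if (is.character(result)) unique(result)
             else unique(result$person_id)
  missing <- setdiff(flagged, labels$person_id)
  if (length(missing))
    abort(sprintf("flagged person '%s' has no reference label", missing[1]),
          class = "claims_linkage_error")
  pos <- labels$person_id[labels$status == "true_positive"]
  neg <- labels$person_id[labels$status == "true_negative"]
  out <- tibble(
    tp = length(intersect(flagged, pos)),
    fp = length(intersect(flagged, neg)),
    fn = length(setdiff(pos, flagged)),
    tn = length(setdiff(neg, flagged))
  )
  class(out) <- c("cd_confusion", class(out))
  if (!is.null(attr(result, "algorithm_id")))
    attr(out, "algorithm_id") <- attr(result, "algorithm_id")
  out
}

#' Score confidence interval for a proportion, corrected for continuity
#'
#' The efficient-score (Wilson) binomial interval with Newcombe's continuity
#' correction. With `p = x/n` and `z` the two-sided normal quantile
#' (`z = 1.96` for 95%, used exactly — the difference from the full-precision
#' quantile is below the 2-decimal reporting precision):
#' \deqn{L = \frac{2np + z^2 - 1 - z\sqrt{z^2 - 2 - 1/n + 4p(n(1-p)+1)}}{2(n+z^2)}}
#' \deqn{U = \frac{2np + z^2 + 1 + z\sqrt{z^2 + 2 - 1/n + 4p(n(1-p)-1)}}{2(n+z^2)}}
#' clamped to `[0, 1]`, with `L = 0` when `x = 0` and `U = 1` when `x = n`.
#'
#' @param x Successes (vectorised).
#' @param n Trials.
#' @param alpha Two-sided level complement (default 0.05).
#' @param z Normal quantile; default 1.96 at `alpha = 0.05`, otherwise the
#'   exact quantile.
#' @return Tibble with `numerator`, `denominator`, `estimate`, `conf.low`,
#'   `conf.high` (all proportions), `alpha`, `method = "score_cc"`.
#' @examples
#' score_ci_cc(81, 115)  # 0.7043 (0.6109, 0.7839)
#' @export
score_ci_cc <- function(x, n, alpha = 0.05,
                        z = if (alpha == 0.05) 1.96 else
                          stats::qnorm(1 - alpha / 2)) {
  if (any(n <= 0)) abort("n must be positive", class = "claims_domain_error")
  if (any(x < 0 | x > n)) abort("x must lie in [0, n]",
                                class = "claims_domain_error")
  p <- x / n
  lo <- (2 * n * p + z^2 - 1 -
           z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
    (2 * (n + z^2))
  hi <- (2 * n * p + z^2 + 1 +
           z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
    (2 * (n + z^2))
  lo <- ifelse(x == 0, 0, pmax(0, lo))
  hi <- ifelse(x == n, 1, pmin(1, hi))
  tibble(numerator = x, denominator = n, estimate = p,
         conf.low = lo, conf.high = hi, alpha = alpha, method = "score_cc")
}

#' Operating characteristics of a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive and negative
#' predictive values `tp/(tp+fp)` and `tn/(tn+fn)`, each with the
#' continuity-corrected score interval. Predictive values are taken directly
#' from the validation cohort (no prevalence adjustment): the negative
#' reference is the whole source population, so cohort prevalence is the
#' population prevalence. A measure with a zero denominator is returned as
#' `NA` (not applicable), never as zero.
#'
#' @param ct A `cd_confusion` row (or anything with `tp`,`fp`,`fn`,`tn`).
#' @param alpha Interval level complement.
#' @return Tibble with one row per measure (`sensitivity`, `specificity`,
#'   `ppv`, `npv`), class `"cd_accuracy"`, carrying `algorithm_id` when the
#'   confusion table knows it.
#' @examples
#' operating_characteristics(tibble::tibble(tp = 81, fp = 71, fn = 34, tn = 235249))
#' @export
operating_characteristics <- function(ct, alpha = 0.05) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(ct)))
  if (ct$tp + ct$fn == 0 || ct$fp + ct$tn == 0)
    abort("reference standard must contain positives and negatives",
          class = "claims_domain_error")
  one <- function(measure, x, n) {
    if (n == 0) {
      return(tibble(measure = measure, numerator = NA_integer_,
                    denominator = 0L, estimate = NA_real_,
                    conf.low = NA_real_, conf.high = NA_real_,
                    alpha = alpha, method = "score_cc"))
    }
    mutate(score_ci_cc(x, n, alpha), measure = measure, .before = 1)
  }
  out <- bind_rows(
    one("sensitivity", ct$tp, ct$tp + ct$fn),
    one("specificity", ct$tn, ct$fp + ct$tn),
    one("ppv", ct$tp, ct$tp + ct$fp),
    one("npv", ct$tn, ct$tn + ct$fn)
  )
  aid <- attr(ct, "algorithm_id")
  if (!is.null(aid)) out <- mutate(out, algorithm_id = aid)
  class(out) <- c("cd_accuracy", class(out))
  out
}

#' Validate the algorithm grid, optionally within age subgroups
#'
#' Re-runs every algorithm and recomputes operating characteristics with the
#' reference standard restricted to children below each age cutoff. True
#' positives are restricted by age at diagnosis; true negatives carry no
#' diagnosis date, so their age is taken at the study-window midpoint (a
#' documented convention, configurable via `negative_age_on`). A cutoff of
#' `Inf` reproduces the full-cohort validation.
#'
#' @param bundle A labeled `claims_bundle`.
#' @param grid Algorithm grid tibble (default all 26).
#' @param age_cutoffs Numeric vector of exclusive upper age bounds in years;
#'   use `Inf` for the unrestricted cohort.
#' @param config A [claims_config()].
#' @param negative_age_on Date at which negatives' ages are measured;
#'   defaults to the study-window midpoint.
#' @param labels Label tibble; defaults to `bundle$labels`.
#' @return Tibble of operating characteristics with `algorithm_id` and
#'   `age_cutoff` columns; measures that are not estimable in a subgroup
#'   (empty denominator) are `NA`.
#' @export
subgroup_validation <- function(bundle, grid = build_algorithm_grid(),
                                age_cutoffs = Inf,
                                config = claims_config(),
                                negative_age_on = NULL,
                                labels = bundle$labels) {
  if (is.null(labels))
    abort("bundle carries no labels", class = "claims_schema_error")
  if (any(age_cutoffs <= 0))
    abort("age cutoffs must be positive", class = "claims_domain_error")
  negative_age_on <- negative_age_on %||%
    (config$study_window[1] +
       as.numeric(config$study_window[2] - config$study_window[1]) %/% 2)
  # negatives may be born after the reference date; age then < 0, below any cutoff
  age_of <- function(birth, on) {
    floor(lubridate::time_length(lubridate::interval(birth, on), "years"))
  }
  lab <- labels |>
    left_join(bundle$registry[c("person_id", "birth_date")], by = "person_id") |>
    mutate(age_ref = ifelse(.data$status == "true_positive",
                            age_of(.data$birth_date,
                                   dplyr::coalesce(.data$diagnosis_date,
                                                   negative_age_on)),
                            age_of(.data$birth_date, negative_age_on)))
  results <- map(seq_len(nrow(grid)),
                 function(i) apply_algorithm(bundle, grid[i, ], config))
  out <- map(age_cutoffs, function(cut) {
    sub <- lab |> filter(is.infinite(cut) | .data$age_ref < cut)
    map(results, function(res) {
      keep <- res[res$person_id %in% sub$person_id, ]
      attr(keep, "algorithm_id") <- attr(res, "algorithm_id")
      if (sum(sub$status == "true_positive") == 0 ||
          sum(sub$status == "true_negative") == 0) {
        return(tibble(measure = c("sensitivity", "specificity", "ppv", "npv"),
                      numerator = NA_integer_, denominator = NA_integer_,
                      estimate = NA_real_, conf.low = NA_real_,
                      conf.high = NA_real_, alpha = config$alpha,
                      method = "score_cc",
                      algorithm_id = attr(res, "algorithm_id"),
                      age_cutoff = cut))
      }
      operating_characteristics(confusion_table(keep, sub), config$alpha) |>
        mutate(age_cutoff = cut)
    }) |> list_rbind()
  }) |> list_rbind()
  class(out) <- c("cd_accuracy", class(out))
  out
}

#' Weighted kappa for two ordinal raters
#'
#' Chance-corrected agreement \eqn{\kappa_w = 1 - \sum w_{ij} o_{ij} / \sum
#' w_{ij} e_{ij}} with disagreement weights over the declared category order
#' (`linear`: \eqn{|i-j|}; `quadratic`, the default for ordinal histology
#' grades: \eqn{(i-j)^2}), observed cell proportions \eqn{o_{ij}} and
#' chance-expected proportions \eqn{e_{ij}} from the product of the two
#' raters' marginals.
#'
#' @param pairs Tibble with columns `rating_a` and `rating_b` (one row per
#'   doubly-rated item), e.g. duplicate Marsh gradings of biopsy reports.
#' @param categories Ordered character vector of all categories, e.g.
#'   `c("none", "3a", "3b", "3c")`.
#' @param weighting `"quadratic"` (default) or `"linear"`.
#' @return One-row tibble `kappa`, `weighting`, `n_items`; `kappa` is `NA`
#'   when both raters use a single identical category (no variance, chance
#'   agreement undefined).
#' @examples
#' pairs <- tibble::tibble(rating_a = c("3a", "3b", "3b"),
#'                         rating_b = c("3a", "3b", "3c"))
#' weighted_kappa(pairs, categories = c("none", "3a", "3b", "3c"))
#' @export
weighted_kappa <- function(pairs, categories,
                           weighting = c("quadratic", "linear")) {
  weighting <- match.arg(weighting)
  stopifnot(nrow(pairs) >= 2)
  a <- factor(pairs$rating_a, levels = categories)
  b <- factor(pairs$rating_b, levels = categories)
  if (anyNA(a) || anyNA(b))
    abort("ratings outside the declared category set",
          class = "claims_domain_error")
  k <- length(categories)
  o <- table(a, b) / nrow(pairs)
  e <- outer(rowSums(o), colSums(o))
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- if (weighting == "quadratic") d^2 else d
  denom <- sum(w * e)
  kap <- if (denom == 0) NA_real_ else 1 - sum(w * o) / denom
  tibble(kappa = kap, weighting = weighting, n_items = nrow(pairs))
}
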