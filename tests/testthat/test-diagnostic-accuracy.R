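test_that("confusion table partitions the labeled cohort", {
  lab <- tibble::tibble(
    person_id = sprintf("p%d", 1:10),
    status = rep(c("true_positive", "true_negative"), each = 5))
  expect_equal(confusion_table(character(0), lab),
               tibble::tibble(tp = 0L, fp = 0L, fn = 5L, tn = 5L),
               ignore_attr = TRUE)
  expect_equal(confusion_table(sprintf("p%d", 1:5), lab),
               tibble::tibble(tp = 5L, fp = 0L, fn = 0L, tn = 5L),
               ignore_attr = TRUE)
  ct <- confusion_table(c("p1", "p6"), lab)
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 4L, tn = 4L))
  expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, nrow(lab))
  expect_error(confusion_table("stranger", lab), "stranger",
               class = "claims_linkage_error")
})

test_that("continuity-corrected score interval reproduces published bounds", {
  # printed as estimate (lower-upper) percentages, 2 dp
  cases <- list(
    list(x = 81, n = 115, est = 70.43, lo = 61.09, hi = 78.39),
    list(x = 81, n = 152, est = 53.29, lo = 45.05, hi = 61.36),
    list(x = 82, n = 115, est = 71.30, lo = 62.00, hi = 79.16),
    list(x = 82, n = 89,  est = 92.13, lo = 83.95, hi = 96.51))
  for (cs in cases) {
    ci <- score_ci_cc(cs$x, cs$n)
    expect_equal(round_half_up(ci$estimate * 100, 2), cs$est)
    expect_equal(round_half_up(ci$conf.low * 100, 2), cs$lo)
    expect_equal(round_half_up(ci$conf.high * 100, 2), cs$hi)
  }
  # boundary rules
  expect_equal(score_ci_cc(0, 10)$conf.low, 0)
  expect_equal(score_ci_cc(10, 10)$conf.high, 1)
  expect_error(score_ci_cc(1, 0), class = "claims_domain_error")
})

test_that("score interval contains the estimate, shrinks with n, and contains the uncorrected interval", {
  wilson <- function(x, n, z = 1.96) {
    p <- x / n
    c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n),
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n))
  }
  withr::local_seed(42)
  for (i in 1:200) {
    n <- sample(1:500, 1)
    x <- sample(0:n, 1)
    ci <- score_ci_cc(x, n)
    expect_true(ci$conf.low <= ci$estimate && ci$estimate <= ci$conf.high)
    w <- wilson(x, n)
    expect_lte(ci$conf.low, w[1] + 1e-12)
    expect_gte(ci$conf.high, w[2] - 1e-12)
  }
  for (p in c(0.1, 0.5, 0.9)) {
    widths <- vapply(c(20, 200, 2000), function(n) {
      ci <- score_ci_cc(round(p * n), n)
      ci$conf.high - ci$conf.low
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
  }
})

test_that("operating characteristics reproduce the published validation rows", {
  ohip13 <- operating_characteristics(
    tibble::tibble(tp = 81, fp = 71, fn = 34, tn = 235249))
  got <- setNames(round_half_up(ohip13$estimate * 100, 2), ohip13$measure)
  expect_equal(got, c(sensitivity = 70.43, specificity = 99.97,
                      ppv = 53.29, npv = 99.99))
  sds1 <- operating_characteristics(
    tibble::tibble(tp = 82, fp = 7, fn = 33, tn = 235313))
  got <- setNames(round_half_up(sds1$estimate * 100, 2), sds1$measure)
  expect_equal(got[c("sensitivity", "ppv")],
               c(sensitivity = 71.30, ppv = 92.13))
  # denominators follow the table margins
  expect_equal(ohip13$denominator,
               c(81 + 34, 71 + 235249, 81 + 71, 235249 + 34))
  # perfect classifier
  perf <- operating_characteristics(
    tibble::tibble(tp = 10, fp = 0, fn = 0, tn = 90))
  expect_equal(perf$estimate, rep(1, 4))
  # nothing flagged: PPV is not applicable, not zero
  none <- operating_characteristics(
    tibble::tibble(tp = 0, fp = 0, fn = 5, tn = 95))
  expect_true(is.na(none$estimate[none$measure == "ppv"]))
  expect_equal(none$estimate[none$measure == "sensitivity"], 0)
})

test_that("age-restricted validation reduces to the full cohort at a non-binding cutoff", {
  fx <- build_validation_fixture(6, 3, 2, 40, "13-OHIP", test_config)
  grid <- algorithm_spec("13-OHIP")
  full <- subgroup_validation(fx$bundle, grid, age_cutoffs = Inf,
                              config = test_config)
  direct <- operating_characteristics(
    confusion_table(apply_algorithm(fx$bundle, "13-OHIP", test_config),
                    fx$bundle$labels))
  expect_equal(full$estimate, direct$estimate)
  # the fixture's children are all ~10 at diagnosis: a cutoff of 5 empties
  # the positive stratum
  sub <- subgroup_validation(fx$bundle, grid, age_cutoffs = 5,
                             config = test_config)
  expect_true(all(is.na(sub$estimate)))
  # age-homogeneous detection: estimates agree across non-binding cutoffs
  sub2 <- subgroup_validation(fx$bundle, grid, age_cutoffs = c(12, 15),
                              config = test_config)
  expect_equal(sub2$estimate[sub2$age_cutoff == 12],
               sub2$estimate[sub2$age_cutoff == 15])
  expect_error(subgroup_validation(fx$bundle, grid, age_cutoffs = -1,
                                   config = test_config),
               class = "claims_domain_error")
})

test_that("weighted kappa matches a hand-worked table and its invariances", {
  # 5 items over ordered categories a<b<c:
  # pairs (a,a),(a,b),(b,b),(c,c),(c,a); linear weights w=|i-j|
  # sum w*o = 1*(1/5) + 2*(1/5) = 0.6
  # marginals: A = (.4,.2,.4), B = (.4,.4,.2)
  # sum w*e = .16+.16+.08+.04+.32+.16 = 0.92  =>  kappa = 1 - 0.6/0.92 = 8/23
  pairs <- tibble::tibble(rating_a = c("a", "a", "b", "c", "c"),
                          rating_b = c("a", "b", "b", "c", "a"))
  k <- weighted_kappa(pairs, categories = c("a", "b", "c"),
                      weighting = "linear")
  expect_equal(k$kappa, 8 / 23, tolerance = 1e-12)
  # perfect agreement over >= 2 categories
  perf <- tibble::tibble(rating_a = c("a", "b", "c"),
                         rating_b = c("a", "b", "c"))
  expect_equal(weighted_kappa(perf, c("a", "b", "c"))$kappa, 1)
  # invariant under order-preserving relabeling
  relab <- c(a = "none", b = "3a", c = "3b")
  k2 <- weighted_kappa(
    tibble::tibble(rating_a = relab[pairs$rating_a],
                   rating_b = relab[pairs$rating_b]),
    categories = c("none", "3a", "3b"), weighting = "linear")
  expect_equal(k2$kappa, k$kappa)
  # degenerate: a single shared category has no chance correction
  flat <- tibble::tibble(rating_a = c("a", "a"), rating_b = c("a", "a"))
  expect_true(is.na(weighted_kappa(flat, c("a", "b"))$kappa))
})

test_that("independent raters give kappa near zero at large n", {
  withr::local_seed(20110629)
  n <- 1e5
  cats <- c("none", "3a", "3b", "3c")
  pairs <- tibble::tibble(
    rating_a = sample(cats, n, TRUE, prob = c(.1, .2, .5, .2)),
    rating_b = sample(cats, n, TRUE, prob = c(.3, .3, .2, .2)))
  for (w in c("linear", "quadratic")) {
    expect_lt(abs(weighted_kappa(pairs, cats, w)$kappa), 0.02)
  }
})
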