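test_that("confusion tallies the 2x2 table and degenerate cases", {
  # 155 samples: 16 true positives all called, no false calls
  truth <- c(rep(TRUE, 16), rep(FALSE, 139))
  calls <- truth
  cm <- confusion(truth, calls)
  expect_equal(as.numeric(cm), c(16, 0, 139, 0))

  cm0 <- confusion(rep(FALSE, 10), rep(FALSE, 10))
  expect_equal(as.numeric(cm0), c(0, 0, 10, 0))

  flipped <- confusion(truth, !truth)
  expect_equal(flipped$fp + flipped$fn, 155)
  expect_error(confusion(TRUE, c(TRUE, FALSE)), "different sample sets")
})

test_that("predictive values are TP/(TP+FP) and TN/(TN+FN), NA on empty denominators", {
  pv <- predictive_values(tibble::tibble(tp = 5, fp = 0, tn = 150, fn = 0))
  expect_equal(pv$ppv, 1); expect_equal(pv$npv, 1)
  expect_equal(predictive_values(tibble::tibble(tp = 1, fp = 1, tn = 0, fn = 0))$ppv, 0.5)
  expect_true(is.na(predictive_values(tibble::tibble(tp = 0, fp = 0, tn = 3, fn = 0))$ppv))
  expect_equal(predictive_values(tibble::tibble(tp = 144, fp = 0, tn = 144, fn = 0))$npv, 1)
})

test_that("exact interval agrees with binom.test and with the k = n closed form", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    got <- ci_exact(k, n)
    want <- binom.test(k, n)$conf.int
    expect_equal(got$lower, want[1], tolerance = 1e-10)
    expect_equal(got$upper, want[2], tolerance = 1e-10)
  }
  for (n in c(1, 5, 11, 16, 139, 144, 150, 500)) {
    expect_equal(ci_exact(n, n)$lower, 0.025^(1 / n), tolerance = 1e-12)
    expect_equal(ci_exact(n, n)$upper, 1)
  }
  expect_error(ci_exact(6, 5), "k <= n")
})

test_that("Wilson interval matches prop.test (no correction) and its closed forms", {
  set.seed(43)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    got <- ci_wilson(k, n)
    # prop.test warns about the chi-squared approximation at small counts;
    # only its Wilson interval is used here
    want <- suppressWarnings(prop.test(k, n, correct = FALSE))$conf.int
    expect_equal(got$lower, want[1], tolerance = 1e-9)
    expect_equal(got$upper, want[2], tolerance = 1e-9)
  }
  z <- qnorm(0.975)
  expect_equal(ci_wilson(150, 150)$lower, 150 / (150 + z^2), tolerance = 1e-12)
  expect_equal(ci_wilson(150, 150)$lower, 0.9750, tolerance = 1e-4)
  expect_equal(ci_wilson(5, 5)$lower, 5 / (5 + z^2), tolerance = 1e-12)
  expect_equal(ci_wilson(5, 5)$lower, 0.5655, tolerance = 1e-4)
  # midpoint identity at k = n/2
  for (n in c(10, 50, 144)) {
    ci <- ci_wilson(n / 2, n)
    expect_equal(mean(c(ci$lower, ci$upper)),
                 (n / 2 + z^2 / 2) / (n + z^2), tolerance = 1e-12)
  }
})

test_that("at k = n the exact bound is more conservative only for small n, and both contain k/n", {
  # the two all-success lower bounds cross: Clopper-Pearson 0.025^(1/n)
  # (~ 1 - 3.689/n) sits below Wilson n/(n+z^2) (~ 1 - 3.841/n) up to
  # n = 45 and above it from n = 46 on — which is why the exact planner
  # needs fewer samples (183 < 189) for a 98% lower bound
  n <- 1:500
  ex <- ci_exact(n, n)
  wi <- ci_wilson(n, n)
  expect_true(all(ex$lower[n <= 45] <= wi$lower[n <= 45] + 1e-12))
  expect_true(all(ex$lower[n >= 46] > wi$lower[n >= 46]))
  set.seed(44)
  for (i in 1:20) {
    nn <- sample(2:300, 1); kk <- sample(0:nn, 1)
    for (ci in list(ci_exact(kk, nn), ci_wilson(kk, nn))) {
      expect_lte(ci$lower, kk / nn + 1e-12)
      expect_gte(ci$upper, kk / nn - 1e-12)
    }
  }
  # widths shrink with n at fixed k/n
  w_exact <- vapply(c(10, 40, 160), function(n) {
    ci <- ci_exact(n / 2, n); ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(w_exact) < 0))
})

test_that("all-success sample-size planner matches brute-force iteration", {
  brute <- function(target, lower_fun) {
    n <- 1
    while (lower_fun(n) < target) n <- n + 1
    n
  }
  z <- qnorm(0.975)
  expect_equal(sample_size_all_success(0.98, "exact"),
               brute(0.98, function(n) 0.025^(1 / n)))
  expect_equal(sample_size_all_success(0.98, "exact"), 183)
  expect_equal(sample_size_all_success(0.98, "wilson"),
               brute(0.98, function(n) n / (n + z^2)))
  expect_equal(sample_size_all_success(0.98, "wilson"), 189)
  expect_lte(sample_size_all_success(0.5, "exact"), 6)
  expect_lte(sample_size_all_success(0.5, "wilson"), 6)
  # looser targets never need more samples
  ns <- vapply(c(0.9, 0.95, 0.98, 0.99), sample_size_all_success, numeric(1),
               method = "exact")
  expect_true(all(diff(ns) > 0))
})

test_that("evaluate_cohort pools both trisomies into combined detection", {
  truth <- tibble::tibble(
    sample = sprintf("s%03d", 1:155),
    karyotype = c(rep("T18", 5), rep("T21", 11), rep("euploid", 139))
  )
  calls <- tidyr::crossing(sample = truth$sample,
                           tibble::tibble(target = c("T18", "T21"),
                                          chrom = c("chr18", "chr21"))) %>%
    dplyr::inner_join(truth, by = "sample") %>%
    dplyr::mutate(z = dplyr::if_else(karyotype == target, 5, 0),
                  cutoff = 2.5,
                  call = dplyr::if_else(z > cutoff, "positive", "negative")) %>%
    dplyr::select(sample, target, chrom, z, cutoff, call)
  ev <- evaluate_cohort(calls, truth, ci_method = "exact")
  sm <- tidy(ev)
  expect_equal(sm$tp[sm$target == "T18"], 5)
  expect_equal(sm$tn[sm$target == "T18"], 150)
  expect_equal(sm$tp[sm$target == "T21"], 11)
  expect_equal(sm$tn[sm$target == "T21"], 144)
  expect_equal(sm$tp[sm$target == "combined"], 16)
  expect_equal(sm$tn[sm$target == "combined"], 139)
  expect_true(all(sm$fp == 0) && all(sm$fn == 0))
  g <- glance(ev)
  expect_equal(g$n_samples, 155)
  expect_equal(g$total_errors, 0)
})
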