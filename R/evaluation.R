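#' 2x2 confusion counts
#'
#' @param truth_positive,called_positive Logical vectors over the same
#'   samples (same length, no NA).
#' @return One-row tibble `(tp, fp, tn, fn)`.
#' @examples
#' confusion(c(TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE))
#' @export
confusion <- function(truth_positive, called_positive) {
  if (length(truth_positive) != length(called_positive)) {
    abort("truth and calls cover different sample sets")
  }
  if (anyNA(truth_positive) || anyNA(called_positive)) abort("NA in labels")
  truth_positive <- as.logical(truth_positive)
  called_positive <- as.logical(called_positive)
  tibble(
    tp = sum(truth_positive & called_positive),
    fp = sum(!truth_positive & called_positive),
    tn = sum(!truth_positive & !called_positive),
    fn = sum(truth_positive & !called_positive)
  )
}

#' Predictive values from confusion counts
#'
#' `PPV = TP / (TP + FP)`, `NPV = TN / (TN + FN)`; a zero denominator gives
#' `NA` (not available), never an error.
#'
#' @param counts One-row tibble or list with `tp`, `fp`, `tn`, `fn`.
#' @return One-row tibble `(ppv, npv, sensitivity, specificity)`;
#'   sensitivity/specificity share the same `NA` convention.
#' @export
predictive_values <- function(counts) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, tibble(
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp)
  ))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from Beta quantiles; at `k = n` the lower limit has the closed
#' form `(alpha/2)^(1/n)` and the upper limit is 1.
#'
#' @param k Number of successes (vectorised).
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Tibble `(lower, upper)`.
#' @examples
#' ci_exact(5, 5)   # lower 0.478: five-of-five successes
#' @export
ci_exact <- function(k, n, conf = 0.95) {
  check_kn(k, n, conf)
  a2 <- (1 - conf) / 2
  tibble(
    lower = ifelse(k == 0, 0, qbeta(a2, k, n - k + 1)),
    upper = ifelse(k == n, 1, qbeta(1 - a2, k + 1, n - k))
  )
}

#' Wilson score binomial confidence interval
#'
#' Inverts the normal score test; at `k = n` the lower limit is
#' `n / (n + z^2)` with `z` the two-sided normal quantile (1.959964 at 95%).
#'
#' @inheritParams ci_exact
#' @return Tibble `(lower, upper)`.
#' @examples
#' ci_wilson(150, 150)  # lower 0.975
#' @export
ci_wilson <- function(k, n, conf = 0.95) {
  check_kn(k, n, conf)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  tibble(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

check_kn <- function(k, n, conf) {
  if (any(n < 1) || any(k < 0) || any(k > n) ||
      any(k != floor(k)) || any(n != floor(n))) {
    abort("need integer 0 <= k <= n with n >= 1")
  }
  stopifnot_scalar_number(conf, "conf", lo = 1e-6, hi = 1 - 1e-6)
  invisible(NULL)
}

binom_ci <- function(k, n, conf, method = c("exact", "wilson")) {
  method <- match.arg(method)
  if (method == "exact") ci_exact(k, n, conf) else ci_wilson(k, n, conf)
}

#' Smallest trial count whose all-success lower CI bound meets a target
#'
#' For planning: the smallest `n` such that observing `n` successes in `n`
#' trials yields a lower confidence bound of at least `target_lower`. Used
#' to size a validation cohort whose NPV/specificity lower bound must clear
#' a benchmark (e.g. 98%).
#'
#' @param target_lower Required lower bound, in (0, 1).
#' @param method `"exact"` (Clopper-Pearson) or `"wilson"`.
#' @param conf Confidence level (default 0.95).
#' @return Smallest integer `n` meeting the target.
#' @examples
#' sample_size_all_success(0.98, "exact")   # 183
#' sample_size_all_success(0.98, "wilson")  # 189
#' @export
sample_size_all_success <- function(target_lower, method = c("exact", "wilson"),
                                    conf = 0.95) {
  method <- match.arg(method)
  stopifnot_scalar_number(target_lower, "target_lower", lo = 1e-9,
                          hi = 1 - 1e-9)
  n <- 1L
  repeat {
    if (binom_ci(n, n, conf, method)$lower >= target_lower) return(n)
    n <- n + 1L
    if (n > 1e7) abort("no n <= 1e7 meets the target")
  }
}

#' Evaluate trisomy calls against karyotype truth
#'
#' Builds per-target and pooled ("combined") confusion summaries with
#' predictive values and binomial confidence intervals. For a target
#' trisomy, truth-positive means the sample carries that karyotype and
#' called-positive means its call on the target chromosome is positive;
#' combined detection pools both trisomies into one positive class over the
#' same samples (positive call on either target chromosome).
#'
#' @param calls Tibble from [classify_calls()].
#' @param truth Tibble `(sample, karyotype)`.
#' @param ci_method `"exact"` (default; matches printed NIPT feasibility
#'   tables) or `"wilson"`.
#' @param conf Confidence level.
#' @param combined Include the pooled row (default `TRUE`).
#' @return A `nipt_eval` object; see [tidy.nipt_eval()] for the summary
#'   tibble `(target, n_positive, tp, fp, tn, fn, sensitivity, specificity,
#'   ppv, npv, ppv_lower, ppv_upper, npv_lower, npv_upper)`.
#' @export
evaluate_cohort <- function(calls, truth, ci_method = c("exact", "wilson"),
                            conf = 0.95, combined = TRUE) {
  ci_method <- match.arg(ci_method)
  assert_columns(calls, c("sample", "target", "call"), "calls")
  assert_columns(truth, c("sample", "karyotype"), "truth")
  if (!setequal(unique(calls$sample), truth$sample)) {
    abort("calls and truth cover different sample sets")
  }
  joined <- calls %>% inner_join(truth, by = "sample")

  one_target <- function(label, truth_pos, called_pos) {
    cm <- confusion(truth_pos, called_pos)
    pv <- predictive_values(cm)
    ppv_ci <- binom_ci(cm$tp, cm$tp + cm$fp, conf, ci_method)
    npv_ci <- binom_ci(cm$tn, cm$tn + cm$fn, conf, ci_method)
    tibble(target = label, n_positive = sum(truth_pos)) %>%
      dplyr::bind_cols(cm, pv) %>%
      mutate(ppv_lower = ppv_ci$lower, ppv_upper = ppv_ci$upper,
             npv_lower = npv_ci$lower, npv_upper = npv_ci$upper)
  }

  rows <- purrr::map_dfr(unique(calls$target), function(tg) {
    d <- joined %>% filter(.data$target == tg)
    one_target(tg, d$karyotype == tg, d$call == "positive")
  })
  if (combined) {
    pooled <- joined %>%
      group_by(.data$sample) %>%
      summarise(
        truth_pos = any(.data$karyotype %in% unique(calls$target)),
        called_pos = any(.data$call == "positive"),
        .groups = "drop"
      )
    rows <- bind_rows(
      rows, one_target("combined", pooled$truth_pos, pooled$called_pos))
  }
  structure(
    list(summary = rows, ci_method = ci_method, conf = conf,
         n_samples = nrow(truth)),
    class = "nipt_eval"
  )
}

#' @export
print.nipt_eval <- function(x, ...) {
  cat(sprintf("<nipt_eval> %d samples, %s %.0f%% CIs\n",
              x$n_samples, x$ci_method, 100 * x$conf))
  print(x$summary, ...)
  invisible(x)
}

#' Tidy and summarise an evaluation
#'
#' `tidy()` returns the per-target summary tibble; `glance()` a one-row
#' overview.
#'
#' @param x A `nipt_eval` from [evaluate_cohort()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nipt_eval <- function(x, ...) x$summary

#' @rdname tidy.nipt_eval
#' @exportS3Method generics::glance
glance.nipt_eval <- function(x, ...) {
  tibble(
    n_samples = x$n_samples,
    n_targets = sum(x$summary$target != "combined"),
    total_errors = sum(x$summary$fp + x$summary$fn),
    ci_method = x$ci_method,
    conf = x$conf
  )
}
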