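#' Select a z-score cutoff by the dot-diagram (Youden) criterion
#'
#' Scans every observed z value as a candidate cutoff for the rule
#' "call positive iff z > cutoff" and returns the one maximising the Youden
#' index (sensitivity + specificity - 1). Ties are broken by the largest
#' qualifying cutoff, so with perfectly separated groups the cutoff equals
#' the maximum of the negative group — the "minimal z-score to discriminate
#' negative versus positive cases" an interactive dot diagram reports.
#'
#' @param negative_z Numeric z values of the negative (euploid) group.
#' @param positive_z Numeric z values of the positive (trisomic) group.
#' @return One-row tibble `(cutoff, sensitivity, specificity, youden)`.
#' @examples
#' select_threshold(c(-3.184, 0.2, 2.459), c(4.017, 10.193))
#' @export
select_threshold <- function(negative_z, positive_z) {
  if (length(negative_z) == 0 || length(positive_z) == 0) {
    abort("both groups must be non-empty")
  }
  if (anyNA(negative_z) || anyNA(positive_z)) abort("z values contain NA")
  cand <- sort(unique(c(negative_z, positive_z)))
  sens <- vapply(cand, function(c) mean(positive_z > c), numeric(1))
  spec <- vapply(cand, function(c) mean(negative_z <= c), numeric(1))
  youden <- sens + spec - 1
  best <- youden >= max(youden) - 1e-12
  i <- max(which(best))  # largest qualifying cutoff
  tibble(cutoff = cand[i], sensitivity = sens[i], specificity = spec[i],
         youden = youden[i])
}

#' Select cutoffs for each trisomy target from cohort z-scores
#'
#' For each target chromosome, negatives are all samples whose karyotype is
#' not that trisomy (euploid and the other trisomy alike) and positives are
#' the samples carrying it, mirroring a per-trisomy dot diagram.
#'
#' @param zscores Tibble `(sample, chrom, z)` from [zscore_profiles()].
#' @param truth Tibble `(sample, karyotype)` with karyotypes in
#'   `{"euploid", "T18", "T21"}`.
#' @param targets Named character vector mapping karyotype label to its
#'   chromosome, default `c(T18 = "chr18", T21 = "chr21")`.
#' @return Tibble `(target, chrom, cutoff, sensitivity, specificity, youden)`.
#' @export
select_thresholds <- function(zscores, truth,
                              targets = c(T18 = "chr18", T21 = "chr21")) {
  assert_columns(zscores, c("sample", "chrom", "z"), "zscores")
  assert_columns(truth, c("sample", "karyotype"), "truth")
  z <- zscores %>% inner_join(truth, by = "sample")
  purrr::imap_dfr(targets, function(target_chrom, karyo) {
    zc <- z %>% filter(.data$chrom == target_chrom)
    if (nrow(zc) == 0) {
      abort(sprintf("no z-scores for chromosome %s", target_chrom))
    }
    pos <- zc$z[zc$karyotype == karyo]
    neg <- zc$z[zc$karyotype != karyo]
    select_threshold(neg, pos) %>%
      mutate(target = karyo, chrom = target_chrom, .before = 1)
  })
}

#' Classification rules from fixed cutoffs
#'
#' @param cutoffs Named numeric vector of z cutoffs keyed by target
#'   karyotype, e.g. `c(T18 = 2.459, T21 = 2.566)`.
#' @param targets Named character vector mapping target to chromosome.
#' @return Tibble `(target, chrom, cutoff)` usable by [classify_calls()].
#' @export
fixed_thresholds <- function(cutoffs,
                             targets = c(T18 = "chr18", T21 = "chr21")) {
  if (is.null(names(cutoffs)) || !all(names(cutoffs) %in% names(targets))) {
    abort("`cutoffs` must be named by target karyotype (e.g. T18, T21)")
  }
  if (any(!is.finite(cutoffs))) abort("cutoffs must be finite")
  tibble(target = names(cutoffs),
         chrom = unname(targets[names(cutoffs)]),
         cutoff = unname(cutoffs))
}

#' Call samples positive or negative against per-chromosome cutoffs
#'
#' A sample is called positive for a target iff its z on the target
#' chromosome strictly exceeds the cutoff (z equal to the cutoff is
#' negative).
#'
#' @param zscores Tibble `(sample, chrom, z)`.
#' @param rules Tibble `(target, chrom, cutoff)` from [select_thresholds()]
#'   or [fixed_thresholds()].
#' @return Tibble `(sample, target, chrom, z, cutoff, call)` with `call` in
#'   `{"positive", "negative"}`.
#' @export
classify_calls <- function(zscores, rules) {
  assert_columns(zscores, c("sample", "chrom", "z"), "zscores")
  assert_columns(rules, c("target", "chrom", "cutoff"), "rules")
  missing <- setdiff(rules$chrom, zscores$chrom)
  if (length(missing) > 0) {
    abort(sprintf("no z-scores for rule chromosome(s): %s",
                  paste(missing, collapse = ", ")))
  }
  zscores %>%
    inner_join(rules %>% select("target", "chrom", "cutoff"), by = "chrom") %>%
    mutate(call = if_else(.data$z > .data$cutoff, "positive", "negative")) %>%
    select("sample", "target", "chrom", "z", "cutoff", "call")
}
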