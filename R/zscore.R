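#' Build a euploid reference panel
#'
#' For every chromosome, the mean and sample standard deviation (n - 1
#' denominator) of the representation statistic over the supplied euploid
#' profiles. All 155 study samples are later scored against this panel; a
#' euploid panel member is not excluded from its own panel by default (see
#' `leave_one_out` in [zscore_profiles()] for the alternative).
#'
#' @param profiles Tibble from [profile_from_counts()] restricted to euploid
#'   samples; at least two samples, one common `mode`.
#' @return A `reference_panel`: tibble `(chrom, mean, sd, n_ref, mode)`.
#' @examples
#' prof <- tibble::tibble(sample = rep(c("a", "b", "c"), each = 1),
#'                        chrom = "chr21", count = c(100, 110, 120),
#'                        statistic = c(100, 110, 120), mode = "count")
#' build_reference(prof)
#' @export
build_reference <- function(profiles) {
  assert_columns(profiles, c("sample", "chrom", "statistic", "mode"),
                 "profiles")
  mode <- unique(profiles$mode)
  if (length(mode) != 1) abort("profiles mix representation modes")
  n_ref <- n_distinct(profiles$sample)
  if (n_ref < 2) abort("reference panel needs at least 2 euploid samples")
  panel <- profiles %>%
    group_by(.data$chrom) %>%
    summarise(mean = mean(.data$statistic), sd = sd(.data$statistic),
              .groups = "drop") %>%
    mutate(n_ref = n_ref, mode = mode)
  if (any(is.na(panel$sd)) || any(panel$sd <= 0)) {
    abort("zero or undefined SD on a scored chromosome; degenerate panel")
  }
  class(panel) <- c("reference_panel", class(panel))
  panel
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d euploid samples, %s mode\n",
              x$n_ref[1], x$mode[1]))
  NextMethod()
}

#' @rdname build_reference
#' @param x A `reference_panel`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.reference_panel <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname build_reference
#' @exportS3Method generics::glance
glance.reference_panel <- function(x, ...) {
  tibble(n_ref = x$n_ref[1], mode = x$mode[1],
         n_chromosomes = nrow(x))
}

#' Per-chromosome z-scores against a euploid panel
#'
#' The aneuploidy statistic: for sample s and chromosome c,
#' `z = (statistic_sc - panel_mean_c) / panel_sd_c`. With `leave_one_out`,
#' a sample present in the panel is scored against the panel rebuilt
#' without it (off by default, matching the all-euploid reference design).
#'
#' @param profiles Tibble from [profile_from_counts()] (any karyotype).
#' @param panel A [build_reference()] panel, or (for `leave_one_out`) the
#'   euploid profiles themselves.
#' @param leave_one_out Logical; rescore panel members excluding themselves.
#'   Requires `panel` to be the euploid profile tibble.
#' @return Tibble `(sample, chrom, statistic, z)`.
#' @export
zscore_profiles <- function(profiles, panel, leave_one_out = FALSE) {
  assert_columns(profiles, c("sample", "chrom", "statistic", "mode"),
                 "profiles")
  if (leave_one_out) {
    assert_columns(panel, c("sample", "chrom", "statistic", "mode"),
                   "panel (euploid profiles)")
    return(purrr::map_dfr(unique(profiles$sample), function(s) {
      ref <- panel %>% filter(.data$sample != s)
      zscore_profiles(profiles %>% filter(.data$sample == s),
                      build_reference(ref))
    }))
  }
  if (!inherits(panel, "reference_panel")) {
    abort("`panel` must be a reference_panel (see build_reference())")
  }
  if (unique(profiles$mode) != panel$mode[1]) {
    abort(sprintf("mode mismatch: profiles are '%s', panel is '%s'",
                  unique(profiles$mode), panel$mode[1]))
  }
  scored <- profiles %>%
    inner_join(as_tibble(unclass(panel))[, c("chrom", "mean", "sd")],
               by = "chrom") %>%
    mutate(z = (.data$statistic - .data$mean) / .data$sd) %>%
    select("sample", "chrom", "statistic", "z")
  if (any(!is.finite(scored$z))) abort("non-finite z-score produced")
  scored
}
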