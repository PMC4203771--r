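#' Dot diagram of z-scores with a classification cutoff
#'
#' The two-group strip plot a cutoff is read off: negative and positive
#' samples as jittered columns of per-chromosome z-scores, with a horizontal
#' line at the cutoff.
#'
#' @param zscores Tibble `(sample, chrom, z)`.
#' @param truth Tibble `(sample, karyotype)`.
#' @param target Target karyotype label (e.g. `"T21"`).
#' @param chrom Chromosome scored for that target (e.g. `"chr21"`).
#' @param cutoff Optional z cutoff to draw; computed by [select_threshold()]
#'   when `NULL`.
#' @return A ggplot object.
#' @export
plot_dot_diagram <- function(zscores, truth, target, chrom, cutoff = NULL) {
  assert_columns(zscores, c("sample", "chrom", "z"), "zscores")
  d <- zscores %>%
    filter(.data$chrom == !!chrom) %>%
    inner_join(truth, by = "sample") %>%
    mutate(group = if_else(.data$karyotype == target, target, "negative"))
  if (is.null(cutoff)) {
    cutoff <- select_threshold(d$z[d$group == "negative"],
                               d$z[d$group == target])$cutoff
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$z)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7, size = 1.8) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::annotate("text", x = 1.5, y = cutoff,
                      label = sprintf("z > %.3f", cutoff), vjust = -0.6) +
    ggplot2::labs(x = NULL, y = sprintf("z-score (%s)", chrom),
                  title = sprintf("Dot diagram: %s", target)) +
    ggplot2::theme_minimal()
}

#' Dot diagrams for every rule of a pipeline run
#'
#' @param object A `nipt_run` from [run_full()].
#' @param truth Tibble `(sample, karyotype)`; when omitted, groups are the
#'   calls themselves.
#' @param ... Unused.
#' @return A ggplot object (faceted by target).
#' @exportS3Method ggplot2::autoplot
autoplot.nipt_run <- function(object, truth = NULL, ...) {
  d <- object$calls
  if (!is.null(truth)) {
    d <- d %>% inner_join(truth, by = "sample") %>%
      mutate(group = if_else(.data$karyotype == .data$target,
                             .data$target, "negative"))
  } else {
    d <- d %>% mutate(group = .data$call)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$z)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7, size = 1.5) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$cutoff),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~target, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "z-score") +
    ggplot2::theme_minimal()
}
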