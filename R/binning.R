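#' Count QC-passed alignments in fixed genomic bins
#'
#' Each alignment increments exactly one bin, chosen by its 5'-most mapped
#' coordinate (`floor(start / bin_size)`); totals are conserved. Alignments
#' on chromosomes absent from the layout are skipped with a message.
#' The returned table carries the complete bin grid, including zero bins.
#'
#' @param alignments Tibble with `chrom` and `start` (0-based) columns, and
#'   optionally `sample`; records should already be deduplicated and
#'   uniquely mapped.
#' @param layout A [make_layout()] object.
#' @return Tibble `(sample, chrom, bin, count)` over the full grid.
#' @examples
#' ly <- make_layout(data.frame(chrom = "chrA", length = 9e5), bin_size = 3e5)
#' aln <- tibble::tibble(chrom = "chrA", start = c(0, 299999, 300000))
#' count_bins(aln, ly)
#' @export
count_bins <- function(alignments, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  assert_columns(alignments, c("chrom", "start"), "alignments")
  if (!"sample" %in% names(alignments)) alignments$sample <- "sample"
  known <- alignments$chrom %in% layout$chromosomes$chrom
  if (any(!known)) {
    message(sprintf("count_bins: skipped %d alignment(s) on chromosome(s) absent from layout: %s",
                    sum(!known),
                    paste(unique(alignments$chrom[!known]), collapse = ", ")))
    alignments <- alignments[known, , drop = FALSE]
  }
  grid <- layout_bins(layout) %>% select("chrom", "bin")
  samples <- unique(alignments$sample)
  if (length(samples) == 0) samples <- "sample"
  full <- tidyr::crossing(sample = samples, grid)
  if (nrow(alignments) == 0) {
    return(full %>% mutate(count = 0L) %>%
             arrange(.data$sample, match(.data$chrom, layout$chromosomes$chrom),
                     .data$bin))
  }
  tallied <- alignments %>%
    mutate(bin = assign_bin(layout, .data$chrom, .data$start)) %>%
    count(.data$sample, .data$chrom, .data$bin, name = "count")
  full %>%
    left_join(tallied, by = c("sample", "chrom", "bin")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0L)) %>%
    arrange(.data$sample, match(.data$chrom, layout$chromosomes$chrom),
            .data$bin)
}

#' Per-chromosome representation profiles
#'
#' Collapses bin counts to per-chromosome totals and, in `"fraction"` mode
#' (the default), divides by the sample's total autosomal count, removing
#' depth differences between samples and the sex-linked chrX/chrY nuisance.
#' `"count"` mode keeps raw chromosome totals, the literal "mapped reads"
#' statistic.
#'
#' @param counts Tibble `(sample?, chrom, bin, count)` as from
#'   [count_bins()] or [simulate_bin_counts()].
#' @param layout A [make_layout()] object.
#' @param mode `"fraction"` (chromosome count / total autosomal count) or
#'   `"count"` (raw chromosome count).
#' @return Tibble `(sample, chrom, count, statistic, mode)`; `statistic` is
#'   what enters the z-score.
#' @examples
#' ly <- make_layout(data.frame(chrom = c("chrA", "chrB"), length = c(9e5, 1e5)))
#' cn <- tibble::tibble(chrom = c("chrA", "chrB"), bin = 0L, count = c(900L, 100L))
#' profile_from_counts(cn, ly)
#' @export
profile_from_counts <- function(counts, layout,
                                mode = c("fraction", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "genome_layout"))
  assert_columns(counts, c("chrom", "bin", "count"), "counts")
  if (!"sample" %in% names(counts)) counts$sample <- "sample"
  if (any(counts$count < 0)) abort("negative bin count")
  prof <- counts %>%
    group_by(.data$sample, .data$chrom) %>%
    summarise(count = sum(.data$count), .groups = "drop_last") %>%
    mutate(auto_total = sum(.data$count[.data$chrom %in% layout$autosomes])) %>%
    ungroup()
  if (mode == "fraction" && any(prof$auto_total == 0)) {
    abort("zero autosomal total; cannot compute fraction-mode profile")
  }
  prof %>%
    mutate(
      statistic = if (mode == "fraction") .data$count / .data$auto_total
                  else as.numeric(.data$count),
      mode = mode
    ) %>%
    select("sample", "chrom", "count", "statistic", "mode") %>%
    arrange(.data$sample, match(.data$chrom, layout$chromosomes$chrom))
}
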