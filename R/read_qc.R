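#' Read-level QC configuration
#'
#' The filters applied to raw reads before binning: 3' quality trimming
#' (trailing bases with Phred quality <= `quality_threshold` are removed),
#' a minimum trimmed length (reads shorter than `min_length` are discarded;
#' exactly `min_length` is retained), an inclusive GC-content window on the
#' retained bases, selection of uniquely mapped alignments, and positional
#' duplicate removal keyed on (chromosome, 0-based 5' start, strand).
#'
#' @param quality_threshold Phred score; trailing bases with quality at or
#'   below it are trimmed (default 15).
#' @param min_length Minimum trimmed read length in bp (default 50).
#' @param gc_min,gc_max Inclusive GC-fraction window (defaults 0.35-0.45).
#' @param unique_rule Optional function taking an alignment tibble and
#'   returning a logical vector; overrides the default uniqueness predicate
#'   (mapped, primary, not supplementary, mapping quality > 0).
#' @return A `qc_config` list.
#' @export
qc_config <- function(quality_threshold = 15, min_length = 50,
                      gc_min = 0.35, gc_max = 0.45, unique_rule = NULL) {
  stopifnot_scalar_number(quality_threshold, "quality_threshold", lo = 0)
  stopifnot_scalar_number(min_length, "min_length", lo = 1)
  stopifnot_scalar_number(gc_min, "gc_min", lo = 0, hi = 1)
  stopifnot_scalar_number(gc_max, "gc_max", lo = 0, hi = 1)
  if (gc_min > gc_max) abort("gc_min must be <= gc_max")
  structure(
    list(quality_threshold = quality_threshold, min_length = min_length,
         gc_min = gc_min, gc_max = gc_max, unique_rule = unique_rule),
    class = "qc_config"
  )
}

phred_from_string <- function(qual) {
  lapply(qual, function(q) if (nchar(q) == 0) integer(0) else utf8ToInt(q) - 33L)
}

#' Trim low-quality 3' tails from reads
#'
#' Removes trailing bases until the last remaining base has Phred quality
#' strictly greater than `quality_threshold`; a read may be trimmed to
#' length zero. No windowed (Mott-style) trimming is performed.
#'
#' @param reads Tibble with columns `bases` and `qual` (Phred+33 string).
#' @param quality_threshold Phred cutoff (trailing bases with quality
#'   `<= quality_threshold` go).
#' @return `reads` with `bases`/`qual` trimmed.
#' @examples
#' r <- tibble::tibble(bases = "ACGTACGT", qual = "IIIIII++")
#' trim_3prime(r, 15)
#' @export
trim_3prime <- function(reads, quality_threshold = 15) {
  assert_columns(reads, c("bases", "qual"), "reads")
  keep <- vapply(phred_from_string(reads$qual), function(q) {
    good <- which(q > quality_threshold)
    if (length(good) == 0) 0L else max(good)
  }, integer(1))
  reads %>% mutate(
    bases = substr(.data$bases, 1L, keep),
    qual = substr(.data$qual, 1L, keep)
  )
}

#' Length filter predicate
#'
#' @param reads Tibble with a `bases` column (already trimmed).
#' @param min_length Minimum retained length; reads shorter than it fail.
#' @return Logical vector: `TRUE` where trimmed length >= `min_length`.
#' @export
passes_length <- function(reads, min_length = 50) {
  assert_columns(reads, "bases", "reads")
  nchar(reads$bases) >= min_length
}

#' GC content of read sequences
#'
#' Ambiguous bases (anything other than G/C/g/c) count as non-GC.
#'
#' @param bases Character vector of sequences (non-empty).
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(bases) {
  n <- nchar(bases)
  if (any(n == 0)) abort("gc_content on empty read; apply the length filter first")
  gc <- nchar(gsub("[^GCgc]", "", bases))
  gc / n
}

#' GC filter predicate (inclusive bounds)
#'
#' @param reads Tibble with a `bases` column (trimmed, non-empty).
#' @param gc_min,gc_max Inclusive GC-fraction window.
#' @return Logical vector: `TRUE` where GC fraction lies in
#'   `[gc_min, gc_max]`.
#' @export
passes_gc <- function(reads, gc_min = 0.35, gc_max = 0.45) {
  assert_columns(reads, "bases", "reads")
  gc <- gc_content(reads$bases)
  gc >= gc_min & gc <= gc_max
}

#' Uniquely-mapped predicate on alignment records
#'
#' If the alignment table carries a logical `unique` column (generator truth
#' tables do), it is used directly. Otherwise the default rule is applied to
#' SAM-style fields: not unmapped (flag 0x4), not secondary (0x100), not
#' supplementary (0x800), and mapping quality > 0. The study never defines
#' uniqueness, so the rule is configurable via `unique_rule`.
#'
#' @param alignments Tibble of alignment records.
#' @param unique_rule Optional function `alignments -> logical`.
#' @return Logical vector.
#' @export
is_uniquely_mapped <- function(alignments, unique_rule = NULL) {
  if (!is.null(unique_rule)) return(unique_rule(alignments))
  if ("unique" %in% names(alignments)) return(as.logical(alignments$unique))
  assert_columns(alignments, c("flag", "mapq"), "alignments")
  flag <- as.integer(alignments$flag)
  !bitwAnd(flag, 0x4) & !bitwAnd(flag, 0x100) & !bitwAnd(flag, 0x800) &
    alignments$mapq > 0
}

#' Remove positional duplicate alignments
#'
#' Keeps at most one alignment per (chromosome, 0-based start, strand) —
#' per sample when a `sample` column is present. Input is stably sorted by
#' (chromosome, start, strand, read id) and the first record of each key is
#' retained, so output is deterministic and the operation is idempotent.
#'
#' @param alignments Tibble with columns `chrom`, `start`, `strand` and
#'   `read_id` (plus optional `sample`).
#' @return Deduplicated tibble in sorted order.
#' @export
remove_duplicates <- function(alignments) {
  assert_columns(alignments, c("chrom", "start", "strand", "read_id"),
                 "alignments")
  key <- intersect(c("sample", "chrom", "start", "strand"), names(alignments))
  alignments %>%
    arrange(across(all_of(c(key, "read_id")))) %>%
    distinct(across(all_of(key)), .keep_all = TRUE)
}

#' Run the full read-level QC pipeline
#'
#' Applies, in order: 3' quality trimming, length filter, GC filter,
#' unique-mapping selection, positional duplicate removal. Sequence filters
#' run on the reads table; mapping filters run on the alignment table joined
#' by `read_id`.
#'
#' @param reads Tibble `(sample?, read_id, bases, qual)`.
#' @param alignments Tibble of alignment records with `read_id`, `chrom`,
#'   `start`, `strand` and either a logical `unique` column or SAM `flag` +
#'   `mapq` fields.
#' @param config A [qc_config()].
#' @return A list: `alignments` (retained records), `reads` (their trimmed
#'   sequences) and `report` (tibble `stage, n_in, n_removed, n_out` of
#'   per-filter attrition, the "% retained" accounting a run log shows).
#' @export
qc_reads <- function(reads, alignments, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  assert_columns(reads, c("read_id", "bases", "qual"), "reads")
  assert_columns(alignments, c("read_id", "chrom", "start", "strand"),
                 "alignments")
  stages <- list()
  note <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1]] <<- tibble(
      stage = stage, n_in = n_in, n_removed = n_in - n_out, n_out = n_out)
  }

  trimmed <- trim_3prime(reads, config$quality_threshold)
  note("trim_3prime", nrow(reads), nrow(trimmed))  # trims bases, drops none

  keep_len <- passes_length(trimmed, config$min_length)
  trimmed <- trimmed[keep_len, , drop = FALSE]
  note("length_filter", length(keep_len), nrow(trimmed))

  keep_gc <- passes_gc(trimmed, config$gc_min, config$gc_max)
  trimmed <- trimmed[keep_gc, , drop = FALSE]
  note("gc_filter", length(keep_gc), nrow(trimmed))

  aln <- alignments %>% filter(.data$read_id %in% trimmed$read_id)
  keep_uni <- is_uniquely_mapped(aln, config$unique_rule)
  aln <- aln[keep_uni, , drop = FALSE]
  note("unique_mapping", length(keep_uni), nrow(aln))

  deduped <- remove_duplicates(aln)
  note("dedup", nrow(aln), nrow(deduped))

  list(
    alignments = deduped,
    reads = trimmed %>% filter(.data$read_id %in% deduped$read_id),
    report = bind_rows(stages)
  )
}
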