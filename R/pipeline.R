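#' Generate a synthetic cohort and write its stage artifacts
#'
#' Runs the generator and writes self-describing TSVs (each with a `#`
#' header carrying the seed and parameters) plus a manifest echoing the
#' configuration. With `what = "reads"` a per-sample FASTQ and a truth
#' alignment TSV are written instead of bin counts.
#'
#' @param config A [sim_config()].
#' @param layout A [make_layout()] object.
#' @param out_dir Output directory (created if missing).
#' @param what `"counts"` (default) for per-bin count tables, `"reads"` for
#'   FASTQ + truth alignments.
#' @return Invisibly, a list with the generated data and written `paths`.
#' @export
run_simulate <- function(config, layout, out_dir,
                         what = c("counts", "reads")) {
  what <- match.arg(what)
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config(); no simulation configuration given")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(seed = config$seed, what = what)
  paths <- list()
  if (what == "counts") {
    cohort <- simulate_bin_counts(config, layout)
    paths$counts <- write_stage_tsv(cohort$counts,
                                    file.path(out_dir, "bin_counts.tsv"), meta)
    paths$truth <- write_stage_tsv(cohort$truth,
                                   file.path(out_dir, "truth.tsv"), meta)
  } else {
    cohort <- simulate_reads(config, layout)
    paths$fastq <- file.path(out_dir, "reads.fastq")
    write_fastq(cohort$reads %>%
                  mutate(read_id = paste(.data$sample, .data$read_id)),
                paths$fastq)
    paths$truth <- write_stage_tsv(cohort$truth,
                                   file.path(out_dir, "truth_alignments.tsv"),
                                   meta)
  }
  manifest <- tibble(
    key = c("seed", "what", "n_euploid", "n_t18", "n_t21",
            "reads_per_sample", "unique_map_rate", "fetal_fraction_mean",
            "fetal_fraction_sd", "duplicate_rate"),
    value = as.character(c(config$seed, what, config$n_euploid, config$n_t18,
                           config$n_t21, config$reads_per_sample,
                           config$unique_map_rate, config$fetal_fraction_mean,
                           config$fetal_fraction_sd, config$duplicate_rate))
  )
  paths$manifest <- write_stage_tsv(manifest,
                                    file.path(out_dir, "manifest.tsv"), meta)
  invisible(c(cohort, list(paths = paths)))
}

#' Run the full analysis from counts (or reads) to an evaluation report
#'
#' Stages: optional read QC, binning, euploid reference panel from labelled
#' euploids, z-scores for every sample, cutoff selection (dot-diagram Youden
#' scan) or fixed cutoffs, calls, and a predictive-value report. With
#' `out_dir`, every stage writes its TSV artifact so any stage can be rerun
#' from disk.
#'
#' @param counts Tibble `(sample, chrom, bin, count)`; omit when giving
#'   `reads` + `alignments`.
#' @param truth Tibble `(sample, karyotype)`; euploid labels select the
#'   reference panel, trisomy labels feed the evaluation.
#' @param layout A [make_layout()] object.
#' @param reads,alignments Optional read-level input run through
#'   [qc_reads()] then [count_bins()].
#' @param qc A [qc_config()] used when reads are given.
#' @param mode Representation mode, `"fraction"` (default) or `"count"`.
#' @param thresholds `NULL` to select cutoffs from the data, or a named
#'   numeric vector of fixed cutoffs, e.g. `c(T18 = 2.459, T21 = 2.566)`.
#' @param targets Named chromosome map, default
#'   `c(T18 = "chr18", T21 = "chr21")`.
#' @param ci_method,conf Confidence interval method and level.
#' @param out_dir Optional artifact directory.
#' @param seed Seed recorded in artifact headers (the analysis itself is
#'   deterministic).
#' @return A `nipt_run` list: `profiles`, `panel`, `zscores`, `rules`,
#'   `calls`, `evaluation`, `qc_report` (if reads given), `paths`.
#' @export
run_full <- function(counts = NULL, truth, layout,
                     reads = NULL, alignments = NULL, qc = qc_config(),
                     mode = c("fraction", "count"), thresholds = NULL,
                     targets = c(T18 = "chr18", T21 = "chr21"),
                     ci_method = c("exact", "wilson"), conf = 0.95,
                     out_dir = NULL, seed = NA_integer_) {
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)
  assert_columns(truth, c("sample", "karyotype"), "truth")
  qc_report <- NULL
  if (is.null(counts)) {
    if (is.null(reads) || is.null(alignments)) {
      abort("give either `counts` or both `reads` and `alignments`")
    }
    qcres <- qc_reads(reads, alignments, qc)
    qc_report <- qcres$report
    counts <- count_bins(qcres$alignments, layout)
  }
  if (nrow(counts) == 0) abort("empty input: no counts to analyse")

  profiles <- profile_from_counts(counts, layout, mode)
  euploid_ids <- truth$sample[truth$karyotype == "euploid"]
  if (length(euploid_ids) < 2) {
    abort("cannot build reference panel: fewer than 2 samples labelled euploid")
  }
  panel <- build_reference(profiles %>%
                             filter(.data$sample %in% euploid_ids))
  zscores <- zscore_profiles(profiles, panel)
  rules <- if (is.null(thresholds)) {
    select_thresholds(zscores, truth, targets)
  } else {
    fixed_thresholds(thresholds, targets)
  }
  calls <- classify_calls(zscores, rules)
  evaluation <- evaluate_cohort(calls, truth, ci_method = ci_method,
                                conf = conf)

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- c(seed = seed, mode = mode, ci = ci_method)
    w <- function(df, name) {
      write_stage_tsv(df, file.path(out_dir, paste0(name, ".tsv")), meta)
    }
    paths <- list(
      profiles = w(profiles, "profiles"),
      panel = w(as_tibble(unclass(panel)), "panel"),
      zscores = w(zscores, "zscores"),
      rules = w(rules, "rules"),
      calls = w(calls, "calls"),
      evaluation = w(tidy(evaluation), "evaluation")
    )
    if (!is.null(qc_report)) paths$qc_report <- w(qc_report, "qc_report")
  }
  structure(
    list(profiles = profiles, panel = panel, zscores = zscores,
         rules = rules, calls = calls, evaluation = evaluation,
         qc_report = qc_report, mode = mode, targets = targets,
         paths = paths),
    class = "nipt_run"
  )
}

#' @export
print.nipt_run <- function(x, ...) {
  cat(sprintf("<nipt_run> %s mode, %d samples\n", x$mode,
              n_distinct(x$calls$sample)))
  cat("Rules:\n"); print(x$rules)
  print(x$evaluation)
  invisible(x)
}
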