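# Shared fixtures built in code: toy genomes and small cohort configs.

toy_layout <- function(bin_size = 1e6) {
  # chrT plays the trisomic-chromosome analog (10% of the genome).
  make_layout(
    data.frame(chrom = c("chrA", "chrB", "chrT"),
               length = c(6e7, 3e7, 1e7)),
    bin_size = bin_size
  )
}

toy_cohort_config <- function(n_euploid = 50, n_t21 = 5, reads = 2e5,
                              seed = 1, ...) {
  sim_config(n_euploid = n_euploid, n_t18 = 0, n_t21 = n_t21,
             reads_per_sample = reads, unique_map_rate = 1,
             t21_chrom = "chrT", seed = seed, ...)
}

# Profiles tibble from a plain per-chromosome statistic table.
profiles_from_stats <- function(df, mode = "count") {
  dplyr::mutate(df, count = statistic, mode = mode)[,
    c("sample", "chrom", "count", "statistic", "mode")]
}
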