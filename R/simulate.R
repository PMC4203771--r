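#' Configuration for the synthetic cfDNA cohort generator
#'
#' Defaults emulate a high-risk NIPT cohort sequenced at shallow depth on a
#' semiconductor platform: 155 pregnancies (139 euploid, 5 trisomy 18,
#' 11 trisomy 21), 6.5 million raw reads per sample of which 59% map
#' uniquely, read lengths around 150 bp, and a fetal fraction averaging 10%
#' with inter-individual spread. Counts are scalable down for desk-scale
#' testing; identical config + seed reproduces identical output.
#'
#' @param n_euploid,n_t18,n_t21 Cohort composition (sample counts).
#' @param reads_per_sample Raw reads per sample before mapping/QC.
#' @param unique_map_rate Fraction of reads that map uniquely.
#' @param fetal_fraction_mean,fetal_fraction_sd Mean and SD of the per-sample
#'   fetal fraction, drawn from a normal truncated to (0, 1).
#' @param read_length_mean,read_length_sd Read length distribution in bp
#'   (normal, truncated at 1).
#' @param duplicate_rate Fraction of emitted reads that are exact positional
#'   duplicates of another read.
#' @param gc_target_mean,gc_target_sd Per-read GC-fraction target
#'   distribution (clamped to \[0, 1\]).
#' @param quality List with `body_q`, `tail_q`, `tail_len`: per-base Phred
#'   scores are `body_q` except for the last `tail_len` bases which get
#'   `tail_q`, emulating 3' quality decay.
#' @param gc_bias Optional tibble `(chrom, bin, weight)` of multiplicative
#'   per-bin weights; `NULL` for uniform.
#' @param t18_chrom,t21_chrom Chromosome carrying the trisomy for T18/T21
#'   samples (override for toy genomes).
#' @param seed Integer RNG seed; recorded in all generator output.
#' @return A `sim_config` list.
#' @examples
#' sim_config(n_euploid = 20, n_t21 = 2, reads_per_sample = 1e5, seed = 7)
#' @export
sim_config <- function(n_euploid = 139, n_t18 = 5, n_t21 = 11,
                       reads_per_sample = 6.5e6, unique_map_rate = 0.59,
                       fetal_fraction_mean = 0.10, fetal_fraction_sd = 0.02,
                       read_length_mean = 150, read_length_sd = 15,
                       duplicate_rate = 0.05,
                       gc_target_mean = 0.40, gc_target_sd = 0.02,
                       quality = list(body_q = 32, tail_q = 12, tail_len = 5),
                       gc_bias = NULL,
                       t18_chrom = "chr18", t21_chrom = "chr21",
                       seed = 1L) {
  for (nm in c("n_euploid", "n_t18", "n_t21", "reads_per_sample")) {
    stopifnot_scalar_number(get(nm), nm, lo = 0)
  }
  for (nm in c("unique_map_rate", "fetal_fraction_mean", "duplicate_rate",
               "gc_target_mean")) {
    stopifnot_scalar_number(get(nm), nm, lo = 0, hi = 1)
  }
  stopifnot_scalar_number(fetal_fraction_sd, "fetal_fraction_sd", lo = 0)
  stopifnot_scalar_number(read_length_mean, "read_length_mean", lo = 1)
  stopifnot_scalar_number(read_length_sd, "read_length_sd", lo = 0)
  stopifnot_scalar_number(gc_target_sd, "gc_target_sd", lo = 0)
  stopifnot_scalar_number(seed, "seed")
  structure(
    list(
      n_euploid = as.integer(n_euploid), n_t18 = as.integer(n_t18),
      n_t21 = as.integer(n_t21),
      reads_per_sample = reads_per_sample,
      unique_map_rate = unique_map_rate,
      fetal_fraction_mean = fetal_fraction_mean,
      fetal_fraction_sd = fetal_fraction_sd,
      read_length_mean = read_length_mean, read_length_sd = read_length_sd,
      duplicate_rate = duplicate_rate,
      gc_target_mean = gc_target_mean, gc_target_sd = gc_target_sd,
      quality = quality, gc_bias = gc_bias,
      t18_chrom = t18_chrom, t21_chrom = t21_chrom,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Resolve the trisomic chromosome for a karyotype label, or NA for euploid.
trisomy_chrom_for <- function(karyotype, config = NULL, trisomy_chrom = NULL) {
  if (!is.null(trisomy_chrom)) return(trisomy_chrom)
  switch(karyotype,
    euploid = NA_character_,
    T18 = (config$t18_chrom %||% "chr18"),
    T21 = (config$t21_chrom %||% "chr21"),
    abort(sprintf("unknown karyotype label: %s", karyotype))
  )
}

# Per-bin sampling weights: bin width times optional GC weight, with the
# trisomic chromosome's bins scaled by (1 + f/2).
bin_weights <- function(layout, gc_bias = NULL, trisomy_chrom = NA,
                        fetal_fraction = 0) {
  bins <- layout_bins(layout)
  w <- bins$width
  if (!is.null(gc_bias)) {
    assert_columns(gc_bias, c("chrom", "bin", "weight"), "gc_bias")
    key <- paste(bins$chrom, bins$bin)
    gw <- setNames(gc_bias$weight, paste(gc_bias$chrom, gc_bias$bin))
    m <- gw[key]
    m[is.na(m)] <- 1
    w <- w * as.numeric(m)
  }
  if (!is.na(trisomy_chrom)) {
    if (!trisomy_chrom %in% bins$chrom) {
      abort(sprintf("trisomic chromosome %s not in layout", trisomy_chrom))
    }
    w[bins$chrom == trisomy_chrom] <- w[bins$chrom == trisomy_chrom] *
      (1 + fetal_fraction / 2)
  }
  bins$weight <- w / sum(w)
  bins
}

#' Expected per-chromosome read proportions under the dosage model
#'
#' The plasma cfDNA pool mixes a maternal (euploid) and a fetal component at
#' fetal fraction `f`. A chromosome present in three fetal copies contributes
#' `(1 - f) + f * 3/2 = 1 + f/2` times its euploid share, so the trisomic
#' chromosome's length-proportional weight is multiplied by `(1 + f/2)`
#' before renormalisation. Euploid samples are unaffected by `f`.
#'
#' @param layout A [make_layout()] object.
#' @param karyotype One of `"euploid"`, `"T18"`, `"T21"`.
#' @param fetal_fraction Fetal fraction in \[0, 1\].
#' @param trisomy_chrom Optional chromosome name overriding the default
#'   chr18/chr21 mapping (for toy genomes).
#' @param gc_bias Optional per-bin weights as in [sim_config()].
#' @return A tibble `(chrom, proportion)` summing to 1.
#' @examples
#' ly <- make_layout(data.frame(chrom = c("chrA", "chrB"), length = c(1e6, 1e6)))
#' expected_chrom_proportions(ly, "T21", 0.10, trisomy_chrom = "chrB")
#' @export
expected_chrom_proportions <- function(layout, karyotype, fetal_fraction,
                                       trisomy_chrom = NULL, gc_bias = NULL) {
  stopifnot_scalar_number(fetal_fraction, "fetal_fraction", lo = 0, hi = 1)
  tc <- trisomy_chrom_for(karyotype, trisomy_chrom = trisomy_chrom)
  bins <- bin_weights(layout, gc_bias, tc, fetal_fraction)
  bins %>%
    group_by(.data$chrom) %>%
    summarise(proportion = sum(.data$weight), .groups = "drop") %>%
    arrange(match(.data$chrom, layout$chromosomes$chrom))
}

# Sample sheet implied by a config: ids, karyotypes, trisomic chromosome.
cohort_sheet <- function(config) {
  tibble(
    sample = c(sprintf("eu_%03d", seq_len(config$n_euploid)),
               sprintf("t18_%02d", seq_len(config$n_t18)),
               sprintf("t21_%02d", seq_len(config$n_t21))),
    karyotype = c(rep("euploid", config$n_euploid),
                  rep("T18", config$n_t18),
                  rep("T21", config$n_t21))
  )
}

#' Simulate per-bin read counts for a cohort
#'
#' The primary desk-scale path: for each sample a fetal fraction is drawn
#' from the truncated normal in the config, expected per-bin proportions are
#' computed under the dosage model, and the sample's retained read total
#' (`reads_per_sample * unique_map_rate`, rounded) is distributed over bins
#' as a single multinomial draw.
#'
#' @param config A [sim_config()].
#' @param layout A [make_layout()] object.
#' @return A list with `counts` (tibble `sample, chrom, bin, count`) and
#'   `truth` (tibble `sample, karyotype, fetal_fraction`); the config seed is
#'   attached as attribute `seed`.
#' @examples
#' ly <- make_layout(data.frame(chrom = c("chrA", "chrB"), length = c(6e6, 3e6)))
#' cohort <- simulate_bin_counts(
#'   sim_config(n_euploid = 5, n_t18 = 0, n_t21 = 1, reads_per_sample = 1e4,
#'              t21_chrom = "chrB", seed = 1), ly)
#' dplyr::count(cohort$counts, sample, wt = count)
#' @export
simulate_bin_counts <- function(config, layout) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "genome_layout"))
  sheet <- cohort_sheet(config)
  retained <- as.integer(round(config$reads_per_sample * config$unique_map_rate))
  if (retained == 0) warning("reads_per_sample * unique_map_rate rounds to 0; all counts are zero")
  base_bins <- bin_weights(layout, config$gc_bias)
  nb <- nrow(base_bins)

  out <- local_seed(config$seed, {
    ff <- rtruncnorm(nrow(sheet), config$fetal_fraction_mean,
                     config$fetal_fraction_sd, lo = 0, hi = 1)
    # exact 0/1 would be outside the open interval; nudge inside
    ff <- pmin(pmax(ff, 1e-6), 1 - 1e-6)
    counts <- matrix(0L, nrow = nb, ncol = nrow(sheet))
    for (i in seq_len(nrow(sheet))) {
      tc <- trisomy_chrom_for(sheet$karyotype[i], config)
      w <- base_bins$weight
      if (!is.na(tc)) {
        sel <- base_bins$chrom == tc
        if (!any(sel)) abort(sprintf("trisomic chromosome %s not in layout", tc))
        w[sel] <- w[sel] * (1 + ff[i] / 2)
        w <- w / sum(w)
      }
      if (retained > 0) counts[, i] <- rmultinom(1, retained, w)[, 1]
    }
    list(ff = ff, counts = counts)
  })

  counts_tbl <- tibble(
    sample = rep(sheet$sample, each = nb),
    chrom = rep(base_bins$chrom, times = nrow(sheet)),
    bin = rep(base_bins$bin, times = nrow(sheet)),
    count = as.integer(out$counts)
  )
  truth <- sheet %>% mutate(fetal_fraction = out$ff)
  structure(list(counts = counts_tbl, truth = truth), seed = config$seed)
}

# Per-base quality vector under the config's 3'-decay model.
read_qualities <- function(len, quality) {
  q <- rep(quality$body_q, len)
  tl <- min(quality$tail_len, len)
  if (tl > 0) q[(len - tl + 1):len] <- quality$tail_q
  q
}

#' Simulate read-level data (FASTQ-style) with truth alignments
#'
#' Exercises the QC stage end-to-end at small scale: reads get lengths from a
#' truncated normal, per-base Phred qualities with a 3' low-quality tail,
#' base composition drawn to a per-read GC target, a `duplicate_rate` share
#' of exact positional duplicates, and a `1 - unique_map_rate` share flagged
#' non-unique in the truth table. Positions follow the same dosage model as
#' [simulate_bin_counts()].
#'
#' @inheritParams simulate_bin_counts
#' @return A list with `reads` (tibble `sample, read_id, bases, qual`; `qual`
#'   is Phred+33 encoded) and `truth` (tibble `sample, read_id, karyotype,
#'   fetal_fraction, chrom, start, strand, unique, duplicate_of`).
#' @export
simulate_reads <- function(config, layout) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "genome_layout"))
  sheet <- cohort_sheet(config)
  n <- as.integer(config$reads_per_sample)
  if (n == 0) warning("reads_per_sample is 0; no reads generated")

  sim_one <- function(sample_id, karyotype, f) {
    n_dup <- as.integer(round(config$duplicate_rate * n))
    n_orig <- n - n_dup
    props <- expected_chrom_proportions(layout, karyotype, f,
                                        gc_bias = config$gc_bias,
                                        trisomy_chrom = trisomy_chrom_for(karyotype, config))
    chrom <- sample(props$chrom, n_orig, replace = TRUE, prob = props$proportion)
    len_chr <- chrom_length(layout, chrom)
    start <- floor(runif(n_orig) * len_chr)
    strand <- sample(c("+", "-"), n_orig, replace = TRUE)
    unique_flag <- runif(n_orig) < config$unique_map_rate
    rl <- pmax(1L, as.integer(round(rnorm(n_orig, config$read_length_mean,
                                          config$read_length_sd))))
    gc <- pmin(pmax(rnorm(n_orig, config$gc_target_mean, config$gc_target_sd), 0), 1)
    bases <- purrr::map2_chr(rl, gc, function(L, g) {
      paste(sample(c("G", "C", "A", "T"), L, replace = TRUE,
                   prob = c(g / 2, g / 2, (1 - g) / 2, (1 - g) / 2)),
            collapse = "")
    })
    qual <- purrr::map_chr(rl, function(L) {
      intToUtf8(read_qualities(L, config$quality) + 33L)
    })
    orig <- tibble(
      sample = sample_id,
      read_id = sprintf("%s_r%06d", sample_id, seq_len(n_orig)),
      bases = bases, qual = qual, chrom = chrom, start = start,
      strand = strand, unique = unique_flag, duplicate_of = NA_character_
    )
    if (n_dup > 0 && n_orig > 0) {
      src <- sample(n_orig, n_dup, replace = TRUE)
      dup <- orig[src, ] %>%
        mutate(duplicate_of = .data$read_id,
               read_id = sprintf("%s_r%06d", sample_id, n_orig + seq_len(n_dup)))
      orig <- bind_rows(orig, dup)
    }
    orig
  }

  all <- local_seed(config$seed, {
    ff <- rtruncnorm(nrow(sheet), config$fetal_fraction_mean,
                     config$fetal_fraction_sd, lo = 0, hi = 1)
    ff <- pmin(pmax(ff, 1e-6), 1 - 1e-6)
    rows <- purrr::pmap(list(sheet$sample, sheet$karyotype, ff), sim_one)
    list(ff = ff, tbl = bind_rows(rows))
  })
  truth_meta <- sheet %>% mutate(fetal_fraction = all$ff)
  tbl <- all$tbl
  structure(
    list(
      reads = tbl %>% select("sample", "read_id", "bases", "qual"),
      truth = tbl %>%
        select("sample", "read_id", "chrom", "start", "strand",
               "unique", "duplicate_of") %>%
        left_join(truth_meta, by = "sample") %>%
        select("sample", "read_id", "karyotype", "fetal_fraction",
               "chrom", "start", "strand", "unique", "duplicate_of")
    ),
    seed = config$seed
  )
}
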