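phred33 <- function(q) intToUtf8(q + 33L)

test_that("3' trimming removes trailing bases at or below the quality threshold", {
  reads <- tibble::tibble(
    bases = c("ACGT", "ACGT", "AC", "ACGT"),
    qual = c(phred33(c(30, 30, 30, 30)),  # untouched
             phred33(c(30, 30, 10, 10)),  # two-base tail trimmed
             phred33(c(10, 10)),          # trimmed to empty
             phred33(c(10, 30, 10, 30)))  # internal low-quality base kept
  )
  out <- trim_3prime(reads, 15)
  expect_equal(out$bases, c("ACGT", "AC", "", "ACGT"))
  expect_equal(nchar(out$qual), nchar(out$bases))
  # quality exactly at threshold is trimmed (strict > survives)
  at <- trim_3prime(tibble::tibble(bases = "AAA", qual = phred33(c(30, 30, 15))), 15)
  expect_equal(at$bases, "AA")
})

test_that("length filter removes reads under 50 bp and keeps exactly 50", {
  reads <- tibble::tibble(bases = strrep("A", c(50, 49, 0, 120)))
  expect_equal(passes_length(reads, 50), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("GC window is inclusive and ambiguous bases count as non-GC", {
  mk <- function(gc_n, total, pad = "A") {
    paste0(strrep("G", gc_n), strrep(pad, total - gc_n))
  }
  reads <- tibble::tibble(bases = c(
    mk(16, 40),   # 40% -> in
    mk(20, 40),   # 50% -> out
    mk(14, 40),   # 35% boundary -> in
    mk(18, 40),   # 45% boundary -> in
    mk(16, 40, pad = "N")  # N's are non-GC: still 40%
  ))
  expect_equal(passes_gc(reads, 0.35, 0.45), c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_error(passes_gc(tibble::tibble(bases = "")), "empty")
})

test_that("duplicate removal keys on (chrom, start, strand), deterministically and idempotently", {
  aln <- tibble::tibble(
    read_id = c("r3", "r1", "r2", "r4", "r5"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(100, 100, 100, 100, 100),
    strand = c("+", "+", "-", "-", "+")
  )
  out <- remove_duplicates(aln)
  # one record per strand on chr1, untouched chr2; first read id by sort order
  expect_equal(nrow(out), 3)
  expect_setequal(out$read_id, c("r1", "r2", "r5"))
  expect_identical(remove_duplicates(out), out)
  expect_lte(nrow(remove_duplicates(aln)), nrow(aln))
})

test_that("uniqueness predicate: unmapped/secondary/supplementary/mapq-0 fail, primary mapq>0 passes", {
  aln <- tibble::tibble(
    read_id = paste0("r", 1:5),
    flag = c(4L, 0L, 256L, 2048L, 16L),
    mapq = c(37L, 37L, 37L, 37L, 0L)
  )
  expect_equal(is_uniquely_mapped(aln), c(FALSE, TRUE, FALSE, FALSE, FALSE))
  # truth tables carry a logical `unique` column used directly
  expect_equal(is_uniquely_mapped(tibble::tibble(unique = c(TRUE, FALSE))),
               c(TRUE, FALSE))
  # and the rule is swappable
  expect_equal(is_uniquely_mapped(aln, function(a) a$mapq >= 37),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("QC pipeline equals brute-force predicate application on generator truth", {
  ly <- toy_layout()
  cfg <- sim_config(n_euploid = 3, n_t18 = 0, n_t21 = 1,
                    reads_per_sample = 800, unique_map_rate = 0.6,
                    duplicate_rate = 0.1, read_length_mean = 70,
                    read_length_sd = 12, t21_chrom = "chrT",
                    quality = list(body_q = 30, tail_q = 10, tail_len = 8),
                    seed = 17)
  rr <- simulate_reads(cfg, ly)
  cfgqc <- qc_config()
  res <- qc_reads(rr$reads, rr$truth, cfgqc)

  # independent brute force over the raw tables
  q <- lapply(rr$reads$qual, function(s) utf8ToInt(s) - 33L)
  keep_at <- vapply(q, function(qq) {
    ok <- which(qq > cfgqc$quality_threshold)
    if (length(ok)) max(ok) else 0L
  }, integer(1))
  seqs <- substr(rr$reads$bases, 1, keep_at)
  len_ok <- nchar(seqs) >= cfgqc$min_length
  gc <- ifelse(nchar(seqs) > 0,
               nchar(gsub("[^GC]", "", seqs)) / nchar(seqs), NA)
  gc_ok <- !is.na(gc) & len_ok & gc >= cfgqc$gc_min & gc <= cfgqc$gc_max
  surviving <- rr$reads$read_id[gc_ok]
  tr <- rr$truth[rr$truth$read_id %in% surviving & rr$truth$unique, ]
  brute_n <- nrow(unique(tr[, c("sample", "chrom", "start", "strand")]))

  expect_equal(nrow(res$alignments), brute_n)
  # attrition report is internally consistent
  expect_equal(res$report$n_in[-1], res$report$n_out[-nrow(res$report)])
  expect_equal(res$report$n_out, res$report$n_in - res$report$n_removed)
})

test_that("SAM text round-trips through the alignment reader with 0-based starts", {
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrA\tLN:60000000",
    "@SQ\tSN:chrT\tLN:10000000",
    # POS is 1-based in SAM; flag 16 = reverse strand; flag 4 = unmapped
    "r1\t0\tchrA\t1\t37\t4M\t*\t0\t0\tACGT\tIIII",
    "r2\t16\tchrT\t300001\t37\t4M\t*\t0\t0\tACGT\tIIII",
    "r3\t0\tchrA\t100\t0\t4M\t*\t0\t0\tACGT\tIIII",
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII"
  )
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  aln <- read_alignments_sam(path)
  expect_equal(nrow(aln), 4)
  r1 <- aln[aln$read_id == "r1", ]
  expect_equal(r1$start, 0)        # SAM POS 1 -> 0-based 0
  r2 <- aln[aln$read_id == "r2", ]
  expect_equal(r2$start, 300000)
  expect_equal(r2$strand, "-")
  expect_equal(is_uniquely_mapped(aln[order(aln$read_id), ]),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("FASTQ writing and reading round-trips reads", {
  reads <- tibble::tibble(
    read_id = c("a", "b"),
    bases = c("ACGTACGT", "GGGCCC"),
    qual = c("IIIIIIII", "IIII++")
  )
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(as.data.frame(back), as.data.frame(reads))
})
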