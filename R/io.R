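#' Read alignments from a SAM file
#'
#' Parses SAM text via Rsamtools (conversion to BAM in a temporary file,
#' then `scanBam`). The file must carry `@SQ` header lines. SAM's 1-based
#' `POS` is converted to the package's 0-based `start` at this single point.
#'
#' @param path Path to a SAM (or BAM) file.
#' @return Tibble `(read_id, flag, chrom, start, strand, mapq)` with one row
#'   per alignment record; unmapped records keep `NA` coordinates.
#' @export
read_alignments_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  tibble(
    read_id = res$qname,
    flag = as.integer(res$flag),
    chrom = as.character(res$rname),
    start = as.numeric(res$pos) - 1,
    strand = as.character(res$strand),
    mapq = as.integer(res$mapq)
  )
}

#' Read and write FASTQ read tables
#'
#' Standard 4-line FASTQ records with Phred+33 qualities, via Biostrings.
#'
#' @param path FASTQ file path.
#' @return `read_fastq()`: tibble `(read_id, bases, qual)`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropped metadata columns when pairing sequences
  # with their qualities; nothing of ours is lost
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(
    read_id = names(x),
    bases = as.character(x),
    qual = as.character(Biostrings::quality(x))
  )
}

#' @rdname read_fastq
#' @param reads Tibble with `read_id`, `bases`, `qual` columns.
#' @return `write_fastq()`: `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  assert_columns(reads, c("read_id", "bases", "qual"), "reads")
  dna <- Biostrings::DNAStringSet(reads$bases)
  names(dna) <- reads$read_id
  Biostrings::writeXStringSet(
    dna, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# Write a TSV with a self-describing comment header (seed, mode, ...).
write_stage_tsv <- function(df, path, meta = character()) {
  header <- sprintf("# niptr %s", paste(names(meta), meta, sep = "=",
                                        collapse = " "))
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

# Read a stage TSV, skipping '#' comment headers.
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
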