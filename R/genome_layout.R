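#' Define a genome layout with a fixed-width bin grid
#'
#' A genome layout is the coordinate system every counting stage shares:
#' an ordered set of chromosomes with lengths, a fixed bin width (300 kb by
#' default, the resolution used for cfDNA aneuploidy screening), and the
#' split into autosomes and sex chromosomes. Bins are half-open
#' `[i * bin_size, (i + 1) * bin_size)` in 0-based coordinates; the last bin
#' of each chromosome may be partial.
#'
#' @param chromosomes A data frame whose first two columns are chromosome
#'   name and length in base pairs (extra columns are ignored).
#' @param bin_size Bin width in base pairs (default 300,000).
#' @param sex_chromosomes Character vector of chromosome names treated as
#'   sex chromosomes; defaults to whichever of `"chrX"`/`"chrY"` are present.
#'   All remaining chromosomes are autosomes.
#' @return A `genome_layout` object: a list with `chromosomes` (tibble of
#'   `chrom`, `length`, `n_bins`), `bin_size`, `autosomes`, `sex_chromosomes`.
#' @examples
#' make_layout(data.frame(chrom = c("chrA", "chrB"), length = c(9e5, 1e5)),
#'             bin_size = 3e5)
#' @export
make_layout <- function(chromosomes, bin_size = 300000,
                        sex_chromosomes = NULL) {
  stopifnot_scalar_number(bin_size, "bin_size", lo = 1)
  df <- as_tibble(chromosomes)
  if (ncol(df) < 2) abort("`chromosomes` needs columns: name, length")
  df <- tibble(chrom = as.character(df[[1]]), length = as.numeric(df[[2]]))
  if (anyDuplicated(df$chrom)) abort("duplicate chromosome name in layout")
  if (any(is.na(df$length)) || any(df$length <= 0)) {
    abort("all chromosome lengths must be positive")
  }
  sex <- sex_chromosomes %||% intersect(c("chrX", "chrY"), df$chrom)
  if (!all(sex %in% df$chrom)) abort("sex_chromosomes not all present in layout")
  df$n_bins <- as.integer(ceiling(df$length / bin_size))
  structure(
    list(
      chromosomes = df,
      bin_size = as.numeric(bin_size),
      autosomes = setdiff(df$chrom, sex),
      sex_chromosomes = sex
    ),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf(
    "<genome_layout> %d chromosomes (%d autosomes), bin size %s bp, %d bins\n",
    nrow(x$chromosomes), length(x$autosomes),
    format(x$bin_size, big.mark = ","), sum(x$chromosomes$n_bins)
  ))
  print(x$chromosomes, ...)
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chromosomes$chrom)
  layout$chromosomes$length[i]
}

#' Map genomic positions to bin indices
#'
#' Bins are half-open and 0-based: position `p` on a chromosome falls in bin
#' `floor(p / bin_size)`. Reads are assigned to exactly one bin by their
#' 5'-most mapped coordinate.
#'
#' @param layout A [make_layout()] object.
#' @param chrom Character vector of chromosome names.
#' @param position Numeric vector of 0-based base coordinates (recycled
#'   against `chrom`).
#' @return Integer vector of 0-based bin indices.
#' @examples
#' ly <- make_layout(data.frame(chrom = "chrA", length = 9e5), bin_size = 3e5)
#' assign_bin(ly, "chrA", c(0, 299999, 300000))
#' @export
assign_bin <- function(layout, chrom, position) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- max(length(chrom), length(position))
  chrom <- rep_len(chrom, n)
  position <- rep_len(position, n)
  len <- chrom_length(layout, chrom)
  if (anyNA(len)) {
    abort(sprintf("unknown chromosome: %s",
                  paste(unique(chrom[is.na(len)]), collapse = ", ")))
  }
  if (any(position < 0) || any(position >= len)) {
    abort("position out of range for its chromosome (0-based, < length)")
  }
  as.integer(floor(position / layout$bin_size))
}

#' Enumerate the bin grid of a layout
#'
#' @param layout A [make_layout()] object.
#' @return A tibble with one row per bin: `chrom`, `bin` (0-based), `start`,
#'   `end` (half-open) and `width` in base pairs.
#' @export
layout_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  ch <- layout$chromosomes
  purrr::map2_dfr(ch$chrom, ch$length, function(cm, len) {
    nb <- ceiling(len / layout$bin_size)
    start <- (seq_len(nb) - 1) * layout$bin_size
    tibble(
      chrom = cm,
      bin = seq_len(nb) - 1L,
      start = start,
      end = pmin(start + layout$bin_size, len),
      width = pmin(start + layout$bin_size, len) - start
    )
  })
}

#' Read a genome layout from a two-column TSV
#'
#' Expects columns chromosome name and length in bp; a header line and `#`
#' comments are tolerated.
#'
#' @inheritParams make_layout
#' @param path Path to the TSV file.
#' @return A `genome_layout`.
#' @export
read_layout <- function(path, bin_size = 300000, sex_chromosomes = NULL) {
  df <- readr::read_tsv(path, col_names = c("chrom", "length"), comment = "#",
                        show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df$length[1])))) {
    df <- df[-1, , drop = FALSE]  # header line
  }
  df$length <- as.numeric(df$length)
  make_layout(df, bin_size = bin_size, sex_chromosomes = sex_chromosomes)
}

# hg19 (GRCh37) primary chromosome lengths, chr1-22 + X/Y; unplaced and alt
# contigs are deliberately excluded from the default layout.
HG19_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
)

#' The hg19 genome layout
#'
#' Primary assembly chromosomes chr1-22, chrX and chrY of hg19/GRCh37 with a
#' 300 kb default bin grid; chrX/chrY are flagged as sex chromosomes.
#'
#' @inheritParams make_layout
#' @param include_sex Keep chrX/chrY in the layout (default `TRUE`; they are
#'   excluded from autosomal denominators regardless).
#' @return A `genome_layout`.
#' @examples
#' hg19_layout()
#' @export
hg19_layout <- function(bin_size = 300000, include_sex = TRUE) {
  lens <- HG19_LENGTHS
  if (!include_sex) lens <- lens[!names(lens) %in% c("chrX", "chrY")]
  make_layout(tibble(chrom = names(lens), length = unname(lens)),
              bin_size = bin_size)
}
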