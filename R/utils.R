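# Internal helpers shared across modules. Coordinates are 0-based half-open
# (BED convention) everywhere inside the package.

# Midpoint of [start, end): start + floor(length / 2).
interval_mid <- function(start, end) {
  start + (end - start) %/% 2L
}

check_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame with chrom/start/end columns.", what))
  }
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.", what,
                  paste(missing, collapse = ", ")))
  }
  bad <- which(!(x$start < x$end))
  if (length(bad)) {
    abort(sprintf("`%s` has start >= end at row(s) %s.", what,
                  paste(head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}

# tibble of chrom/start/end -> GRanges (1-based closed internally), strand
# ignored so overlap queries are purely positional.
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# For each row of `x`, does it overlap any interval in `y`?
overlap_any <- function(x, y) {
  if (nrow(x) == 0L) return(logical(0))
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges0(x), as_granges0(y),
                                 ignore.strand = TRUE)) > 0L
}

# DNA alphabet machinery -----------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

# Character string -> integer codes A/C/G/T -> 1..4, anything else (N) -> 5.
dna_codes <- function(seq) {
  lut <- rep(5L, 128L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(seq)]
}

codes_to_dna <- function(codes) {
  intToUtf8(utf8ToInt("ACGTN")[codes])
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# substring extraction on a named character genome, 0-based half-open coords
genome_slice <- function(genome, chrom, start, end) {
  if (is(genome, "DNAStringSet")) genome <- setNames(as.character(genome), names(genome))
  bad <- !chrom %in% names(genome)
  if (any(bad)) {
    abort(sprintf("Chromosome(s) not in genome: %s.",
                  paste(unique(chrom[bad]), collapse = ", ")))
  }
  substring(genome[chrom], start + 1L, end)
}

genome_lengths <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else {
    vapply(genome, nchar, integer(1))
  }
}
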