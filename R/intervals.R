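#' Read a BED-like file into a tibble of genomic intervals
#'
#' Parses tab-separated BED3/BED6 (and BED with extra columns) into a tibble
#' with 0-based half-open coordinates. Malformed lines (non-integer
#' coordinates, `start >= end`, fewer than three fields) raise an error naming
#' the offending line number.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @param dialect One of `"auto"`, `"bed3"`, `"bed6"`, `"extra"`. `"auto"`
#'   keeps whatever columns are present; `"bed3"`/`"bed6"` check the column
#'   count. Extra columns beyond the sixth are preserved as `extra1`,
#'   `extra2`, ... character columns.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand` plus any extra columns, in file order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t300\tpk1\t0\t+", f)
#' read_bed(f)
#' @export
read_bed <- function(path, dialect = c("auto", "bed3", "bed6", "extra")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("Line %d has fewer than 3 tab-separated fields.",
                  which(nf < 3L)[1]))
  }
  if (dialect == "bed3" && any(nf != 3L)) {
    abort(sprintf("Line %d is not BED3 (expected 3 fields, got %d).",
                  which(nf != 3L)[1], nf[which(nf != 3L)[1]]))
  }
  if (dialect == "bed6" && any(nf < 6L)) {
    abort(sprintf("Line %d is not BED6 (expected >= 6 fields).",
                  which(nf < 6L)[1]))
  }
  ncol <- min(nf)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- get(1)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("Line %d has non-integer coordinates.", bad[1]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    abort(sprintf("Line %d has start >= end (%d >= %d).",
                  bad[1], start[bad[1]], end[bad[1]]))
  }
  if (any(!nzchar(chrom))) {
    abort(sprintf("Line %d has an empty chromosome name.",
                  which(!nzchar(chrom))[1]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (ncol >= 4L) out$name <- get(4)
  if (ncol >= 5L) out$score <- get(5)
  if (ncol >= 6L) {
    strand <- get(6)
    ok <- strand %in% c("+", "-", ".")
    if (any(!ok)) {
      abort(sprintf("Line %d has invalid strand '%s'.", which(!ok)[1],
                    strand[which(!ok)[1]]))
    }
    out$strand <- strand
  }
  if (ncol > 6L) {
    for (i in 7:ncol) out[[paste0("extra", i - 6L)]] <- get(i)
  }
  out
}

#' Write intervals to a BED file
#'
#' Writes `chrom`, `start`, `end` and, if present, `name`, `score`, `strand`
#' and any further columns as tab-separated BED (no header). Round-trips with
#' [read_bed()] bit-exactly on coordinates.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: fill gaps so later columns stay in place
  if ("strand" %in% cols) {
    if (!"name" %in% cols) x$name <- "."
    if (!"score" %in% cols) x$score <- 0
    cols <- c("chrom", "start", "end", "name", "score", "strand")
  } else if ("score" %in% cols && !"name" %in% cols) {
    x$name <- "."
    cols <- c("chrom", "start", "end", "name", "score")
  }
  extra <- grep("^extra[0-9]+$", names(x), value = TRUE)
  out <- as.data.frame(x[, c(cols, extra), drop = FALSE])
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Normalize ChIP-seq peaks to a fixed length about their centers
#'
#' Re-centers every peak on its midpoint and extends/trims it to
#' `target_length` bp, the standard pre-processing step before motif scanning
#' so every peak contributes an equal-width window. Peaks are clipped at
#' coordinate 0 (and may then be shorter than the target); no clipping is done
#' at chromosome ends unless `chrom_lengths` is supplied.
#'
#' @param peaks A tibble of intervals (`chrom`, `start`, `end`, ...). Extra
#'   columns are carried through.
#' @param target_length Desired peak length in bp (default 200).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   right-edge clipping.
#' @return The input tibble with `start`/`end` replaced by the normalized
#'   coordinates.
#' @examples
#' normalize_peaks(tibble::tibble(chrom = "chr1", start = 100, end = 400))
#' @export
normalize_peaks <- function(peaks, target_length = 200L, chrom_lengths = NULL) {
  check_intervals(peaks, "peaks")
  if (target_length < 1L) abort("`target_length` must be >= 1.")
  mid <- interval_mid(peaks$start, peaks$end)
  half <- target_length %/% 2L
  # ideal window is [mid - half, mid - half + target_length); clip at 0
  lo <- mid - half
  start <- pmax(0L, as.integer(lo))
  end <- as.integer(lo + target_length)
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[peaks$chrom])
    end <- pmin(end, as.integer(lim))
  }
  peaks$start <- start
  peaks$end <- end
  peaks
}

#' Pairwise interval predicates
#'
#' `overlaps()` tests whether intervals overlap by at least 1 bp;
#' `center_within()` tests whether interval midpoints are within `margin` bp
#' of each other (the "peak center within +/- 200 bp of a site" rule used for
#' co-factor overlap). Both are vectorized over parallel rows and require the
#' same chromosome.
#'
#' @param a,b Data frames of intervals with equal row counts (or one row,
#'   recycled).
#' @param margin Maximum midpoint distance in bp for `center_within()`.
#' @return A logical vector.
#' @export
overlaps <- function(a, b) {
  check_intervals(a, "a"); check_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), ]
  b <- b[rep_len(seq_len(nrow(b)), n), ]
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' @rdname overlaps
#' @export
center_within <- function(a, b, margin = 200L) {
  check_intervals(a, "a"); check_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), ]
  b <- b[rep_len(seq_len(nrow(b)), n), ]
  a$chrom == b$chrom &
    abs(interval_mid(a$start, a$end) - interval_mid(b$start, b$end)) <= margin
}
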