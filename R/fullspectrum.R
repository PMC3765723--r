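#' Extract motif-oriented extended sequences around binding sites
#'
#' Pulls the genomic sequence of each site plus `flank` bp on each side, with
#' minus-strand sites reverse-complemented so the motif always reads on the
#' forward side and the core sits at a fixed offset (`flank`). Sites too
#' close to a contig edge are skipped with a warning.
#'
#' @param sites Tibble of site intervals with `strand`.
#' @param genome Named character vector or `DNAStringSet`.
#' @param flank Flank width in bp on each side (default 30).
#' @return A character vector of sequences, all of length
#'   `core + 2 * flank`, named by `chrom:start-end(strand)`.
#' @export
extract_extended_sequences <- function(sites, genome, flank = 30L) {
  check_intervals(sites, "sites")
  lens <- genome_lengths(genome)
  lo <- sites$start - flank
  hi <- sites$end + flank
  ok <- lo >= 0L & hi <= lens[sites$chrom]
  if (any(!ok)) {
    warn(sprintf("%d site(s) too close to a contig edge were skipped.",
                 sum(!ok)))
  }
  s <- sites[ok, , drop = FALSE]
  seqs <- genome_slice(genome, s$chrom, s$start - flank, s$end + flank)
  minus <- s$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  setNames(seqs, sprintf("%s:%d-%d(%s)", s$chrom, s$start, s$end, s$strand))
}

kmer_index <- function(codes_mat, k) {
  # codes_mat: n x k integer codes (1..4); returns 1-based k-mer index,
  # NA if any code is 5 (N)
  idx <- rep(0L, nrow(codes_mat))
  bad <- rep(FALSE, nrow(codes_mat))
  for (j in seq_len(k)) {
    cj <- codes_mat[, j]
    bad <- bad | cj > 4L
    idx <- idx * 4L + (cj - 1L)
  }
  idx[bad] <- NA_integer_
  idx + 1L
}

all_kmers <- function(k) {
  g <- do.call(expand.grid, rep(list(DNA_BASES), k))
  # first base varies slowest to match kmer_index ordering
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
}

#' Positional k-mer presence counts over extended sequences
#'
#' At each of the `L - k + 1` start positions of the extended window, counts
#' the number of sequences in which each of the `4^k` k-mers occurs (per
#' sequence 0/1 at each position, since one position holds exactly one
#' k-mer). For the default 30 + 16 + 30 geometry and k = 5 this is the
#' 72-position x 1,024-k-mer count table from which composite flanking motifs
#' are built.
#'
#' @param seqs Character vector of equal-length extended sequences.
#' @param k Word length (default 5).
#' @return An object of class `kmer_counts`: list with `counts`
#'   (positions x 4^k integer matrix, rows = 0-based start offsets), `k`,
#'   `n_seq`, `length`.
#' @export
positional_kmer_counts <- function(seqs, k = 5L) {
  if (length(seqs) == 0L) abort("`seqs` must be non-empty.")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort("All sequences must have the same length.")
  if (L < k) abort("Sequences shorter than `k`.")
  n_pos <- L - k + 1L
  codes <- matrix(dna_codes(paste(seqs, collapse = "")), nrow = length(seqs),
                  ncol = L, byrow = TRUE)
  counts <- matrix(0L, nrow = n_pos, ncol = 4L^k)
  for (p in seq_len(n_pos)) {
    idx <- kmer_index(codes[, p:(p + k - 1L), drop = FALSE], k)
    tab <- tabulate(idx, nbins = 4L^k)
    counts[p, ] <- tab
  }
  colnames(counts) <- all_kmers(k)
  structure(list(counts = counts, k = as.integer(k),
                 n_seq = length(seqs), length = as.integer(L)),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("<kmer_counts> %d positions x %d %d-mers over %d sequences\n",
              nrow(x$counts), ncol(x$counts), x$k, x$n_seq))
  invisible(x)
}

#' @export
tidy.kmer_counts <- function(x, ...) {
  tibble(
    position = rep(seq_len(nrow(x$counts)) - 1L, times = ncol(x$counts)),
    kmer = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
}

side_positions <- function(side, flank, core, k, n_pos) {
  # 0-based window start offsets belonging to each side; a k-mer is assigned
  # to the side holding its start
  if (side == "left") {
    0:(flank - 1L)
  } else {
    (flank + core):(n_pos - 1L)
  }
}

#' Build a composite flanking motif from ranked positional k-mers
#'
#' Restricts the count table to the chosen flank, ranks k-mers by their
#' maximum single-position count within that flank, takes the `top_n`, and
#' accumulates each one's positional counts into per-offset base weights
#' (count x indicator of the k-mer's base at the covered offset); columns
#' are then normalized to probabilities. The result is the data-driven
#' composite motif for that side of the core (the 33/34-mer-style upstream
#' composite or the 20/26-mer-style downstream one).
#'
#' @param counts A [positional_kmer_counts()] result.
#' @param side `"left"` or `"right"` of the core motif.
#' @param top_n Number of top-ranked k-mers to combine (default 50).
#' @param flank,core Window geometry in bp (defaults 30 and 16); must match
#'   the geometry used to build the sequences.
#' @return An object of class `composite_motif`: `probs` (width x 4 column-
#'   normalized), `offsets` (0-based offsets in the extended window covered
#'   by the matrix), `side`, `kmers` (tibble of contributing k-mers with their
#'   ranking statistic).
#' @export
build_composite_motif <- function(counts, side = c("left", "right"),
                                  top_n = 50L, flank = 30L, core = 16L) {
  side <- match.arg(side)
  k <- counts$k
  n_pos <- nrow(counts$counts)
  if (n_pos != flank + flank + core - k + 1L) {
    abort("Count table geometry does not match `flank`/`core`/`k`.")
  }
  pos <- side_positions(side, flank, core, k, n_pos)
  sub <- counts$counts[pos + 1L, , drop = FALSE]
  stat <- apply(sub, 2, max)
  present <- which(stat > 0L)
  if (length(present) < top_n) {
    warn(sprintf("Only %d distinct k-mers present on the %s side (top_n = %d); using all.",
                 length(present), side, top_n))
  }
  top <- present[order(stat[present], decreasing = TRUE)][seq_len(min(top_n, length(present)))]
  off_range <- range(pos) + c(0L, k - 1L)
  width <- diff(off_range) + 1L
  W <- matrix(0, nrow = width, ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  kmer_strings <- colnames(counts$counts)[top]
  for (i in seq_along(top)) {
    km_codes <- dna_codes(kmer_strings[i])
    cnts <- sub[, top[i]]
    for (pi in which(cnts > 0L)) {
      p0 <- pos[pi]                       # 0-based start offset in window
      rows <- (p0 - off_range[1]) + seq_len(k)
      W[cbind(rows, km_codes)] <- W[cbind(rows, km_codes)] + cnts[pi]
    }
  }
  cs <- rowSums(W)
  zero <- cs == 0
  if (any(zero)) W[zero, ] <- 0.25
  probs <- W / ifelse(rowSums(W) == 0, 1, rowSums(W))
  structure(
    list(probs = probs, offsets = off_range[1]:off_range[2], side = side,
         kmers = tibble(kmer = kmer_strings, max_count = as.integer(stat[top])),
         flank = as.integer(flank), core = as.integer(core)),
    class = "composite_motif")
}

#' @export
print.composite_motif <- function(x, ...) {
  cat(sprintf("<composite_motif> %s side, width %d (offsets %d..%d), %d k-mers\n",
              x$side, nrow(x$probs), min(x$offsets), max(x$offsets),
              nrow(x$kmers)))
  invisible(x)
}

#' Convert a composite motif to a scorable PWM model
#' @param x A `composite_motif`.
#' @inheritParams pwm_model
#' @return A `pwm_model` over the composite's covered offsets.
#' @export
as_pwm_model <- function(x, background = rep(0.25, 4), pseudocount = 1e-3) {
  pwm_model(x$probs, background = background, pseudocount = pseudocount)
}

#' Write a composite motif as a JASPAR-style position frequency matrix
#'
#' Four rows (A, C, G, T) of per-position weights, plus a side-car TSV of the
#' contributing k-mers.
#'
#' @param x A `composite_motif`.
#' @param path Output path for the matrix; k-mers go to `paste0(path, ".kmers.tsv")`.
#' @export
write_composite_motif <- function(x, path) {
  lines <- vapply(1:4, function(b) {
    sprintf("%s  [ %s ]", DNA_BASES[b],
            paste(sprintf("%.4f", x$probs[, b]), collapse = " "))
  }, character(1))
  readr::write_lines(c(sprintf(">composite_%s", x$side), lines), path)
  readr::write_tsv(x$kmers, paste0(path, ".kmers.tsv"), progress = FALSE)
  invisible(path)
}

#' Prevalence of a motif among classes of extended sequences
#'
#' Scores each class's extended sequences with the motif anchored at its
#' fixed offset in the window (core-anchored, forward orientation, since the
#' sequences are motif-oriented) and reports the fraction passing the exact
#' p-value cutoff.
#'
#' @param seq_classes Named list of character vectors of equal-length
#'   extended sequences (one element per site class).
#' @param motif A `composite_motif` (anchored at its own offsets) or a
#'   `pwm_model` (requires `offset`).
#' @param pvalue_cutoff Exact p-value cutoff (default 0.0005).
#' @param offset 0-based anchor offset in the window for a plain `pwm_model`.
#' @param granularity Score discretization step.
#' @return A tibble: `class`, `n`, `n_match`, `prevalence`.
#' @export
motif_prevalence <- function(seq_classes, motif, pvalue_cutoff = 5e-4,
                             offset = NULL, granularity = 1e-3) {
  if (inherits(motif, "composite_motif")) {
    offset <- min(motif$offsets)
    motif <- as_pwm_model(motif)
  }
  if (is.null(offset)) abort("`offset` is required for a plain pwm_model.")
  if (!length(seq_classes) || any(!lengths(seq_classes))) {
    abort("Every class must contain at least one sequence.")
  }
  dist <- score_distribution(motif, granularity)
  purrr::imap(seq_classes, function(seqs, cls) {
    win <- substring(seqs, offset + 1L, offset + motif$width)
    if (any(nchar(win) < motif$width)) {
      abort("Motif anchored past the end of the sequences.")
    }
    units <- vapply(win, function(s) {
      codes <- dna_codes(s)
      if (any(codes > 4L)) return(NA_real_)
      sum(dist$units[cbind(seq_len(motif$width), codes)])
    }, double(1), USE.NAMES = FALSE)
    pv <- pvalue_at_units(dist, ifelse(is.na(units), -Inf, units))
    tibble(class = cls, n = length(seqs), n_match = sum(pv <= pvalue_cutoff),
           prevalence = mean(pv <= pvalue_cutoff))
  }) |> bind_rows()
}
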