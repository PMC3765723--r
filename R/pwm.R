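#' Position weight matrix model
#'
#' Constructs a PWM model from a width x 4 matrix of base probabilities (or
#' counts, which are normalized per row). Scoring is log-odds against the
#' background with a pseudocount added to both numerator and denominator:
#' \deqn{s(x) = \sum_i \log(p_i(x_i) + c) - \log(b(x_i) + c)}
#' so zero matrix entries stay finite.
#'
#' @param x Numeric matrix, rows = motif positions, columns = A, C, G, T.
#'   Counts are accepted and normalized row-wise.
#' @param background Background base probabilities (A, C, G, T); default
#'   uniform 0.25.
#' @param pseudocount Small fraction added to matrix and background
#'   probabilities before taking log-odds (default 0.001).
#' @return An object of class `pwm_model` with elements `probs`, `background`,
#'   `pseudocount`, `width` and the precomputed log-odds matrix `lod`
#'   (width x 5; 5th column is N, scored `-Inf` so windows containing N are
#'   skipped).
#' @examples
#' pwm <- pwm_model(matrix(c(0.97, 0.01, 0.01, 0.01), 1, 4))
#' score_window(pwm, "A")
#' @export
pwm_model <- function(x, background = rep(0.25, 4), pseudocount = 1e-3) {
  x <- as.matrix(x)
  if (ncol(x) != 4L) abort("PWM matrix must have 4 columns (A, C, G, T).")
  if (nrow(x) < 1L) abort("PWM must have width >= 1.")
  if (any(x < 0)) abort("PWM entries must be non-negative.")
  rs <- rowSums(x)
  if (any(rs <= 0)) abort("Every PWM row must have positive total.")
  probs <- x / rs
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be 4 non-negative probabilities summing to 1.")
  }
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  lod <- log(sweep(probs + pseudocount, 2, background + pseudocount, "/"))
  lod <- cbind(lod, N = -Inf)
  colnames(lod) <- c(DNA_BASES, "N")
  colnames(probs) <- DNA_BASES
  structure(
    list(probs = probs, background = background, pseudocount = pseudocount,
         width = nrow(probs), lod = lod),
    class = "pwm_model"
  )
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model> width %d, pseudocount %g\n", x$width, x$pseudocount))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param pwm A `pwm_model`.
#' @return A character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 1, which.max)], collapse = "")
}

# log-odds of the reverse-complement scan: position j of the minus-strand
# window scores base complement at motif position w+1-j.
pwm_lod_revcomp <- function(pwm) {
  comp <- c(4L, 3L, 2L, 1L, 5L)  # A<->T, C<->G, N->N
  pwm$lod[rev(seq_len(pwm$width)), comp, drop = FALSE]
}

#' Read / write a PWM as a plain-text matrix
#'
#' The text format is whitespace-separated, one motif position per row,
#' columns A C G T (counts or probabilities), optionally with a `#` header.
#'
#' @param path File path.
#' @inheritParams pwm_model
#' @return For `read_pwm()`, a `pwm_model`.
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 1e-3) {
  if (!file.exists(path)) abort(sprintf("PWM file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(trimws(lines), "#")]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "[ \t]+"), as.numeric))
  pwm_model(m, background = background, pseudocount = pseudocount)
}

#' @rdname read_pwm
#' @param pwm A `pwm_model`.
#' @export
write_pwm <- function(pwm, path) {
  header <- sprintf("# %s", paste(DNA_BASES, collapse = " "))
  body <- apply(pwm$probs, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Example 16-bp CTCF core matrix
#'
#' A consensus-derived example matrix for the canonical 16-bp CTCF zinc-finger
#' core motif, shipped for examples and tests (the matrix used on real data
#' should come from de novo discovery on the ChIP-seq peaks and be supplied
#' via [read_pwm()]). It is synthetic: built from the familiar
#' CCASYAGRKGGCRSYG-like consensus with strong (0.85) dominant bases and
#' two-way degeneracy at the S/Y/R/K positions.
#'
#' @inheritParams pwm_model
#' @return A `pwm_model` of width 16.
#' @export
ctcf_example_pwm <- function(background = rep(0.25, 4), pseudocount = 1e-3) {
  read_pwm(system.file("extdata", "ctcf_core_pwm.txt", package = "ctcfconst",
                       mustWork = TRUE),
           background = background, pseudocount = pseudocount)
}

#' Score a single window under a PWM
#'
#' @param pwm A `pwm_model`.
#' @param seq A DNA string exactly `pwm$width` long (A/C/G/T/N).
#' @param strand `"+"` scores the sequence as given; `"-"` scores its reverse
#'   complement. Any N gives `-Inf`.
#' @return The log-odds score.
#' @export
score_window <- function(pwm, seq, strand = "+") {
  codes <- dna_codes(seq)
  if (length(codes) != pwm$width) {
    abort(sprintf("Window length %d != PWM width %d.", length(codes), pwm$width))
  }
  lod <- if (strand == "-") pwm_lod_revcomp(pwm) else pwm$lod
  sum(lod[cbind(seq_len(pwm$width), codes)])
}

#' Exact PWM score distribution under the background model
#'
#' Computes, by dynamic programming (convolution of per-position discretized
#' score distributions), the exact probability of every achievable discretized
#' log-odds score for a random background sequence, and from it the tail
#' function \eqn{P(\mathrm{score} \ge s)}. This is what turns a score cutoff
#' into an exact p-value (e.g. the 0.0005 site-calling cutoff).
#'
#' @param pwm A `pwm_model`.
#' @param granularity Score discretization step in log-odds units
#'   (default 1e-3).
#' @return An object of class `score_distribution` with integer-unit score
#'   support `lo:hi`, probability vector `prob`, non-increasing `tail`, the
#'   `granularity` and the discretized per-position score matrix `units` used
#'   for scanning (so scan scores and p-values are mutually consistent).
#' @examples
#' sd1 <- score_distribution(pwm_model(matrix(c(1, 0, 0, 0), 1, 4)))
#' tidy(sd1)
#' @export
score_distribution <- function(pwm, granularity = 1e-3) {
  if (granularity <= 0) abort("`granularity` must be > 0.")
  units <- round(pwm$lod[, 1:4, drop = FALSE] / granularity)
  storage.mode(units) <- "integer"
  lo_j <- apply(units, 1, min)
  hi_j <- apply(units, 1, max)
  lo <- sum(lo_j); hi <- sum(hi_j)
  prob <- 1
  cur_lo <- 0L
  bg <- pwm$background
  for (j in seq_len(pwm$width)) {
    new_lo <- cur_lo + lo_j[j]
    new_len <- (cur_lo + hi_j[j]) - new_lo + length(prob)
    nxt <- numeric(new_len)
    for (b in 1:4) {
      off <- cur_lo + units[j, b] - new_lo
      idx <- seq_along(prob) + off
      nxt[idx] <- nxt[idx] + prob * bg[b]
    }
    prob <- nxt
    cur_lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(prob)))
  structure(
    list(lo = as.integer(cur_lo), hi = as.integer(cur_lo + length(prob) - 1L),
         prob = prob, tail = tail_p, granularity = granularity,
         units = cbind(units, N = NA_integer_), width = pwm$width),
    class = "score_distribution"
  )
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "<score_distribution> width %d, granularity %g, score range [%.3f, %.3f]\n",
    x$width, x$granularity, x$lo * x$granularity, x$hi * x$granularity))
  invisible(x)
}

#' @export
tidy.score_distribution <- function(x, ...) {
  tibble(score = (x$lo:x$hi) * x$granularity, prob = x$prob, tail = x$tail)
}

#' Exact p-value for a PWM score
#'
#' @param dist A [score_distribution()].
#' @param score Log-odds score(s); discretized to the distribution's
#'   granularity before lookup.
#' @return \eqn{P(\mathrm{score} \ge s)} under the background model. `-Inf`
#'   maps to 1, scores above the maximum to 0.
#' @export
pwm_pvalue <- function(dist, score) {
  units <- ifelse(is.finite(score), round(score / dist$granularity), -Inf)
  pvalue_at_units(dist, units)
}

pvalue_at_units <- function(dist, units) {
  p <- numeric(length(units))
  below <- !is.finite(units) | units < dist$lo
  above <- is.finite(units) & units > dist$hi
  mid <- !below & !above
  p[below] <- 1
  p[above] <- 0
  p[mid] <- dist$tail[units[mid] - dist$lo + 1L]
  p
}

# Core scanning engine: best passing window per sequence.
#
# seqs: character vector. Returns a tibble with one row per sequence that has
# at least one finite-score window passing the cutoff: seq_id, offset
# (0-based), strand, score (discretized units * granularity), pvalue.
# Tie-break: highest score, then leftmost offset, then "+" strand.
scan_best <- function(seqs, pwm, dist, pvalue_cutoff = 5e-4) {
  w <- pwm$width
  keep <- nchar(seqs) >= w
  if (!any(keep)) {
    return(tibble(seq_id = integer(), offset = integer(), strand = character(),
                  score = double(), pvalue = double()))
  }
  idx_keep <- which(keep)
  ss <- unname(seqs[keep])
  lens <- nchar(ss)
  concat <- paste(ss, collapse = "N")
  codes <- dna_codes(concat)
  n_win <- length(codes) - w + 1L
  if (n_win < 1L) {
    return(tibble(seq_id = integer(), offset = integer(), strand = character(),
                  score = double(), pvalue = double()))
  }
  units_f <- cbind(dist$units[, 1:4, drop = FALSE], N = NA_integer_)
  comp <- c(4L, 3L, 2L, 1L, 5L)
  units_r <- units_f[rev(seq_len(w)), comp, drop = FALSE]
  score_pass <- function(U) {
    s <- numeric(n_win)
    nas <- FALSE
    for (j in seq_len(w)) {
      v <- U[j, codes[j:(j + n_win - 1L)]]
      s <- s + v
      nas <- nas | is.na(v)
    }
    s[nas] <- -Inf
    s
  }
  sf <- score_pass(units_f)
  sr <- score_pass(units_r)
  # map windows back to sequences: sequence i occupies a stretch of
  # lens[i] - w + 1 valid window starts, then (w - 1) + 1 boundary starts
  # whose windows cross the N separator (scored -Inf, harmless).
  starts <- cumsum(c(0L, head(lens, -1L) + 1L))     # 0-based seq starts in concat
  win_start0 <- seq_len(n_win) - 1L
  seq_of_win <- findInterval(win_start0, starts)    # 1-based index into ss
  offset <- win_start0 - starts[seq_of_win]
  valid <- offset <= (lens[seq_of_win] - w)
  sid <- idx_keep[seq_of_win[valid]]
  off <- offset[valid]
  vf <- sf[valid]; vr <- sr[valid]
  pf <- pvalue_at_units(dist, vf)
  pr <- pvalue_at_units(dist, vr)
  kf <- is.finite(vf) & pf <= pvalue_cutoff
  kr <- is.finite(vr) & pr <= pvalue_cutoff
  res <- tibble(
    seq_id = c(sid[kf], sid[kr]),
    offset = c(off[kf], off[kr]),
    strand = rep(c("+", "-"), c(sum(kf), sum(kr))),
    units = c(vf[kf], vr[kr]),
    pvalue = c(pf[kf], pr[kr])
  )
  if (nrow(res) == 0L) {
    return(tibble(seq_id = integer(), offset = integer(), strand = character(),
                  score = double(), pvalue = double()))
  }
  ord <- order(res$seq_id, -res$units, res$offset, res$strand != "+")
  res <- res[ord, ]
  res <- res[!duplicated(res$seq_id), ]
  tibble(seq_id = res$seq_id, offset = res$offset, strand = res$strand,
         score = res$units * dist$granularity, pvalue = res$pvalue)
}

#' Call the best binding site in each peak
#'
#' Scans both strands of every normalized peak sequence and keeps, per peak,
#' the single highest-scoring window whose exact p-value passes the cutoff
#' (default 0.0005); peaks with no passing window yield no site. Ties are
#' broken by leftmost start, then + strand.
#'
#' @param peaks Tibble of peak intervals (`chrom`, `start`, `end`; any other
#'   columns such as `cell_line`/`dataset` are carried onto the sites).
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param pwm A `pwm_model`.
#' @param pvalue_cutoff Exact-p-value cutoff for calling a site.
#' @param granularity Score discretization step for the exact distribution.
#' @param dist Optionally, a precomputed [score_distribution()] for `pwm`.
#' @return A tibble of binding sites: `chrom`, `start`, `end` (site interval,
#'   width = PWM width), `strand`, `score`, `pvalue`, plus the peak's carried
#'   columns and `peak_row` (row index into `peaks`).
#' @export
call_sites <- function(peaks, genome, pwm, pvalue_cutoff = 5e-4,
                       granularity = 1e-3, dist = NULL) {
  check_intervals(peaks, "peaks")
  if (is.null(dist)) dist <- score_distribution(pwm, granularity)
  seqs <- genome_slice(genome, peaks$chrom, peaks$start, peaks$end)
  hits <- scan_best(seqs, pwm, dist, pvalue_cutoff)
  carried <- peaks[hits$seq_id, setdiff(names(peaks), c("start", "end", "strand", "score")),
                   drop = FALSE]
  out <- tibble(
    chrom = peaks$chrom[hits$seq_id],
    start = peaks$start[hits$seq_id] + hits$offset,
    end = peaks$start[hits$seq_id] + hits$offset + pwm$width,
    strand = hits$strand,
    score = hits$score,
    pvalue = hits$pvalue,
    peak_row = hits$seq_id
  )
  bind_cols_safe(out, carried[, setdiff(names(carried), c("chrom")), drop = FALSE])
}

bind_cols_safe <- function(x, y) {
  for (nm in names(y)) x[[nm]] <- y[[nm]]
  x
}

#' Write binding sites as BED6 with score and p-value extra columns
#' @param sites Site tibble from [call_sites()].
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  out <- tibble(
    chrom = sites$chrom, start = sites$start, end = sites$end,
    name = if ("cell_line" %in% names(sites)) sites$cell_line else ".",
    score = 0, strand = sites$strand,
    extra1 = sprintf("%.4f", sites$score),
    extra2 = format(sites$pvalue, digits = 4)
  )
  write_bed(out, path)
}
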