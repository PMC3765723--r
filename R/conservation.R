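#' Multiple-alignment blocks and species-level motif conservation
#'
#' An alignment block is represented as a tibble with columns `species`,
#' `chrom`, `start`, `size`, `strand`, `src_size`, `text` (gapped sequence),
#' the first row being the reference. [read_maf()] parses the standard MAF
#' "a"/"s" line format into a list of such blocks; [write_maf()] is its
#' inverse.
#'
#' @param path MAF file path.
#' @return For `read_maf()`, a list of block tibbles in file order.
#' @name maf_io
NULL

#' @rdname maf_io
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) abort(sprintf("MAF file not found: %s", path))
  lines <- readr::read_lines(path)
  blocks <- list()
  cur <- list()
  flush <- function() {
    if (!length(cur)) return(NULL)
    bind_rows(cur)
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      b <- flush()
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- list()
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7L) abort(sprintf("Malformed MAF s-line: '%s'", ln))
      cur[[length(cur) + 1L]] <- tibble(
        species = sub("\\..*$", "", f[2]),
        chrom = sub("^[^.]*\\.?", "", f[2]),
        start = as.integer(f[3]), size = as.integer(f[4]),
        strand = f[5], src_size = as.integer(f[6]), text = f[7])
    }
  }
  b <- flush()
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' @rdname maf_io
#' @param blocks List of block tibbles.
#' @export
write_maf <- function(blocks, path) {
  out <- c("##maf version=1")
  for (b in blocks) {
    out <- c(out, "a score=0.0")
    src <- ifelse(nzchar(b$chrom), paste0(b$species, ".", b$chrom), b$species)
    out <- c(out, sprintf("s %s %d %d %s %d %s", src, b$start, b$size,
                          b$strand, b$src_size, b$text), "")
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Merge consecutive alignment blocks spanning one query interval
#'
#' Concatenates, per species, the gapped rows of blocks that tile a single
#' query region (sorted, non-overlapping on the reference); species absent
#' from a block are padded with gaps of that block's alignment width. The
#' reference row of the merged block spans the union of the inputs.
#'
#' @param blocks List of block tibbles (see [read_maf()]), sorted by
#'   reference coordinate.
#' @return A single merged block tibble.
#' @export
merge_blocks <- function(blocks) {
  if (!length(blocks)) abort("No blocks to merge.")
  if (length(blocks) == 1L) return(blocks[[1]])
  ref <- vapply(blocks, function(b) b$species[1], character(1))
  if (length(unique(ref)) != 1L) abort("Blocks disagree on the reference species.")
  ref_rows <- bind_rows(lapply(blocks, function(b) b[1, ]))
  if (is.unsorted(ref_rows$start)) abort("Blocks must be sorted by reference coordinate.")
  ends <- ref_rows$start + ref_rows$size
  if (any(ref_rows$start[-1] < ends[-length(ends)])) {
    abort("Blocks overlap on the reference.")
  }
  species <- unique(unlist(lapply(blocks, function(b) b$species)))
  widths <- vapply(blocks, function(b) nchar(b$text[1]), integer(1))
  rows <- lapply(species, function(sp) {
    pieces <- character(length(blocks))
    meta <- NULL
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      hit <- which(b$species == sp)
      if (length(hit)) {
        pieces[i] <- b$text[hit[1]]
        if (is.null(meta)) meta <- b[hit[1], ]
      } else {
        pieces[i] <- strrep("-", widths[i])
      }
    }
    sizes <- vapply(blocks, function(b) {
      h <- which(b$species == sp)
      if (length(h)) b$size[h[1]] else 0L
    }, integer(1))
    tibble(species = sp, chrom = meta$chrom,
           start = meta$start, size = sum(sizes), strand = meta$strand,
           src_size = meta$src_size, text = paste(pieces, collapse = ""))
  })
  out <- bind_rows(rows)
  # put the reference first and give it the union span
  ri <- which(out$species == ref[1])
  out <- bind_rows(out[ri, ], out[-ri, ])
  out$start[1] <- ref_rows$start[1]
  out$size[1] <- sum(ref_rows$size)
  out
}

#' Count species whose aligned sequence contains a motif hit
#'
#' Strips gaps from each species' row, scans both strands with the PWM, and
#' counts the species (reference included) with at least one window passing
#' the exact p-value cutoff. Rows shorter than the PWM width after gap
#' removal, or made entirely of gaps/missing data, cannot hit.
#'
#' @param block A block tibble (see [read_maf()]).
#' @param pwm A `pwm_model`.
#' @param pvalue_cutoff Exact p-value cutoff (default 0.0005).
#' @param dist Optional precomputed [score_distribution()].
#' @return Integer count of species with a hit.
#' @export
species_with_hit <- function(block, pwm, pvalue_cutoff = 5e-4, dist = NULL) {
  if (!nrow(block)) abort("Empty alignment block.")
  if (is.null(dist)) dist <- score_distribution(pwm)
  seqs <- gsub("-", "", block$text, fixed = TRUE)
  keep <- nchar(seqs) >= pwm$width
  if (!any(keep)) return(0L)
  hits <- scan_best(seqs[keep], pwm, dist, pvalue_cutoff)
  length(unique(block$species[keep][hits$seq_id]))
}

#' Species hit counts for many sites at once
#'
#' @param site_blocks List of block tibbles, one merged block per site.
#' @inheritParams species_with_hit
#' @return A tibble: `site` (list index), `n_species_hit`.
#' @export
conservation_counts <- function(site_blocks, pwm, pvalue_cutoff = 5e-4) {
  dist <- score_distribution(pwm)
  # flatten all rows into one scan for speed, then re-group by site
  all_rows <- bind_rows(lapply(seq_along(site_blocks), function(i) {
    b <- site_blocks[[i]]
    tibble(site = i, species = b$species,
           seq = gsub("-", "", b$text, fixed = TRUE))
  }))
  keep <- nchar(all_rows$seq) >= pwm$width
  counts <- integer(length(site_blocks))
  if (any(keep)) {
    rows <- all_rows[keep, ]
    hits <- scan_best(rows$seq, pwm, dist, pvalue_cutoff)
    hit_rows <- rows[hits$seq_id, ]
    per_site <- hit_rows |>
      distinct(.data$site, .data$species) |>
      count(.data$site)
    counts[per_site$site] <- per_site$n
  }
  tibble(site = seq_along(site_blocks), n_species_hit = counts)
}

#' Estimate the per-species motif retention probability from hit counts
#'
#' The fraction of non-reference species with a hit overestimates the true
#' retention probability because a species can hit by chance anywhere in its
#' scanned span. This estimator subtracts the chance-hit probability, which
#' is computed exactly from the PWM score distribution: the per-window pass
#' probability is the largest achievable tail value not exceeding the
#' p-value cutoff, and a row of length L admits `2 * (L - width + 1)`
#' windows (treated as independent; the correlation between overlapping
#' windows is negligible at these tail probabilities):
#' `retention = (raw - fp) / (1 - fp)` with
#' `raw = mean((count - 1) / (n_species - 1))`.
#'
#' @param counts Integer vector of per-site species hit counts (reference
#'   species included in each count).
#' @param n_species Number of species per alignment.
#' @param pwm The `pwm_model` used for scanning.
#' @param seq_length Length of each species' scanned sequence.
#' @param pvalue_cutoff The scan cutoff.
#' @param granularity Score discretization step.
#' @return A one-row tibble: `raw_fraction`, `chance_hit`, `retention`.
#' @export
estimate_retention <- function(counts, n_species, pwm, seq_length,
                               pvalue_cutoff = 5e-4, granularity = 1e-3) {
  dist <- score_distribution(pwm, granularity)
  passing <- dist$tail[dist$tail <= pvalue_cutoff]
  alpha <- if (length(passing)) max(passing) else 0
  n_tests <- 2L * (seq_length - pwm$width + 1L)
  fp <- 1 - (1 - alpha)^n_tests
  raw <- mean((counts - 1) / (n_species - 1))
  tibble(raw_fraction = raw, chance_hit = fp,
         retention = (raw - fp) / (1 - fp))
}

#' Summarize species-conservation counts for two site classes
#'
#' Five-number summary plus mean of the per-site species counts, per class --
#' the numbers behind a conservation boxplot comparison of constitutive vs
#' non-constitutive sites.
#'
#' @param ... Named integer vectors of per-site species counts, one per class.
#' @return An object of class `conservation_summary`: tibble with `class`,
#'   `n`, `mean`, `min`, `q1`, `median`, `q3`, `max`; the raw counts are kept
#'   in the `counts` attribute for plotting.
#' @export
conservation_summary <- function(...) {
  classes <- list(...)
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    names(classes) <- paste0("class", seq_along(classes))
  }
  if (any(!lengths(classes))) abort("Every class must be non-empty.")
  out <- purrr::imap(classes, function(x, nm) {
    q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    tibble(class = nm, n = length(x), mean = mean(x), min = q[1], q1 = q[2],
           median = q[3], q3 = q[4], max = q[5])
  }) |> bind_rows()
  attr(out, "counts") <- classes
  class(out) <- c("conservation_summary", class(out))
  out
}

#' @export
tidy.conservation_summary <- function(x, ...) {
  tibble::as_tibble(x[, c("class", "n", "mean", "min", "q1", "median", "q3", "max")])
}

#' Boxplot of species-conservation counts per class
#' @param object A [conservation_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_summary <- function(object, ...) {
  counts <- attr(object, "counts")
  df <- bind_rows(purrr::imap(counts, ~ tibble(class = .y, n_species = .x)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n_species,
                                   fill = .data$class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "species with a motif hit") +
    ggplot2::theme_minimal()
}
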