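#' Annotate sites by genomic context relative to genes
#'
#' Labels each site (by its midpoint) with the first matching rule:
#' `TSS` if within `tss_window` bp of any gene's transcription start site,
#' else `in_gene` if between any gene's TSS and transcription end,
#' else `others`.
#'
#' @param sites Tibble of site intervals.
#' @param genes Tibble of gene models with columns `chrom`, `start`, `end`
#'   (gene span, 0-based half-open), `strand` (`+`/`-`; TSS is `start` on `+`
#'   and `end - 1` on `-`), optionally `gene_id`.
#' @param tss_window Half-width of the TSS window in bp (default 5000).
#' @return `sites` with an added `annotation` factor column
#'   (`TSS`/`in_gene`/`others`).
#' @export
annotate_sites <- function(sites, genes, tss_window = 5000L) {
  check_intervals(sites, "sites")
  check_intervals(genes, "genes")
  if (!"strand" %in% names(genes)) abort("`genes` needs a `strand` column.")
  mid <- interval_mid(sites$start, sites$end)
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  pts <- tibble(chrom = sites$chrom, start = mid, end = mid + 1L)
  near_tss <- overlap_any(
    pts, tibble(chrom = genes$chrom, start = pmax(0L, tss - tss_window),
                end = tss + tss_window + 1L))
  in_gene <- overlap_any(pts, genes)
  sites$annotation <- factor(
    ifelse(near_tss, "TSS", ifelse(in_gene, "in_gene", "others")),
    levels = c("TSS", "in_gene", "others"))
  sites
}

#' Per-offset feature coverage profile around site centers
#'
#' For every offset o in -halfwidth..+halfwidth, computes the fraction of
#' sites whose (center + o) position is covered by at least one feature
#' interval -- e.g. the CpG-island density profile within +/-2.5 kb of
#' binding sites.
#'
#' @param sites Tibble of site intervals (non-empty).
#' @param features Tibble of feature intervals (e.g. CpG islands).
#' @param halfwidth Profile half-width in bp (default 2500).
#' @return A tibble (`density_profile`): `offset`, `value` (fraction in
#'   `[0, 1]`), length `2 * halfwidth + 1`.
#' @export
feature_density_profile <- function(sites, features, halfwidth = 2500L) {
  check_intervals(sites, "sites")
  if (nrow(sites) == 0L) abort("`sites` must be non-empty.")
  offsets <- seq.int(-halfwidth, halfwidth)
  counts <- numeric(length(offsets))
  if (nrow(features) > 0L) {
    check_intervals(features, "features")
    mid <- interval_mid(sites$start, sites$end)
    feats <- split(features, features$chrom)
    for (i in seq_len(nrow(sites))) {
      f <- feats[[sites$chrom[i]]]
      if (is.null(f)) next
      lo <- mid[i] - halfwidth
      hi <- mid[i] + halfwidth
      f <- f[f$start <= hi & f$end > lo, , drop = FALSE]
      if (nrow(f) == 0L) next
      covered <- logical(length(offsets))   # 0/1 per site even if features overlap
      for (j in seq_len(nrow(f))) {
        a <- max(f$start[j], lo) - lo + 1L
        b <- min(f$end[j] - 1L, hi) - lo + 1L
        covered[a:b] <- TRUE
      }
      counts <- counts + covered
    }
  }
  tibble_profile(offsets, counts / nrow(sites))
}

tibble_profile <- function(offsets, values) {
  out <- tibble(offset = as.integer(offsets), value = values)
  class(out) <- c("density_profile", class(out))
  out
}

#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "offset from site center (bp)", y = "feature density") +
    ggplot2::theme_minimal()
}

#' Fraction of sites with a co-located factor peak
#'
#' For each cell line present in `factor_peaks`, the fraction of sites having
#' at least one factor peak whose center lies within +/- `margin` bp of the
#' site center (the co-factor overlap statistic used for DNase/FAIRE/histone
#' marks).
#'
#' @param sites Tibble of site intervals.
#' @param factor_peaks Tibble of factor peaks; if it has a `cell_line` column
#'   the fraction is computed per cell line.
#' @param margin Center-to-center distance in bp (default 200).
#' @return A tibble with columns `cell_line` (if present), `n_sites`,
#'   `fraction`. Empty `sites` gives `NA` fractions.
#' @export
factor_overlap_fraction <- function(sites, factor_peaks, margin = 200L) {
  check_intervals(sites, "sites")
  frac_one <- function(pk) {
    if (nrow(sites) == 0L) return(NA_real_)
    if (nrow(pk) == 0L) return(0)
    smid <- interval_mid(sites$start, sites$end)
    pmid <- interval_mid(pk$start, pk$end)
    hit <- logical(nrow(sites))
    for (ch in unique(sites$chrom)) {
      si <- which(sites$chrom == ch)
      pc <- sort(pmid[pk$chrom == ch])
      if (length(pc) == 0L) next
      # nearest peak center within +/- margin via sorted search
      idx <- findInterval(smid[si], pc)
      left <- ifelse(idx >= 1L, pc[pmax(idx, 1L)], -Inf)
      right <- ifelse(idx < length(pc), pc[pmin(idx + 1L, length(pc))], Inf)
      hit[si] <- (smid[si] - left) <= margin | (right - smid[si]) <= margin
    }
    mean(hit)
  }
  if ("cell_line" %in% names(factor_peaks)) {
    factor_peaks |>
      group_by(.data$cell_line) |>
      dplyr::group_modify(~ tibble(n_sites = nrow(sites),
                                   fraction = frac_one(.x))) |>
      ungroup()
  } else {
    tibble(n_sites = nrow(sites), fraction = frac_one(factor_peaks))
  }
}
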