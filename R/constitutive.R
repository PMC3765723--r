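#' Aggregate per-dataset binding sites into an occurrence table
#'
#' Collapses replicate datasets within a cell line to unique sites, then
#' counts, for every unique site identity (chrom, start, end, strand), the
#' number of distinct cell lines in which it was found. Site identity is
#' exact coordinate + strand equality by default; `tolerance > 0` switches on
#' a fuzzy mode that single-links sites whose starts are within `tolerance`
#' bp (same chrom/strand) before counting, for noisy real data.
#'
#' @param sites Tibble of binding sites with columns `chrom`, `start`, `end`,
#'   `strand` and `cell_line` (a `dataset` column, if present, is ignored for
#'   counting: replicates collapse).
#' @param n_cell_lines Total number of cell lines surveyed. Defaults to the
#'   number of distinct `cell_line` values present.
#' @param tolerance Fuzzy-match tolerance in bp (default 0 = exact identity).
#' @return A tibble (`occurrence_table`): `chrom`, `start`, `end`, `strand`,
#'   `n_lines`, one row per unique site, with attribute `n_cell_lines`.
#' @export
aggregate_sites <- function(sites, n_cell_lines = NULL, tolerance = 0L) {
  check_intervals(sites, "sites")
  if (!all(c("strand", "cell_line") %in% names(sites))) {
    abort("`sites` needs `strand` and `cell_line` columns.")
  }
  if (is.null(n_cell_lines)) n_cell_lines <- dplyr::n_distinct(sites$cell_line)
  if (n_cell_lines == 0L) abort("No cell lines to aggregate over.")
  x <- distinct(sites, .data$chrom, .data$start, .data$end, .data$strand,
                .data$cell_line)
  if (tolerance > 0L) {
    x <- x |>
      group_by(.data$chrom, .data$strand) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(cluster = cumsum(c(1L, diff(.data$start) > tolerance))) |>
      group_by(.data$chrom, .data$strand, .data$cluster) |>
      mutate(start = min(.data$start), end = max(.data$end)) |>
      ungroup() |>
      select(-"cluster") |>
      distinct(.data$chrom, .data$start, .data$end, .data$strand,
               .data$cell_line)
  }
  out <- x |>
    count(.data$chrom, .data$start, .data$end, .data$strand,
          name = "n_lines") |>
    arrange(.data$chrom, .data$start)
  attr(out, "n_cell_lines") <- as.integer(n_cell_lines)
  class(out) <- c("occurrence_table", class(out))
  out
}

#' Minimum cell-line count implied by a constitutive fraction
#'
#' A site is constitutive when it is found in strictly more than
#' `fraction` of the surveyed cell lines, so the minimum qualifying count is
#' `floor(fraction * n) + 1` (e.g. 51 of 56, 6 of 6, 4 of 4 at fraction 0.9).
#'
#' @param n_cell_lines Number of cell lines surveyed.
#' @param fraction Constitutive fraction threshold in (0, 1); default 0.9.
#' @return Integer minimum count.
#' @export
constitutive_min_count <- function(n_cell_lines, fraction = 0.9) {
  if (any(fraction <= 0 | fraction >= 1)) abort("`fraction` must be in (0, 1).")
  as.integer(floor(fraction * n_cell_lines + 1e-9)) + 1L
}

#' Call constitutive sites from an occurrence table
#'
#' Keeps the site identities found in strictly more than `fraction` of the
#' surveyed cell lines (the >90 percent rule by default).
#'
#' @param occ An [aggregate_sites()] occurrence table (or any tibble with an
#'   `n_lines` column and an `n_cell_lines` attribute/argument).
#' @param fraction Constitutive fraction threshold; default 0.9.
#' @param n_cell_lines Override for the survey size; defaults to the table's
#'   `n_cell_lines` attribute.
#' @return The constitutive subset of `occ`, same columns.
#' @export
call_constitutive <- function(occ, fraction = 0.9, n_cell_lines = NULL) {
  n_cell_lines <- n_cell_lines %||% attr(occ, "n_cell_lines")
  if (is.null(n_cell_lines) || n_cell_lines < 1L) {
    abort("Survey size `n_cell_lines` is missing or zero.")
  }
  min_count <- constitutive_min_count(n_cell_lines, fraction)
  out <- occ[occ$n_lines >= min_count, , drop = FALSE]
  attr(out, "n_cell_lines") <- as.integer(n_cell_lines)
  attr(out, "min_count") <- min_count
  out
}

#' Classify constitutive CTCF sites against cohesin
#'
#' Partitions constitutive CTCF sites into three classes:
#' * `cCTCF_cCohesin` - the site identity is also constitutive in both Rad21
#'   and Smc3 peak scans (intersection of the three constitutive sets);
#' * `cCTCF_non_cohesin` - the site overlaps no cohesin peak in any cell line;
#' * `cCTCF_other` - everything else (cohesin in some but not enough lines).
#'
#' @param cctcf Constitutive CTCF site tibble (`chrom`, `start`, `end`,
#'   `strand`).
#' @param crad21,csmc3 Constitutive site tibbles from scanning Rad21 / Smc3
#'   peaks with the same PWM (each judged against its own cell-line count).
#' @param cohesin_peaks Tibble of all per-cell-line cohesin (Rad21 + Smc3)
#'   peaks, used for the "no cohesin anywhere" test via interval overlap.
#' @return `cctcf` with an added `class` factor column; the three classes
#'   partition the input.
#' @export
classify_sites <- function(cctcf, crad21, csmc3, cohesin_peaks) {
  key <- function(x) paste(x$chrom, x$start, x$end, x$strand)
  in_rad <- key(cctcf) %in% key(crad21)
  in_smc <- key(cctcf) %in% key(csmc3)
  any_cohesin <- overlap_any(cctcf, cohesin_peaks)
  cls <- ifelse(in_rad & in_smc, "cCTCF_cCohesin",
                ifelse(!any_cohesin, "cCTCF_non_cohesin", "cCTCF_other"))
  cctcf$class <- factor(cls, levels = c("cCTCF_cCohesin", "cCTCF_non_cohesin",
                                        "cCTCF_other"))
  cctcf
}

#' Write an occurrence table (chrom, start, end, strand, cell-line count TSV)
#' @param occ Occurrence table from [aggregate_sites()].
#' @param path Output path.
#' @export
write_occurrence <- function(occ, path) {
  readr::write_tsv(
    as.data.frame(occ[, c("chrom", "start", "end", "strand", "n_lines")]),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @export
glance.occurrence_table <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    n_cell_lines = attr(x, "n_cell_lines"),
    n_singleton = sum(x$n_lines == 1L),
    n_all_lines = sum(x$n_lines == attr(x, "n_cell_lines"))
  )
}

#' Histogram of site occurrence across cell lines
#'
#' The occurrence-distribution plot: number of unique sites found in exactly
#' k cell lines, the display on which the constitutive right tail sits.
#'
#' @param occ Occurrence table from [aggregate_sites()].
#' @param fraction Constitutive fraction to mark (vertical line).
#' @return A ggplot object.
#' @export
plot_occurrence <- function(occ, fraction = 0.9) {
  n <- attr(occ, "n_cell_lines")
  p <- ggplot2::ggplot(occ, ggplot2::aes(x = .data$n_lines)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::labs(x = "number of cell lines", y = "unique sites") +
    ggplot2::theme_minimal()
  if (!is.null(n)) {
    p <- p + ggplot2::geom_vline(
      xintercept = constitutive_min_count(n, fraction) - 0.5,
      linetype = "dashed", colour = "red")
  }
  p
}
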