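#' Read ChIA-PET interaction pairs from paired-BED
#'
#' Format: `chrom1 start1 end1 chrom2 start2 end2 [score]`, tab-separated,
#' no header. Pairs are unordered; every downstream statistic is invariant to
#' swapping region1 and region2.
#'
#' @param path File path.
#' @return A tibble: `pair_id`, `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2` (plus `score` if present).
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) abort(sprintf("Interaction file not found: %s", path))
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) < 6L) abort("Paired-BED needs at least 6 columns.")
  out <- tibble(
    pair_id = seq_len(nrow(x)),
    chrom1 = as.character(x[[1]]), start1 = as.integer(x[[2]]),
    end1 = as.integer(x[[3]]),
    chrom2 = as.character(x[[4]]), start2 = as.integer(x[[5]]),
    end2 = as.integer(x[[6]]))
  if (ncol(x) >= 7L) out$score <- x[[7]]
  bad <- which(out$start1 >= out$end1 | out$start2 >= out$end2)
  if (length(bad)) abort(sprintf("Line %d has start >= end.", bad[1]))
  out
}

#' @rdname read_interactions
#' @param pairs Interaction tibble.
#' @export
write_interactions <- function(pairs, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  readr::write_tsv(as.data.frame(pairs[, cols]), path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

pair_regions <- function(pairs) {
  bind_rows(
    tibble(pair_id = pairs$pair_id, region = 1L, chrom = pairs$chrom1,
           start = pairs$start1, end = pairs$end1),
    tibble(pair_id = pairs$pair_id, region = 2L, chrom = pairs$chrom2,
           start = pairs$start2, end = pairs$end2))
}

#' Count sites contained in any interaction region
#'
#' A site counts once if it overlaps at least one region of at least one
#' interaction pair, regardless of how many pairs it touches.
#'
#' @param sites Tibble of site intervals.
#' @param pairs Interaction tibble from [read_interactions()].
#' @return A tibble: `n_sites`, `n_in_interaction`, `proportion`.
#' @export
sites_in_interactions <- function(sites, pairs) {
  check_intervals(sites, "sites")
  regions <- pair_regions(pairs)
  inside <- overlap_any(sites, regions)
  tibble(n_sites = nrow(sites), n_in_interaction = sum(inside),
         proportion = if (nrow(sites)) mean(inside) else NA_real_)
}

#' One-sided enrichment test on a 2x2 in-interaction table
#'
#' Compares the in-interaction proportions of two site classes. The odds
#' ratio is the sample cross-product ratio \eqn{(a/b) / (c/d)} with
#' a = class-1 sites in interactions, b = class-1 sites not in interactions,
#' and c, d likewise for class 2. The p-value is the one-sided Fisher exact
#' test (hypergeometric upper tail, alternative "greater": class 1 more
#' enriched).
#'
#' @param in1,total1 In-interaction count and total for class 1.
#' @param in2,total2 Likewise for class 2.
#' @param labels Optional character vector of two class labels.
#' @return An object of class `ctcf_enrichment` with the 2x2 table, the
#'   odds ratio (possibly `Inf`, flagged via `zero_cell`), proportions and
#'   p-value. Use [tidy()] for a one-row tibble.
#' @examples
#' enrichment_test(in1 = 14178, total1 = 23577, in2 = 13316, total2 = 81464)
#' @export
enrichment_test <- function(in1, total1, in2, total2,
                            labels = c("class1", "class2")) {
  if (any(c(in1, total1, in2, total2) < 0) || in1 > total1 || in2 > total2) {
    abort("Counts must be non-negative with in <= total.")
  }
  a <- in1; b <- total1 - in1; c_ <- in2; d <- total2 - in2
  if (a + b + c_ + d == 0) abort("Empty contingency table.")
  zero_cell <- (b == 0 || c_ == 0) && (a > 0 && d > 0)
  or <- (a / b) / (c_ / d)
  p <- phyper(a - 1, m = a + b, n = c_ + d, k = a + c_, lower.tail = FALSE)
  structure(
    list(table = matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                        dimnames = list(labels, c("in", "not_in"))),
         odds_ratio = or, p_value = p, zero_cell = zero_cell,
         proportions = setNames(c(a / total1, c_ / total2), labels)),
    class = "ctcf_enrichment")
}

#' @export
print.ctcf_enrichment <- function(x, ...) {
  cat("<ctcf_enrichment> one-sided Fisher exact test\n")
  print(x$table)
  cat(sprintf("proportions: %.3f vs %.3f\n", x$proportions[1], x$proportions[2]))
  cat(sprintf("odds ratio = %.2f, p-value = %.3g%s\n", x$odds_ratio, x$p_value,
              if (x$zero_cell) " (zero cell: odds ratio unstable)" else ""))
  invisible(x)
}

#' @export
tidy.ctcf_enrichment <- function(x, ...) {
  tibble(
    class1 = rownames(x$table)[1], class2 = rownames(x$table)[2],
    in1 = x$table[1, 1], total1 = sum(x$table[1, ]),
    in2 = x$table[2, 1], total2 = sum(x$table[2, ]),
    proportion1 = unname(x$proportions[1]),
    proportion2 = unname(x$proportions[2]),
    odds_ratio = x$odds_ratio, p_value = x$p_value)
}

#' @export
glance.ctcf_enrichment <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
         zero_cell = x$zero_cell)
}

#' Fractional counting of interaction pair types
#'
#' Labels each interaction region with the set of distinct site classes it
#' contains (constitutive and/or non-constitutive CTCF; "neither" if none),
#' then distributes each pair's unit weight uniformly over the Cartesian
#' product of its two label sets and accumulates the six unordered type
#' combinations. The counts (possibly fractional) sum exactly to the number
#' of pairs.
#'
#' @param pairs Interaction tibble.
#' @param cctcf_sites,nonconst_sites Disjoint tibbles of site intervals.
#' @return An object of class `pair_type_counts`: tibble `type1`, `type2`,
#'   `count`, `percent`, with attribute `n_pairs`.
#' @export
fractional_type_counts <- function(pairs, cctcf_sites, nonconst_sites) {
  regions <- pair_regions(pairs)
  has_c <- overlap_any(regions, cctcf_sites)
  has_n <- overlap_any(regions, nonconst_sites)
  lab <- function(cc, nn) {
    if (cc && nn) c("cCTCF", "non_constitutive")
    else if (cc) "cCTCF"
    else if (nn) "non_constitutive"
    else "neither"
  }
  n_pairs <- nrow(pairs)
  labels1 <- vector("list", n_pairs)
  labels2 <- vector("list", n_pairs)
  idx <- split(seq_len(nrow(regions)), regions$region)
  r1 <- regions[idx[[1]], ]; r2 <- regions[idx[[2]], ]
  ord1 <- match(pairs$pair_id, r1$pair_id)
  ord2 <- match(pairs$pair_id, r2$pair_id)
  hc1 <- has_c[idx[[1]]][ord1]; hn1 <- has_n[idx[[1]]][ord1]
  hc2 <- has_c[idx[[2]]][ord2]; hn2 <- has_n[idx[[2]]][ord2]
  lev <- c("cCTCF", "non_constitutive", "neither")
  acc <- matrix(0, 3, 3, dimnames = list(lev, lev))
  for (i in seq_len(n_pairs)) {
    l1 <- lab(hc1[i], hn1[i]); l2 <- lab(hc2[i], hn2[i])
    w <- 1 / (length(l1) * length(l2))
    for (x in l1) for (y in l2) {
      u <- sort(match(c(x, y), lev))
      acc[u[1], u[2]] <- acc[u[1], u[2]] + w
    }
  }
  combos <- tibble(
    type1 = lev[c(1, 1, 1, 2, 2, 3)],
    type2 = lev[c(1, 2, 3, 2, 3, 3)])
  combos$count <- acc[cbind(match(combos$type1, lev), match(combos$type2, lev))]
  combos$percent <- if (n_pairs) 100 * combos$count / n_pairs else NA_real_
  attr(combos, "n_pairs") <- n_pairs
  class(combos) <- c("pair_type_counts", class(combos))
  combos
}

#' @export
tidy.pair_type_counts <- function(x, ...) {
  as_tibble(x[, c("type1", "type2", "count", "percent")])
}

#' @export
glance.pair_type_counts <- function(x, ...) {
  tibble(n_pairs = attr(x, "n_pairs"), total_count = sum(x$count))
}

#' Write pair-type counts as a TSV (category, count, percent)
#' @param x A [fractional_type_counts()] result.
#' @param path Output path.
#' @export
write_pair_types <- function(x, path) {
  out <- tibble(category = paste(x$type1, x$type2, sep = " / "),
                count = sprintf("%.2f", x$count),
                percent = sprintf("%.1f%%", x$percent))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
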