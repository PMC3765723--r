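#' Assign intervals to topological domains by midpoint
#'
#' An interval belongs to the unique domain containing its midpoint (domains
#' are non-overlapping and half-open, so a midpoint exactly on a domain start
#' belongs to that domain).
#'
#' @param x Tibble of intervals.
#' @param domains Tibble of domain intervals (`chrom`, `start`, `end`),
#'   non-overlapping within a chromosome.
#' @return `x` with added columns `domain` (row index into `domains`, `NA` if
#'   outside every domain), `domain_start`, `domain_end`.
#' @export
assign_domains <- function(x, domains) {
  check_intervals(x, "x"); check_intervals(domains, "domains")
  mid <- interval_mid(x$start, x$end)
  dom <- rep(NA_integer_, nrow(x))
  for (ch in unique(x$chrom)) {
    di <- which(domains$chrom == ch)
    if (!length(di)) next
    d <- domains[di, ]
    o <- order(d$start)
    d <- d[o, ]; di <- di[o]
    xi <- which(x$chrom == ch)
    k <- findInterval(mid[xi], d$start)
    ok <- k >= 1L & mid[xi] < d$end[pmax(k, 1L)]
    dom[xi[ok]] <- di[k[ok]]
  }
  x$domain <- dom
  x$domain_start <- domains$start[dom]
  x$domain_end <- domains$end[dom]
  x
}

#' Classify interaction pairs relative to topological domains
#'
#' Assigns each region (by midpoint) to a domain and labels every pair:
#' `same_domain` (both regions in one domain), `cross_domain` (both in
#' domains but different ones), `partly_outside` (one region outside),
#' `outside` (both outside). Same-domain status is only meaningful for
#' intra-chromosomal pairs; inter-chromosomal pairs with both regions in
#' domains are `cross_domain`.
#'
#' @param pairs Interaction tibble.
#' @param domains Domain tibble.
#' @return `pairs` with an added `domain_label` factor; summary fractions via
#'   [glance()]: `frac_both_in_domains` and `frac_same_domain` (among
#'   intra-chromosomal pairs with both regions in domains).
#' @export
classify_interactions_by_domain <- function(pairs, domains) {
  r1 <- assign_domains(tibble(chrom = pairs$chrom1, start = pairs$start1,
                              end = pairs$end1), domains)
  r2 <- assign_domains(tibble(chrom = pairs$chrom2, start = pairs$start2,
                              end = pairs$end2), domains)
  in1 <- !is.na(r1$domain); in2 <- !is.na(r2$domain)
  lab <- ifelse(in1 & in2,
                ifelse(r1$domain == r2$domain, "same_domain", "cross_domain"),
                ifelse(in1 | in2, "partly_outside", "outside"))
  pairs$domain_label <- factor(lab, levels = c("same_domain", "cross_domain",
                                               "partly_outside", "outside"))
  intra <- pairs$chrom1 == pairs$chrom2
  both_in <- in1 & in2
  attr(pairs, "domain_summary") <- tibble(
    n_pairs = nrow(pairs),
    frac_both_in_domains = mean(both_in),
    frac_same_domain = if (any(intra & both_in)) {
      mean(lab[intra & both_in] == "same_domain")
    } else NA_real_)
  class(pairs) <- c("domain_classified_pairs", class(pairs))
  pairs
}

#' @export
glance.domain_classified_pairs <- function(x, ...) {
  attr(x, "domain_summary")
}

#' Distance from sites to the nearest domain boundary, standardized
#'
#' For every site inside a domain, the raw distance is the bp distance from
#' the site midpoint to the nearer of the two domain boundaries. To make
#' distances comparable across domains of different sizes, each raw distance
#' is rescaled as if its domain had the median domain length:
#' `standardized = raw * median_length / domain_length`.
#'
#' @param sites Tibble of site intervals.
#' @param domains Domain tibble.
#' @param median_length Standardizing length in bp; defaults to the median
#'   domain length of `domains`.
#' @return A tibble of the in-domain sites with `raw` and `standardized`
#'   distance columns (sites outside every domain are dropped).
#' @export
boundary_distances <- function(sites, domains, median_length = NULL) {
  median_length <- median_length %||% median(domains$end - domains$start)
  x <- assign_domains(sites, domains)
  x <- x[!is.na(x$domain), , drop = FALSE]
  mid <- as.numeric(interval_mid(x$start, x$end))
  x$raw <- pmin(mid - x$domain_start, x$domain_end - mid)
  x$standardized <- x$raw * median_length / (x$domain_end - x$domain_start)
  x
}

#' Gaussian kernel density of boundary distances with reflection at zero
#'
#' Kernel density estimate of (standardized) boundary distances using
#' Silverman's rule-of-thumb bandwidth, with boundary reflection at 0 so no
#' density mass leaks below zero. The reported mode is the argmax of the
#' estimated density on the non-negative axis.
#'
#' @param distances Numeric vector of distances (>= 0), length >= 2.
#' @param bw Bandwidth: `"silverman"` (default, `stats::bw.nrd0`) or a
#'   number.
#' @param n Grid size for the density curve.
#' @return An object of class `distance_kde`: tibble `x`, `density`, with
#'   attributes `mode`, `bandwidth`, `n_obs`.
#' @export
kde_distances <- function(distances, bw = "silverman", n = 512L) {
  distances <- distances[is.finite(distances)]
  if (length(distances) < 2L) abort("Need at least two distances.")
  if (length(unique(distances)) == 1L) {
    warn("All distances identical; returning a degenerate (delta-like) density.")
    out <- tibble(x = distances[1], density = Inf)
    attr(out, "mode") <- distances[1]
    attr(out, "bandwidth") <- 0
    attr(out, "n_obs") <- length(distances)
    class(out) <- c("distance_kde", class(out))
    return(out)
  }
  bwv <- if (identical(bw, "silverman")) stats::bw.nrd0(distances) else bw
  # reflection: estimate on c(x, -x), keep x >= 0, double the mass
  d <- density(c(distances, -distances), bw = bwv, n = 2L * n,
               from = 0, to = max(distances) + 3 * bwv)
  out <- tibble(x = d$x, density = 2 * d$y)
  attr(out, "mode") <- d$x[which.max(d$y)]
  attr(out, "bandwidth") <- bwv
  attr(out, "n_obs") <- length(distances)
  class(out) <- c("distance_kde", class(out))
  out
}

#' @export
glance.distance_kde <- function(x, ...) {
  tibble(mode = attr(x, "mode"), bandwidth = attr(x, "bandwidth"),
         n_obs = attr(x, "n_obs"))
}

#' @export
autoplot.distance_kde <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_vline(xintercept = attr(object, "mode"),
                        linetype = "dashed") +
    ggplot2::labs(x = "standardized distance to nearest boundary (bp)",
                  y = "density") +
    ggplot2::theme_minimal()
}
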