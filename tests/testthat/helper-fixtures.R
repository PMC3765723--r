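# Shared fixtures: all synthetic, built in code at test time.

rand_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

random_pwm <- function(width, seed = NULL, background = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(width * 4), width, 4)
  pwm_model(m, background = background)
}

# Independent oracle for the exact score distribution: enumerate all 4^w
# sequences, score with the same discretized unit matrix, and accumulate
# background probabilities per achievable unit score.
brute_force_tail <- function(pwm, dist) {
  w <- pwm$width
  grid <- as.matrix(do.call(expand.grid, rep(list(1:4), w)))
  sc <- integer(nrow(grid))
  for (j in seq_len(w)) sc <- sc + dist$units[j, grid[, j]]
  pr <- rep(1, nrow(grid))
  for (j in seq_len(w)) pr <- pr * pwm$background[grid[, j]]
  vapply(dist$lo:dist$hi, function(u) sum(pr[sc >= u]), numeric(1))
}

# Independent one-sided Fisher oracle: explicit hypergeometric tail sum.
hyper_tail_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- a:min(m, k)
  sum(dhyper(xs, m, n, k))
}

# Coordinate-only random sites on the configured chromosomes, spaced so
# 2-kb anchors never touch a neighbouring site.
make_coord_sites <- function(n, chrom_lengths, spacing = 2400L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slots <- dplyr::bind_rows(lapply(names(chrom_lengths), function(ch) {
    tibble::tibble(chrom = ch,
                   start = seq(5000L, chrom_lengths[[ch]] - 5000L,
                               by = spacing))
  }))
  stopifnot(nrow(slots) >= n)
  picked <- slots[sample.int(nrow(slots), n), ]
  tibble::tibble(chrom = picked$chrom, start = as.integer(picked$start),
                 end = as.integer(picked$start + 16L), strand = "+")
}

tiny_genome <- function(lengths = c(chr1 = 10000L), seed = 1) {
  set.seed(seed)
  vapply(lengths, function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

implant <- function(genome, chrom, pos0, word) {
  g <- genome[[chrom]]
  substr(g, pos0 + 1L, pos0 + nchar(word)) <- word
  genome[[chrom]] <- g
  genome
}
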