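test_that("log-odds scoring matches the closed form", {
  p1 <- pwm_model(matrix(c(1, 0, 0, 0), 1, 4), pseudocount = 0)
  expect_equal(score_window(p1, "A"), log(1 / 0.25))
  expect_equal(score_window(p1, "C"), -Inf)

  p2 <- pwm_model(matrix(c(1, 0, 0, 0), 1, 4), pseudocount = 0.01)
  expect_equal(score_window(p2, "C"), log(0.01 / 0.26))

  # reverse strand scores the reverse complement
  expect_equal(score_window(p1, "T", strand = "-"), log(1 / 0.25))
  expect_error(score_window(p1, "AC"), "length")
})

test_that("palindromic PWMs score both strands identically", {
  # ACGT-positional palindrome: revcomp of consensus equals consensus
  m <- rbind(c(.7, .1, .1, .1), c(.1, .7, .1, .1),
             c(.1, .1, .7, .1), c(.1, .1, .1, .7))
  pwm <- pwm_model(m)
  for (s in c("ACGT", "TTTT", "GATC")) {
    expect_equal(score_window(pwm, s, "+"), score_window(pwm, s, "-"))
  }
})

test_that("windows containing N are invalidated, not averaged", {
  pwm <- random_pwm(4, seed = 2)
  expect_equal(score_window(pwm, "ACNT"), -Inf)
  d <- score_distribution(pwm)
  hits <- ctcfconst:::scan_best(c("ACNTACNT"), pwm, d, pvalue_cutoff = 1)
  expect_true(all(hits$offset == 4L) || nrow(hits) <= 1L)
})

test_that("exact p-value table equals brute-force enumeration up to width 8", {
  for (w in 1:8) {
    pwm <- random_pwm(w, seed = 100 + w)
    d <- score_distribution(pwm, granularity = 1e-3)
    expect_equal(d$tail, brute_force_tail(pwm, d), tolerance = 1e-12,
                 info = paste("width", w))
  }
  # non-uniform background too
  pwm <- random_pwm(5, seed = 77, background = c(.3, .2, .2, .3))
  d <- score_distribution(pwm)
  expect_equal(d$tail, brute_force_tail(pwm, d), tolerance = 1e-12)
})

test_that("score distribution tail is normalized and monotone", {
  pwm <- random_pwm(6, seed = 9)
  d <- score_distribution(pwm)
  expect_equal(pwm_pvalue(d, -Inf), 1)
  expect_equal(d$tail[1], 1)          # tail at the minimum achievable score
  expect_true(all(diff(d$tail) <= 1e-15))
  expect_equal(pwm_pvalue(d, (d$hi + 10) * d$granularity), 0)

  # width-1 uniform-background sanity: best base has tail 0.25
  p1 <- pwm_model(matrix(c(.9, .05, .03, .02), 1, 4))
  d1 <- score_distribution(p1)
  expect_equal(pwm_pvalue(d1, score_window(p1, "A")), 0.25)
})

test_that("best site per peak: implant found, ties broken leftmost then plus", {
  pwm <- ctcf_example_pwm()
  cons <- pwm_consensus(pwm)
  g <- tiny_genome(c(chr1 = 2000L), seed = 4)
  g <- implant(g, "chr1", 600L, cons)
  pk <- tibble::tibble(chrom = "chr1", start = 500L, end = 700L)
  s <- call_sites(pk, g, pwm)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 600L)
  expect_equal(s$strand, "+")
  expect_true(s$pvalue <= 5e-4)

  # two identical implants: the leftmost wins
  g2 <- implant(implant(tiny_genome(c(chr1 = 2000L), seed = 8),
                        "chr1", 510L, cons), "chr1", 550L, cons)
  s2 <- call_sites(tibble::tibble(chrom = "chr1", start = 500L, end = 700L),
                   g2, pwm)
  expect_equal(s2$start, 510L)

  # minus-strand implant is found on the minus strand
  g3 <- implant(tiny_genome(c(chr1 = 2000L), seed = 12), "chr1", 620L,
                as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons))))
  s3 <- call_sites(tibble::tibble(chrom = "chr1", start = 500L, end = 800L),
                   g3, pwm)
  expect_equal(s3$start, 620L)
  expect_equal(s3$strand, "-")
})

test_that("raising the p-value cutoff never loses called peaks", {
  pwm <- ctcf_example_pwm()
  g <- tiny_genome(c(chr1 = 60000L), seed = 21)
  pk <- tibble::tibble(chrom = "chr1",
                       start = seq(0L, 59000L, by = 300L))
  pk$end <- pk$start + 200L
  cuts <- c(1e-5, 1e-4, 5e-4, 5e-3)
  ns <- vapply(cuts, function(ct) nrow(call_sites(pk, g, pwm, ct)), numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("chance hit rate on random peaks is consistent with the family-wise bound", {
  pwm <- ctcf_example_pwm()
  d <- score_distribution(pwm)
  alpha <- max(d$tail[d$tail <= 5e-4])
  naive <- 1 - (1 - alpha)^(2 * (200 - pwm$width + 1))
  set.seed(31)
  g <- setNames(paste(rand_dna(1, 200 * 1500)), "chr1")
  pk <- tibble::tibble(chrom = "chr1",
                       start = seq(0L, by = 200L, length.out = 1500L))
  pk$end <- pk$start + 200L
  obs <- nrow(call_sites(pk, g, pwm)) / 1500
  # overlapping windows are positively correlated, so the observed rate sits
  # at or just below the independence bound
  expect_lt(obs, 1.15 * naive)
  expect_gt(obs, 0.6 * naive)
})

test_that("per-dataset call rate tracks the implant probability in 0.8-0.95", {
  pwm <- ctcf_example_pwm()
  cons <- pwm_consensus(pwm)
  set.seed(55)
  for (p_implant in c(0.8, 0.95)) {
    n <- 400L
    g <- setNames(paste(rand_dna(1, 200 * n)), "chr1")
    has <- runif(n) < p_implant
    for (i in which(has)) g <- implant(g, "chr1", (i - 1L) * 200L + 90L, cons)
    pk <- tibble::tibble(chrom = "chr1",
                         start = seq(0L, by = 200L, length.out = n))
    pk$end <- pk$start + 200L
    rate <- nrow(call_sites(pk, g, pwm)) / n
    expect_equal(rate, p_implant + (1 - p_implant) * 0.12, tolerance = 0.07)
  }
})

test_that("PWM text round-trip preserves probabilities", {
  pwm <- random_pwm(7, seed = 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_equal(back$probs, pwm$probs, tolerance = 1e-5,
               ignore_attr = TRUE)
})
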