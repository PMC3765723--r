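mk_pairs <- function(r1, r2, chrom = "chr1") {
  tibble::tibble(pair_id = seq_along(r1),
                 chrom1 = chrom, start1 = r1, end1 = r1 + 2000L,
                 chrom2 = chrom, start2 = r2, end2 = r2 + 2000L)
}

test_that("a site in regions of several pairs is counted once", {
  site <- tibble::tibble(chrom = "chr1", start = 1500L, end = 1516L)
  pairs <- mk_pairs(c(1000L, 1200L, 900L), c(50000L, 60000L, 70000L))
  out <- sites_in_interactions(site, pairs)
  expect_equal(out$n_in_interaction, 1L)
  expect_equal(out$proportion, 1)
  none <- sites_in_interactions(site, pairs[0, ])
  expect_equal(none$n_in_interaction, 0L)
  expect_equal(none$n_sites, 1L)
})

test_that("printed contingency counts reproduce the published odds ratios", {
  # K562 cCTCF vs non-constitutive
  e1 <- enrichment_test(14178, 23577, 13316, 81464)
  expect_equal(round(e1$odds_ratio, 1), 7.7)
  expect_lt(e1$p_value, 1e-300)
  # MCF7
  e2 <- enrichment_test(19398, 23641, 23701, 67752)
  expect_equal(round(e2$odds_ratio, 1), 8.5)
  # K562 cCTCF/cCohesin vs cCTCF without cCohesin
  e3 <- enrichment_test(8714, 12014, 5464, 11563)
  expect_equal(round(e3$odds_ratio, 1), 2.9)
  # MCF7 likewise
  e4 <- enrichment_test(10796, 12001, 8602, 11640)
  expect_equal(round(e4$odds_ratio, 1), 3.2)
  # and the printed proportions
  expect_equal(round(e1$proportions[[1]], 2), 0.60)
  expect_equal(round(e1$proportions[[2]], 2), 0.16)
  expect_equal(round(e2$proportions[[1]], 2), 0.82)
  expect_equal(round(e3$proportions[[1]], 2), 0.73)
})

test_that("the symmetric table gives odds ratio 1 and the exact tail p", {
  e <- enrichment_test(10, 20, 10, 20)
  expect_equal(e$odds_ratio, 1)
  expect_equal(e$p_value, hyper_tail_oracle(10, 10, 10, 10))
  expect_equal(e$p_value, 0.6238144, tolerance = 1e-6)
})

test_that("one-sided Fisher p matches the hypergeometric-sum oracle", {
  set.seed(8)
  for (i in 1:200) {
    r1 <- sample.int(50, 1); r2 <- sample.int(50, 1)
    a <- sample.int(r1 + 1, 1) - 1L; c_ <- sample.int(r2 + 1, 1) - 1L
    e <- enrichment_test(a, r1, c_, r2)
    expect_equal(e$p_value, hyper_tail_oracle(a, r1 - a, c_, r2 - c_),
                 tolerance = 1e-12)
  }
  # and stats::fisher.test agrees on a handful of tables
  for (tb in list(c(8, 20, 3, 25), c(1, 10, 5, 12), c(30, 40, 10, 45))) {
    e <- enrichment_test(tb[1], tb[2], tb[3], tb[4])
    ft <- stats::fisher.test(matrix(c(tb[1], tb[2] - tb[1],
                                      tb[3], tb[4] - tb[3]), 2,
                                    byrow = TRUE),
                             alternative = "greater")
    expect_equal(e$p_value, ft$p.value, tolerance = 1e-9)
  }
})

test_that("zero-cell odds ratios are flagged as infinite", {
  e <- enrichment_test(10, 10, 5, 20)
  expect_true(is.infinite(e$odds_ratio))
  expect_true(e$zero_cell)
  expect_error(enrichment_test(5, 3, 1, 2), "in <= total")
})

test_that("fractional counting reproduces the worked half-count example", {
  # region1 holds a cCTCF and a non-constitutive site, region2 one
  # non-constitutive site
  pairs <- mk_pairs(1000L, 50000L)
  cctcf <- tibble::tibble(chrom = "chr1", start = 1100L, end = 1116L)
  nonc <- tibble::tibble(chrom = "chr1", start = c(1400L, 50500L),
                         end = c(1416L, 50516L))
  fc <- fractional_type_counts(pairs, cctcf, nonc)
  get <- function(t1, t2) fc$count[fc$type1 == t1 & fc$type2 == t2]
  expect_equal(get("cCTCF", "non_constitutive"), 0.5)
  expect_equal(get("non_constitutive", "non_constitutive"), 0.5)
  expect_equal(sum(fc$count), 1)

  # both regions single cCTCF
  fc2 <- fractional_type_counts(mk_pairs(1000L, 50000L),
                                tibble::tibble(chrom = "chr1",
                                               start = c(1100L, 50100L),
                                               end = c(1116L, 50116L)),
                                nonc[0, ])
  expect_equal(fc2$count[fc2$type1 == "cCTCF" & fc2$type2 == "cCTCF"], 1)

  # both regions {cCTCF, nonconst}: quarter / half / quarter
  cctcf3 <- tibble::tibble(chrom = "chr1", start = c(1100L, 50100L),
                           end = c(1116L, 50116L))
  nonc3 <- tibble::tibble(chrom = "chr1", start = c(1400L, 50400L),
                          end = c(1416L, 50416L))
  fc3 <- fractional_type_counts(mk_pairs(1000L, 50000L), cctcf3, nonc3)
  get3 <- function(t1, t2) fc3$count[fc3$type1 == t1 & fc3$type2 == t2]
  expect_equal(get3("cCTCF", "cCTCF"), 0.25)
  expect_equal(get3("cCTCF", "non_constitutive"), 0.5)
  expect_equal(get3("non_constitutive", "non_constitutive"), 0.25)
})

test_that("fractional counts sum exactly to the pair count on random input", {
  set.seed(12)
  n <- 400L
  pairs <- mk_pairs(sample.int(1e6, n), sample.int(1e6, n))
  cctcf <- tibble::tibble(chrom = "chr1", start = sample.int(1e6, 300))
  cctcf$end <- cctcf$start + 16L
  nonc <- tibble::tibble(chrom = "chr1", start = sample.int(1e6, 300))
  nonc$end <- nonc$start + 16L
  fc <- fractional_type_counts(pairs, cctcf, nonc)
  expect_equal(sum(fc$count), n)
  expect_equal(glance(fc)$total_count, n)

  # swapping region1/region2 of every pair changes nothing
  swapped <- dplyr::rename(pairs, chrom1 = chrom2, start1 = start2,
                           end1 = end2, chrom2 = chrom1, start2 = start1,
                           end2 = end1)
  fcs <- fractional_type_counts(swapped, cctcf, nonc)
  expect_equal(fc$count, fcs$count)
})

test_that("paired-BED interaction round-trip preserves coordinates", {
  pairs <- mk_pairs(c(100L, 5000L), c(90000L, 70000L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(pairs, f)
  back <- read_interactions(f)
  expect_equal(back[, -1], pairs[, -1])
})
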