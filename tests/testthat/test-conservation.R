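block_of <- function(species, texts, start = 1000L, chrom = "chr1") {
  tibble::tibble(species = species, chrom = chrom, start = start,
                 size = nchar(gsub("-", "", texts)), strand = "+",
                 src_size = 1e6L, text = texts)
}

test_that("merge_blocks concatenates rows and gap-fills absent species", {
  b1 <- block_of(c("hg19", "sp1"), c("ACGT", "AC-T"), start = 100L)
  b2 <- block_of(c("hg19", "sp2"), c("TTGG", "TTGG"), start = 104L)
  expect_identical(merge_blocks(list(b1)), b1)
  m <- merge_blocks(list(b1, b2))
  expect_equal(m$text[m$species == "hg19"], "ACGTTTGG")
  expect_equal(m$text[m$species == "sp1"], "AC-T----")
  expect_equal(m$text[m$species == "sp2"], "----TTGG")
  expect_equal(m$start[1], 100L)
  expect_equal(m$size[1], 8L)
  # overlapping blocks are a hard error
  b2bad <- block_of("hg19", "TTGG", start = 102L)
  expect_error(merge_blocks(list(b1, b2bad)), "overlap")
})

test_that("species_with_hit counts gap-stripped rows passing the cutoff", {
  pwm <- ctcf_example_pwm()
  cons <- pwm_consensus(pwm)
  ref <- paste0("ACGTACGTAC", cons, "GTACGTACGT")
  one <- block_of("hg19", ref)
  expect_equal(species_with_hit(one, pwm), 1L)

  five <- block_of(paste0("sp", 1:5), rep(ref, 5))
  expect_equal(species_with_hit(five, pwm), 5L)

  # gapped copy of the same sequence still hits after stripping
  gapped <- paste0(substr(ref, 1, 5), "--", substr(ref, 6, nchar(ref)))
  expect_equal(species_with_hit(block_of(c("hg19", "sp1"), c(ref, gapped)),
                                pwm), 2L)

  # row shorter than the PWM width after gap removal cannot hit
  shorty <- block_of(c("hg19", "sp1"), c(ref, paste0("ACGT", strrep("-", 32))))
  expect_equal(species_with_hit(shorty, pwm), 1L)
  expect_lte(species_with_hit(five, pwm), nrow(five))
})

test_that("MAF write/read round-trips block structure", {
  b1 <- block_of(c("hg19.chr1", "sp1.chr4"), c("ACGTAC", "AC--AC"))
  b1$species <- c("hg19", "sp1"); b1$chrom <- c("chr1", "chr4")
  f <- withr::local_tempfile(fileext = ".maf")
  write_maf(list(b1, b1), f)
  back <- read_maf(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$species, c("hg19", "sp1"))
  expect_equal(back[[1]]$text, c("ACGTAC", "AC--AC"))
  expect_equal(back[[1]]$start, c(1000L, 1000L))
})

test_that("split blocks merge back to identical hit counts", {
  cfg <- ctcf_sim_config(seed = 33, n_species = 12L)
  pwm <- ctcf_example_pwm()
  whole <- simulate_alignments(cfg, n_sites = 30L, retention = 0.5, pwm = pwm)
  split <- simulate_alignments(cfg, n_sites = 30L, retention = 0.5, pwm = pwm,
                               split = TRUE)
  merged <- lapply(split$blocks, merge_blocks)
  c_whole <- conservation_counts(lapply(whole$blocks, merge_blocks), pwm)
  c_split <- conservation_counts(merged, pwm)
  expect_identical(c_whole$n_species_hit, c_split$n_species_hit)
})

test_that("full retention gives hits in every species", {
  cfg <- ctcf_sim_config(seed = 3, n_species = 10L)
  aln <- simulate_alignments(cfg, n_sites = 20L, retention = 1, pwm = ctcf_example_pwm())
  cc <- conservation_counts(lapply(aln$blocks, merge_blocks), ctcf_example_pwm())
  expect_true(all(cc$n_species_hit == 10L))
})

test_that("planted retention probabilities are recovered", {
  cfg <- ctcf_sim_config(seed = 47)
  pwm <- ctcf_example_pwm()
  for (ret in c(20 / 46, 10 / 46)) {
    aln <- simulate_alignments(cfg, n_sites = 600L, retention = ret,
                               pwm = pwm, seed_offset = round(100 * ret))
    cc <- conservation_counts(lapply(aln$blocks, merge_blocks), pwm)
    est <- estimate_retention(cc$n_species_hit, cfg$n_species, pwm,
                              seq_length = 36L)
    expect_equal(est$retention, ret, tolerance = 0.1)
  }
})

test_that("conservation summaries are deterministic functions of the counts", {
  s <- conservation_summary(a = c(20, 20, 20), b = c(20, 20, 20))
  expect_equal(s$mean, c(20, 20))
  expect_equal(s$median, c(20, 20))
  expect_equal(tidy(s)[tidy(s)$class == "a", -1],
               tidy(s)[tidy(s)$class == "b", -1])
  expect_error(conservation_summary(a = numeric(0)), "non-empty")
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})
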