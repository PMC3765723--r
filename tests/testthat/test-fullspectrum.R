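test_that("extended sequence extraction is oriented and edge-safe", {
  pwm <- ctcf_example_pwm()
  cons <- pwm_consensus(pwm)
  g <- tiny_genome(c(chr1 = 3000L), seed = 2)
  g <- implant(g, "chr1", 1000L, cons)
  sites <- tibble::tibble(chrom = "chr1", start = c(1000L, 10L),
                          end = c(1016L, 26L), strand = c("+", "+"))
  expect_warning(seqs <- extract_extended_sequences(sites, g, flank = 30L),
                 "skipped")
  expect_length(seqs, 1L)
  expect_equal(unname(nchar(seqs)), 76L)
  expect_equal(unname(substr(seqs, 31L, 46L)), cons)

  # minus-strand site: extended string is the reverse complement slice
  sites_m <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1016L,
                            strand = "-")
  sm <- extract_extended_sequences(sites_m, g, flank = 30L)
  fwd <- extract_extended_sequences(
    dplyr::mutate(sites_m, strand = "+"), g, flank = 30L)
  expect_equal(unname(sm),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(unname(fwd)))))
})

test_that("positional k-mer geometry: 72 positions and 1024 columns", {
  seqs <- rand_dna(5, 76, seed = 7)
  pk <- positional_kmer_counts(seqs, k = 5L)
  expect_equal(nrow(pk$counts), 72L)      # 30 + 30 + 16 - 5 + 1
  expect_equal(ncol(pk$counts), 1024L)
  expect_error(positional_kmer_counts(c("ACGT", "ACGTT")), "same length")
})

test_that("presence counting is per-sequence 0/1 with one k-mer per position", {
  seqs <- rep(rand_dna(1, 40, seed = 9), 3)
  pk <- positional_kmer_counts(seqs, k = 5L)
  expect_true(all(pk$counts[pk$counts > 0] == 3L))
  # each sequence contributes exactly one k-mer per position
  expect_true(all(rowSums(pk$counts) == 3L))
  # N voids the window
  pkN <- positional_kmer_counts(c("ACGTNACGTA"), k = 5L)
  expect_equal(rowSums(pkN$counts), c(0, 0, 0, 0, 0, 1))
})

test_that("composite from a degenerate input reproduces the shared word", {
  # every sequence has the same left-flank word at a fixed offset
  base <- rand_dna(20, 76, seed = 13)
  word <- "GGATC"
  seqs <- vapply(base, function(s) { substr(s, 11, 15) <- word; s },
                 character(1), USE.NAMES = FALSE)
  pk <- positional_kmer_counts(seqs, k = 5L)
  cm <- suppressWarnings(build_composite_motif(pk, "left", top_n = 1L))
  # offsets covered 0..33; the word occupies window offsets 10..14
  hit <- cm$probs[cm$offsets %in% 10:14, ]
  expect_equal(ctcfconst:::DNA_BASES[apply(hit, 1, which.max)],
               strsplit(word, "")[[1]])
  expect_equal(cm$kmers$kmer[1], word)
  expect_equal(unname(rowSums(cm$probs)), rep(1, nrow(cm$probs)))
})

test_that("an implanted right-flank repeat is recovered by the ranking", {
  set.seed(41)
  seqs <- rand_dna(300, 76)
  implant_word <- "GGAGGAGGAG"
  sel <- runif(300) < 0.6
  seqs[sel] <- vapply(seqs[sel], function(s) {
    substr(s, 47, 56) <- implant_word; s
  }, character(1), USE.NAMES = FALSE)
  pk <- positional_kmer_counts(seqs, k = 5L)
  cm <- build_composite_motif(pk, "right", top_n = 50L)
  # the repeat contains only three distinct 5-mers; they must lead the ranking
  top3 <- cm$kmers$kmer[1:3]
  expect_true(all(vapply(top3, function(km)
    grepl(km, implant_word, fixed = TRUE), logical(1))))
  # dominant composite bases reconstruct the implant at its offsets
  rows <- cm$offsets %in% 46:55
  rec <- paste(ctcfconst:::DNA_BASES[apply(cm$probs[rows, ], 1, which.max)],
               collapse = "")
  expect_equal(rec, implant_word)
})

test_that("composite construction is invariant to sequence order", {
  seqs <- rand_dna(50, 76, seed = 77)
  pk1 <- positional_kmer_counts(seqs, 5L)
  pk2 <- positional_kmer_counts(rev(seqs), 5L)
  c1 <- suppressWarnings(build_composite_motif(pk1, "left", 20L))
  c2 <- suppressWarnings(build_composite_motif(pk2, "left", 20L))
  expect_equal(c1$probs, c2$probs)
})

test_that("motif prevalence recovers a planted flank implant rate", {
  set.seed(59)
  n <- 1200L
  seqs <- rand_dna(n, 76)
  word <- "TGCAGTACCACTGGAG"
  sel <- runif(n) < 0.15
  seqs[sel] <- vapply(seqs[sel], function(s) {
    substr(s, 15, 30) <- word; s
  }, character(1), USE.NAMES = FALSE)
  wm <- pwm_model(t(vapply(strsplit(word, "")[[1]], function(b) {
    v <- rep(0.02, 4); v[match(b, c("A", "C", "G", "T"))] <- 0.94; v
  }, numeric(4))))
  prev <- motif_prevalence(list(planted = seqs), wm, offset = 14L)
  expect_equal(prev$prevalence, 0.15, tolerance = 0.25)
  # never-implanted class: prevalence is the false-positive rate
  prev0 <- motif_prevalence(list(bg = rand_dna(1200, 76)), wm, offset = 14L)
  expect_lt(prev0$prevalence, 0.01)
  expect_error(motif_prevalence(list(empty = character(0)), wm, offset = 0L),
               "at least one")
})

test_that("composite PFM writer emits four JASPAR-style rows", {
  pk <- positional_kmer_counts(rand_dna(10, 76, seed = 3), 5L)
  cm <- suppressWarnings(build_composite_motif(pk, "right", 10L))
  f <- withr::local_tempfile(fileext = ".pfm")
  write_composite_motif(cm, f)
  lines <- readLines(f)
  expect_equal(length(lines), 5L)
  expect_true(startsWith(lines[2], "A"))
  expect_true(file.exists(paste0(f, ".kmers.tsv")))
})
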