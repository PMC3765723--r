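small_cfg <- function(...) {
  base <- list(seed = 5, chrom_lengths = c(chr1 = 8e5, chr2 = 8e5),
               n_constitutive = 50L, n_shared = 20L,
               n_specific_per_line = 3L, n_interaction_pairs = 200L,
               n_genes = 8L)
  do.call(ctcf_sim_config, utils::modifyList(base, list(...)))
}

test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  s1 <- simulate_sites(cfg, g1); s2 <- simulate_sites(cfg, g2)
  expect_identical(s1, s2)
  p1 <- simulate_peak_sets(cfg, s1$sites)
  p2 <- simulate_peak_sets(cfg, s2$sites)
  expect_identical(p1, p2)
  expect_identical(simulate_domains(cfg), simulate_domains(cfg))
})

test_that("genome has the configured size and near-uniform composition", {
  cfg <- ctcf_sim_config(seed = 2, chrom_lengths = c(chrA = 1e5, chrB = 2e5))
  g <- simulate_genome(cfg)
  expect_equal(unname(nchar(g)), c(1e5, 2e5))
  tab <- table(strsplit(g[["chrA"]], "")[[1]])
  # 3-sigma binomial bound around 0.25 at n = 1e5
  expect_true(all(abs(tab / 1e5 - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
})

test_that("planted sites have expected tier structure and implants", {
  cfg <- small_cfg()
  st <- simulate_sites(cfg, simulate_genome(cfg))
  sites <- st$sites
  expect_equal(sum(sites$tier == "constitutive"), 50L)
  expect_equal(sum(sites$tier == "specific"), 3L * 56L)
  expect_true(all(sites$implanted[sites$tier == "constitutive"]))
  # implanted consensus is present in the genome at the site coordinates
  pwm <- ctcf_example_pwm()
  i <- which(sites$tier == "constitutive")[1]
  seq <- substr(st$genome[[sites$chrom[i]]], sites$start[i] + 1L,
                sites$end[i])
  if (sites$strand[i] == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  expect_equal(seq, pwm_consensus(pwm))
  # sites are non-overlapping with generous spacing
  sites <- dplyr::arrange(sites, chrom, start)
  gaps <- diff(sites$start)
  same <- sites$chrom[-1] == sites$chrom[-nrow(sites)]
  expect_true(all(gaps[same] >= cfg$site_spacing))
})

test_that("per-line occurrence matches the dropout expectation", {
  cfg <- small_cfg(dropout = 0.02, n_constitutive = 150L)
  st <- simulate_sites(cfg, simulate_genome(cfg))
  peaks <- simulate_peak_sets(cfg, st$sites)
  ctcf <- peaks[peaks$factor == "CTCF", ]
  occ <- dplyr::count(ctcf, site_id)
  const_ids <- st$sites$site_id[st$sites$tier == "constitutive"]
  counts <- occ$n[occ$site_id %in% const_ids]
  expect_equal(mean(counts), 56 * 0.98, tolerance = 0.01)
  # specific sites appear in exactly one line
  spec_ids <- st$sites$site_id[st$sites$tier == "specific"]
  expect_true(all(occ$n[occ$site_id %in% spec_ids] == 1L))
})

test_that("full cohesin co-location yields peaks in every cohesin line", {
  cfg <- small_cfg(cohesin_full_prob = 1, cohesin_none_prob = 0)
  st <- simulate_sites(cfg, simulate_genome(cfg))
  peaks <- simulate_peak_sets(cfg, st$sites)
  const_ids <- st$sites$site_id[st$sites$tier == "constitutive"]
  coh <- peaks[peaks$factor != "CTCF", ]
  per_site <- dplyr::count(dplyr::distinct(coh, site_id, factor, cell_line),
                           site_id)
  expect_true(all(const_ids %in% per_site$site_id))
  expect_true(all(per_site$n[per_site$site_id %in% const_ids] ==
                    cfg$n_rad21_lines + cfg$n_smc3_lines))
})

test_that("a null odds-ratio target is realized near 1", {
  cfg <- ctcf_sim_config(seed = 29, chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
                         n_interaction_pairs = 3000L, target_or = 1)
  set.seed(29)
  cc <- make_coord_sites(400, cfg$chrom_lengths)
  nc <- make_coord_sites(2000, cfg$chrom_lengths)
  # keep the two site sets disjoint
  key <- paste(nc$chrom, nc$start)
  nc <- nc[!key %in% paste(cc$chrom, cc$start), ]
  dom <- simulate_domains(cfg)
  sim <- simulate_interactions(cfg, cc, nc, dom)
  e <- enrichment_test(
    sites_in_interactions(cc, sim$pairs)$n_in_interaction, nrow(cc),
    sites_in_interactions(nc, sim$pairs)$n_in_interaction, nrow(nc))
  expect_equal(e$odds_ratio, 1, tolerance = 0.35)
})

test_that("an infeasible odds-ratio target errors with guidance", {
  cfg <- small_cfg(n_interaction_pairs = 10L, target_or = 50)
  set.seed(1)
  cc <- make_coord_sites(100, c(chr1 = 8e5, chr2 = 8e5), spacing = 2400L)
  nc <- make_coord_sites(100, c(chr1 = 8e5, chr2 = 8e5), spacing = 3000L)
  dom <- simulate_domains(ctcf_sim_config(seed = 2,
                                          chrom_lengths = c(chr1 = 2e7)))
  expect_error(simulate_interactions(cfg, cc, nc, dom), "infeasible")
})

test_that("selected sites are always inside a pair region, unselected never", {
  cfg <- ctcf_sim_config(seed = 41, chrom_lengths = c(chr1 = 2e7),
                         n_interaction_pairs = 500L)
  set.seed(41)
  cc <- make_coord_sites(150, cfg$chrom_lengths)
  nc <- make_coord_sites(150, cfg$chrom_lengths)
  key <- paste(nc$chrom, nc$start)
  nc <- nc[!key %in% paste(cc$chrom, cc$start), ]
  dom <- simulate_domains(cfg)
  sim <- simulate_interactions(cfg, cc, nc, dom)
  regions <- dplyr::bind_rows(
    tibble::tibble(chrom = sim$pairs$chrom1, start = sim$pairs$start1,
                   end = sim$pairs$end1),
    tibble::tibble(chrom = sim$pairs$chrom2, start = sim$pairs$start2,
                   end = sim$pairs$end2))
  mem <- sim$membership
  in_cc <- ctcfconst:::overlap_any(cc, regions)
  expect_identical(in_cc, mem$selected[mem$class == "cCTCF"])
  in_nc <- ctcfconst:::overlap_any(nc, regions)
  expect_identical(in_nc, mem$selected[mem$class != "cCTCF"])
})

test_that("domain lengths track the configured median and mean", {
  cfg <- ctcf_sim_config(seed = 13,
                         chrom_lengths = c(chr1 = 6e7, chr2 = 6e7))
  dom <- simulate_domains(cfg)
  len <- dom$end - dom$start
  expect_gt(nrow(dom), 50)
  expect_equal(median(len), 680e3, tolerance = 0.15)
  expect_equal(mean(len), 852e3, tolerance = 0.15)
  # non-overlapping and sorted within chromosomes
  by_ch <- split(dom, dom$chrom)
  for (d in by_ch) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
})
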