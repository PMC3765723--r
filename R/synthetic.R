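# Synthetic study generator: emulates the statistical structure of a
# multi-cell-line CTCF/cohesin ChIP-seq compendium -- a constitutive core of
# sites shared by almost all cell lines, cell-specific singletons, cohesin
# co-localization, ChIA-PET pairs enriched for constitutive sites at a target
# odds ratio, topological domains holding most interactions, and
# multi-species alignments with class-dependent motif retention -- so every
# analysis stage can be scored against planted ground truth.

#' Configuration for the synthetic CTCF study generator
#'
#' Defaults are the study conditions of the analysis the package implements:
#' 56 CTCF cell lines (6 Rad21, 4 Smc3), 200-bp peaks, the >90 percent
#' constitutive rule, in-interaction probabilities 0.60/0.16 (odds ratio
#' 7.7), 87 percent of pairs inside domains with 80 percent of those in the
#' same domain, domain lengths with mean/median 852/680 kb, 46 alignment
#' species with retention 20/46 vs 10/46, and DNase co-location 0.74.
#' Per-cell-line dropout defaults to 0.025, the value at which the expected
#' share of constitutive sites seen in all 56 lines matches the observed
#' ~24 percent.
#'
#' @param seed Integer seed fixing all generator output bit-exactly.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_cell_lines,n_rad21_lines,n_smc3_lines Survey sizes per factor.
#' @param n_constitutive,n_shared,n_specific_per_line Site tier sizes;
#'   "shared" sites appear in 2-10 random lines, "specific" in exactly one.
#' @param dropout Per-cell-line probability that a constitutive site's peak
#'   is missed.
#' @param peak_length,peak_jitter Peak geometry (bp).
#' @param n_replicates CTCF replicate datasets per cell line.
#' @param implant_prob_specific,implant_prob_shared Probability that a
#'   non-constitutive site carries the core motif (constitutive sites always
#'   do); tunes the per-dataset site-call rate into the 80-95 percent range.
#' @param cohesin_full_prob,cohesin_none_prob Probability that a constitutive
#'   site has cohesin peaks in all cohesin lines / in none (remainder:
#'   partial, 1-3 lines).
#' @param cohesin_dropout Per-line dropout for cohesin peaks (default 0).
#' @param flank_left_prob,flank_right_prob Named vectors (`cohesin`,
#'   `non_cohesin`) of probabilities that a constitutive site carries the
#'   extended left / right flank word.
#' @param site_spacing Minimum spacing between planted sites (bp); keeps
#'   2-kb interaction anchors from touching neighbouring sites.
#' @param n_interaction_pairs,anchor_width,target_or,p_nonconst_in ChIA-PET
#'   generator: pair count, anchor width (bp), planted odds ratio, planted
#'   in-interaction probability for non-constitutive sites.
#' @param frac_pairs_in_domains,same_domain_frac Planted domain placement of
#'   interaction pairs.
#' @param domain_median,domain_mean,domain_gap_range Domain length
#'   distribution (log-normal with this median and mean) and inter-domain
#'   gap range (bp).
#' @param n_species,retention_cctcf,retention_nonconst,alignment_flank
#'   Conservation generator: species count, per-species motif retention
#'   probability per class, flank bp around the core in each alignment row.
#' @param n_genes,gene_length_range Gene-annotation generator.
#' @param dnase_colocal_prob Probability a site has a co-located open
#'   chromatin peak per cell line.
#' @return A list of class `ctcf_sim_config`.
#' @export
ctcf_sim_config <- function(
    seed = 1L,
    chrom_lengths = c(chr1 = 3e6, chr2 = 3e6),
    n_cell_lines = 56L, n_rad21_lines = 6L, n_smc3_lines = 4L,
    n_constitutive = 300L, n_shared = 100L, n_specific_per_line = 25L,
    dropout = 0.025,
    peak_length = 200L, peak_jitter = 20L, n_replicates = 1L,
    implant_prob_specific = 0.875, implant_prob_shared = 0.875,
    cohesin_full_prob = 0.51, cohesin_none_prob = 0.04,
    cohesin_dropout = 0,
    flank_left_prob = c(cohesin = 0.148, non_cohesin = 0.038),
    flank_right_prob = c(cohesin = 0.082, non_cohesin = 0.037),
    site_spacing = 2400L,
    n_interaction_pairs = 2000L, anchor_width = 2000L,
    target_or = 7.7, p_nonconst_in = 0.16,
    frac_pairs_in_domains = 0.87, same_domain_frac = 0.8,
    domain_median = 680e3, domain_mean = 852e3,
    domain_gap_range = c(2e4, 8e4),
    n_species = 46L, retention_cctcf = 20 / 46, retention_nonconst = 10 / 46,
    alignment_flank = 10L,
    n_genes = 40L, gene_length_range = c(5e3, 2e5),
    dnase_colocal_prob = 0.74) {
  cfg <- as.list(environment())
  probs <- c(dropout, implant_prob_specific, implant_prob_shared,
             cohesin_full_prob, cohesin_none_prob, cohesin_dropout,
             flank_left_prob, flank_right_prob, p_nonconst_in,
             frac_pairs_in_domains, same_domain_frac,
             retention_cctcf, retention_nonconst, dnase_colocal_prob)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must be in [0, 1].")
  if (cohesin_full_prob + cohesin_none_prob > 1) {
    abort("cohesin_full_prob + cohesin_none_prob must be <= 1.")
  }
  if (any(chrom_lengths < 1e4)) abort("Chromosome lengths must be >= 10 kb.")
  if (target_or <= 0) abort("`target_or` must be > 0.")
  if (domain_mean < domain_median) abort("`domain_mean` must be >= `domain_median`.")
  structure(cfg, class = "ctcf_sim_config")
}

sim_seed <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(config$seed + offset)
  invisible(NULL)
}

#' Generate a random genome
#'
#' I.i.d. uniform A/C/G/T sequences for each configured chromosome,
#' reproducible from the seed.
#'
#' @param config A [ctcf_sim_config()].
#' @return Named character vector of chromosome sequences.
#' @export
simulate_genome <- function(config) {
  sim_seed(config, 0L)
  vapply(config$chrom_lengths, function(len) {
    intToUtf8(utf8ToInt("ACGT")[sample.int(4L, len, replace = TRUE)])
  }, character(1))
}

# fixed flank words used for full-spectrum implants (left word abuts the
# core on its 5' side, right word on its 3' side of the oriented window)
FLANK_LEFT_WORD <- "TGCAGTACCACTGGAG"   # 16 bp -> 16+16 = 32/33-mer analogue
FLANK_RIGHT_WORD <- "GGAGGAGGAG"        # 10 bp GAGA-repeat-like

#' Plant binding sites and implant motifs into a genome
#'
#' Chooses non-overlapping site positions (spacing `site_spacing`), assigns
#' each to a tier (constitutive / shared-in-2-10-lines / cell-specific),
#' draws strand, cohesin status and flank-word implants, and writes the core
#' consensus (and any flank words) into the genome sequence at the oriented
#' offsets.
#'
#' @param config A [ctcf_sim_config()].
#' @param genome Named character vector from [simulate_genome()].
#' @param pwm The `pwm_model` whose consensus is implanted.
#' @return A list: `genome` (with implants), `sites` (truth tibble:
#'   `site_id`, `chrom`, `start`, `end`, `strand`, `tier`, `cell_line`
#'   (specific tier), `lines` (list column, shared tier), `cohesin`,
#'   `implanted`, `flank_left`, `flank_right`).
#' @export
simulate_sites <- function(config, genome, pwm = ctcf_example_pwm()) {
  sim_seed(config, 1L)
  w <- pwm$width
  flank <- 30L
  n_specific <- config$n_specific_per_line * config$n_cell_lines
  n_total <- config$n_constitutive + config$n_shared + n_specific
  slots <- purrr::imap(config$chrom_lengths, function(len, ch) {
    pos <- seq.int(200L + flank, len - 200L - flank - w, by = config$site_spacing)
    tibble(chrom = ch, start = pos)
  }) |> bind_rows()
  if (nrow(slots) < n_total) {
    abort(sprintf("Genome too small: %d site slots available, %d needed.",
                  nrow(slots), n_total))
  }
  picked <- slots[sample.int(nrow(slots), n_total), ]
  sites <- tibble(
    site_id = seq_len(n_total),
    chrom = picked$chrom,
    start = as.integer(picked$start),
    end = as.integer(picked$start + w),
    strand = sample(c("+", "-"), n_total, replace = TRUE),
    tier = rep(c("constitutive", "shared", "specific"),
               c(config$n_constitutive, config$n_shared, n_specific)))
  lines <- paste0("L", seq_len(config$n_cell_lines))
  sites$cell_line <- NA_character_
  sites$cell_line[sites$tier == "specific"] <-
    rep(lines, each = config$n_specific_per_line)
  sites$lines <- vector("list", n_total)
  shared_idx <- which(sites$tier == "shared")
  sites$lines[shared_idx] <- lapply(shared_idx, function(i) {
    sample(lines, sample(2:10, 1))
  })
  is_const <- sites$tier == "constitutive"
  coh <- rep(NA_character_, n_total)
  coh[is_const] <- sample(
    c("full", "none", "partial"), sum(is_const), replace = TRUE,
    prob = c(config$cohesin_full_prob, config$cohesin_none_prob,
             1 - config$cohesin_full_prob - config$cohesin_none_prob))
  sites$cohesin <- coh
  sites$implanted <- TRUE
  sites$implanted[sites$tier == "specific"] <-
    runif(n_specific) < config$implant_prob_specific
  sites$implanted[sites$tier == "shared"] <-
    runif(config$n_shared) < config$implant_prob_shared
  # flank words only examined for constitutive sites, by cohesin class
  pl <- ifelse(coh == "full", config$flank_left_prob[["cohesin"]],
               config$flank_left_prob[["non_cohesin"]])
  pr <- ifelse(coh == "full", config$flank_right_prob[["cohesin"]],
               config$flank_right_prob[["non_cohesin"]])
  sites$flank_left <- !is.na(coh) & runif(n_total) < pl
  sites$flank_right <- !is.na(coh) & runif(n_total) < pr
  consensus <- pwm_consensus(pwm)
  lw <- nchar(FLANK_LEFT_WORD); rw <- nchar(FLANK_RIGHT_WORD)
  for (i in seq_len(n_total)) {
    if (!sites$implanted[i]) next
    s <- sites$start[i]; ch <- sites$chrom[i]
    window <- genome_slice(genome, ch, s - flank, s + w + flank)
    if (sites$strand[i] == "-") window <- revcomp(window)
    substr(window, flank + 1L, flank + w) <- consensus
    if (sites$flank_left[i]) {
      substr(window, flank - lw + 1L, flank) <- FLANK_LEFT_WORD
    }
    if (sites$flank_right[i]) {
      substr(window, flank + w + 1L, flank + w + rw) <- FLANK_RIGHT_WORD
    }
    if (sites$strand[i] == "-") window <- revcomp(window)
    g <- genome[[ch]]
    substr(g, s - flank + 1L, s + w + flank) <- window
    genome[[ch]] <- g
  }
  list(genome = genome, sites = sites)
}

#' Generate per-cell-line ChIP-seq peak sets over planted sites
#'
#' CTCF peaks: constitutive sites appear in each cell line with probability
#' `1 - dropout`, shared sites in their assigned lines, specific sites in
#' exactly one line; peak centers jitter around the site center. Cohesin
#' (Rad21/Smc3) peaks cover constitutive sites according to their planted
#' cohesin status (`full` = every cohesin line, `partial` = 1-3 lines,
#' `none`).
#'
#' @param config A [ctcf_sim_config()].
#' @param sites Truth tibble from [simulate_sites()].
#' @return A tibble of peaks: `chrom`, `start`, `end`, `factor`, `cell_line`,
#'   `dataset`, `site_id`.
#' @export
simulate_peak_sets <- function(config, sites) {
  sim_seed(config, 2L)
  half <- config$peak_length %/% 2L
  jit <- config$peak_jitter
  mk_peaks <- function(idx, fac, line, rep_id) {
    if (!length(idx)) return(NULL)
    center <- interval_mid(sites$start[idx], sites$end[idx]) +
      sample(seq.int(-jit, jit), length(idx), replace = TRUE)
    tibble(chrom = sites$chrom[idx],
           start = as.integer(center - half),
           end = as.integer(center - half + config$peak_length),
           factor = fac, cell_line = line,
           dataset = sprintf("%s_%s_rep%d", fac, line, rep_id),
           site_id = sites$site_id[idx])
  }
  lines <- paste0("L", seq_len(config$n_cell_lines))
  const_idx <- which(sites$tier == "constitutive")
  out <- list()
  for (line in lines) {
    in_line <- c(
      const_idx[runif(length(const_idx)) >= config$dropout],
      which(sites$tier == "specific" & sites$cell_line == line),
      which(sites$tier == "shared" &
              purrr::map_lgl(sites$lines, ~ line %in% .x)))
    for (r in seq_len(config$n_replicates)) {
      out[[length(out) + 1L]] <- mk_peaks(in_line, "CTCF", line, r)
    }
  }
  coh_lines <- list(
    Rad21 = paste0("R", seq_len(config$n_rad21_lines)),
    Smc3 = paste0("S", seq_len(config$n_smc3_lines)))
  for (fac in names(coh_lines)) {
    full_idx <- which(!is.na(sites$cohesin) & sites$cohesin == "full")
    part_idx <- which(!is.na(sites$cohesin) & sites$cohesin == "partial")
    part_pick <- lapply(part_idx, function(i) {
      sample(coh_lines[[fac]], sample(1:3, 1))
    })
    for (line in coh_lines[[fac]]) {
      idx <- c(
        full_idx[runif(length(full_idx)) >= config$cohesin_dropout],
        part_idx[purrr::map_lgl(part_pick, ~ line %in% .x)])
      out[[length(out) + 1L]] <- mk_peaks(idx, fac, line, 1L)
    }
  }
  bind_rows(out)
}

#' Generate topological domains tiling the chromosomes
#'
#' Log-normal domain lengths with the configured median and mean, separated
#' by uniform gaps, tiled from the start of each chromosome.
#'
#' @param config A [ctcf_sim_config()].
#' @return A tibble: `chrom`, `start`, `end`, sorted and non-overlapping.
#' @export
simulate_domains <- function(config) {
  sim_seed(config, 3L)
  meanlog <- log(config$domain_median)
  sdlog <- sqrt(2 * log(config$domain_mean / config$domain_median))
  out <- list()
  for (ch in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[ch]]
    pos <- 0
    repeat {
      gap <- runif(1, config$domain_gap_range[1], config$domain_gap_range[2])
      dlen <- stats::rlnorm(1, meanlog, sdlog)
      if (pos + gap + dlen > len) break
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start = as.integer(round(pos + gap)),
        end = as.integer(round(pos + gap + dlen)))
      pos <- pos + gap + dlen
    }
  }
  bind_rows(out)
}

#' Generate ChIA-PET interaction pairs with planted enrichment
#'
#' Each constitutive site joins an interaction with probability p1 and each
#' non-constitutive site with probability p2 = `p_nonconst_in`, where p1 is
#' chosen so that the in-interaction odds ratio equals `target_or` in
#' expectation. Every selected site gets a 2-kb anchor that appears in at
#' least one pair; background anchors avoid all sites, so unselected sites
#' are in no pair. A planted fraction of pairs has both anchors inside
#' domains, and of those (same chromosome) a planted fraction in the same
#' domain.
#'
#' @param config A [ctcf_sim_config()].
#' @param cctcf_sites,nonconst_sites Site tibbles (truth tiers or pipeline
#'   calls).
#' @param domains Domain tibble from [simulate_domains()].
#' @return A list: `pairs` (tibble `pair_id`, `chrom1`, ..., `end2`),
#'   `membership` (tibble `site_id`, `class`, `selected`), `p1`, `p2`.
#' @export
simulate_interactions <- function(config, cctcf_sites, nonconst_sites,
                                  domains) {
  sim_seed(config, 4L)
  p2 <- config$p_nonconst_in
  if (p2 <= 0 || p2 >= 1) abort("`p_nonconst_in` must be in (0, 1).")
  odds1 <- config$target_or * p2 / (1 - p2)
  p1 <- odds1 / (1 + odds1)
  n_pairs <- config$n_interaction_pairs
  aw <- config$anchor_width
  sel_c <- runif(nrow(cctcf_sites)) < p1
  sel_n <- runif(nrow(nonconst_sites)) < p2
  site_anchor <- function(s, sel, cls) {
    if (!any(sel)) return(NULL)
    mid <- interval_mid(s$start[sel], s$end[sel])
    tibble(chrom = s$chrom[sel], start = as.integer(mid - aw %/% 2L),
           end = as.integer(mid + aw %/% 2L), required = TRUE, class = cls)
  }
  req <- bind_rows(site_anchor(cctcf_sites, sel_c, "cCTCF"),
                   site_anchor(nonconst_sites, sel_n, "non_constitutive"))
  n_req <- if (is.null(req)) 0L else nrow(req)
  if (n_req > n_pairs) {
    abort(sprintf(
      "Odds ratio %.2f infeasible: %d selected sites need anchors but only %d pairs requested; increase `n_interaction_pairs` or reduce site counts.",
      config$target_or, n_req, n_pairs))
  }
  all_sites <- bind_rows(cctcf_sites[, c("chrom", "start", "end")],
                         nonconst_sites[, c("chrom", "start", "end")])
  n_bg <- max(200L, 2L * n_pairs - n_req)
  bg <- list(); have <- 0L
  lens <- config$chrom_lengths
  while (have < n_bg) {
    need <- ceiling((n_bg - have) * 1.4)
    ch <- sample(names(lens), need, replace = TRUE,
                 prob = lens / sum(lens))
    ctr <- floor(runif(need, aw, unname(lens[ch]) - aw))
    cand <- tibble(chrom = ch, start = as.integer(ctr - aw %/% 2L),
                   end = as.integer(ctr + aw %/% 2L))
    cand <- cand[!overlap_any(cand, all_sites), , drop = FALSE]
    if (nrow(cand)) { bg[[length(bg) + 1L]] <- cand; have <- have + nrow(cand) }
  }
  bg <- bind_rows(bg)[seq_len(n_bg), ]
  bg$required <- FALSE; bg$class <- "neither"
  anchors <- bind_rows(req, bg)
  anchors <- assign_domains(anchors, domains)
  anchors$id <- seq_len(nrow(anchors))
  in_dom <- !is.na(anchors$domain)
  by_domain <- split(anchors$id[in_dom], anchors$domain[in_dom])
  out_ids <- anchors$id[!in_dom]
  if (!length(out_ids)) {
    warn("No out-of-domain anchors available; all pairs will be in domains.")
  }
  dom_chrom <- domains$chrom
  req_ids <- anchors$id[anchors$required]
  req_queue <- req_ids[sample.int(length(req_ids))]
  f_in <- config$frac_pairs_in_domains
  f_same <- config$same_domain_frac
  cat_probs <- c(same = f_in * f_same, cross = f_in * (1 - f_same),
                 out = 1 - f_in)
  pick <- function(ids, avoid = NULL) {
    pool <- setdiff(ids, avoid)
    if (!length(pool)) pool <- ids
    pool[sample.int(length(pool), 1L)]
  }
  r1 <- integer(n_pairs); r2 <- integer(n_pairs)
  cats <- sample(names(cat_probs), n_pairs, replace = TRUE, prob = cat_probs)
  in_ids <- anchors$id[in_dom]
  for (i in seq_len(n_pairs)) {
    required1 <- i <= length(req_queue)
    a1 <- if (required1) req_queue[i] else
      anchors$id[sample.int(nrow(anchors), 1L)]
    cat <- cats[i]
    if (!required1 && cat != "out" && is.na(anchors$domain[a1]) &&
        length(in_ids)) {
      a1 <- in_ids[sample.int(length(in_ids), 1L)]
    }
    d1 <- anchors$domain[a1]
    if (is.na(d1)) cat <- "out"
    a2 <- switch(
      cat,
      same = pick(by_domain[[as.character(d1)]], avoid = a1),
      cross = {
        same_chrom <- which(dom_chrom == anchors$chrom[a1])
        cand_doms <- setdiff(intersect(as.integer(names(by_domain)), same_chrom), d1)
        if (!length(cand_doms)) {
          cand_doms <- setdiff(as.integer(names(by_domain)), d1)
        }
        if (!length(cand_doms)) {
          pick(by_domain[[as.character(d1)]], avoid = a1)  # single-domain fallback
        } else {
          dpick <- cand_doms[sample.int(length(cand_doms), 1L)]
          pick(by_domain[[as.character(dpick)]])
        }
      },
      out = if (length(out_ids)) pick(out_ids, avoid = a1) else
        anchors$id[sample.int(nrow(anchors), 1L)])
    r1[i] <- a1; r2[i] <- a2
  }
  pairs <- tibble(
    pair_id = seq_len(n_pairs),
    chrom1 = anchors$chrom[r1], start1 = anchors$start[r1],
    end1 = anchors$end[r1],
    chrom2 = anchors$chrom[r2], start2 = anchors$start[r2],
    end2 = anchors$end[r2])
  membership <- bind_rows(
    tibble(class = "cCTCF", row = seq_len(nrow(cctcf_sites)),
           selected = sel_c),
    tibble(class = "non_constitutive", row = seq_len(nrow(nonconst_sites)),
           selected = sel_n))
  list(pairs = pairs, membership = membership, p1 = p1, p2 = p2)
}

#' Generate multi-species alignment blocks with planted motif retention
#'
#' One merged (or optionally split-in-two) alignment block per site: the
#' reference row carries the core consensus with `alignment_flank` bp of
#' random flank; each other species retains the reference sequence with the
#' planted probability, otherwise its row is random sequence of the same
#' length.
#'
#' @param config A [ctcf_sim_config()].
#' @param n_sites Number of sites to simulate.
#' @param retention Per-species motif retention probability.
#' @param pwm `pwm_model` whose consensus marks a retained motif.
#' @param split Split each block in two at an internal column (exercises
#'   [merge_blocks()]).
#' @param seed_offset Internal stream offset so different classes generated
#'   from one config do not share random draws.
#' @return A list: `blocks` (list of per-site block lists), `retention`.
#' @export
simulate_alignments <- function(config, n_sites, retention,
                                pwm = ctcf_example_pwm(), split = FALSE,
                                seed_offset = 5L) {
  sim_seed(config, seed_offset)
  w <- pwm$width
  fl <- config$alignment_flank
  L <- w + 2L * fl
  n_sp <- config$n_species
  species <- c("hg19", sprintf("sp%02d", seq_len(n_sp - 1L)))
  consensus <- pwm_consensus(pwm)
  acgt <- utf8ToInt("ACGT")
  rand_seq <- function(n) {
    if (!n) return(character(0))
    chars <- acgt[sample.int(4L, n * L, replace = TRUE)]
    vapply(seq_len(n), function(i) intToUtf8(chars[((i - 1L) * L + 1L):(i * L)]),
           character(1))
  }
  blocks <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    ref <- rand_seq(1L)
    substr(ref, fl + 1L, fl + w) <- consensus
    retained <- c(TRUE, runif(n_sp - 1L) < retention)
    rows <- ifelse(retained, ref, NA)
    rows[is.na(rows)] <- rand_seq(sum(is.na(rows)))
    start0 <- 1000L + i * 100L
    block <- tibble(
      species = species, chrom = "chr1", start = start0, size = L,
      strand = "+", src_size = 1000000L, text = rows)
    blocks[[i]] <- if (split) {
      cut <- L %/% 2L
      b1 <- block; b1$text <- substr(block$text, 1L, cut); b1$size <- cut
      b2 <- block; b2$text <- substr(block$text, cut + 1L, L)
      b2$size <- L - cut; b2$start <- block$start + cut
      list(b1, b2)
    } else {
      list(block)
    }
  }
  list(blocks = blocks, retention = retention)
}

#' Generate gene models and CpG-island-like features
#'
#' Random non-overlapping gene spans with strand; CpG-island intervals are
#' placed at the TSS of a fraction of genes (promoter-associated), the
#' pattern that makes TSS-proximal sites CpG-dense.
#'
#' @param config A [ctcf_sim_config()].
#' @param cpg_fraction Fraction of genes given a TSS CpG island.
#' @param cpg_width CpG island width (bp).
#' @return A list: `genes` (tibble `gene_id`, `chrom`, `start`, `end`,
#'   `strand`), `cpg` (tibble `chrom`, `start`, `end`).
#' @export
simulate_genes <- function(config, cpg_fraction = 0.6, cpg_width = 1000L) {
  sim_seed(config, 6L)
  lens <- config$chrom_lengths
  per_chrom <- ceiling(config$n_genes / length(lens))
  genes <- purrr::imap(lens, function(len, ch) {
    glen <- floor(runif(per_chrom, config$gene_length_range[1],
                        config$gene_length_range[2]))
    start <- sort(floor(runif(per_chrom, 1e4, len - max(glen) - 1e4)))
    tibble(chrom = ch, start = as.integer(start),
           end = as.integer(start + glen),
           strand = sample(c("+", "-"), per_chrom, replace = TRUE))
  }) |> bind_rows()
  genes$gene_id <- sprintf("gene%03d", seq_len(nrow(genes)))
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  has_cpg <- runif(nrow(genes)) < cpg_fraction
  cpg <- tibble(chrom = genes$chrom[has_cpg],
                start = as.integer(pmax(0L, tss[has_cpg] - cpg_width %/% 2L)),
                end = as.integer(tss[has_cpg] + cpg_width %/% 2L))
  list(genes = genes[, c("gene_id", "chrom", "start", "end", "strand")],
       cpg = cpg)
}

#' Generate co-factor (e.g. DNase) peaks co-located with a site subset
#'
#' Per cell line, each site gets a co-located factor peak (center within
#' +/-150 bp of the site center) with probability `prob`; background peaks
#' avoiding all sites are added on top.
#'
#' @param config A [ctcf_sim_config()].
#' @param sites Site tibble to co-locate against.
#' @param prob Co-location probability (defaults to the config's
#'   `dnase_colocal_prob`).
#' @param n_lines Number of cell lines to emit.
#' @param n_background Background peaks per cell line.
#' @return A tibble of peaks with `cell_line`.
#' @export
simulate_factor_peaks <- function(config, sites, prob = NULL, n_lines = 4L,
                                  n_background = 200L) {
  sim_seed(config, 7L)
  prob <- prob %||% config$dnase_colocal_prob
  half <- config$peak_length %/% 2L
  lens <- config$chrom_lengths
  out <- list()
  for (line in paste0("D", seq_len(n_lines))) {
    sel <- runif(nrow(sites)) < prob
    mid <- interval_mid(sites$start[sel], sites$end[sel]) +
      sample(seq.int(-150L, 150L), sum(sel), replace = TRUE)
    coloc <- tibble(chrom = sites$chrom[sel],
                    start = as.integer(mid - half),
                    end = as.integer(mid + half), cell_line = line)
    ch <- sample(names(lens), n_background, replace = TRUE,
                 prob = lens / sum(lens))
    ctr <- floor(runif(n_background, 500, unname(lens[ch]) - 500))
    bgp <- tibble(chrom = ch, start = as.integer(ctr - half),
                  end = as.integer(ctr + half), cell_line = line)
    # background peaks must not sit near any site center
    near <- overlap_any(
      tibble(chrom = bgp$chrom, start = bgp$start - 200L,
             end = bgp$end + 200L), sites)
    out[[length(out) + 1L]] <- bind_rows(coloc, bgp[!near, ])
  }
  bind_rows(out)
}

#' Generate a complete synthetic study
#'
#' Runs every generator in dependency order and returns all inputs plus
#' ground truth: genome with implanted motifs, per-cell-line CTCF and
#' cohesin peaks, domains, interaction pairs, alignments for the
#' constitutive and 2-10-line comparator classes, genes/CpG islands and
#' DNase-like peaks.
#'
#' @param config A [ctcf_sim_config()].
#' @param pwm `pwm_model` used for implants.
#' @param alignments Set `FALSE` to skip the (slower) alignment generator.
#' @return A named list with elements `config`, `genome`, `sites` (truth),
#'   `peaks`, `domains`, `interactions`, `alignments_cctcf`,
#'   `alignments_nonconst`, `genes`, `cpg`, `dnase_peaks`.
#' @export
simulate_ctcf_study <- function(config = ctcf_sim_config(),
                                pwm = ctcf_example_pwm(),
                                alignments = TRUE) {
  genome <- simulate_genome(config)
  planted <- simulate_sites(config, genome, pwm)
  peaks <- simulate_peak_sets(config, planted$sites)
  domains <- simulate_domains(config)
  truth <- planted$sites
  cctcf <- truth[truth$tier == "constitutive", ]
  nonconst <- truth[truth$tier != "constitutive", ]
  interactions <- simulate_interactions(config, cctcf, nonconst, domains)
  n_aln <- min(200L, nrow(cctcf))
  aln_c <- aln_n <- NULL
  if (isTRUE(alignments)) {
    aln_c <- simulate_alignments(config, n_aln, config$retention_cctcf,
                                 pwm = pwm, seed_offset = 5L)
    aln_n <- simulate_alignments(config, n_aln, config$retention_nonconst,
                                 pwm = pwm, seed_offset = 8L)
  }
  ann <- simulate_genes(config)
  dnase <- simulate_factor_peaks(config, cctcf[cctcf$cohesin == "full", ])
  list(config = config, genome = planted$genome, sites = truth,
       peaks = peaks, domains = domains, interactions = interactions,
       alignments_cctcf = aln_c, alignments_nonconst = aln_n,
       genes = ann$genes, cpg = ann$cpg, dnase_peaks = dnase)
}
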