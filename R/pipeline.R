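#' Pipeline configuration
#'
#' Bundles the analysis thresholds (defaults equal to the study's printed
#' parameterization: 200-bp peaks, exact-p cutoff 0.0005, constitutive
#' fraction 0.9, 5-kb TSS window, 2.5-kb CpG half-width, 200-bp center
#' margin, 30-bp flanks, 5-mers, top 50 k-mers) with a synthetic-data
#' configuration and an output directory.
#'
#' @param outdir Output directory for stage artifacts.
#' @param sim A [ctcf_sim_config()] for the `simulate` stage.
#' @param peak_length,pvalue_cutoff,constitutive_fraction,tss_window
#'   Analysis thresholds (see module functions).
#' @param cpg_halfwidth,center_margin,flank,k,top_n Further thresholds.
#' @param granularity PWM score discretization step.
#' @param pwm_path Plain-text PWM path; `NULL` uses the packaged example
#'   matrix.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("ctcfconst_"),
                            sim = ctcf_sim_config(),
                            peak_length = 200L, pvalue_cutoff = 5e-4,
                            constitutive_fraction = 0.9, tss_window = 5000L,
                            cpg_halfwidth = 2500L, center_margin = 200L,
                            flank = 30L, k = 5L, top_n = 50L,
                            granularity = 1e-3, pwm_path = NULL) {
  cfg <- as.list(environment())
  pos <- c(peak_length, pvalue_cutoff, constitutive_fraction, tss_window,
           cpg_halfwidth, center_margin, flank, k, top_n, granularity)
  if (any(pos <= 0)) abort("All thresholds must be positive.")
  if (constitutive_fraction >= 1) abort("`constitutive_fraction` must be < 1.")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; a `sim` mapping holds
#' [ctcf_sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$chrom_lengths)) {
    sim_args$chrom_lengths <- unlist(sim_args$chrom_lengths)
  }
  y$sim <- do.call(ctcf_sim_config, sim_args)
  do.call(pipeline_config, y)
}

pfile <- function(config, ...) file.path(config$outdir, ...)

need_file <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("Stage '%s' needs missing input: %s", stage, path))
  }
  path
}

write_manifest <- function(config, stage, params, outputs) {
  sums <- tools::md5sum(outputs)
  yaml::write_yaml(
    list(stage = stage, parameters = params,
         outputs = as.list(setNames(unname(sums), basename(outputs)))),
    pfile(config, sprintf("manifest_%s.yaml", stage)))
  invisible(sums)
}

load_pwm <- function(config) {
  if (is.null(config$pwm_path)) ctcf_example_pwm() else read_pwm(config$pwm_path)
}

read_genome_fa <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  setNames(as.character(g), sub("\\s.*$", "", names(g)))
}

#' Run the analysis pipeline
#'
#' Executes the stages in dependency order, reading and writing plain-text
#' artifacts under the config's output directory; each stage writes a
#' manifest of its parameters and output checksums, so identical inputs and
#' seed give bit-identical artifacts.
#'
#' Stages: `simulate` (generate all inputs), `call_sites` (PWM scan of every
#' dataset's normalized peaks), `constitutive` (occurrence table, >90 percent
#' call, cohesin classification), `annotate` (TSS/in-gene classes, CpG
#' density, DNase overlap), `motifs` (positional k-mers and composite
#' flanking motifs), `conserve` (species hit counts per class),
#' `interactions` (enrichment and fractional pair-type counts), `domains`
#' (pair classification and boundary-distance density), or `all`.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @param stages Character vector of stage names, or `"all"`.
#' @return Invisibly, a named list of the key per-stage results.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config)) config <- read_pipeline_config(config)
  all_stages <- c("simulate", "call_sites", "constitutive", "annotate",
                  "motifs", "conserve", "interactions", "domains")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  for (st in stages) {
    res[[st]] <- switch(
      st,
      simulate = stage_simulate(config),
      call_sites = stage_call_sites(config),
      constitutive = stage_constitutive(config),
      annotate = stage_annotate(config),
      motifs = stage_motifs(config),
      conserve = stage_conserve(config),
      interactions = stage_interactions(config),
      domains = stage_domains(config))
  }
  invisible(res)
}

stage_simulate <- function(config) {
  study <- simulate_ctcf_study(config$sim, pwm = load_pwm(config))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(study$genome),
                              pfile(config, "genome.fa"))
  readr::write_tsv(study$peaks, pfile(config, "peaks.tsv"), progress = FALSE)
  write_bed(study$domains, pfile(config, "domains.bed"))
  write_interactions(study$interactions$pairs, pfile(config, "interactions.tsv"))
  truth <- study$sites
  truth$lines <- vapply(truth$lines, function(x)
    if (is.null(x)) "" else paste(x, collapse = ","), character(1))
  readr::write_tsv(truth, pfile(config, "truth_sites.tsv"), progress = FALSE)
  readr::write_tsv(study$interactions$membership,
                   pfile(config, "truth_interactions.tsv"), progress = FALSE)
  readr::write_tsv(study$genes, pfile(config, "genes.tsv"), progress = FALSE)
  write_bed(study$cpg, pfile(config, "cpg.bed"))
  readr::write_tsv(study$dnase_peaks, pfile(config, "dnase_peaks.tsv"),
                   progress = FALSE)
  if (!is.null(study$alignments_cctcf)) {
    write_maf(purrr::flatten(study$alignments_cctcf$blocks),
              pfile(config, "alignments_cctcf.maf"))
    write_maf(purrr::flatten(study$alignments_nonconst$blocks),
              pfile(config, "alignments_nonconst.maf"))
  }
  outs <- pfile(config, c("genome.fa", "peaks.tsv", "domains.bed",
                          "interactions.tsv", "truth_sites.tsv"))
  write_manifest(config, "simulate",
                 list(seed = config$sim$seed,
                      n_cell_lines = config$sim$n_cell_lines), outs)
  study
}

stage_call_sites <- function(config) {
  genome <- read_genome_fa(need_file(pfile(config, "genome.fa"), "call_sites"))
  peaks <- readr::read_tsv(need_file(pfile(config, "peaks.tsv"), "call_sites"),
                           show_col_types = FALSE, progress = FALSE)
  pwm <- load_pwm(config)
  peaks <- normalize_peaks(peaks, config$peak_length,
                           chrom_lengths = genome_lengths(genome))
  sites <- call_sites(peaks, genome, pwm,
                      pvalue_cutoff = config$pvalue_cutoff,
                      granularity = config$granularity)
  message(sprintf("call_sites: %d sites in %d peaks (%.1f%% of peaks)",
                  nrow(sites), nrow(peaks), 100 * nrow(sites) / nrow(peaks)))
  readr::write_tsv(sites, pfile(config, "sites.tsv"), progress = FALSE)
  write_manifest(config, "call_sites",
                 list(pvalue_cutoff = config$pvalue_cutoff,
                      peak_length = config$peak_length),
                 pfile(config, "sites.tsv"))
  sites
}

read_sites_tsv <- function(config, stage) {
  readr::read_tsv(need_file(pfile(config, "sites.tsv"), stage),
                  show_col_types = FALSE, progress = FALSE)
}

stage_constitutive <- function(config) {
  sites <- read_sites_tsv(config, "constitutive")
  ctcf <- sites[sites$factor == "CTCF", ]
  occ <- aggregate_sites(ctcf, n_cell_lines = config$sim$n_cell_lines)
  cctcf <- call_constitutive(occ, config$constitutive_fraction)
  message(sprintf(
    "constitutive: fraction %.2f of %d lines -> min count %d; %d of %d sites constitutive",
    config$constitutive_fraction, attr(occ, "n_cell_lines"),
    attr(cctcf, "min_count"), nrow(cctcf), nrow(occ)))
  crad <- call_constitutive(
    aggregate_sites(sites[sites$factor == "Rad21", ],
                    n_cell_lines = config$sim$n_rad21_lines),
    config$constitutive_fraction)
  csmc <- call_constitutive(
    aggregate_sites(sites[sites$factor == "Smc3", ],
                    n_cell_lines = config$sim$n_smc3_lines),
    config$constitutive_fraction)
  peaks <- readr::read_tsv(need_file(pfile(config, "peaks.tsv"), "constitutive"),
                           show_col_types = FALSE, progress = FALSE)
  cohesin_peaks <- normalize_peaks(peaks[peaks$factor != "CTCF", ],
                                   config$peak_length)
  classes <- classify_sites(cctcf, crad, csmc, cohesin_peaks)
  message(sprintf("constitutive: %s",
                  paste(sprintf("%s=%d", levels(classes$class),
                                tabulate(classes$class, 3L)), collapse = ", ")))
  write_occurrence(occ, pfile(config, "occurrence.tsv"))
  readr::write_tsv(classes, pfile(config, "cctcf_classes.tsv"), progress = FALSE)
  write_manifest(config, "constitutive",
                 list(fraction = config$constitutive_fraction,
                      min_count = attr(cctcf, "min_count")),
                 pfile(config, c("occurrence.tsv", "cctcf_classes.tsv")))
  list(occurrence = occ, classes = classes)
}

read_classes_tsv <- function(config, stage) {
  readr::read_tsv(need_file(pfile(config, "cctcf_classes.tsv"), stage),
                  show_col_types = FALSE, progress = FALSE)
}

stage_annotate <- function(config) {
  classes <- read_classes_tsv(config, "annotate")
  genes <- readr::read_tsv(need_file(pfile(config, "genes.tsv"), "annotate"),
                           show_col_types = FALSE, progress = FALSE)
  cpg <- read_bed(need_file(pfile(config, "cpg.bed"), "annotate"))
  dnase <- readr::read_tsv(need_file(pfile(config, "dnase_peaks.tsv"), "annotate"),
                           show_col_types = FALSE, progress = FALSE)
  ann <- annotate_sites(classes, genes, config$tss_window)
  prof <- feature_density_profile(classes, cpg, config$cpg_halfwidth)
  coh <- classes[classes$class == "cCTCF_cCohesin", ]
  dn_frac <- factor_overlap_fraction(coh, dnase, config$center_margin)
  readr::write_tsv(ann, pfile(config, "annotated_sites.tsv"), progress = FALSE)
  readr::write_tsv(prof, pfile(config, "cpg_profile.tsv"), progress = FALSE)
  readr::write_tsv(dn_frac, pfile(config, "dnase_overlap.tsv"), progress = FALSE)
  write_manifest(config, "annotate",
                 list(tss_window = config$tss_window,
                      cpg_halfwidth = config$cpg_halfwidth,
                      center_margin = config$center_margin),
                 pfile(config, c("annotated_sites.tsv", "cpg_profile.tsv",
                                 "dnase_overlap.tsv")))
  list(annotated = ann, profile = prof, dnase = dn_frac)
}

stage_motifs <- function(config) {
  classes <- read_classes_tsv(config, "motifs")
  genome <- read_genome_fa(need_file(pfile(config, "genome.fa"), "motifs"))
  coh <- classes[classes$class == "cCTCF_cCohesin", ]
  seqs <- extract_extended_sequences(coh, genome, config$flank)
  counts <- positional_kmer_counts(seqs, config$k)
  left <- build_composite_motif(counts, "left", config$top_n,
                                flank = config$flank)
  right <- build_composite_motif(counts, "right", config$top_n,
                                 flank = config$flank)
  message(sprintf("motifs: %d positions x %d k-mers from %d sequences",
                  nrow(counts$counts), ncol(counts$counts), counts$n_seq))
  write_composite_motif(left, pfile(config, "composite_left.pfm"))
  write_composite_motif(right, pfile(config, "composite_right.pfm"))
  write_manifest(config, "motifs",
                 list(k = config$k, top_n = config$top_n, flank = config$flank),
                 pfile(config, c("composite_left.pfm", "composite_right.pfm")))
  list(counts = counts, left = left, right = right)
}

stage_conserve <- function(config) {
  pwm <- load_pwm(config)
  res <- lapply(c(cctcf = "alignments_cctcf.maf",
                  nonconst = "alignments_nonconst.maf"), function(f) {
    blocks <- read_maf(need_file(pfile(config, f), "conserve"))
    conservation_counts(blocks, pwm, config$pvalue_cutoff)
  })
  summ <- conservation_summary(cctcf = res$cctcf$n_species_hit,
                               nonconst = res$nonconst$n_species_hit)
  message(sprintf("conserve: mean species %.1f (cCTCF) vs %.1f (non-constitutive)",
                  summ$mean[1], summ$mean[2]))
  readr::write_tsv(tidy(summ), pfile(config, "conservation.tsv"),
                   progress = FALSE)
  write_manifest(config, "conserve",
                 list(pvalue_cutoff = config$pvalue_cutoff),
                 pfile(config, "conservation.tsv"))
  summ
}

stage_interactions <- function(config) {
  pairs <- read_interactions(need_file(pfile(config, "interactions.tsv"),
                                       "interactions"))
  classes <- read_classes_tsv(config, "interactions")
  truth <- readr::read_tsv(need_file(pfile(config, "truth_sites.tsv"),
                                     "interactions"),
                           show_col_types = FALSE, progress = FALSE)
  nonconst <- truth[truth$tier != "constitutive",
                    c("chrom", "start", "end", "strand")]
  cc <- sites_in_interactions(classes, pairs)
  nc <- sites_in_interactions(nonconst, pairs)
  enr <- enrichment_test(cc$n_in_interaction, cc$n_sites,
                         nc$n_in_interaction, nc$n_sites,
                         labels = c("cCTCF", "non_constitutive"))
  types <- fractional_type_counts(pairs, classes, nonconst)
  message(sprintf("interactions: OR %.2f (p = %.3g); proportions %.2f vs %.2f",
                  enr$odds_ratio, enr$p_value, enr$proportions[1],
                  enr$proportions[2]))
  readr::write_tsv(tidy(enr), pfile(config, "enrichment.tsv"), progress = FALSE)
  write_pair_types(types, pfile(config, "pair_types.tsv"))
  write_manifest(config, "interactions", list(),
                 pfile(config, c("enrichment.tsv", "pair_types.tsv")))
  list(enrichment = enr, types = types)
}

stage_domains <- function(config) {
  pairs <- read_interactions(need_file(pfile(config, "interactions.tsv"),
                                       "domains"))
  domains <- read_bed(need_file(pfile(config, "domains.bed"), "domains"))
  classes <- read_classes_tsv(config, "domains")
  cls <- classify_interactions_by_domain(pairs, domains)
  dist <- boundary_distances(classes, domains)
  kde <- if (nrow(dist) >= 2L) kde_distances(dist$standardized) else NULL
  g <- glance(cls)
  message(sprintf(
    "domains: %.0f%% of pairs inside domains; %.0f%% of those same-domain",
    100 * g$frac_both_in_domains, 100 * g$frac_same_domain))
  readr::write_tsv(as_tibble(cls), pfile(config, "pair_domains.tsv"),
                   progress = FALSE)
  readr::write_tsv(dist, pfile(config, "boundary_distances.tsv"),
                   progress = FALSE)
  write_manifest(config, "domains", list(),
                 pfile(config, c("pair_domains.tsv", "boundary_distances.tsv")))
  list(pairs = cls, distances = dist, kde = kde)
}
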