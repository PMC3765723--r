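# ctcfconst

Constitutive CTCF/cohesin binding-site analysis in R.

CTCF is an eleven-zinc-finger DNA-binding protein central to genome
organization; together with the cohesin complex (proxied in ChIP-seq by its
Rad21 and Smc3 subunits) it anchors chromatin loops and sits at the borders
of topological domains. Across a large compendium of cell lines, a distinct
class of CTCF binding sites is bound almost everywhere — *constitutive*
sites, defined as motif sites found in strictly more than 90% of surveyed
cell lines. `ctcfconst` implements the full analysis that identifies and
characterizes this class for anyone working with multi-cell-line ChIP-seq
compendia:

* **Site prediction.** Each 200-bp normalized peak is scanned on both
  strands with a position weight matrix (PWM). Scores are log-odds
  `s(x) = Σᵢ log(pᵢ(xᵢ) + c) − log(b(xᵢ) + c)` and are converted to *exact*
  p-values via a dynamic-programming convolution of the per-position
  discretized score distributions under the background model; the single
  best window with `p ≤ 5 × 10⁻⁴` is the peak's binding site.
* **Constitutive calling.** Sites are aggregated across datasets into an
  occurrence table (replicates collapse; identity is exact
  coordinate + strand); a site found in more than a fraction `f = 0.9` of
  `N` cell lines (minimum count `⌊fN⌋ + 1`, e.g. 51 of 56) is constitutive.
  Constitutive CTCF sites are classified against cohesin into
  cCTCF/cCohesin, cCTCF-non-cohesin, and the unclassified remainder.
* **Characterization.** Genomic context (TSS / in-gene / other), CpG-island
  density profiles, co-factor peak-center overlap (±200 bp); full-spectrum
  flanking motifs from positional 5-mer counts over the 30+16+30 bp window
  (72 positions × 1,024 words, top-50 composites per side); cross-species
  conservation as the number of alignment species containing a motif hit.
* **Interactions and domains.** Enrichment of site classes in ChIA-PET
  interaction regions (cross-product odds ratio `(a/b)/(c/d)` with a
  one-sided Fisher exact p-value), fractional counting of interaction pair
  types (each pair distributes unit weight over the label combinations of
  its two regions, so counts sum exactly to the number of pairs), and
  placement of sites and pairs relative to topological domains, including
  boundary distances standardized to the median domain length and their
  kernel density.
* **Synthetic data.** A seed-reproducible generator emulates every input —
  a constitutive core with per-cell-line dropout, cell-specific singletons,
  cohesin co-location, interaction pairs at a planted odds ratio, domains
  holding a planted fraction of pairs, alignments with class-dependent motif
  retention — together with ground truth, so the whole pipeline is testable
  without any external downloads.

All user-facing functions take and return tibbles and chain with the pipe;
result objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*`
ggplot2 helpers.

## Worked example

Enrichment of constitutive sites in ChIA-PET interactions from a published
contingency table (23,577 cCTCF sites of which 14,178 fall inside an
interaction region, versus 81,464 non-constitutive sites with 13,316):

```r
library(ctcfconst)

enrichment_test(14178, 23577, 13316, 81464,
                labels = c("cCTCF", "non_constitutive"))
#> <ctcf_enrichment> one-sided Fisher exact test
#>                     in not_in
#> cCTCF            14178   9399
#> non_constitutive 13316  68148
#> proportions: 0.601 vs 0.163
#> odds ratio = 7.72, p-value = 0
```

60% of constitutive sites sit inside an interaction region against 16% of
non-constitutive ones — 7.7-fold greater odds, overwhelming evidence that
chromatin interactions are anchored preferentially at constitutive sites.

A miniature end-to-end run on synthetic data (60 planted constitutive sites
across 56 cell lines, 2.5% per-line dropout):

```r
cfg <- ctcf_sim_config(seed = 42, chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                       n_constitutive = 60, n_shared = 20,
                       n_specific_per_line = 4)
pwm  <- ctcf_example_pwm()
st   <- simulate_sites(cfg, simulate_genome(cfg), pwm)
pk   <- simulate_peak_sets(cfg, st$sites)
ctcf <- normalize_peaks(dplyr::filter(pk, factor == "CTCF"),
                        chrom_lengths = cfg$chrom_lengths)
occ  <- call_sites(ctcf, st$genome, pwm) |> aggregate_sites(n_cell_lines = 56)
glance(occ)
#> # A tibble: 1 × 4
#>   n_sites n_cell_lines n_singleton n_all_lines
#>     <int>        <int>       <int>       <int>
#> 1     274           56         198          10

cctcf <- call_constitutive(occ, 0.9)
nrow(cctcf)          # 60  — every planted constitutive site, none spurious
attr(cctcf, "min_count")  # 51
```

274 unique sites are found, most of them cell-line singletons; exactly the
60 planted constitutive identities clear the ≥51-of-56 bar.
`plot_occurrence(occ)` draws the occurrence histogram with the constitutive
cutoff marked; `run_pipeline(pipeline_config(...), "all")` chains every
stage (simulate → call_sites → constitutive → annotate → motifs → conserve →
interactions → domains) with per-stage manifests and checksummed artifacts.

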