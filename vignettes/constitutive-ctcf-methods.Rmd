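---
title: "Methods: constitutive CTCF/cohesin site analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constitutive CTCF/cohesin site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcfconst)
```

# The model and its assumptions

`ctcfconst` operationalizes "constitutive binding" as a property of motif
sites, not peaks: within every ChIP-seq peak the single best PWM hit is the
site, sites are matched across datasets by exact coordinate and strand, and
a site is constitutive when it is found in strictly more than a fraction
$f$ (default 0.9) of the surveyed cell lines. The minimum qualifying count
is therefore $\lfloor fN \rfloor + 1$: 51 of 56, 6 of 6, 4 of 4. The
underlying assumptions are that (i) a genomic motif instance yields the same
best-hit coordinates in every cell line whose peak covers it, so exact
identity is the right default matcher, and (ii) per-cell-line peak loss is
roughly independent across lines, so occurrence counts are approximately
binomial. Assumption (i) can fail on noisy real data (slightly shifted
summits, secondary motifs); `aggregate_sites(tolerance = )` provides a
single-linkage fuzzy matcher for that case, off by default because exact
matching is the cleanly interpretable definition.

All coordinates are 0-based half-open (BED convention). The midpoint of an
interval is `start + floor(length / 2)`; this deterministic choice matters
only for odd-length intervals and 16-bp sites, where any convention differs
by at most 1 bp. Peaks are normalized to 200 bp about their midpoint before
scanning; clipping is applied at coordinate 0 (a clipped peak may be
shorter), and at chromosome ends only when lengths are supplied.

# PWM scanning and exact p-values

Scoring is log-odds against a background model with a pseudocount $c$ added
to both numerator and denominator,
$s(x) = \sum_i \log(p_i(x_i) + c) - \log(b(x_i) + c)$, so zero matrix
entries stay finite. Defaults: uniform background (the simplest reproducible
choice; configurable), pseudocount $10^{-3}$, and windows containing N are
invalid rather than averaged — the conservative choice that cannot create
spurious high scores.

P-values are exact under the background model: per-position scores are
discretized at granularity $10^{-3}$ log-odds units and convolved by
dynamic programming into the full score distribution, whose upper tail is
$P(\text{score} \ge s)$. Scanning uses the same discretized unit scores, so
a scanned score and its p-value are always mutually consistent; the
continuous log-odds value is recomputed for reported sites. The granularity
is a size/accuracy trade-off: at $10^{-3}$ the table for a 16-bp matrix has
about 40,000 support points and the discretization error is far below any
decision threshold. Correctness is established in the test suite by
exhaustive enumeration of all $4^w$ sequences for widths up to 8, where the
dynamic program must (and does) agree with brute force exactly.

Within a peak the best passing window wins; ties break by leftmost start,
then + strand — an arbitrary but deterministic rule. The site's strand is
the scan strand of the winning window. The default cutoff
$p \le 5 \times 10^{-4}$ makes the per-200-bp-peak family-wise chance hit
probability about 0.13 (370 tests), which the Monte-Carlo test verifies
sits at or just below the independence bound (overlapping windows are
positively correlated).

The packaged 16-bp example matrix (`ctcf_example_pwm()`) is synthetic,
consensus-derived (CCASYAGRKGGCRSYG-like, 0.85 dominant bases, two-way
degenerate S/Y/R/K positions). It exists for examples and tests; analyses
of real data should supply the de-novo matrix for their peak sets via
`read_pwm()`.

# Cohesin classification

Constitutive status for cohesin is evaluated the same way, on the CTCF
motif hit inside Rad21 and Smc3 peaks, against each factor's own cell-line
count. The intersection of the three constitutive sets (by site identity)
is the cCTCF/cCohesin class; cCTCF sites overlapping *no* cohesin peak in
any cell line (interval overlap of the 16-bp site with the normalized
200-bp peaks) are cCTCF-non-cohesin; the remainder — cohesin in some but
not enough lines — stays unclassified. The overlap reading (site-in-peak
rather than site-in-constitutive-peak-only) was an open choice; interval
overlap with any per-cell-line peak is the more conservative definition of
"without any cohesin".

# Annotation conventions

A site is annotated by its midpoint with the first matching rule:
`TSS` within ±5 kb of any gene's transcription start, else `in_gene` within
any gene span, else `others`. A site near any TSS is `TSS` even while
inside another gene — rule order, not gene precedence, decides. The
CpG-density display is a per-offset coverage fraction: at offset
$o \in [-2500, 2500]$, the fraction of sites whose midpoint$+o$ is covered
by at least one feature interval. No smoothing is applied; the estimator is
already an average over sites. Co-factor association uses peak-center
distance: the fraction of sites with a factor peak center within ±200 bp of
the site center, computed per cell line.

# Full-spectrum flanking motifs

Extended sequences are the site ±30 bp, minus-strand sites
reverse-complemented so the core always occupies offsets 30–45 of the 76-bp
window. At each of the $30+30+16-5+1 = 72$ window start positions the
number of sequences containing each of the $4^5 = 1024$ 5-mers is counted —
presence is per-sequence 0/1, and each sequence holds exactly one 5-mer per
position, so row sums equal the sequence count.

Composites are built per side. A 5-mer belongs to the side holding its
start: left = starts 0–29 (covering offsets 0–33), right = starts 46–71
(offsets 46–75); windows starting inside the core belong to neither. The
ranking statistic is the k-mer's **maximum single-position count** within
its side, not the positional sum: positional specificity is what separates
motif words from composition bias (a genuinely open choice — the sum is
available by modifying one line, and the test suite's implant-recovery
property holds under either). The top 50 k-mers contribute
count × base-indicator into the composite's per-offset base weights, and
columns are normalized. Both side composites are emitted at their covered
widths (34 bp left, 30 bp right by default); no attempt is made to split a
side's pattern into alternative published lengths automatically, since
whether the downstream pattern is one motif or two is empirically
undecided. Prevalence of a motif in a site class is scored core-anchored:
the composite (or a supplied matrix at a given offset) is evaluated at its
fixed window offset in the oriented sequences, against its own exact
p-value distribution.

# Conservation

Each site's alignment block (site ±10 bp) is scanned species by species:
gaps are stripped, both strands scanned, and the site counts as conserved
in a species if any window passes the same $5\times10^{-4}$ cutoff. Both
strands is the permissive, symmetric choice; a hit anywhere in the 36-bp
span counts, since requiring positional overlap inside an alignment would
entangle conservation with alignment quality. Species with rows shorter
than the PWM width after gap removal (or absent from the block) count as
absent. Multiple blocks tiling one query are merged by per-species
concatenation with gap fill for absent species.

Because a 36-bp random row passes the cutoff with probability
$\approx 1-(1-\alpha)^{2\cdot21} \approx 0.017$ (where $\alpha$ is the
largest achievable tail value under the cutoff), the raw fraction of
species with hits overestimates true motif retention.
`estimate_retention()` removes this bias exactly:
$\hat r = (\text{raw} - \mathrm{fp})/(1 - \mathrm{fp})$ with the chance-hit
probability computed from the score distribution itself. Windows are
treated as independent in fp; their positive correlation makes the
correction very slightly conservative, an error far below the 0.02
tolerance the recovery tests use. The non-constitutive comparator class in
the generator is the sites found in 2–10 cell lines, matching the sampling
frame such comparisons use on real data.

# ChIA-PET enrichment and fractional counting

A site is "in interactions" if it overlaps at least one region of at least
one pair — once, regardless of multiplicity. Enrichment between two site
classes is the sample cross-product odds ratio $(a/b)/(c/d)$ with a
one-sided Fisher exact p-value (the hypergeometric upper tail; the test
suite checks it against an explicit term-by-term hypergeometric sum, and
the conditional-MLE odds ratio of `fisher.test` is deliberately not used
because published values for such tables are cross-product ratios).

Fractional type counting labels each region with the **set of distinct
classes** present ({constitutive}, {non-constitutive}, both, or neither)
and spreads each pair's unit weight uniformly over the Cartesian product of
its two label sets, accumulating unordered combinations. Weighting by
distinct labels rather than by site multiplicities is a genuine reading
choice; it is the one under which the worked half-count example and the
exact-total invariant (counts sum to the number of pairs, verified on
10,000 random pairs) both hold, and multiplicity weighting would break
neither but change category proportions. Replicate interaction experiments
are analyzed separately.

# Topological domains

Intervals are assigned to the unique domain containing their midpoint
(half-open, so a midpoint on a domain start belongs to that domain). Pairs
are `same_domain`, `cross_domain`, `partly_outside` or `outside`;
same-domain fractions are reported among intra-chromosomal pairs with both
regions in domains. Boundary distance is from the site midpoint to the
nearer domain edge, and is standardized as
$\text{raw} \times \text{median length}/\text{domain length}$ — i.e.
distances are expressed as if every domain had the median length. This
proportional rescaling is the only reading of "standardized to the median
length" that makes densities comparable across domain sizes (truncation
would not). The kernel density uses a Gaussian kernel with Silverman's
rule-of-thumb bandwidth and reflection at zero so no mass leaks below zero;
the mode is the argmax on the non-negative axis. Degenerate (constant)
inputs return a flagged delta-like result.

# The synthetic study generator

The generator's defaults are the study conditions: 56 CTCF cell lines, 6
Rad21 and 4 Smc3 lines, 200-bp peaks, the 0.9 constitutive fraction,
in-interaction probabilities 0.60/0.16 (odds ratio 7.7), 87% of pairs
inside domains with 80% of those same-domain, log-normal domain lengths
with median 680 kb and mean 852 kb, 46 species with retention 20/46 versus
10/46, and DNase co-location 0.74. Per-cell-line dropout defaults to
0.025, the value at which the binomial occurrence model reproduces the
observed share of constitutive sites present in *all* 56 lines
($P(X{=}56)/P(X{\ge}51) \approx 0.24$); at this dropout the expected
recovery of planted constitutive sites exceeds 99.9%, while dropout at the
upper end of what the 0.9 fraction tolerates (0.05) would already push
recovery down to roughly 93% — the threshold arithmetic is unforgiving near
its edge.

Sites are planted on a spacing grid (2.4 kb) so that 2-kb interaction
anchors can never touch a neighbouring site; real peak sets have
overlapping peaks across datasets, which the fuzzy matcher addresses
separately. Constitutive sites always carry the core consensus (they are
defined by motif identity); cell-specific and 2–10-line sites carry it with
probability 0.875, placing per-dataset call rates in the 80–95% band.
Cohesin status per constitutive site is full (0.51) / none (0.04) /
partial (the remainder), mirroring the observed class proportions.

Interaction pairs realize a planted odds ratio by construction: each
constitutive site joins with probability $p_1$ solving
$\mathrm{OR} = \frac{p_1/(1-p_1)}{p_2/(1-p_2)}$ at $p_2 = 0.16$, every
selected site's anchor appears in at least one pair, and background
anchors avoid all sites, so membership is exactly the Bernoulli draw and
the realized odds ratio is unbiased (its Monte-Carlo spread at 5,000 pairs
has log-sd ≈ 0.10, so recovery is asserted on the geometric mean over
three seeds). Domain placement is drawn per pair (in-domain ×
same/cross-domain); the only systematic deviation is that a selected
site's anchor occasionally falls outside all domains, trimming the
realized in-domain fraction by about one percentage point below its
planted 0.87.

Alignment rows either retain the reference sequence exactly (probability =
the class's retention) or are uniform random; blocks can be emitted split
in two to exercise the merger. What the generator does **not** emulate:
non-uniform genomic base composition, overlapping/shifted peaks between
datasets, alignment gaps within retained rows, distance-dependent
interaction frequencies, and correlated dropout between related cell
lines. Passing tests therefore demonstrate correctness of the inference
machinery under the stated statistical structure, not robustness to every
artifact of real ENCODE-scale data.

# Problem sizes and determinism

The test and acceptance runs use deliberately scaled problem sizes chosen
to give each statistical check adequate power: 200 planted constitutive
sites across 56 cell lines on a 6-Mb two-chromosome genome for full-scan
recovery; 5,000 interaction pairs over 500 + 3,000 sites on 40 Mb of
coordinates (×3 seeds) for odds-ratio and domain-placement recovery; 5,000
alignments × 46 species per class for retention (where the estimator's
observed error is below 0.001 against a 0.02 tolerance); exhaustive
enumeration to width 8 for the score distribution and all 2×2 tables with
total ≤ 30 plus randomized margin-≤50 tables for the Fisher oracle. Every
generator consumes an explicit seed and is bit-reproducible; pipeline
stages write checksum manifests so identical inputs and seed give
bit-identical artifacts.

# Known limitations

Exact-coordinate site identity is brittle on real data (use the fuzzy
matcher); the uniform background overstates motif surprise in GC-skewed
regions; conservation is a species count, not a phylogenetic model, so
clade structure is ignored; composite motif construction has no EM
refinement and its ranking statistic is a design choice; and the pipeline's
interaction stage compares called constitutive sites against
generator-truth non-constitutive sites, which is the correct comparison on
synthetic data but must be replaced by per-cell-line called site lists on
real compendia.
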