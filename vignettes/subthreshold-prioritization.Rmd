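---
title: "Prioritizing sub-threshold GWAS loci with epigenomic annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing sub-threshold GWAS loci with epigenomic annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subthresh)
```

## The problem

Genome-wide association studies declare a locus significant at
p < 5×10⁻⁸, a Bonferroni-style bar that modest-effect variants in
realistic cohorts often miss. Signals with 5×10⁻⁸ < p < 10⁻⁴
("sub-threshold" loci) contain real biology diluted by a high false
positive rate. The premise of this package is that regulatory
annotations — chromatin-state enhancer calls in the trait-relevant
tissue and associated functional marks — carry enough information to
separate real sub-threshold loci from noise, because causal
non-coding variants concentrate in active tissue-specific enhancers.
`subthresh` implements the statistical machinery for that program:
enrichment testing, locus construction, prioritization, target-gene
linking, and the molecular read-outs (allelic imbalance, 4C contacts)
used to validate prioritized loci.

## Matched-control enrichment

The unit of counting is the **locus**: a lead SNP plus all panel SNPs
in strong LD (r² > 0.8, strict). A locus overlaps an annotation if at
least one member SNP lies inside at least one interval; a locus counts
once no matter how many members overlap. A SNP overlaps by its single
base — no padding — with BED intervals interpreted 0-based half-open
and SNP positions 1-based.

Counting overlaps of trait loci against a *random-region* null is
biased: GWAS lead SNPs are not random positions. The null here is
built from **matched control leads** drawn from genotyping-array SNPs
whose genetic covariates fall within tolerance windows of the test
lead: LD block size ±5 SNPs, MAF ±0.1, distance to nearest gene ±25 kb
(applied only when the lead is outside a gene), number of genes within
±500 kb ±3. All windows are inclusive. Each permutation draws one
matched control per test lead, independently and with replacement
across permutations, expands it by the same r² > 0.8 rule, and counts
locus-level overlaps. GC-content matching is deliberately not applied.
Matching is genome-wide rather than chromosome-wise.

The enrichment z-score uses the sample standard deviation of the null
counts (denominator B−1; at typical permutation counts the distinction
from B is irrelevant). The empirical p carries the add-one correction
(1 + exceedances)/(1 + B) and therefore can never be zero — with 10⁵
permutations its floor is just under 10⁻⁵. When the null is degenerate
(sd = 0) the result is flagged and z is reported as 0 when the
observed count equals the null value, ±Inf otherwise.

Because annotation overlap probability varies with locus extent, and
the tolerance windows are coarse, matching removes most but not all
covariate dependence; residual miscalibration is small (a fraction of
a null SD) and conservative-to-neutral in our null simulations.

The motif-disruption variant of the statistic counts loci with a
member SNP inside an enhancer *and* inside a motif instance of an
expressed TF (expression ≥ 1 RPKM in the reference tissue).
"Disruption" is realized as positional overlap with a motif instance,
not as an allele-specific score change — a deliberate simplification,
flagged to users. The negative control re-places motif instances
uniformly at random (chromosome chosen proportional to length),
preserving instance count and lengths; with no genome sequence in the
synthetic setting, sequence-level remapping is abstracted to position
shuffling.

## Locus construction and pruning

Sub-threshold loci are defined from summary statistics by: (1)
removing every SNP within 1 Mb (inclusive — the conservative reading
of "within") of any member of a known locus, plus any masked regions
(e.g. the extended MHC region, which concentrates a large share of
low-p SNPs); (2) restricting to p < 10⁻⁴ (strict); (3) greedy pruning:
sort by ascending p (ties broken by SNP id), keep a SNP iff its r²
with every kept SNP is ≤ 0.2. The pairwise removal rule ("drop the
weaker of any pair in LD") does not by itself define a unique result
on LD chains; greedy-by-significance is the standard clumping
realization and is order-deterministic — the output is invariant to
input row order. Each pruned SNP is attached to the most significant
surviving SNP it conflicted with.

Loci whose leads are themselves in LD are merged; a member shared
between two *non-merged* loci is assigned to exactly one, uniformly at
random under the caller's seed, so loci are disjoint sets.

For gene linking, locus members are filtered to plausible causal
candidates: a member is retained iff its −log₁₀ p is at least 80% of
the locus maximum (equality retains; the exclusion rule is "lower
than").

r² can come from a precomputed table (pairs absent from the table are
treated as unlinked) or be computed on demand from phased haplotypes
as D²/(p_A q_A p_B q_B); which estimator a user prefers depends on
their reference panel, so both routes are supported and r² from
genotype correlation can be supplied via the table route.

## Sliding-threshold enrichment

For each cutoff c on a −log₁₀ p grid (0 to 10, step 0.1), the fold is
the proportion of annotation-overlapping SNPs with p < 10⁻ᶜ (strict)
divided by the proportion among all SNPs. Exclusions are applied
*before* the curve is computed and the foreground membership is
recomputed afterwards. Fold is reported as undefined (not ∞) at
cutoffs with no background SNP. Refined curves recompute the same
statistic on the subset of enhancers whose mean signal (e.g. DHS read
density or H3K27ac) passes a cutoff; a refinement that empties the
enhancer set is an error rather than a silent empty curve.

Replication against a second GWAS assigns each locus the minimum
p-value over its strong-LD partners of the per-SNP minimum across the
replication traits; absence from the replication data is a value
(`NA`), and such loci simply drop out of downstream 2×2 tables.
Nominal significance is fixed at p < 0.05.

## Enhancer features

Signal density over an enhancer is the per-base mean with uncovered
bases counted as 0 (bedGraph sparse semantics). Group comparisons
report the ratio of medians, oriented foreground/background, with a
two-sided Mann-Whitney p. Methylation calls are tissue-specific when
the reference tissue differs from the mean of the comparison tissues
by **both** 2 comparison-tissue standard deviations (sample SD over
the comparison tissues only — the reference is excluded so it cannot
shrink its own yardstick) **and** 15 percentage points; both criteria
are inclusive ("at least"). Conservation uses the best 100-bp window
(step 1 bp, ties leftmost; enhancers shorter than the window fall back
to the whole-enhancer mean and are flagged), compared against
size-matched (±1 kb) random background sets because longer enhancers
mechanically contain better best-windows.

## Enhancer–gene linking

Candidate targets of an enhancer are genes with TSS within ±500 kb of
the enhancer midpoint (midpoint-to-TSS is the single well-defined
distance per pair) and expression ≥ 1 RPKM in both the reference
tissue and the differentiated-cardiomyocyte column. The link test
splits the tissue panel by whether the enhancer is called active
(≥1 bp overlap with that tissue's enhancer calls) and asks, one-sided,
whether the candidate gene is expressed higher in active tissues. The
exact permutation distribution of the rank sum (shift-algorithm
recursion over midranks, so ties are handled exactly) is used whenever
the product of group sizes is ≤ 400; larger splits use the
tie-corrected normal approximation with continuity correction. A gene
whose split is degenerate (enhancer active everywhere or nowhere) is
skipped with an explicit reason, so every candidate is accounted for
as linked / not linked / skipped. The nearest-gene baseline returns
the k nearest TSSs within 1 Mb (ties lexicographic), optionally
expression-filtered.

## Allelic imbalance

Without genotypes, a SNP is treated as heterozygous when reads
carrying each allele map to ≥ 3 unique positions. The imbalance test
is the exact binomial test of the reference count against 0.5, applied
only at SNPs with **more than 21 reads** (strictly greater, as the
rule is stated). The two-sided p doubles the smaller tail, capped
at 1 — identical to the minimum-likelihood rule at p₀ = 0.5.
Benjamini–Hochberg correction is applied across the tested family
(intended: all heterozygous enhancer-overlapping SNPs). Unique-position
counts are consumed as input; read mapping is out of scope and the
synthetic generator fabricates them.

## 4C-seq peak calling

Coverage is smoothed by a centered running mean over 21 fragment ends,
truncated at the profile edges (no padding; centered windows are the
standard reading of a running mean). Contact probability in an
unstructured fiber decays monotonically with distance, so the
background is the least-squares non-increasing fit (pool-adjacent
violators) of the smoothed signal against distance, fitted
independently upstream and downstream of the viewpoint. Residuals are
pooled per side — matching the independent fits — and fragends with
residual > Q3 + q·IQR (q = 5 for promoter-interaction calls) are
significant; consecutive significant fragends merge into one peak with
no gap tolerance. Thresholding is scale-equivariant: rescaling counts
rescales residuals and threshold together, leaving the significant set
unchanged. A flat profile has all-zero residuals and, with the strict
inequality, no peaks. Promoters are strand-aware TSS−2.5 kb windows;
reported interactions are limited to ±500 kb around the viewpoint.

## Power projections

The association z-statistic is modeled as Normal(NCP, 1) with
NCP ∝ √n. From a locus with power π₀ in a cohort of n₀ at two-sided
level α: NCP₀ = z_{α/2} − Φ⁻¹(1 − π₀), the target
NCP₁ = z_{α/2} + Φ⁻¹(π₁), and n₁ = n₀·(NCP₁/NCP₀)². The projection
ignores the far opposite tail (negligible at GWAS α) and reports both
the raw and nearest-hundred cohort size. A power below the α-implied
floor makes NCP₀ non-positive and is an error.

## The synthetic data generator

The generator produces inputs with the statistical structure the
analysis assumes, not a portrait of the human genome:

* **LD** is exchangeable within non-overlapping 20-kb blocks (a single
  within-block r², default 0.9; zero across blocks). This is
  deliberately simpler than distance-decaying LD: it makes exact
  oracles for expansion/pruning trivial while still exercising the
  r² = 0.8/0.2 threshold logic. Partner z-statistics follow the
  single-causal-variant approximation
  z = r·z_lead + √(1−r²)·ε.
* **MAF** is uniform on (0, 0.5] (array SNPs are ascertained toward
  common variants, and a flat distribution keeps every ±0.1 matching
  window well populated). **Genes** sit on a jittered grid (default
  150 per 10-Mb chromosome, 10 kb long) so that the distance-to-gene
  and gene-count covariates span densely populated ranges; under the
  defaults every lead has dozens-to-hundreds of matched control
  candidates.
* **Tissue panels**: enhancers occupy non-overlapping slots; each is
  active in the reference tissue and independently in each other
  tissue with probability 0.3 (59 tissues). Each enhancer's nearest
  gene is its planted target, with log-expression raised by
  `expression_effect_delta` (default 3) noise-SDs in active tissues.
  Acetylation-like signal is elevated and percent methylation
  depressed inside "strong" enhancers.
* **Allele counts**: depths ~ Poisson(60); balanced SNPs draw
  reference reads at probability 0.5, imbalanced ones at
  `imbalance_ratio`.
* **4C** counts are Poisson around λ(d) = scale·(1+d)^(−exponent)
  (defaults 1000 and 0.5), fragends every 264 bp (the median
  restriction-fragment spacing) over 2000 fragends per side (~528 kb,
  past the ±500 kb reporting window), with planted contacts as
  multiplicative fold windows. The decay defaults keep the Poisson
  noise floor of the near-viewpoint region within the robust
  Q3 + 5·IQR threshold computed from the whole side: under a much
  steeper decay the handful of viewpoint-proximal fragends carry
  absolute noise far above the far-field residual spread that sets
  the IQR, which is a property of the calling rule itself that users
  should keep in mind for viewpoints with extreme proximal coverage.
  Poisson (no overdispersion) is the simplest model that exercises
  the caller; overdispersion is a config extension, not the default.

What the generator does **not** emulate: coalescent LD structure and
recombination hotspots, genome sequence (motif shuffling is positional
only), read-level artifacts, expression compositionality, chromatin
domain structure in 4C profiles. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery under its
stated assumptions, not performance on real epigenomes.

## Problem sizes and numerical choices

The packaged analyses and checks run at desk scale, chosen to keep the
full suite in minutes on one core: 10⁴ SNPs on 4×10-Mb chromosomes,
400 enhancers × 59 tissues, 999–10⁴ permutations for enrichment
(10⁵ is the recommended production setting and the default in
`pipeline_config()`), 200 replicates for calibration checks, 10⁵
draws for the power-model simulation. Other numerical conventions:
exact tests switch to approximations only where stated (rank-sum
product > 400); quantiles use R's default type-7 definition; isotonic
regression is `stats::isoreg` (an exact PAVA); empirical p-values
always carry the add-one correction; all stochastic code paths take
explicit seeds and are bit-reproducible given (config, seed).

## Known limitations

* Matching tolerances are fixed windows; no caliper weighting or
  rejection sampling to equalize covariate densities, so very unusual
  leads can have few candidates (an error, by design, rather than a
  silent relaxation).
* The 80%-of-max causal filter and the 0.05 linking threshold are
  conventions, not calibrated decision rules.
* The Bayesian interval helper (`beta_interval`) uses a uniform prior
  and equal tails; published intervals under unstated priors will not
  reproduce exactly.
* 4C calling assumes a single viewpoint per profile and does not
  normalize across viewpoints or replicates.
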