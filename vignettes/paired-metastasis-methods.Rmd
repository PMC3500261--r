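---
title: "Methods: comparative exome analysis of paired tumor metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative exome analysis of paired tumor metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairmet)
```

pairmet compares the somatic alteration landscapes of two anatomically
distinct metastases sequenced together with a matched normal sample from
the same patient. The question it answers is how much of the mutational
and copy-number landscape the two lesions share — that is, how much of
it was already present in the founding clone before dissemination. This
vignette documents the statistical model of every stage, the numerical
choices made, and the limits of what the package computes.

## The genotype model

Genotypes are called per position from pileup evidence (the observed
base and its phred quality for each read). With error probability
$e = 10^{-q/10}$, a read supports its observed base with probability
$1 - e$ and each of the other three bases with $e/3$. A diploid
genotype $g = \{a_1, a_2\}$ emits a read from either allele with equal
probability, so the per-read likelihood is

$$P(b \mid g) = \tfrac{1}{2}\,P(b \mid a_1) + \tfrac{1}{2}\,P(b \mid a_2).$$

The ten unordered genotypes over $\{A,C,G,T\}$ are scored by the product
of per-read likelihoods (a flat prior by default, so the posterior
ranking equals the likelihood ranking; `call_genotype()` accepts an
explicit 10-element prior). The **MPG score** (most probable genotype
score) is the *natural-log* likelihood gap between the best and
second-best genotype. Two derived quantities gate all downstream
analyses:

* `mpg >= 10`: an inclusive absolute-confidence threshold;
* `mpg / coverage > 0.5`: a strict per-read confidence ratio.

**Why natural log.** Each clean, concordant read separates a homozygous
genotype from its best heterozygous competitor by
$\ln\!\big(\tfrac{1-e}{(1-e+e/3)/2}\big) \approx \ln 2 \approx 0.693$
per read, so confident homozygous calls have an MPG/coverage ratio just
below 0.69 and comfortably clear the 0.5 gate. Had the gap been taken in
log10, the same geometry caps the homozygous ratio at
$\log_{10} 2 \approx 0.301 < 0.5$, and *every homozygous call* — the
matched normal at a somatic candidate site, every LOH call — would fail
the ratio gate, leaving the somatic set empty by construction. The
heterozygous cap is $\ln 4 \approx 1.39$ per read. The 0.5 threshold is
only coherent on the natural-log scale, so that is the scale the package
uses, and `mpg_cov_ratio` is reported unrounded.

Ties in the likelihood ranking are broken toward the lexicographically
earlier genotype so calls are reproducible; a genuine tie has MPG 0 and
is rejected by both gates anyway. Positions with no usable reads are
explicit no-calls (`NA` genotype, ratio `NA`), and non-ACGT observations
are dropped with a warning and a per-position `n_skipped` count.

## The somatic filtering cascade

`somatic_cascade()` reduces the tumor genotype table to somatic variants
in four audited stages, each reporting `input = passed + failed`:

1. **Candidates** — positions where the tumor genotype contains a
   non-reference allele.
2. **Known-variant removal** — `build_common_panel()` marks a site as a
   known (likely germline or artifactual) variant when at least 3
   independent callers support it *and* its population allele frequency
   strictly exceeds 0.05; `filter_known()` removes exact
   chromosome/position/alternate-allele matches. Both inputs are
   optional; omitting them disables the stage without changing its
   bookkeeping.
3. **Quality gate** — the MPG and ratio thresholds above, applied to
   *all three* samples at the site (tumor, the other metastasis, and
   the normal), so a variant is only trusted where every sample is
   confidently genotyped. Sites uncovered in any sample fail.
4. **Normal subtraction** — the alternate allele must be present in the
   tumor genotype and absent from the normal genotype. Sites passing
   are classified by zygosity: a heterozygous tumor genotype is an
   ordinary somatic call, a homozygous-alternate one is flagged `LOH`.

Variants are then annotated against an exon model: codons are
reconstructed from the spliced CDS (reverse-complemented for
minus-strand genes), substitutions classified as synonymous, missense or
nonsense, positions within 2 bp of an exon boundary as `splice_site`,
and length-changing variants as `frameshift` or `inframe_indel` by
length modulo 3. Intronic and intergenic changes are annotated but
excluded from the NS/S tables.

## Concordance, spectrum, and the dinucleotide signature

`compare_metastases()` does exact set arithmetic on
(chromosome, position, ref, alt) keys, split into non-synonymous
(missense + nonsense + splice-site) and synonymous classes, and reports
the percentage of variants found in both metastases per class and
overall. Printed percentages use **half-up rounding** to 2 decimals
(`round_half_up()`), matching how summary tables are conventionally
printed; R's default banker's rounding would differ on exact halves.
Indels are excluded from the substitution table and reported in an
`indels` attribute, because the percentage denominators are defined over
substitutions; the N/S ratio (`ns_ratio()`, one decimal) is similarly a
substitution statistic. Where published totals are internally
inconsistent at the margin (e.g. an NS total that differs from its
printed breakdown by a few indels), the package reports both numbers and
does not force agreement.

The mutation spectrum collapses the 12 raw substitutions onto 6
pyrimidine-anchored classes (a G>A change *is* a C:G>T:A transition read
from the other strand). The excess of C:G>T:A transitions — the
ultraviolet signature — is tested with an exact one-sided binomial test
against the uniform null proportion 1/6; a chi-square goodness-of-fit
alternative is available. `find_dinucleotides()` pairs adjacent
substitutions left-to-right without overlap and flags CC>TT / GG>AA
events as UV-characteristic. Dinucleotide events are counted
*separately* while their constituent SNVs remain in the substitution
totals; nothing in the conventions of such tables says they must be
excluded, and keeping them makes the totals additive.

## Pseudo-CGH copy-number profiling

Rather than binning the genome by fixed width, `define_windows()` reads
blocks of a fixed number of aligned reads (default 1000) in the
**normal** sample, so every window carries the same amount of normal
evidence and window width adapts to capture density — wide windows in
sparse regions, narrow in dense ones. A trailing block remainder is
merged into the last window, and windows never span chromosomes. The
per-window statistic is

$$r_i = \log_2 \frac{t_i \, s + 0.5}{n_i + 0.5}, \qquad
  s = \frac{\sum_i n_i}{\sum_i t_i},$$

with $t_i, n_i$ the tumor and normal read counts and $s$ the
library-size factor. The 0.5 pseudocount is applied *after* scaling the
tumor count: this keeps two exactness properties simultaneously —
identical libraries give exactly 0 everywhere, and a uniformly duplicated
tumor library also gives exactly 0 (the size factor absorbs the
doubling). Applying the pseudocount before scaling would break the
second property.

### Circular binary segmentation

Profiles are segmented per chromosome by a from-scratch implementation
of circular binary segmentation (`segment_profile()`, C++ core). Within
a region, the statistic is the maximal standardized mean difference
between an arc $x_{i+1..j}$ and its complement over all arc pairs
$(i, j)$ with both parts at least `min_width` windows, scaled by the
fixed region standard deviation. Significance is assessed by a
permutation test (default 1000 shuffles of the region's values) with
early stopping once the exceedance count makes $p \ge \alpha$
inevitable; accepted splits recurse on both halves via an explicit
stack. Regions under `min_windows` stay whole. The permutation stream is
seeded, so a fixed seed reproduces the segmentation exactly.

### Noise calibration and difference calling

The derivative log-ratio spread (`dlrs()`) estimates profile noise
robustly from first differences of adjacent windows:
$\mathrm{DLRS} = \mathrm{IQR}(\Delta r) / (1.34\sqrt{2})$. For iid
Gaussian windows with standard deviation $\sigma$, differences have
standard deviation $\sigma\sqrt{2}$ and IQR $\approx 1.349\,\sigma\sqrt 2$,
so DLRS returns $\approx \sigma$ (the constant 1.34 is the conventional
normal-IQR divisor; the residual +0.7% bias is irrelevant at threshold
granularity). Differences never span chromosomes; per-chromosome values
are pooled by a weighted median. At typical exome noise of
$\sigma \approx 0.117$, three spreads land at $\approx 0.35$ — the
rationale for the difference threshold below.

`diff_segments()` projects both segmentations onto the common window
grid and calls a window *different* when the absolute difference of
segment means **strictly** exceeds 0.35 log2 units. Contiguous differing
windows merge into regions. Because it is unstated whether such summary
percentages are conventionally window-counted or base-pair-weighted,
both are emitted (`percent_windows`, `percent_bp`), each to 2 decimals,
half-up.

## Loss of heterozygosity

`loh_bins()` tiles each chromosome with fixed 5 Mb bins from coordinate
1. A site is *informative* when the normal is confidently heterozygous
(both quality gates); it shows LOH when the tumor is confidently
homozygous there. The bin statistic is the LOH fraction among
informative sites. Bins with fewer than `min_sites` (default 10)
informative sites report `NA` rather than an unstable ratio — this
minimum is a package decision, made explicit and configurable, not an
inherited convention. `flag_cn_loh()` intersects bins with the
segmentation: a bin with LOH fraction ≥ 0.8 whose
overlap-weighted segment mean lies within ±0.2 log2 units of zero is
flagged copy-neutral LOH (LOH without copy loss, e.g. from mitotic
recombination).

## Gene-set enrichment

`merge_gene_hits()` forms the hit list as the union of genes carrying
damaging somatic variants (NS classes plus frameshift/inframe) and genes
overlapping segments with $|\bar r| > 0.35$. `enrich()` computes the
hypergeometric upper-tail probability of each set's overlap
(`stats::phyper`) and adjusts across sets by Benjamini–Hochberg
(`stats::p.adjust`); both are standard library routines, and the test
suite re-derives each against independent brute-force enumerations. The
universe must contain every hit (violations are an error listing the
offenders) and defaults to the full gene model — the annotation-restricted
alternative is the caller's responsibility via the `universe` argument,
since the "right" universe is a judgment call the package cannot make.
`shared_enriched()` intersects the significant sets of the two
metastases.

## What the synthetic generator emulates

`simulation_config()` defaults describe the study conditions this
package is built around: two ~20 Mb chromosomes standing in for an exome
at desk scale, 480 founder mutations shared by both metastases plus 10
private to each (96% sharing), a 65% UV fraction of C>T changes at C:G
pairs plus CC>TT dinucleotide events, mean depth 103×, germline
heterozygous sites every ~10 kb for LOH analysis, planted copy-number
segments with known log2 ratios (including a 0.58 ≈ 3:2 gain), planted
LOH regions, a 200 000-read alignment track per sample whose local rate
follows the planted copy ratios, and a random gene-set collection. Every
planted event is returned as ground truth, so each stage can be tested
for *recovery*, not just self-consistency. The read-position track is
scaled down from the full study's read count — windows of 1000 normal
reads are kept at their standard size, so the synthetic genome yields
hundreds rather than tens of thousands of windows.

Deliberate simplifications: reads are positions, not alignments (no
mapping error, GC bias, or mates); base qualities are constant at the
configured error rate; indels are not planted (indel *handling* is
tested with hand-built cases); tumor purity defaults to 1.0 — real
purity estimates are rarely available for archival pairs, and an
optional `tumor_purity` parameter mixes normal reads in when impurity
matters.

## Reproducibility and scope

Every stochastic step is seeded: the simulator by `config$seed`, CBS
permutations by `segment_profile(seed=)`, and `run_pipeline(seed=)`
covers the whole run, whose JSON manifest records the package version,
seed, thresholds, per-stage conservation tallies, and output checksums.
Identical inputs and seed reproduce byte-identical outputs.

The test suite validates *arithmetic and statistical machinery*: printed
summary-table percentages recomputed from their own counts, oracle
equivalence for the genotyper and the enrichment statistics, recovery of
planted truth from synthetic data. It does not — and cannot — recompute
any empirical result from the original tumors, since raw patient
sequencing data is not available; no test asserts biological claims
(which genes are altered, which pathways are enriched in real
melanomas). Runtime numerics in this document's formulas are exercised
by `tests/testthat/test-acceptance.R` and recomputed from scratch by
`scripts/acceptance.R`.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(genome_length = 4e6, n_chromosomes = 2,
                         n_genes = 60, n_founder_mutations = 96,
                         n_private_mutations_per_met = 2,
                         het_site_spacing = 4e3, n_reads_normal = 4e4,
                         seed = 42)
trio <- generate_trio(cfg)
run <- run_pipeline(trio, seed = 1)
print(run)
run$concordance
```

The same stages are available individually (`call_genotypes()`,
`somatic_cascade()`, `compare_metastases()`, `define_windows()` /
`compute_log2_ratios()` / `segment_profile()` / `diff_segments()`,
`loh_bins()` / `flag_cn_loh()`, `enrich()`), and as CLI subcommands in
`inst/cli/pairmet.R` (`simulate`, `genotype`, `filter`, `concordance`,
`cnv`, `loh`, `enrich`, `run`).
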