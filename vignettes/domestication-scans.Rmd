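---
title: "Detecting domestication signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domestication signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domescan)
```

# The problem

Crop domestication leaves characteristic marks in genome-wide SNP data.
A favoured haplotype sweeping to fixation strips diversity from the
surrounding region in the cultivated gene pool while the wild progenitor
keeps it; different cultivated races may fix the *same* haplotype
(shared descent) or *different* ones (convergent, independent
domestication); and regions under selection should coincide with the
QTL likelihood intervals that biparental crosses map for domestication
traits more often than chance allows. `domescan` packages the
statistics needed to make each of those statements quantitative for a
highly inbreeding diploid such as sorghum: a windowed
wild/cultivated heterozygosity-ratio scan, Hudson's $F_{ST}$, composite
LD and its decay extent, a two-locus haplotype-sharing ratio, an exact
hypergeometric bin-overlap test, LD-adjusted significance thresholds,
genetic-physical interval anchoring and RGB $\to$ CIE-L\*a\*b\* seed
color phenotyping — together with a seeded simulator that plants all of
these signals with recorded truth.

# Statistical model and procedures

## Expected heterozygosity and the window scan

For a biallelic site with alternate-allele frequency $p$ the expected
heterozygosity is $H = 2p(1-p)$, computed from non-missing calls only
(complete case per site; the rule matters for raw, unimputed inputs and
is stated rather than left implicit). Each chromosome is tiled with
consecutive, non-overlapping windows of exactly $k$ SNPs (default
$k = 500$); a trailing remainder of fewer than $k$ sites is dropped so
the window count is deterministic. Per window the scan reports
$\bar H_w$ (wild group mean over sites with wild calls), $\bar H_c$
(pooled cultivated mean) and the ratio $\bar H_w / \bar H_c$.

Two design points were genuinely open:

* **Ratio of means, not mean of ratios.** Per-site ratios are undefined
  wherever $H_c = 0$ — exactly the sites a sweep produces — so the
  window statistic is the ratio of the window means, which is finite
  unless the *whole* window has lost cultivated diversity.
* **Infinite-ratio windows.** A window with $\bar H_c = 0$ and
  $\bar H_w > 0$ is flagged infinite and ranks above every finite ratio
  in percentile calling: total loss of cultivated diversity is the
  strongest possible sweep signal, not a missing value.

Signature regions are called at an empirical-quantile cutoff
(`topPercentileRegions()`, type-7 quantile): the top 5% for
genome-wide description, the top 1% for the overlap test below. Ties at
the cutoff are kept and adjacent qualifying windows are merged. The
quantile is taken once over the whole genome rather than per
chromosome; per-chromosome calling would let a chromosome with no sweep
donate spurious "top" windows.

## $F_{ST}$

`fst()` defaults to Hudson's estimator as a ratio of averages,
$$\hat F_{ST} = \frac{\sum_i N_i}{\sum_i D_i},\qquad
  N_i = (p_{1i}-p_{2i})^2 - \tfrac{p_{1i}(1-p_{1i})}{m_{1i}-1}
        - \tfrac{p_{2i}(1-p_{2i})}{m_{2i}-1},\qquad
  D_i = p_{1i}(1-p_{2i}) + p_{2i}(1-p_{1i}),$$
with $m$ the sampled allele counts. The estimator is robust to unequal
sample sizes (wild panels are typically an order of magnitude smaller
than cultivated ones), and the ratio-of-averages form avoids the
instability of averaging per-site ratios. Negative estimates are
reported as computed, not truncated: they are informative about
sampling noise near zero differentiation. A Weir–Cockerham variant is
available behind `estimator = "wc"` as a cross-check; the two agree
closely on balanced designs and diverge in the known ways on unbalanced
ones.

## LD and the decay extent

$r^2$ is the squared Pearson correlation of dosage vectors over
samples called at both sites (composite LD). No phasing is attempted:
in a population with selfing rates near 0.95, almost all calls are
homozygous and composite LD is essentially haplotype LD. The decay
extent (`ldDecayExtent()`) averages pairwise $r^2$ in distance bins
(defaults: 10 kb bins, 1 Mb horizon, chosen so a 150 kb extent is
resolved with an order of magnitude to spare) and reports the left
edge of the first bin whose mean drops below the background level
(default $r^2 < 0.1$); if no bin does, the horizon is returned with a
flag rather than a fabricated number.

## Two-locus haplotype sharing

For an ordered SNP set (either the association peak plus all sites with
$r^2 \ge 0.6$ to it, or the first $n$ sites of a declared region), each
consecutive site pair contributes a multiset of two-locus haplotypes:
every individual homozygous and non-missing at both sites donates the
ordered pair of its homozygous alleles. Heterozygous or missing
individuals are skipped for that pair only. This is a deliberately
phasing-free rule — justified by high selfing — and it makes the
statistic conservative where residual heterozygosity is common.

The sharing ratio between two populations pools over pairs:
$$\mathrm{ratio} = \frac{\sum_{\text{pairs}} |T_A \cap T_B|}
                        {\sum_{\text{pairs}} |T_A \cup T_B|},$$
where $T$ is the *set* of haplotype types observed. Pooling before
dividing avoids 0/0 pairs; using type sets rather than frequencies
makes the ratio insensitive to sample-size imbalance. Both choices were
open — a frequency-weighted or per-pair-averaged variant would also be
defensible — and the type-based pooled form is the one whose
qualitative contrasts (shared-sweep pairs score high, independently
swept pairs low, wild–cultivated lowest) the simulation suite verifies.
Absolute values from real panels will depend on this definitional
choice.

## Hypergeometric overlap test

Each chromosome of the genetic map is tiled with 30 cM bins (the width
of a typical QTL likelihood interval, so one bin ≈ one QTL-resolvable
unit; the last bin per chromosome is truncated). With $n$ bins total,
$l$ holding a selection signal, $s$ holding a QTL and $m$ holding both,
the evidence against independent placement is the upper tail
$$P(X \ge m) = \sum_{k=m}^{\min(l,s)}
  \frac{\binom{l}{k}\binom{n-l}{s-k}}{\binom{n}{s}},$$
summed in log space. A bin "has" a feature if any feature interval
overlaps it by a positive cM length. Intervals supplied in bp are
converted through the map by piecewise-linear interpolation (exact at
markers, refusing to extrapolate outside the mapped range). QTL
intervals known only in genetic coordinates are anchored to the genome
by the two aligned flanking markers nearest the likelihood peak,
skipping markers without physical alignment.

Tests at $n \le 25$ verify the tail against exhaustive
binomial-coefficient enumeration to $10^{-10}$ and against
`phyper()`; calibration runs confirm super-uniformity of the p-value
under uniform interval placement.

## Significance thresholds

`bonferroni(alpha, n)` is $\alpha/n$. Because dense SNPs in a selfing
species are far from independent tests, `ldAdjustedThreshold()` divides
the genome size by the average LD extent to get the effective test
count (kept real-valued: flooring a ~4867-bin count changes nothing
meaningful), and corrects $\alpha$ by that count instead; with a 730 Mb
genome and 150 kb LD the cutoff is $1.03\times10^{-5}$, i.e. order
$10^{-5}$. The LD extent may be supplied or estimated from data via
`ldDecayExtent()`; the pipeline wires the estimate in by default.

One arithmetic footnote: $0.05/265{,}487 = 1.8833\times10^{-7}$, which
is conventionally quoted as $1.89\times10^{-7}$; the package reports
the exact value.

## Color phenotyping

Seed colors are averaged per genotype in RGB (channel-wise mean over
the imaged seeds, rounded half-up) and the mean color is converted
sRGB $\to$ linear RGB $\to$ XYZ $\to$ CIE-L\*a\*b\*. Averaging before
conversion matches the phenotyping procedure the statistic is meant to
reproduce; the operations do not commute, so the order is fixed. The
conversion assumes sRGB primaries and D65/2° — cameras and illuminants
of field phenotyping are rarely profiled, so absolute Lab values from
real images are profile-dependent; relative contrasts are not. The
reference white is taken as the conversion matrix's own image of
(1,1,1), so pure white maps to exactly $L=100, a=b=0$.

# The simulator: what it emulates, and what it does not

`simulateCohort()` generates cohorts with the four properties the
statistics above rely on:

* **Population differentiation** via Balding–Nichols: ancestral
  frequencies $p \sim \mathrm{Beta}(0.8, 0.8)$ truncated to
  $[0.05, 0.95]$, population frequencies
  $\mathrm{Beta}\!\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$.
  This gives direct, analytic control of pairwise $F_{ST}$ — which is
  what parameter-recovery tests need — at a fraction of the cost of a
  coalescent simulation.
* **LD** by founder-block copying: within each block of
  `block_length_bp`, `n_founders` haplotypes are drawn per population
  and individuals copy whole-block founders. LD is strong within a
  block and absent across blocks, so the block length maps directly
  onto the decay-extent estimate. Few founders mean strong LD but also
  extra drift: the founder bottleneck inflates realized differentiation
  above the configured $F$. The two regimes therefore serve different
  studies — `n_founders = 2`–`6` for LD and sweep structure,
  `n_founders = Inf` (direct draws from the population frequencies,
  the plain Balding–Nichols limit) when an estimator is being
  calibrated against the configured $F$.
* **Inbreeding** as the probability (default 0.95) that an
  individual's two block copies are identical, mimicking a "largely
  inbreeding" species without modelling generations of selfing.
* **Sweeps** as replacement of a haplotype copy's alleles inside the
  sweep interval by a designated sweep haplotype with probability
  $1 - \text{retention}$. Sweep haplotypes are drawn once per
  `haplotype_id` from the ancestral frequencies, so two populations
  given the same id share one domestication event while distinct ids
  model convergent, independent events — the exact contrast the
  sharing ratio is meant to detect. Retention 0 produces complete
  fixation and hence the infinite-ratio flag in the scan.

The default cohort is one wild population of 31 accessions plus five
cultivated races totalling 471, with divergence levels spanning
weak (wild–bicolor-like, $F \approx 0.02$–0.05) to strong
(kafir-like, $F = 0.4$), 150 kb blocks, and ~2,000 sites per
chromosome on ten 70 Mb chromosomes — a desk-scale sketch of a
GBS panel (about 13× sparser than ~265k genome-wide SNPs, with the
same 730 Mb genome extent).

What the simulator does **not** emulate: coalescent genealogies and
recombination gradients, allele-frequency spectra shaped by real
demography, genotyping error beyond uniform missingness, linked
selection outside the declared sweep intervals, and any phenotype
other than palette-plus-noise seed color. Passing tests therefore
demonstrate that the estimators recover *planted* signals under the
package's own generative assumptions — a necessary condition, not
field validation on real panels.

# Numerical choices and degenerate inputs

* Internal physical coordinates are 1-based closed, the convention of
  the `GRanges` containers the package is built on; BED I/O converts
  to 0-based half-open at the boundary and VCF stays 1-based. Keeping
  the container's native convention means zero off-by-one arithmetic
  anywhere except the two format writers.
* Multiallelic VCF records are rejected by default or dropped behind a
  flag; they are never split, because two biallelic records at one
  position would violate the strictly-increasing-position invariant
  that windowing and interval logic rely on.
* Unsorted input positions are a format error, not silently reordered.
* Percentile cutoffs use R's default type-7 quantile; infinite-ratio
  windows participate as $+\infty$, and a cutoff that interpolates into
  the infinite tail becomes $+\infty$ itself (only infinite windows
  qualify).
* `fst()` excludes sites with no calls in either population; a
  duplicated-population comparison yields a small negative estimate of
  order $-1/(m-1)$, which is reported, not clipped.
* The hypergeometric tail is summed in log space with a max-shift; the
  PMF at impossible $k$ is exactly 0.
* Genetic-map interpolation refuses to extrapolate beyond the mapped
  range, and anchoring skips markers without physical alignment
  (`bp = NA` is legal in a `GeneticMap` for exactly this case).
* All simulation functions take explicit integer seeds and reset the
  RNG via `set.seed()`; the pipeline derives per-stage seeds from one
  top-level seed so a single integer reproduces a full run
  byte-for-byte.

# Problem sizes

The shipped test and verification suites run at desk scale, chosen so
the full suite completes in a few minutes: $F_{ST}$ recovery at 2
populations × 100 samples × 5,000 sites over 10 seeds; sweep recovery
at 10 chromosomes × 2,500 sites (500 windows of 50 SNPs) over 20
seeds; overlap-test calibration at 1,000 null placements and 200
powered placements on a 50-bin map; haplotype sharing at 3 populations
× 25 samples over 10 seeds; LD decay at 2,000 sites × 60 samples.
Window size, site counts and replicate numbers are arguments, so any
of these scale up unchanged.

# Known limitations

* The sharing ratio is type-based and pooled; published
  frequency-based variants will differ numerically on the same data.
* The scan assumes dosage data dense enough that 500-SNP windows are
  sub-chromosomal; for sparse panels reduce `window_sites`.
* Hudson's $F_{ST}$ treats the two sampled allele copies of an
  individual as independent; under extreme inbreeding the effective
  allele count is closer to the individual count, leaving a small
  positive bias of order $1/(2n)$ that the recovery tests bound.
* The hypergeometric test conditions on the realized bin counts and,
  being discrete, is conservative near small $n$.
* `GeneticMap` interpolation is piecewise linear; strongly non-linear
  recombination landscapes between sparse markers are smoothed over.
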