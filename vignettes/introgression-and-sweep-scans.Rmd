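---
title: "Diagnostic-marker introgression and selective-sweep scans: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic-marker introgression and selective-sweep scans: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fugupop)
```

# The problem

Closely related marine fish species such as the pufferfishes of the
genus *Takifugu* hybridize in nature. Given a multi-species
whole-genome resequencing cohort, three questions recur:

1. Which variant sites are *diagnostic* for a species — fixed for one
   allele in that species and for the other allele in everything else?
2. Given a diagnostic panel between two species, how much of each
   individual's genome derives from the other species (its hybrid
   index), and is hybridization *asymmetric* — does the maternally
   inherited mitochondrial genome disagree with the autosomes?
3. Which genomic regions show the signature of a selective sweep in
   one species — extreme differentiation from its relatives combined
   with a collapse of its own diversity?

`fugupop` implements the full chain from a multi-sample VCF to these
answers, together with a seeded simulator that generates cohorts with
*known* fixed differences, hybrids, introgression tracts and sweeps,
so that every downstream statistic can be validated against planted
truth rather than against itself.

# Statistical machinery

## Site filtering

`filter_sites()` reproduces the strict VCFTOOLS-style site filter
used for resequencing callsets: biallelic sites only (multi-allelic
records are dropped, not split), minor allele count at least 2 over
non-missing calls, and at most 2 missing genotype calls per site.
Missing genotypes are never imputed as reference; a half-missing
diploid call counts as missing. The filter is idempotent and order
preserving.

## FST

Two per-site estimators are available, both returned as separate
numerator and denominator so windows combine sites as a *ratio of
sums* (the standard, low-count-stable choice) rather than a mean of
ratios:

* **Weir–Cockerham (1984) θ** (default): the among-population variance
  component $a$ over $a+b+c$, computed from per-group sample sizes,
  allele frequencies and observed heterozygosity. Defined for diploid
  sites.
* **Hudson (1992)**: $F_{ST} = (p_1-p_2)^2 / \big(p_1(1-p_2) +
  p_2(1-p_1)\big) = 1 - H_w/H_b$ from sample allele frequencies.
  This plain form is exactly 1 iff the called data show a fixed
  difference, exactly 0 at equal frequencies, never exceeds 1, and
  applies to haploid (mitochondrial) data as well. The sample-size
  corrected variant found elsewhere is deliberately not used: it is
  negative for identical finite samples, which breaks the clean
  "fixed difference ⇔ FST = 1" correspondence the diagnostic-marker
  machinery relies on.

Diagnostic-site discovery itself (`find_diagnostic_sites()`) uses the
estimator-free fixed-difference rule — all called copies on one side
carry one allele, all called copies on the other side the other — so
it is unaffected by the estimator choice and works for the haploid
mitochondrial contig.

## Diversity, Tajima's D, LD

Per-site nucleotide diversity is the unbiased pairwise heterozygosity
$\hat\pi = n_{ref}\, n_{alt} / \binom{n}{2}$ over $n$ called allele
copies; windowed π divides the *sum* of per-site values by the full
window span in bp, so invariant positions contribute zero (the
convention under which published windowed-π distributions for this
genus are reported). Tajima's D uses the standard 1989 constants
$a_1 \dots e_2$; because real windows mix sites with different
missingness, the sample size $n$ is taken as the median called-copy
count across the window's sites — a pragmatic choice the tests pin
down. $S = 0$ windows are reported missing, never zero. LD decay is
the squared Pearson correlation of unphased ALT-dosage vectors
(Rogers–Huff style composite r²), binned by pair distance; for $m$
samples the no-linkage sampling baseline is $1/(m-1)$, which is what
the curve decays *to*, not zero.

## Hybrid index and mitochondrial assignment

Over a fixed-difference panel the model-based ancestry estimate of an
admixture analysis reduces, in expectation, to a deterministic count:
the fraction of an individual's called allele copies at panel sites
that carry the donor side's allele (`introgression_ratio()`). An F1
is heterozygous at every panel site and scores exactly 0.5; a k-th
generation backcross to the recurrent parent has expectation
$2^{-(k+1)}$. `mito_assign()` tallies the haploid mitochondrial
haplotype against the two panel sides and assigns the majority side;
heterozygous mitochondrial calls are rejected as data
inconsistencies. Discordance between a confident autosomal
introgression signal and a clean opposite-side mitochondrial
haplotype is the classic signature of asymmetric hybridization (one
direction of cross dominating).

## Two-pass panel discovery and the ILS floor

Hybrid individuals hide exactly the fixed differences they
contaminate, so a panel discovered with hybrids included is both
small and — critically — *blind to the hybrids themselves*: the
surviving sites are the ones where the hybrids happen to look
purebred. `two_pass_panel()` therefore flags admixed individuals
leave-one-out: the panel is rediscovered with each individual
excluded (releasing the sites that individual suppressed) and the
individual's donor-allele fraction is measured over its own
leave-one-out panel. Flagged individuals are removed and the
remaining ones re-examined until a fixed point; removing individuals
can only release sites, so the final purebred panel is a superset of
the provisional one.

Two subtleties shape the defaults:

* **The ILS floor.** A pure individual that holds the last minority
  copies of a nearly fixed ancestral polymorphism releases that site
  into its own leave-one-out panel, where its copies then read as
  "donor" alleles. Site by site this is indistinguishable from
  introgression — it is the same incomplete-lineage-sorting ambiguity
  that inflates introgression estimates on relaxed panels in real
  data. At five individuals per species and realistic polymorphism
  density this floor sits at a few percent (we measure 0.03–0.08),
  so the autosomal flag threshold defaults to 0.1: above the floor,
  below the F1/BC1 signals of 0.5/0.25. The per-individual
  *reporting* threshold of `introgression_ratio()` stays at 0.01,
  where panel-size-500 binomial noise under purity misclassifies
  under 1% of pure individuals.
* **The mitochondrial arm.** Backcrossing dilutes the autosomal
  signal geometrically, but the maternal line is copied intact, so an
  individual whose mitochondrial haplotype matches the *opposite*
  side on the leave-one-out mitochondrial panel is flagged regardless
  of its autosomal ratio. This deterministically exposes
  maternal-donor hybrids of any generation — including ones whose
  autosomal leave-one-out ratio is exactly 0 because every informative
  site was suppressed by the other hybrids still present. No flag is
  ever issued from a panel smaller than 50 autosomal or 5
  mitochondrial sites, and the iteration never empties a side.

## Genome scans

* `homozygote_ratio_scan()`: for a third-party query group and a
  panel between sides A and B, each window reports
  $\log_{10}\big((n_{A\,hom} + c)/(n_{B\,hom} + c)\big)$ with
  pseudocount $c = 1$ (real panels produce zero denominators; the
  pseudocount keeps every window finite). A site counts as side-fixed
  only when every called query genotype is homozygous and the side
  allele's frequency is 1.0 (configurable). Windows tile
  non-overlapping at 100 kb by default; a step is configurable but a
  genome-wide ratio track is the parsimonious reading of this scan.
  `detect_tracts()` then calls maximal runs of at least `min_run`
  windows beyond a ±1 threshold on the same side.
* `sweep_scan()`: 50 kb windows sliding by 10 kb; a window is
  selected when its FST (focal vs pooled complement) reaches the
  dataset's own empirical 99th percentile (linear interpolation; an
  absolute cutoff like 0.225 is dataset-specific and not portable),
  OR $|\log_2 \overline{(\pi_x/\pi_{focal})}|$ exceeds 1.5, where the
  average runs over the complement species x — read literally as the
  mean of per-species ratios, not a ratio of means. Windows with zero
  focal diversity yield a *missing* ratio rather than infinity,
  mirroring the dash entries such tables print. Overlapping or
  book-ended selected windows merge into candidate regions; both the
  selected-window count and the merged length are reported, since the
  two summaries answer different questions.
* `fine_scan()`: the same statistics at 1 kb / 500 bp inside one
  region, with the complement pooled into a single residual group —
  the per-gene view in which a sweep appears as a focal diversity
  trough with negative focal Tajima's D.

# The simulator: what it emulates, and what not

`simulate_cohort()` is a frequency-structure generator, not a
coalescent simulator: the downstream statistics depend only on
per-site frequency and genotype structure, and this design keeps the
generator seedable, fast and analytically checkable.

* **Species-specific fixed differences** are planted at a configurable
  per-bp density per species (default 1 per 10 kb): the focal species
  fixed for the alternate allele, every other species fixed reference.
  A configurable fraction (default 10%) are emitted as 1 bp indels,
  since real diagnostic panels mix SNPs and indels.
* **Shared polymorphism** is planted at 1 site per 100 bp. Each site
  draws a *carrier set* of species — a clade of the fixed ladder
  topology (a single species or a sister pair) with probability
  $1 - \text{ils\_fraction}$, or a deliberately discordant non-clade
  pair otherwise. Within a carrier species the derived-copy count
  $i$ is drawn with $P(i) \propto 1/i$, the constant-size neutral
  site-frequency spectrum. This choice is what makes
  $E[\hat\pi_{sum}] = S/a_1$ exactly and centres Tajima's D at zero
  on null data; a Beta(α, β) population-frequency model is available
  (`diversity_model = "beta"`) but is *not* the default, because its
  SFS is not neutral and would bias D. The default density is
  calibrated so per-species windowed diversity lands near
  5×10⁻⁴ per bp, the realistic scale for this genus; at much sparser
  densities the π-ratio sweep arm becomes noise-limited.
* **Linkage** comes from haplotype blocks: within an
  exponential-length block (mean 20 kb) the sites of one species
  share a slot permutation for their derived copies, so r² decays
  from high within-block values to the $1/(m-1)$ baseline at the
  block scale. Marginal per-site distributions are untouched, so
  frequencies, π, D and panels are unaffected.
* **Hybrids** are built from exponential recombination tracts (mean
  300 kb by default): one haplotype fully recurrent, the other tiled
  into tracts that are donor-origin with probability 1 (F1) or
  $2^{-k}$ (BC$_k$), each copy drawn from the origin species'
  realized frequencies. The mitochondrial haplotype is copied from
  the maternal species (default: the donor, the maternal side of the
  emulated asymmetric cross). The realized donor fraction at panel
  sites is recorded as truth; at a complete fixed-difference panel
  the measured ratio equals it exactly, which is why per-individual
  recovery is tested against realized truth while the cohort mean is
  tested against the generation expectation. For cohort-mean checks
  the tract mean matters: with 50 BC1 individuals on a 4 Mb genome,
  Var(mean) ≈ (1/4)·(2·tract_mean/L)/50, so a 10 kb tract mean puts
  3 SE at ~0.0075, inside a 1% recovery band, while 300 kb tracts
  would not resolve 1%.
* **Sweeps** thin the focal species' segregating sites inside the
  interval: each survives with probability 1/factor, reducing
  expected π by exactly the configured factor.
* **Species-level donor blocks** make every individual of a species
  draw both copies from the donor's frequencies inside the block —
  the fixed, homozygous introgression tracts that the
  homozygote-ratio scan maps.
* **Mitochondria** are a dedicated haploid contig with
  species-assigned fixed sites (150 by default, round-robin across
  species, so every species pair has markers).

What the generator does **not** emulate: genealogical correlation
between sites (no coalescent trees), demographic history (growth,
bottlenecks, migration), realistic indel length spectra,
base-calling or genotyping error, and — by default — missing data
(`missing_rate` exists but defaults to 0, since the emulated input is
a post-QC callset; missingness handling in the statistics is
exercised by fuzzed unit tests instead). Passing tests on this
generator therefore validates the *statistical machinery and its
contracts*, not robustness to upstream calling artifacts.

# Numerical choices and degenerate inputs

* Internally positions are 1-based (VCF convention); every exported
  interval (windows, BED) is 0-based half-open. One convention per
  format, stated once.
* Undefined values are missing (`NA`/"NA"), never 0: FST with a zero
  denominator, π-ratio with zero focal diversity, Tajima's D with no
  segregating site, LD bins without pairs, ratio windows without
  panel sites.
* Quantile thresholds use the empirical type-7 (linearly
  interpolated) quantile; windows at or above the threshold are
  selected, so the null selection rate is 1% by construction.
* Ties: a query-group frequency of exactly 0.5 at a panel site is
  unresolved — excluded from both numerator and denominator of the
  major-allele-source fraction and reported separately.
* Merging treats book-ended windows (shared boundary) as adjacent,
  since 10 kb-step windows overlap by construction; merging is
  idempotent.
* All randomness in the simulator flows from one seed, and the RNG
  state of the caller is saved and restored, so identical
  configurations are byte-identical on disk and simulation never
  perturbs surrounding code.

# Problem sizes

The default cohort is 10 species × 5 individuals on two 2 Mb
autosomes plus a 16.5 kb mitochondrial contig (~44,000 sites × 54
samples in the workflow configuration) — large enough that windowed
scans have ~200 windows per contig and pair panels have ~800 markers,
small enough that the full test suite runs in well under a minute and
the complete analysis workflow in a few minutes on one CPU. The
acceptance script regenerates every cohort it measures from its
`--seed` argument.

# Known limitations

* The diagnostic-allele fraction equals model-based ancestry only in
  expectation; per-individual equality with an admixture-model
  estimate is not claimed, and on panels of highly differentiated but
  non-fixed markers (FST > 0.8) a pure individual's expected ratio is
  strictly positive.
* At small per-species sample sizes the ILS floor limits how weak an
  autosomal admixture signal can be flagged; deeper backcrosses are
  reliably caught only through the maternal line. This mirrors the
  biology: detection probability genuinely declines with each
  backcross generation.
* The W-C estimator is undefined for haploid data; mitochondrial
  differentiation should be assessed with the Hudson estimator or the
  fixed-difference rule.
* `detect_tracts()` resolves tracts at window granularity; tracts
  much shorter than the window size are invisible by construction.
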