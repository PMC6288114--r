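---
title: "Window-based ancestry mapping of mosaic genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based ancestry mapping of mosaic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicmap)
```

## The problem

Composite cattle breeds such as the Brahman carry mosaic genomes: a mostly
*Bos indicus* background interrupted by *Bos taurus* segments introduced
during breed formation ("grading up", the repeated backcrossing of taurine
females to indicine bulls).  Given whole-genome genotypes for an admixed
cohort and alternate-allele frequencies for two diverged reference panels,
`mosaicmap` assigns each 250 kb window of each animal to one ancestry,
calls contiguous introgressed segments, and asks whether the longest
observed segments are longer than neutral breed history can explain --
evidence of selection.  Around that core it also detects cohort-fixed
alternate alleles with annotation-class enrichment tests, builds
permutation nulls for annotation-keyword enrichment, and scans windowed
read depth for duplication/deletion signatures at candidate loci such as
the polled locus on chromosome 1.

## The per-SNP differentiation statistic

For one SNP, let $P_{BT}$ be the alternate-allele frequency in a reference
panel and $P_{brai} \in \{0, 0.5, 1\}$ the focal animal's genotype call
treated as a one-animal "population".  With
$\bar p = (P_{BT} + P_{brai})/2$,

$$H_s = P_{BT}(1 - P_{BT}) + P_{brai}(1 - P_{brai}), \qquad
  H_t = 2 \bar p (1 - \bar p),$$

the statistic is $(H_t - H_s)/H_t$, which simplifies algebraically to
$(P_{BT} - P_{brai})^2 / (2 H_t)$.  It is 0 when the call matches the
panel frequency, 1 at a fixed difference, and undefined when
$H_t = 0$ (animal and panel both monomorphic for the same allele -- such
sites carry no ancestry information and are excluded).  Per-SNP values are
averaged within fixed, adjacent, non-overlapping windows anchored at
position 1 (`win_index = (pos - 1) %/% 250000`).  The statistic is
computed twice per animal, against the taurine and the indicine panel; the
window is assigned to the ancestry whose panel it differs from *least*.

Key tunables, with defaults:

* `window` (250,000 bp): small enough for segment resolution, large
  enough that sequence data provides a robust per-window mean.
* `min_snps` (10 per window per panel): windows below this are no-calls.
  The threshold is deliberately permissive; with whole-genome data,
  windows typically contain hundreds of shared SNPs.
* Missing genotypes are skipped for that animal only.
* Exact ties between the two panels are no-calls in window classification;
  in the per-animal genome-wide taurine-window fraction they contribute
  half a window to each side, so that running identical panels on both
  sides yields the uninformative answer 0.5 rather than 0.

Genome-wide composition pools per-SNP values (the n-weighted mean of
window means), not the unweighted mean of windows, so SNP-dense windows
carry proportionally more weight.  Both the per-animal pooled value and
the cohort mean are reported, since a printed "global" value may be
either.

Percent differences between the two sides use the *symmetric* form
$100\,(a - b) / ((a+b)/2)$.  This form was identified by
reverse-engineering the reported fixed-allele annotation table: the
intergenic row (57.685% of fixed sites against a 67.32% genome-wide
baseline) reproduces the printed $-15.416$ only under the symmetric
formula.  The same convention is used for per-window taurine-vs-indicine
contrasts, with positive values marking taurine-like windows.

## Segments and the neutral null

Maximal runs of identically-classified windows become segments.  No-call
windows break runs (absence of evidence is not continuation), and runs
never bridge chromosome boundaries.  Segment-length spectra (in windows,
pooled over animals; per-animal tables are also available) are compared
between the real cohort and a neutral simulation by tail exceedance: the
fraction of simulated segments at least as long as the longest observed
one.  Exceedance 0 is the "no neutral segment that long" outcome that
argues for selection.  No formal test is attached, matching the
qualitative form in which such evidence is usually argued.

The neutral null is a forward Wright-Fisher simulation of breed formation:
an ancestral diploid population (N = 10,000) at mutation-drift
equilibrium, a split into taurine and indicine founder populations that
diverge for a tunable number of generations, then a 30-generation
admixture phase.  Loci of 10,000 kb recombine freely with each other and
carry at most one within-locus crossover per meiosis (rate 0.01/locus),
with infinite-sites mutation at 0.01/locus/gamete/generation.  No
selection anywhere.

Two admixture designs are provided, because the historical record supports
both readings: `"cross"` (default) forms an F1 and continues random mating
within the hybrid population, and `"grading_up"` repeatedly backcrosses to
indicine sires (taurine fraction halving each generation).  Both report
their realized admixture fraction; neither is asserted as the breed's exact
historical design.

### Implementation and rescaling

The pre-admixture phases track allele frequencies only: per-generation
binomial resampling is the exact marginal distribution of the
individual-based model when linkage equilibrium holds, which it does to
excellent approximation within large randomly-mating founder populations,
and no quantity computed before admixture depends on within-population
LD.  The ancestral population is initialized at the stationary neutral
frequency spectrum ($P(k) \propto 1/k$) with the expected number of
segregating sites ($\theta \sum_{i<2N} 1/i$ per locus), and the burn-in
generations are then run explicitly on top.  Haplotypes are realized
explicitly at admixture onset, and the admixture phase is fully
individual-based: every admixed site traces to a labelled founder
haplotype, so ancestry tracts, drift, and within-cohort coalescence during
the 30 generations are all real.  Mutation during the 30 admixture
generations is omitted (its expected contribution is a few thousand
singletons, negligible for every statistic computed).

Desk-scale runs use `scale_factor` $s$: population size and the burn-in
and divergence generation counts divide by $s$ while per-generation rates
multiply by $s$, preserving $t/2N$ and $\theta = 4N\mu$ -- the two
quantities that determine drift differentiation and diversity.  The
30-generation admixture phase and the admixed population size are *not*
rescaled: they are absolute historical quantities whose tract-length and
drift structure ($30/2N_{adm}$) would be distorted by compression.

Divergence generations are tuned to a target FST by bisection
(`tune_divergence`): the separation time is adjusted until the simulated
admixed-vs-taurine differentiation matches the observed level (0.25).  A fixed generation
count is not transferable between simulators, because the achieved FST
depends on the mutation model; the tuning target is the invariant.

FST is the Weir & Cockerham (1984) two-population variance-components
estimator with sample-size correction; the genome-wide mean is the
ratio-of-sums ("weighted") form, as in vcftools.  Sites with fewer than
two non-missing genotypes in either sample are skipped, and sites
monomorphic for the same allele in both are excluded from the mean.

Problem sizes used by the shipped tests and the acceptance script: 20x
rescaling (N = 500, 5,000 burn-in and a few thousand divergence
generations), one locus for tuning evaluations and three loci (about
15,000 segregating sites, of which >10,000 enter the FST mean) for the
ten measurement replicates.  These sizes were chosen so the full
simulation study reruns in minutes on one core while keeping Monte-Carlo
error well inside the +/-0.05 band used for the FST comparison.

## Synthetic cohorts

The synthetic-data generators define the study conditions for every test:

* **Founder panels** follow the Balding-Nichols model: ancestral
  frequency $p \sim U(0.05, 0.95)$ (the narrowed range avoids
  near-monomorphic degenerate sites), daughters
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, under which Weir-Cockerham
  FST between daughter samples estimates $F$ directly.  $F = 0$ bypasses
  the Beta draw.  The default divergence in recovery tests is $F = 0.25$,
  the differentiation level of the real admixed-vs-taurine comparison.
* **Mosaic cohorts** tile each haplotype with exponential ancestry tracts
  (Markovian switch process; mean tract length defaults near
  $1/(g\,r) \approx 3\text{-}5$ Mb for a breed formed ~30 generations
  back), draw tract origins i.i.d. with the target taurine fraction
  (10%, the breed's approximate taurine content), and sample alleles from
  the origin population's frequency.  Ground-truth tracts are returned
  for recovery tests.  Coordinates are 1-based inclusive throughout, and
  a configurable missing-genotype rate (default 0) exercises
  missing-data handling.
* **Depth profiles** are Poisson per 50 bp window with mean
  `depth x window x copy-factor`; a homozygous single-copy duplication
  has factor 2, heterozygous 1.5, a homozygous deletion 0, prorated over
  partial windows.  Defaults emulate the sequenced cohort: 12.5x mean
  coverage, the 212 bp Celtic-type duplication and the replaced 10 bp at
  chr1:1,706,051-1,706,060, and the 80 kb Friesian interval as presets.
* **Read intervals** place fixed-length reads uniformly; deletion
  carriers lose reads that would span the deleted interval, which is the
  signature used for spanning-read deletion evidence.

What these generators deliberately do *not* emulate: linkage
disequilibrium within reference panels, genotyping error, variable SNP
density, reference-genome assembly artefacts (a known alternative
explanation for apparent introgression near copy-number-variable
regions), or mapping bias in depth profiles.  Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
models, not robustness to every artefact of real sequence data.

## Coverage scanning at candidate loci

Group depth profiles are standardized to SD-from-mean units within their
own group across the windows of the region (population SD; a constant
profile warns and returns zeros).  Standardizing each group separately
means differing cohort sequencing depths cannot mimic copy-number
differences.  Duplications are called as maximal runs of at least 4
consecutive windows with carrier-minus-reference z at or above 2.0 --
defaults chosen so a >=200 bp event in 50 bp windows is detectable while
single-window noise is not.  The fold change over a called run is the
ratio of group-mean-normalized depths, an estimator of the copy factor;
boundary windows partially covered by the event pull it slightly below
the nominal factor (about 1.9 observed for a planted factor-2 event),
which is well inside the +/-0.2 band used in validation.  An alternative
standardization -- per window across animals rather than per group across
windows -- would need per-animal profiles; the per-group form matches
plotting one curve per group.

## Enrichment machinery

The annotation-class chi-square compares fixed-site class counts to
expectations proportional to genome-wide class counts (Pearson statistic,
df = classes - 1, classes with expected < 5 pooled into "other" -- the
standard validity rule).  Reported chi-square values for such tables
depend on the exact contingency construction, so none is hard-coded as an
expectation.
The keyword permutation null draws gene sets of matched size i.i.d.
without replacement from the gene universe (as the text procedure
describes; genomic clustering of genes within windows is deliberately not
modelled) and records binary per-permutation keyword occurrence, with
gene-count weighting as an option.  Empirical p-values use the add-one
rule $(k+1)/(n_{perm}+1)$, so "never observed in 100 permutations"
reports $p = 1/101$ rather than 0.

## Known limitations

* The window classifier is threshold-based, not probabilistic: no HMM
  smoothing, no phasing, no genotype likelihoods.
* Allele mismatches at shared genomic locations between cohort and panel
  are dropped and logged, never strand-flipped.
* Sex chromosomes are processed like autosomes; male X dosage is not
  modelled.
* The spectrum comparison is descriptive (tail exceedance), not a
  calibrated test.
* The forward simulator omits within-founder LD at admixture onset and
  admixture-phase mutation, as discussed above.
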