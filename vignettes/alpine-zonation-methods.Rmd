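---
title: "Methods: from MOTU tables to niches along alpine gradients"
author: "alpzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MOTU tables to niches along alpine gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpzone)
```

## The problem

Soil eDNA metabarcoding surveys of green algae (Chlorophyta) along
elevational gradients produce a MOTU x PCR read-count table contaminated by
several well-known artefacts: off-target amplification, rare sequence
variants generated during PCR, reagent and cross-contamination visible in
negative controls, and outright failed amplifications. `alpzone` implements
the post-sequencing arc of such a study: table-level quality control, Hill
diversity along discretized gradients, Hellinger-based community turnover
with constrained ordination, robust marker-to-marker comparison, and
per-taxon niche inference with a permutation test of specialization. A
synthetic study generator with full ground truth makes every stage testable
without any sequencing data.

## Quality control chain

Filters run in a fixed order, each returning the filtered table plus a
report whose removal counts reconcile exactly with the matrix dimensions:

1. **Amplicon length** — inclusive bounds per marker: 65--200 bp for the
   Chlorophyta 18S-V7 marker (Chlo01) and the general eukaryote marker
   (Euka03), 65--130 bp for the Chlorophyceae 23S marker (Chlo02).
   Inclusivity at the bounds is a deliberate choice; both endpoints are
   plausible amplicons.
2. **Rarity** — a MOTU is kept only if some single PCR shows *more than*
   10 of its reads; variants that never exceed 10 reads anywhere are PCR
   artefacts with high probability.
3. **Target clade** — lineage must contain the target clade at any rank.
4. **Contaminants** — a MOTU whose maximum abundance across negative
   controls strictly exceeds its maximum across samples is removed.
   Abundance defaults to within-PCR relative frequency, because blanks run
   at depths orders of magnitude below samples; a raw-read mode exists.
   Positive controls take part in neither side of the comparison.
5. **Failed PCRs** — total reads below 200 (Chlo01/Chlo02) or 1,000
   (Euka03) mark an amplification as unreliable. We read the thresholds as
   minima to reach: rejecting *high*-coverage PCRs would defeat the
   filter's purpose, so the direction is configurable but defaults to
   "reject below". The threshold applies after clade restriction (also
   configurable).
6. **Replicate outliers** — each replicate's profile is
   Hellinger-transformed (square roots of within-PCR relative frequencies)
   and its Euclidean distance to the unweighted barycenter of its sample's
   replicates computed; distances pool across samples and a Tukey fence
   (Q3 + 1.5 IQR, configurable) flags outliers. The fence was chosen
   because the pooled distance distribution is right-skewed with a long
   tail of genuinely aberrant replicates.

Replicates then aggregate per sample as the mean of relative-frequency
vectors, re-normalized — the simplest rule that weights replicates equally
regardless of depth.

## Diversity

Hill numbers `^qD = (sum p_i^q)^(1/(1-q))` (exponential Shannon entropy at
q = 1) express diversity as an effective number of equally abundant taxa; q
= 1 is the default because it down-weights precisely the low-frequency
artefactual variants metabarcoding produces. Beta diversity is the
multiplicative ratio gamma/alpha, with gamma computed on the mean of sample
frequency vectors so that both levels weight samples equally.

Gradient effects are assessed by cutting each gradient into seven
equal-width slices over its observed range (equal width, not equal count,
so slice labels are interpretable intervals; an equal-count mode exists),
computing the one-factor ANOVA R² and a Kruskal--Wallis p per gradient, and
adjusting p-values across gradients by Benjamini--Hochberg. Slice means
carry normal-approximation 95% confidence intervals. Empty slices are
merged away with a message. Diversity is computed per PCR by default (each
PCR is an independent detection experiment); a per-sample mode uses the
aggregated matrix.

## Ordination

Collinear environmental variables are screened by iterative VIF removal
(VIF = 1/(1−R²), threshold 5), with deterministic tie-breaks (larger VIF,
then alphabetical) so results do not depend on column order.

Community turnover uses Euclidean distances on the Hellinger-transformed
matrix, embedded by classical PCoA (double-centering + eigendecomposition;
negative eigenvalues are reported and their axes dropped). Constrained
ordination is a partial RDA written directly as linear algebra: community
and scaled predictors are residualized on the conditioning block (Site, as
treatment contrasts), the community regressed on predictors, and the
fitted values eigendecomposed. The adjusted R² uses the Ezekiel formula
1 − (1−R²)(n−1)/(n−m−1). Permutation p-values permute rows of the
*residualized* community (reduced-model permutation, the standard scheme
for partial models; free permutation is available), with the
include-observed convention (1 + exceedances)/(n_perm + 1). Forward-backward
selection greedily adds the candidate with the smallest marginal
permutation p (< 0.05), then removes any selected variable whose marginal p
rises above the threshold. Per-variable contributions are partial adjusted
R² differences (full model minus model without the variable), reported
unclipped — slightly negative partials are informative on noisy data.

The marker-comparison regression is a Tukey-bisquare IRLS fit (c = 4.685,
MAD residual scale, convergence at 1e-8 coefficient change or 50
iterations) between log10 relative frequencies, with zero-frequency pairs
excluded and counted; the reported R² is weighted.

## Niche inference

For each taxon, with abundance weights normalized over samples and the
environment standardized, the niche decomposes additively into
**marginality** (squared distance of the weighted centroid from the origin
— the average sampled environment), **marginal tolerance** (weighted
variance of projections onto the marginality axis) and **residual
tolerance** (the remainder). A taxon is *specialized* if its marginality is
larger than expected under random placement **or** its marginal tolerance
smaller — two one-sided permutation tests (n = 999) obtained by permuting
the taxon's weights across samples, each at alpha = 0.05 (the same level as
the pipeline's other tests; the union of the two has a null rate just under
2 alpha, which the calibration tests verify). Permuting weight vectors
taxon-by-taxon is equivalent to permuting sample rows under exchangeability
and vectorizes cleanly.

Optimal ranges come from the abundance-weighted Gaussian kernel density of
a variable across samples, with Silverman's bandwidth computed on the
weighted values using the effective sample size 1/sum(w²) (a fixed
bandwidth is available for strict reproducibility across designs). The
range is the smallest interval around the density peak holding 50% of the
weighted mass, grown outward always on the denser side; 50% is a
definitional choice, exposed as a parameter. The per-taxon p-value
compares read-weighted variable values against all sampled values with a
Mann--Whitney statistic whose normal approximation uses the weights'
effective sample size; a presence-based unweighted alternative is provided,
since either comparison is defensible. The niche PCA runs on the taxa x
variables matrix of optimum-interval midpoints (centered, scaled), and the
first-axis scores of two designated classes are compared by Mann--Whitney.

## The synthetic study generator

The generator emulates the design of an alpine soil survey: 5 sites
covering staggered sub-ranges of 1,250--2,940 m sampled every 200 m, two
soil horizons (litter nutrient-enriched), PCR triplicates, extraction and
PCR blanks, positive controls carrying a 13-species mock community with
halving concentrations, and a Trebouxiophyceae-dominated class mixture.
Ground truth (niche optima and breadths, spiked contaminant identities,
forced failures) is returned alongside the data, so parameter-recovery is
testable.

Choices the design leaves open, and how they were fixed:

* **Abundance model.** Gaussian response curves per taxon over elevation
  and pH, multiplied into expected within-sample relative abundances, then
  Dirichlet-multinomial counts (`dispersion` 0.005; 0 recovers plain
  multinomial). Unimodal responses match how read frequencies behave along
  gradients, and the Dirichlet-multinomial gives a single overdispersion
  knob.
* **Generalists are the abundant, flat background.** A generalist's
  breadth spans several times the sampled range on every gradient and its
  peak abundance is 5x a specialist's. This mirrors field data, where
  cosmopolitan taxa dominate reads — and it matters statistically: relative
  frequencies are compositional, so a flat taxon still inherits structure
  from whatever varies around it. Keeping the flat fraction dominant keeps
  the total mass near-constant, so generalists behave as proper nulls for
  the specialization test.
* **Class-level pH effect.** The Chlorophyceae : Trebouxiophyceae balance
  shifts logistically with pH (slope 0.75 by default, applied to
  specialists only). With the default class mixture heavily unbalanced, a
  stronger slope makes the total specialist mass trend with pH and leaks
  niche structure into every taxon's relative frequency; 0.75 keeps a
  recoverable class trend while leaving flat taxa effectively null.
* **Depth per PCR.** Negative binomial (size 8) around 10,000 reads — an
  invented default, as no empirical depth distribution is implied by the
  design; forced failures draw Poisson depths far below the marker's
  acceptance threshold.
* **Environment.** Continuous variables come from a Gaussian copula
  conditioned on standardized elevation with a configurable correlation
  matrix (default: FDD strongly elevation-linked, pH/Nitrogen/CWD
  declining with elevation), then map to field-realistic scales. Carbon
  and OrganicMatter are derived from Nitrogen and C/N, planting the strong
  collinearity the VIF screen exists to remove. The matrix must be
  positive semi-definite; it is checked, not repaired.
* **Contaminants** appear in blanks at high intensity with a small Poisson
  spillover into samples, so the contaminant rule sees both clear hits and
  near-misses. They are annotated inside the target clade — contamination
  that the clade filter would remove anyway would make the rule untestable.
* **Blank background** draws a few reads from the ten most abundant taxa,
  emulating low-level carry-over without letting a rare taxon dominate a
  blank by chance.

## What passing tests do and do not show

The generator's communities are smooth Gaussian-niche assemblages with
exchangeable overdispersion. Real metabarcoding data add taxonomic
misannotation, tag jumps, chimeras, spatial autocorrelation between nearby
samples, and non-Gaussian (e.g. skewed or bimodal) responses — none of
which are emulated, so recovery rates measured here are upper bounds on
field performance. Conversely, the oracle-equivalence tests (VIF against
the inverse correlation matrix, RDA against explicit least squares and
against vegan, the OMI decomposition against a brute-force weighted
variance, PCoA against PCA, Mann--Whitney against exact enumeration) hold
regardless of the data model.

Problem sizes in the test suite were chosen to exercise each property at
useful statistical resolution: 500 replicates for null-uniformity checks
(Kolmogorov--Smirnov at alpha = 0.01), 500 null taxa for the dual-flag
calibration, 50 generated studies for parameter recovery, permutation
counts of 199--999 depending on the p-value resolution each assertion
needs.

## Known limitations

* One marker per generated table; cross-marker comparison is emulated by
  re-detecting the same communities with log-normal detection noise.
* The dual specialization criterion is a union of two 5% tests: its null
  firing rate is by construction just under 10%, and compositional
  structure in relative-frequency data adds about one point. Flat taxa in
  dominant-background communities sit right at that boundary; interpret
  specialization calls near alpha accordingly.
* The weighted Mann--Whitney in `optimal_range()` relies on an
  effective-sample-size normal approximation; with very concentrated
  weights it is conservative.
* Aggregation across replicates (mean of relative frequencies) and the
  50% optimal-range mass are simple defaults; both are parameters, not
  conclusions.
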