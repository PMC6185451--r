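---
title: "Detecting batch-effect genotyping errors from interchromosomal LD"
author: "ildqc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting batch-effect genotyping errors from interchromosomal LD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ildqc)
```

# The model

Large genotype panels are assembled from sequencing runs that differ in
center, chemistry, coverage, and capture technology. Each such batch leaves
its own fingerprint of recurrent artifacts — predominantly false
heterozygous calls at sites that are genuinely homozygous. Because the same
artifact recurs in the same individuals at many sites, the spurious minor
alleles *co-occur across chromosomes* within those individuals. For a
randomly mating population, population genetics expects no linkage
disequilibrium between chromosomes; observing it in excess is therefore a
signature of sample-level technical structure (or, rarely, strong epistatic
selection — which is why the package also ships a two-locus Wright–Fisher
simulator to quantify what selection could plausibly sustain).

## Composite genotypic LD

Phase is unknown, so the package uses the composite genotypic
disequilibrium. For loci A and B with minor-allele copy counts 0/1/2, the
nine joint genotype counts n1...n9 give the maximum-likelihood AB-gamete
count `ΣAB = 2 n1 + n2 + n4 + n5/2` (a double-minor homozygote pair
necessarily carries two AB gametes, the double heterozygote carries one
with probability 1/2), and `D_AB = ΣAB/n − 2 pA pB`. Equivalently, a
sample's contribution is `gA·gB/2`, which is how the vectorized scan
computes all pairs with a handful of matrix cross-products, with missing
genotypes removed pairwise.

Significance per population uses the χ²(1) T2 statistic with
Hardy–Weinberg-corrected variances, converted to a one-tailed p for
*positive* association (batch errors push minor alleles into coupling;
negative association is exposed behind `alternative = "negative"` but is
not part of the default pipeline). Because the χ² approximation is wild in
the far tail at realistic sample sizes — a handful of rare-allele carriers
coinciding produces absurdly small approximate p — every pair whose
Fisher-combined approximate p falls below `100/nSNP²` is re-evaluated with
a one-tailed exact test, and that exact value replaces the approximation.

## The exact test on carrier status

An exact one-tailed test on the full 3×3 genotype table requires a
normalization of the 9-cell space that is not uniquely defined. This
package instead collapses each locus to carrier status (≥ 1 minor allele) and tests the
double-carrier count against the hypergeometric null with fixed margins.
This is deterministic, integer-valued, targets the same positive
alternative, and — critically — is honest about discreteness: a pair of
doubleton variants sharing both carriers gets p ≈ 2·10⁻⁴, not the 10⁻²⁰
the χ² tail would claim. The sporadic-linkage control this provides is
what makes the empirical FDR workable at desk scale. The cost is some
power against signals carried by homozygote co-occurrence, which the
carrier collapse cannot see.

## Empirical FDR by chromosome permutation

The null is built by independently permuting, within each population, the
per-sample genotype vectors of each chromosome across individuals. This
preserves every within-chromosome property exactly (frequencies,
heterozygosity, local LD) and destroys only cross-chromosome association.
`FDR(t)` is the mean count of permuted p ≤ t over replicates divided by
the observed count, evaluated at each pair's own p, clipped to [0, 1], and
made monotone (each pair gets the best rate achievable at or above its
p — the step-up convention). Three replicates suffice for the pair-scan
FDR because each replicate contributes the full complement of null pairs;
the clustering null (below) uses more because its statistic is one number
per replicate.

## nAB: the per-individual error burden

Each sample's contribution to a linked pair is its Eq.-weight
(`2, 1, 1, 1/2, 0` by genotype configuration); summing over the link set
gives `nAB`. By construction the per-sample contributions of a pair sum
exactly to that pair's ΣAB — the conservation property the tests assert
exactly, not approximately. Two questions are asked of the profile, both
against permuted profiles computed over the *same* pair set:

* **variance excess** — ratio of observed to mean permuted variance, with
  a one-tailed one-sample t-test of the permuted variances against the
  observed value;
* **clustering support** — 1-D Gaussian mixtures with K = 1…9 fitted by
  EM (k-means++ initialization, 10 restarts, tolerance 1e-8), scored by
  AICc with m = 3K−1 parameters; the statistic is AICc(K=1) − AICc(best),
  ranked against the permuted-null statistics.

Component variances are floored at (0.1·sd)² of the data. This is the one
genuinely delicate numerical choice: with a lower floor, a spurious narrow
component can extract an unbounded likelihood gain from two coincidentally
close points, and K = 1 data stop being recognized as such; with this
floor, genuine point masses (which real nAB profiles contain) still fit
tightly while the spurious gain is capped below the AICc penalty. The best
K is the smallest K within 2 AICc units of the minimum (parsimony).

## The error call

For every variant genome-wide — not only LD-scanned ones — the response is
minor-allele presence per chromosome copy (two rows per sample; the
carrying copy of a heterozygote is arbitrary but fixed, and the
sample-level random intercept absorbs that arbitrariness). A per-population
logistic LRT of the slope on z(nAB) (aggregating the two copies to a
binomial, which has the identical likelihood) is Fisher-combined as a
prescreen; variants below 0.01 get the full mixed model

```
full: presence ~ z_nAB + (1|Population) + (0 + z_nAB|Population) + (1|Sample)
null: presence ~ (1|Population) + (1|Sample)
```

fitted by Laplace approximation (lme4, bobyqa), with LRT df = 2 (df = 1
for single-population data, where the population terms collapse). z(nAB)
is computed once per iteration over the full analyzed cohort; the
alternative (per-population z) differs only by the population intercepts
the mixed model already carries.

**Multiplicity.** The BH family is *all* scanned variants: the mixed-model
p where computed, the prescreen p otherwise. The prescreen is a
computational shortcut, not a family reduction — correcting only within
the prescreen-selected set would test a set selected by (effectively) the
same statistic against itself, and in simulation flags nearly every
selected null variant. With the genome-wide family, selected null variants
land at q ≈ 0.5 and planted errors at q < 10⁻⁶. Flagging additionally
requires a mixed-model test, at q ≤ 0.05.

## Iteration and stopping

Step 1 runs once. Each subsequent round removes pairs containing flagged
variants from the link set (the variants stay in the matrix so diagnostics
can inspect them), recomputes nAB, and re-tests the burden. The pipeline
proceeds while *at least one* of the two burden tests is significant at
0.05 and stops when neither is. The all-or-nothing alternative (require
both) fails in a regime that large panels never encounter:
with a link set of one or two pairs the nAB profile is a few point masses,
the permuted profiles are too, and the clustering statistic is as extreme
under the null as observed (empirical p ≈ 1) even when the variance ratio
is large at p < 10⁻³. Requiring both would silently abort exactly the
small-data runs the variance test correctly diagnoses.

# The synthetic world

`simulate_genotypes()` draws a MAF per variant and then Hardy–Weinberg
genotypes independently per sample and chromosome — zero cross-chromosome
LD by construction, one or more populations sharing MAFs. Two spectra:

* `uniform` on [0.05, 0.5] — the common-variant regime, the package
  default, used for the null-calibration world;
* `sfs`, density ∝ 1/x on [0.01, 0.5] — the neutral site-frequency
  spectrum, the desk-scale stand-in for resampling a real reference panel,
  whose frequency spectrum is rare-dominated down to the 1–5% class.
  Recovery experiments use this spectrum: with the
  uniform spectrum, false heterozygotes land on common sites where ten
  affected carriers cannot shift carrier counts enough for any pair to
  reach genome-wide significance, and the recovery question becomes
  vacuous.

`inject_errors()` picks an error batch (default 20% of individuals),
affected individuals within it (default 50% of the batch), and error sites
(default 0.1% of sites), then deterministically sets genotype 0 → 1 at
each affected × site combination — the recurrent-error model of a batch
effect. Genotypes already carrying the allele are left unchanged and the
realized per-site-per-individual error rate is reported.

What a green recovery test does **not** establish: power at realistic
scale. With 5,000 sites the design plants only 5 error sites (≈ 10
cross-chromosome error pairs); whether any pair reaches the empirical-FDR
threshold depends on at least two error sites drawing a low base MAF, so
roughly half of random seeds yield an empty link set and no recovery at
all. At realistic scale (~10⁵ sites, hence ~10² error sites and ~10³–10⁴
error pairs) this fragility disappears. The acceptance test pins a seed where
the signal exists and verifies the machinery recovers it; the fragility is
a property of the scaled-down world, not of the implementation. Relatedly,
the link-set cutoff for recovery runs is the default FDR < 5%: measurement
across seeds showed the relaxed 20% cutoff (meant for low-power scans)
admits sporadic pairs whose carriers contaminate the nAB profile and whose
variants get flagged, hurting precision and cluster recovery at every seed
tested while AUROC stays above 0.9 under both.

The two-locus Wright–Fisher simulator tracks the four gamete counts in a
constant pool; each generation first recombines (random perfect pairing;
discordant double-heterozygous pairings {AB,ab} ↔ {Ab,aB} switch phase
with probability r) and then resamples multinomially with fitness 1+s per
gamete. Neutrally, E[D_t] = D₀(1−r)ᵗ up to O(1/N) drift terms — the
acceptance check uses N = 2,000 gametes and t ≤ 4 so the O(1/N) bias sits
an order of magnitude below the Monte-Carlo standard error at 10⁴
replicates.

A note on the null-calibration check of the nAB variance ratio: on clean
data the link set is empty, so the check needs a stand-in pair set. A set
selected by observed p (e.g. the 100 smallest) is the wrong stand-in — the
selection itself inflates the observed variance roughly two-fold relative
to permuted profiles, measuring selection bias rather than calibration.
The calibration check therefore uses a seeded *random* set of 100
cross-chromosome pairs, where the ratio is ≈ 1 on clean data. The
pipeline's own variance test never faces this situation: it only runs on
FDR-significant link sets, and on clean data it is not reached at all.

# Numerical and degenerate-input policy

* p-values are floored at machine epsilon before log-combination
  (Fisher's method), and T2 denominators at 1e-12.
* Monomorphic loci make a pair untestable in that population; populations
  are dropped from the Fisher combination, and a pair untestable
  everywhere is dropped.
* Perfect separation in the prescreen falls back to a weakly
  L2-penalized IRLS fit (λ = 0.01 on the slope), flagged.
* Mixed-model non-convergence falls back to the prescreen p, flagged
  `approximate`.
* An empty link set yields an all-zero profile with a warning, and the
  pipeline reports the dataset homogeneous — the expected outcome on a
  single-technology panel.
* An FDR cutoff of 0 disables linking outright (empirical FDR can be
  exactly 0).
* All randomness flows from one master seed through derived sub-seeds;
  reruns with the same config are byte-identical.

# Known limitations

* The exact test sees carrier status only; associations expressed through
  homozygote excess lose power relative to a (non-reproducible) exact test
  on the full 3×3 table.
* Within-chromosome LD is out of scope by design; so are phasing,
  imputation, and annotation-dependent diagnostics (GC context,
  homopolymers, synonymy).
* Metadata association (center/coverage/chip) is deliberately not
  modeled — the per-sample profile TSV is the hook for users to do this
  with their own spreadsheets.
* The mixed model treats two copies per sample; for X/Y or other
  hemizygous records the coding is undefined, which is why only autosomal
  biallelic SNVs are read.
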