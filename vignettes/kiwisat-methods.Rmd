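---
title: "Methods: consensus genotyping, error rates and monitoring statistics in kiwisat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus genotyping, error rates and monitoring statistics in kiwisat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kiwisat)
```

`kiwisat` analyses noninvasive genetic samples from kiwi: replicated
microsatellite amplifications are condensed into consensus genotypes,
scored for quality, screened for genotyping errors, and fed into
population-genetic, sexing, ordination and qPCR-QC summaries. This
vignette explains the models behind each stage, the tunable parameters,
the synthetic-data generator, and the design choices made where more than
one convention exists.

## The multi-tube consensus model

Low-template DNA (fecal swabs, shed feathers) amplifies unreliably: a
reaction may fail outright, a heterozygote may lose one allele (allelic
dropout, ADO), and stutter artifacts may add a spurious allele (false
allele, FA). The classic defence is the multi-tube approach: amplify each
sample × locus R times (R = 4 here) and call a consensus.

`call_consensus()` counts, per sample × locus, the number of *positive*
(non-failed) replicates in which each allele appears:

* heterozygote A/B when exactly two alleles each reach `het_min`
  (default 2) positive replicates;
* homozygote A/A when one allele reaches `hom_min` (default 3) and no
  second allele reaches `het_min`;
* three or more alleles reaching `het_min` is conflicting evidence: the
  locus is left missing with flag `"conflict"` rather than erroring, since
  downstream filters are the right place to deal with bad loci;
* anything weaker is missing (`"low_support"`, or `"failed"` when nothing
  amplified).

The thresholds are not universal constants; 2-of-4 / 3-of-4 is standard
multi-tube practice at quadruplicate depth and conservative enough that
zero-error evidence always reproduces truth, which the test suite pins.
Both are arguments, so stricter designs (e.g. `hom_min = 4`) are one
keystroke away.

When a high-quality reference genotype exists for a bird (in the field:
a plucked-feather profile), `reference=` overrides the replicate call and
replicates are scored against it. This matters for error estimation
(below): scoring against an independent reference removes the selection
bias that consensus-conditioned scoring introduces.

## Quality index

Each replicate scores 1 iff its complete single-locus genotype equals the
consensus — a dropout replicate showing one consensus allele scores 0, as
does a failed replicate. QI(sample, locus) is the mean replicate score;
QI(sample) is the mean over *consensus-defined* loci; the cohort summary
is mean ± SD over samples.

Two edge conventions deserve note. A locus where every replicate failed
has QI 0 (total failure is the worst observable quality), but loci with
*no defined consensus* are excluded from the per-sample mean — otherwise
QI = 1 would not be equivalent to "every replicate matches at every
defined locus", an equivalence the tests assert. A sample with no
consensus anywhere has undefined (NA) QI. Genotype success uses the
conventional QI ≥ 0.75 rule, boundary inclusive; `filter_samples()`
removes samples missing consensus at more than 2 loci. Both thresholds
are arguments.

## Error rates

`error_rates()` follows the GIMLET convention of scoring each replicate
against its consensus profile. With "positive" = non-failed:

* amplification failure = failed replicates / all replicates;
* ADO = positive replicates at heterozygous-consensus sample-loci showing
  exactly one consensus allele and nothing else, over positive replicates
  at heterozygous-consensus sample-loci;
* FA = positive replicates containing ≥ 1 allele absent from the
  consensus, over positive replicates at consensus-defined sample-loci.

Conventions differ between implementations on two points, so both are
fixed here explicitly and test-pinned: the FA denominator includes *all*
consensus-defined sample-loci (not only heterozygous ones), and the
"across loci" / "across samples" summaries are unweighted means of the
per-locus / per-sample rates (pooled ratios are reported alongside). A
unit with no heterozygous consensus has undefined ADO — reported missing,
never zero.

Under the generator's observation model the reference-scored estimators
are unbiased up to an ADO × FA interaction of order `ado_prob × fa_prob`
(a dropout replicate that also gains a false allele is no longer a clean
single-allele pattern). The parameter-recovery suite runs 200 samples ×
23 loci × 4 replicates at fail 0.06 / ADO 0.20 / FA 0.01 — fecal-swab-like
rates — and requires each pooled estimate within 3 Monte Carlo SE of its
generating value.

## Diversity, PI and PIsibs

Frequencies are allele counts over 2 × typed individuals per population ×
locus. Per locus: He = 1 − Σpᵢ², Ho = heterozygotes/typed, F_IS =
(He − Ho)/He (undefined at monomorphic loci and excluded from means).
Population values are unweighted means over loci. Two deliberate choices:

* He defaults to the uncorrected 1 − Σpᵢ²; the small-sample `2n/(2n−1)`
  variant is available via `unbiased = TRUE`. Published species tables do
  not discriminate between the two at their printed precision.
* Population F_IS is reported both as the mean of per-locus F_IS
  (`fis_mean`) and as `(mean He − mean Ho)/mean He` (`fis_ratio`); the two
  estimators genuinely disagree on real data and reported values in the
  literature are often not reproducible from the species-level means
  alone, so both are exposed rather than silently choosing one.

Private alleles are counted on frequency support (freq > 0) with no
minimum-frequency filter.

The probability that two unrelated Hardy–Weinberg individuals share a
single-locus genotype is PI = 2(Σpᵢ²)² − Σpᵢ⁴; the full-sibling analogue
is PIsibs = ¼ + ½Σpᵢ² + ½(Σpᵢ²)² − ¼Σpᵢ⁴ ≥ PI. Both formulas are verified
in the tests against brute-force enumeration — PI over all genotype
pairs, PIsibs over all parental genotype pairs and Mendelian offspring
distributions — to 1 × 10⁻¹² on a thousand random frequency vectors.
`cumulative_pi()` multiplies across loci (independence assumed), in panel
order by default; ordering was left unspecified in the motivating work,
and panel order is the neutral choice, with most-informative-first
available. The sex-linked locus is included when its frequencies are
supplied — mirroring "all 23 loci" accounting despite non-HWE inheritance
— and can be excluded by passing it to `exclude=`.

## Sex determination

Z37B produces a 92 bp W fragment in all five species and species-specific
Z fragments (mantelli 96/98/100, australis 96/98, rowi 96, owenii 94,
haastii 94; the 98/100 alleles are lineage restricted). ZW systems fail
asymmetrically under dropout — a female can masquerade as a male, never
the reverse — so `sex_call()` requires only one W-bearing positive
replicate for a female but `min_pos_male = 2` W-free positive replicates
plus an observed Z fragment for a male; thinner evidence is `ambiguous`.
Fragments are matched exactly in integer base pairs (the simulator and
ladder are discrete; no ±1 bp tolerance), out-of-pool fragments are
annotated rather than fatal, and lineage-restricted alleles observed
outside their declared lineage are flagged but accepted for the species.

## Genotype matching

`match_genotypes()` scores all pairs on loci typed in both, flags pairs
with ≤ `max_mismatch` mismatches over ≥ `min_shared_loci` shared loci,
and is monotone in `max_mismatch`. The tests verify that observed match
counts on simulated unrelated individuals agree with the PI-based
expectation `C(n,2) × Π PI_l` within a generous Monte Carlo band (pairs
share individuals, so the count is over-dispersed relative to binomial).

## Ordination

The codominant genotypic distance is computed per locus as half the
squared Euclidean distance between allele-count vectors, which reproduces
the standard values (ii–ii 0, ij–ij 0, ii–ij 1, ij–ik 1, ij–kl 2, ii–jk
3, ii–jj 4), summed over loci typed in both samples. Missing loci are
skipped; with `scaling = "mean"` the sum is rescaled by total/shared loci
so partially typed samples remain comparable. Genotype interpolation for
missing data (as some desktop packages do) is deliberately not
replicated: rescaling is transparent and keeps the metric's meaning.
Pairs sharing zero loci are an error, not a guess.

`pcoa()` is classical metric scaling: Gower-center −d²/2, eigendecompose,
scale eigenvectors by √λ. Negative eigenvalues (possible, since the
distance need not be Euclidean) are reported and their axes dropped;
percent variance is relative to the positive-eigenvalue total. The
implementation is cross-checked against an independent classical-scaling
implementation (`ape::pcoa`) in the tests.

## qPCR quantification and inhibition

`fit_standard_curve()` regresses Cq on log₁₀(concentration) over ≥ 3
distinct standards (the canonical design is ten serial dilutions from 5
to 0.002 ng/µl in triplicate); efficiency is 10^(−1/slope) − 1 with a
warning outside [0.9, 1.1]. Back-transformation averages replicate Cq
*on the Cq scale* before inverting — matching how mean Cq values are
reported in practice — rather than averaging concentrations.

The inhibition test spikes each extract with 2.5 ng/µl of standard and
compares against spike-only positive controls: ΔCq = spiked-sample mean
Cq − control mean Cq, with failed wells imputed at 45 (the total cycle
count). Copurified inhibitors delay amplification, so ΔCq > 0 flags
inhibition (threshold configurable; clean extracts typically sit slightly
negative because the sample contributes a little extra template). The
spiked wells are compared to spike-only controls, matching the described
plate design; whether the tiny sample-template contribution should be
subtracted is unknowable from the design, and at fecal target
concentrations (pg/µl against a 2.5 ng/µl spike) it amounts to a few
hundredths of a cycle. Target-to-total ratios reconcile pg/µl target
against ng/µl fluorometric totals as a percentage.

## The synthetic-data generator

The generator exists so that every downstream stage has data with the
statistical structure the analysis assumes:

* **Populations** (`simulate_populations()`): each autosomal locus gets a
  shared allele support drawn from its repeat-unit ladder and
  per-population frequency vectors from a symmetric Dirichlet
  (concentration 1 by default; 0.5 for more skewed, species-like
  spectra). Private alleles are injected as ladder sizes unused by any
  other population, at frequency 0.1 before renormalization, making
  "private" literal: support disjoint by construction.
* **Individuals** (`simulate_individuals()`): autosomal genotypes follow
  HWE with inbreeding, P(AA) = p² + fp(1 − p), P(AB) = 2pq(1 − f), with f
  applied per locus independently (no identity disequilibrium). Females
  get {92, Z}, males two independent Z draws from the species (and
  lineage) pool.
* **Replicates** (`simulate_replicates()`): per replicate, failure with
  `fail_prob`; dropout of one uniformly chosen allele with `ado_prob`,
  heterozygotes only (so the ADO estimator targets `ado_prob` directly);
  a stutter-like false allele ±1 repeat unit from a true allele with
  `fa_prob`, clipped to the locus range and never colliding with a true
  allele — a stutter identical to a real allele is unobservable as an
  error, so the rate parameter refers to observable artifacts. The
  per-replicate error process behind published error-rate tables is never
  stated explicitly anywhere; this observation model is one consistent
  reading, chosen to make parameter recovery exact in expectation.
* **qPCR plates** (`simulate_qpcr()`): Cq = intercept + slope·log₁₀(conc)
  + noise + shift, with standards, unknowns, spiked wells and controls.

Default conditions mirror the study design: 22 autosomal loci + Z37B,
quadruplicate PCRs, failure ~6–28%, ADO ~12–25%, FA ~0.3–1.9% depending
on sample type, ten-dilution standard curves. For species-level
simulations the per-species private-allele counts reported for the five
recognised species (69, 21, 6, 4, 21) are used as the generator
condition; a handful of private alleles models within-species
populations, not species divergence, and understates the separation that
species-level ordination shows on real data.

What the generator does *not* emulate: peak heights and stutter ladders
(no electropherograms), linkage and identity disequilibrium, null
alleles, allele-size-dependent dropout, degradation gradients within a
sample, and spatial sampling structure. Passing tests therefore
demonstrate the pipeline's correctness under a clean probabilistic error
model, not robustness to every pathology of real trace DNA.

## Problem sizes and numerical choices

The test suite runs at deliberately modest scale chosen to make Monte
Carlo checks sharp but quick: parameter recovery at 200 samples × 23
loci × 4 replicates; HWE and heterozygosity convergence at n = 500;
PI-oracle equivalence on 1,000 random vectors (tolerance 1 × 10⁻¹²);
ordination at 5 species × 15 birds; the sexing validation cohort at 130
known-sex birds. Eigendecomposition tolerances scale with the largest
eigenvalue (relative 1 × 10⁻⁹); frequency vectors must sum to 1 within
1 × 10⁻⁶ at the user boundary and are constructed to 1 × 10⁻⁹
internally. Ties in consensus support are impossible by construction
(calls depend on counts reaching thresholds, not on ordering); ties in
the informative PI ordering fall back to input order.

## Known limitations

* No probabilistic genotype calling (no likelihoods, no peak heights);
  the consensus rules are counts over replicates.
* Error-rate denominator conventions vary across published software
  versions; the ones here are documented and pinned but not the only
  defensible reading.
* PI accumulation assumes locus independence.
* The PCoA handles missing data by rescaling, not interpolation, so
  coordinates are not numerically identical to tools that interpolate.
* Sexing assumes the species (and optionally lineage) of each sample is
  known; it interprets fragments, it does not assign taxa.
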