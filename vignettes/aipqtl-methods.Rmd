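---
title: "Models and design choices in aipqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in aipqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aipqtl)
```

aipqtl implements the statistical core of a two-population dissection of
a quantitative behavioural trait — alcohol sensitivity measured as
inebriometer elution time — together with a forward simulator of the
complete experimental design. This vignette records the models, their
assumptions, and the design decisions that were genuinely open, so that
a user can judge what a passing test suite does and does not establish.

## The phenotype model

Flies in an ethanol-saturated column elute when they lose postural
control; collection happens at fixed intervals, so the observable is the
*bin edge*, not a continuous time. `simulate_elution()` therefore draws

y = grand_mean + Σ dosage·effect + sex_effect·[male] +
tolerance_shift·[E2] + N(0, residual_sd)

and discretizes with `ceiling(y / bin_width) * bin_width`, floored at
one bin (a fly cannot elute before the first collection). Defaults:
grand mean 7 min and residual SD 2 min, matching the scale on which line
means of real panels spread over roughly 1–16 min with a control line
near 6 min; sex effect 0.7 min (males elute later); tolerance shift
1.5 min at the second exposure; 1-minute bins. QTL effects are additive
in allele dosage — dominance and epistasis are deliberately outside the
generator, because every downstream estimator in the package is built
on the additive model and tests should not silently depend on
unmodelled genetic architecture.

## The advanced intercross simulator

`make_founder_panel()` creates fully inbred, fully homozygous founder
lines at biallelic sites. A `private_fraction` of sites carries the
alternate allele in exactly one line; with six equally represented
founders such alleles enter the base population at frequency 1/6
(0.167) — the reason extreme-QTL designs can interrogate alleles too
rare to test in the source panel. Non-private sites get the alternate
allele in two to *n*−1 lines so that the private fraction is controlled
exactly and every site segregates.

`diallel_base_population()` crosses every unordered pair of distinct
lines (15 pairs for six lines) with equal offspring counts: each
founder contributes exactly 1/*n* of base haplotypes, and within-line
crosses are excluded. `advance_generations()` then mates at random:
for each offspring an ordered pair of distinct parents is drawn
uniformly (random union of gametes, selfing excluded — with N = 300 the
distinction between this scheme and monogamous pairing is immaterial
for drift at the time scales simulated).

Three choices here were genuinely open:

* **Achiasmatic males.** *Drosophila* males undergo no meiotic
  recombination. The simulator recombines female gametes only (exposed
  as `female_meiosis_only`), which halves the effective recombination
  rate relative to the female map — a property the test suite checks by
  comparing junction accumulation under both settings.
* **Crossover model.** Poisson crossover counts with mean equal to the
  map length in Morgans and uniform positions, no interference. This is
  the simplest model consistent with a uniform-rate genetic map; with
  chromosome-scale maps of ~1 Morgan, interference mainly affects
  double-crossover spacing, which none of the implemented statistics
  use.
* **Census vs effective size.** The maintenance population size of 300
  is treated as a *census* size. Under random union of gametes census
  and effective size are close, and none of the package's claims depend
  on the distinction; the parameter is exposed so users can separate
  them.

Haplotypes are stored as founder mosaics (segment lists in cM), so
per-generation cost is independent of the number of sites; genotypes
are recovered by founder lookup only when phenotypes or pools are
needed.

The genetic map defaults to three chromosomes of 66, 108 and 110 cM
(X and the two large autosomes, roughly the *D. melanogaster* female
map) with uniform recombination along physical coordinates. Real maps
have centromeric suppression and the dot chromosome; neither matters
for the statistics under test, but absolute localization widths in real
data will differ from simulated ones.

## Variance partitioning and heritability

`partition_variance()` implements the method-of-moments solution of the
balanced nested-factorial ANOVA *Y = μ + L + F + L×F + Rep(L×F) + ε*
with line random and the crossed factor (sex or exposure) fixed:

* σ̂²\_ε = MS\_within
* σ̂²\_Rep = (MS\_Rep − MS\_within)/f
* σ̂²\_{L×F} = (MS\_{L×F} − MS\_Rep)/(r·f)
* σ̂²\_L = (MS\_L − MS\_{L×F})/(s·r·f)

with f flies per replicate, r replicates per cell, s factor levels.
Mean squares are computed in closed form from cell means — numerically
identical to `aov()` error strata (the tests verify this) but hundreds
of times faster at the 115,000-row scale of a full panel design, which
is what makes replicate-simulation calibration cheap. Design choices:

* **σ²\_P excludes the replicate component** (σ²\_P = σ²\_G + σ²\_ε);
  `include_rep_in_P = TRUE` adds it. The default treats replicate as a
  nuisance environmental stratum rather than part of the phenotypic
  variance a selectionist would see.
* **Negative estimates are truncated to zero after all four components
  are solved**, not sequentially — standard ANOVA practice; it keeps
  H² in [0, 1] without letting the truncation of one component
  contaminate another.
* **Unbalanced data are rejected, not approximated.** Expected mean
  squares are only exact under balance; `rebalance_elutions()` restores
  balance by seeded subsampling when a few observations are lost.
* F ratios follow the expected-mean-squares ladder (L over L×F, the
  fixed factor over L×F, L×F over Rep, Rep over within). REML and
  Satterthwaite degrees of freedom are out of scope: the estimator is
  the classical balanced-ANOVA one and is tested as such.

The estimator is unbiased in simulation: over 200 replicate draws of a
205-line × 2-sex × 2-replicate × 70-fly design the mean recovered H²
sits within ±0.02 of the generating value (0.42 and 0.38 in the two
reference configurations) — this is exactly what `scripts/acceptance.R`
recomputes.

Tolerance is scored per line as T = (E2−E1)/(Ē2−Ē1) with unweighted
line-mean averages, so mean(T) = 1 identically; the scaling makes lines
comparable across experiments whose overall tolerance induction
differs. Genetic correlations across sex/exposure conditions are
reported as plain Pearson correlations of line means — with inbred
lines and balanced designs the line mean is the natural genotypic-value
estimate, and the variance-component-ratio estimator is out of scope.

## The pooled allele-frequency Z test

For each site, with pool frequencies p_S, p_R estimated from read
counts and p₀ their average,

Z = (p_S − p_R) / √( p₀(1−p₀)(2/n + 1/d_S + 1/d_R) )

The variance has two independent layers: drawing n chromosomes per pool
from the source population contributes p(1−p)/n per pool (the 2/n), and
sequencing each pool to finite depth contributes p(1−p)/d per pool. The
symmetric 1/d_S + 1/d_R form is the only dimensionally coherent way to
combine the two depths, and in the deep-sequencing limit the statistic
converges to the classical two-proportion z-test on n chromosomes per
pool — a limit the tests check, along with Monte-Carlo calibration of
the type-I error at depths ≥ 30 and antisymmetry under pool exchange.

Conventions: `n` defaults to twice the pool size for autosomes and
should be set to the pool size for the X chromosome in male pools
(`run_xqtl()` accepts a per-chromosome named vector); p-values are
two-sided (the hypothesis is a difference, with no a-priori direction);
sites with p₀ ∈ {0, 1} carry no information and are flagged degenerate
with Z = 0, p = 1; p-values are floored at the smallest positive
representable double so that −log₁₀(p) stays finite. Scans report both
the Bonferroni call at α/m and a nominal 10⁻⁵ call, because in practice
sub-threshold recurrent hits feed the candidate-gene machinery.

Truncation selection uses exact pool sizes: elution minutes are tied by
construction (binned collection), so boundary ties are broken by a
seeded uniform draw rather than by row order.

## Line-mean association

`single_variant_tests()` is deliberately simple: covariates are
regressed out of line means once, then each variant with MAF strictly
above 0.05 is tested by regression on dosage, which for homozygous
inbred lines is identical to a two-class equal-variance t-test (an
identity the tests verify). No genomic-relatedness random effect is
fitted — that adjustment belongs to dedicated mixed-model GWAS
infrastructure, and a generic covariate matrix stands in for systematic
effects such as endosymbiont infection or inversion karyotype. P-values
from this module are therefore anti-conservative in structured panels;
its role here is to feed ranked candidate lists, not to publish
per-variant significance.

## Candidate overlap and its permutation null

Genes are tagged by variants within the gene body ± 1 kb (configurable;
interval arithmetic via GenomicRanges, with coordinates converted from
BED/GFF3 conventions exactly once at the file boundary). The overlap
statistic is the number of genes recurring in at least two per-analysis
candidate sets. The null replaces each analysis's set by a uniform
random draw of the same size from the universe of testable genes —
conditioning on the observed set sizes, the minimal sufficient
structure; permuting at gene level rather than variant level avoids
re-deriving gene sets under an arbitrary variant-to-gene multiplicity
model, and keeping the set sizes fixed is what makes the statistic
exchangeable under the null. The add-one estimator
(1 + #{perm ≥ obs})/(B + 1) never returns zero and has floor 1/(B+1) —
0.001 at B = 1000.

## One-linker subnetworks

From a global genetic or physical interaction graph (processed
independently, as the two edge types answer different questions), the
extracted subnetwork contains all candidate–candidate edges plus every
non-candidate adjacent to at least two distinct candidates, with
exactly its candidate edges. A non-candidate adjacent to a single
candidate is excluded — it bridges nothing. The operation is idempotent
and equals exhaustive enumeration of candidate-to-candidate paths of
length ≤ 2 (property-tested against a brute-force oracle on random
graphs). Candidates connected only through two or more intervening
non-candidates stay disconnected: one linker is the designed limit of
inferential charity toward un-nominated genes.

## Expression (ΔCt) analysis

Technical replicates are averaged before any statistic (wells on a
plate are not independent evidence); ΔCt = Ct(gene) − Ct(reference)
within each sex × pool × biological-replicate stratum, which cancels
plate-level shifts exactly. Pool comparisons use the equal-variance
Student's t-test on biological replicates (Welch behind a flag), and
the candidate-vs-random comparison classifies transcripts as altered at
p < 0.05 and applies a one-sided Fisher's exact test, because the
scientific claim is directional (candidates *more* often altered).
Amplification-efficiency correction and fold-change transforms are out
of scope: every inference here is on the ΔCt scale.

## Numerical and reproducibility choices

* One integer seed per stochastic entry point; internal stages derive
  independent sub-streams deterministically, so adding a stage never
  perturbs another's draws, and equal seeds give bit-identical results.
* Mean squares at rounding-noise level (constant responses) are treated
  as exact zeros in the mutant ANOVA (F = 0, p = 1) instead of
  producing 0/0 artefacts.
* Degenerate inputs fail loudly and specifically: strata without
  control observations, unbalanced designs, monomorphic panels,
  candidate sets exceeding the universe, heterozygous records in
  founder VCFs, malformed TSV lines (cited by number).

## What the simulator does and does not establish

The generator reproduces the statistical skeleton the estimators
assume: founder structure with private alleles, drift under random
mating with female-only recombination, additive QTL effects, binned
phenotypes, truncation selection, and the two-layer sampling noise of
pooled sequencing. It omits dominance and epistasis, interference,
non-uniform recombination, genotyping error, alignment artefacts,
indels and structural variation, and environmental block effects beyond
the replicate stratum. Passing tests therefore demonstrate that the
estimators are correct and calibrated *under the stated model*; they do
not certify performance on real sequencing data, where the excluded
error modes dominate the difficulty.

Test and acceptance problem sizes were chosen to make Monte-Carlo error
small relative to the tolerances while keeping the default suite fast:
200 replicate panels for heritability recovery, 30,000–40,000 sites for
Z-test calibration, nine end-to-end AIP replicates (25 generations,
N = 300, 2,000-fly cohorts, 90 sites) for planted-QTL localization.

## The pipeline surface

`run_pipeline()` binds the stages into seeded, manifest-logged runs
from a single YAML/list configuration with strict key validation; file
formats (minimal VCF, TSV dialects, BED, GFF3, edge lists, GraphML) are
handled by dedicated readers/writers with round-trip fidelity. The
package's functions, this vignette, and `scripts/acceptance.R` are the
intended interface; there is no shell subcommand layer, as every
documented workflow is two to ten lines of R.
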