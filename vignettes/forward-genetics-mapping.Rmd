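---
title: "Mapping a recessive lethal by recombination, complementation and tiling PCR"
author: "flymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive lethal by recombination, complementation and tiling PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymap)
```

# The mapping problem

A recessive lethal mutation on Drosophila chromosome 3, kept in stock over a
balancer chromosome (TM6B, marked with dominant Tubby and itself
homozygous-lethal), must be localized with classical genetics alone: no
sequencing of the mutant stock, no deposited accessions. The workflow this
package implements is the standard three-tier strategy:

1. **Meiotic recombination mapping.** Females heterozygous in *repulsion
   phase* — the lethal on one homolog, a multiply marked chromosome carrying
   eight visible recessives (*ru h th st cu sr e ca*) on the other — are
   testcrossed. Each scored F3 male carries one maternal recombination
   product, transmitted intact because Drosophila males do not recombine.
   Whether that chromosome also carries the lethal is determined by an
   individual testcross to lethal/balancer females: absence of the
   diagnostic non-balancer progeny class marks the male's chromosome as
   lethal-bearing (`inferLStatus()`).
2. **Complementation mapping.** Deficiencies (molecularly defined deletions)
   spanning the chromosome are crossed to the mutant; failure to complement
   places the lethal inside the deleted interval. Intersecting failures and
   excluding complementers on the polytene band lattice yields a candidate
   band interval; lethal insertion alleles of genes in or near that interval
   then identify the gene (`solveRegion()`, `checkAllelism()`).
3. **Molecular fine mapping.** Overlapping PCR amplicons tile the candidate
   gene; amplicons that fail or shift in size localize the lesion to base
   pair resolution, and size arithmetic estimates the insertion
   (`findLesionInterval()`, `insertionSize()`). Semi-quantitative
   target/control densitometry summarizes copy-number and expression assays
   (`relativeAbundance()`).

Stage-survival and fertility tables surrounding the mapping are handled by
the viability module (`stageProportion()`, `expectedClasses()`,
`goodnessOfFit()`, `arcsineSqrt()`, `fertilitySummary()`).

# The core statistic

For each visible marker the scored males are classified against the lethal
locus. In repulsion phase the *parental* classes are (marker wild-type,
lethal present) and (marker mutant, lethal absent); the exchanged
combinations are *recombinant*. The two-point recombination frequency is

$$\mathrm{RF} = 100 \cdot \frac{R}{P + R}$$

in percent, read directly as map distance in centiMorgans for closely
linked pairs. Confidence intervals are Clopper–Pearson exact binomial
intervals: recombinant counts next to a tightly linked marker are tiny
(often 0–8 of 113), where normal approximations misbehave.

```{r rf}
counts <- readPairCounts(system.file("extdata", "table3_pair_counts.tsv",
                                     package = "flymap"))
estimateRF(counts)
```

Published RF tables truncate rather than round the display (8/113 prints as
7.07); `formatRF()` reproduces that convention. Replicated crosses pool by
component-wise summation (`poolCounts()`), which is exactly equivalent to
tallying the concatenated male table.

## Locus placement

Two placement methods are provided.

**Flank subtraction** reproduces the classical printed arithmetic. The
anchor is the marker with the smallest RF (ties broken toward the larger
sample). Each informative marker implies a locus position
$\mathrm{pos}(m) - \mathrm{rf}(m)$ if the locus lies to the marker's left,
$\mathrm{pos}(m) + \mathrm{rf}(m)$ if to its right; the side whose implied
positions agree best (smallest sum of squared deviations from their mean)
is chosen, and the bounds are the min and max implied positions over the
informative set. The default informative set is the two smallest-RF
markers; an anchor with RF exactly 0 has an ambiguous side and is excluded
from the bounds (its position alone would pin the locus). With the refined
frequencies of the three informative markers this yields the interval
below.

```{r place}
refined <- read.delim(system.file("extdata", "table4_refined_rf.tsv",
                                  package = "flymap"), comment.char = "#")
placeLocus(refined, rucucaMap())
```

A caution that the package makes explicit: these bounds are a *range of
point estimates*, not a confidence interval. Two roughly unbiased implied
positions straddle the true locus only about half the time, so the flank
interval's coverage does not improve with sample size. It is the right tool
for reproducing the classical arithmetic, not for uncertainty statements.

**Least squares** estimates the locus as the grid point (0.01 cM
resolution) minimizing $\sum_m (\mathrm{rf}(m) - |\mathrm{pos}(m) - x|)^2$,
with a bootstrap percentile interval over markers. This interval is the
package's uncertainty-aware placement and is what the parameter-recovery
tests exercise: on synthetic experiments at the 113-male scale it covers
the hidden locus in well over 90% of seeded replicates, and coverage does
not degrade as more males are scored. Markers near 50% RF are effectively
unlinked and carry no distance information; exclude them via the
`informative` argument when fitting (the package's own tests do so when
quantifying estimator bias).

RF percent is used as cM directly (identity map function), matching the
classical arithmetic; Haldane or Kosambi corrections can be applied to the
`rf` column before placement if desired.

# The band lattice

Polytene band nomenclature (arm, division, letter A–F, sub-band) is
discretized into a finite lattice: every (division, letter, sub-band
1..`maxSubband`) triple is one cell. `maxSubband` defaults to 20, a
deliberately generous fixture constant — published band lists never
enumerate sub-band counts per letter, and the solver's set algebra only
requires that no real sub-band index exceed it. Band endpoints written
without a sub-band (e.g. `72A`) span their whole letter. Deficiency
breakpoint uncertainty is out of scope: deleted intervals are taken at face
value, and the solver's guarantees are relative to the stated breakpoints.

The solver intersects failing deletions and subtracts complementing ones
with interval algebra (IRanges); a brute-force per-band voting oracle in
the test suite verifies the equivalence on random lattices. Two error modes
are distinguished and named: disjoint failing deficiencies (an impossible
panel — some outcome is wrong) and a complementing deficiency covering the
whole core (likewise). With noise in outcomes these errors fire exactly
when no single band satisfies every outcome.

Allelism verdicts admit an adjacency `radius` (default: one division)
because a deficiency grid can bracket a region that merely abuts the causal
gene's band — a solved region ending at 71F5 should still nominate a gene
annotated at 72A1 for allele-level testing, which is the step that actually
decides.

# The synthetic-experiment generator

Every input the pipeline consumes can be generated with the statistical
structure the analysis assumes, so all stages are testable without wet-lab
data:

* **Gametes** (`simulateGametes()`): repulsion-phase female meiosis. The
  default crossover model is `"haldane"` — recombination independent across
  marker intervals with probability given by the Haldane map function
  (equivalent to Poisson crossovers without interference). A
  `"fixed_count"` model and a `"gamma_interference"` renewal model are
  available; nothing in the analysis depends on interference, so the
  no-interference default is the neutral choice.
* **The mapping experiment** (`simulateMappingExperiment()`): 113 scored
  males by default (the scale of the real cross), 50 testcross progeny per
  male, no male recombination, lethal-state determination through the same
  `inferLStatus()` rule the analysis uses, and a locus-state
  misclassification rate defaulting to 0 — a nonzero default would silently
  bias RF upward.
* **Deficiency panels** (`simulateDeficiencyPanel()`): uniform random
  breakpoints on a band lattice around the hidden band; outcome is
  containment of the truth, flipped with probability `noiseRate` (capped at
  0.2).
* **Tiling panels** (`simulateTilingPCR()`): deterministic geometry; the
  amplicon spanning the hidden insertion reports wild-type size plus
  insertion size, or fails when that exceeds the long-range ceiling
  (default 3 kb, a standard-extension Taq regime).
* **Stage survival** (`simulateStageSurvival()`): multinomial genotype
  classes thinned binomially per stage; survival 0 encodes balancer or
  homozygous lethality.

All generators are bit-reproducible given their seed; no generator touches
global RNG state. What the simulator does **not** emulate: viability
differences among marker phenotypes, crossover suppression near
centromeres, chromatid interference, partially scorable recessive markers
in the testcross (every marker is assumed fully observable in scored
males), and real deficiency breakpoint uncertainty. Passing tests therefore
demonstrate the statistical machinery, not robustness to those biological
complications.

# Numerical and design choices

* Genomic coordinates are 1-based and fully inclusive
  (`length = end − start + 1`): the printed 945 bp candidate region forces
  this convention.
* Marker positions ship as a standard chromosome-3 fixture
  (`rucucaMap()`: ru 0.0 … ca 100.7 cM) and are user-overridable via
  `readMarkerMap()`; placement results inherit whatever map is supplied.
* Clopper–Pearson at 95% is the default interval everywhere a proportion is
  estimated (RF, fertility), via the beta-quantile form; the test suite
  checks it against direct bisection of the binomial CDF.
* Goodness of fit uses the Pearson chi-square statistic for three or more
  classes and an exact binomial p-value for two (the Pearson value is still
  reported); type-I error is calibrated on null simulations in the test
  suite.
* A tiling amplicon counts as anomalous when it fails outright or its
  product deviates from wild-type size by more than 10% (both regimes occur
  with real insertions, depending on extension conditions).
* Size-shift display: percentages match published precision, but
  comparisons in tests use raw ratios with absolute tolerance 0.1, because
  published tables mix rounding and truncation (66.88 prints as 66.8, 21.27
  as 21.3).
* Pipeline configs are JSON only: one fewer dependency than YAML and
  lossless round-tripping of numeric parameters. Every report embeds the
  seed, an MD5 hash of the configuration and the package version; identical
  config and seed give byte-identical outputs.
* The pipeline stages mirror command-line subcommands (simulate, map_rf,
  place, complementation, tiling, viability) but are exposed as ordinary
  functions; `runPipeline()` is the orchestration entry point.

## Problem sizes used in the checks

The shipped tests run the gamete calibration at 10,000 gametes (3 binomial
SE against the Haldane map function), parameter recovery at 200 seeded
replicates of 113 and 452 males, the complementation voting oracle on
10-division lattices, the tiling containment check on 100 noise-free
panels, and goodness-of-fit calibration on 1,000 null simulations — sizes
chosen so each property is sharply resolved while the whole suite stays
interactive.

# Known limitations

* Pairwise mapping only: no multipoint likelihood or HMM reconstruction.
* The flank-subtraction interval is not a confidence interval (see above).
* Band-lattice arithmetic treats breakpoints as exact.
* Repeat-ladder amplification profiles (multiple products from one primer
  pair off a tandem expansion) are outside the lesion finder's model; only
  their interpretation can be recorded in reports.
* One-way ANOVA across replicate groups is deliberately not re-implemented;
  use `stats::aov` on arcsine-transformed proportions.
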