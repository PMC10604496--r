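---
title: "Reducing microsatellite panels with PIC-seeded ant colony optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing microsatellite panels with PIC-seeded ant colony optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picaco)
```

## The problem

Microsatellite surveys in conservation genetics and breeding routinely
genotype 20-30 loci per individual, yet budgets often force a choice: fewer
individuals or fewer markers. `picaco` addresses the second option in a
principled way. Given a codominant diploid genotype table, it searches for
the smallest marker panel whose **average genetic distance (AGD)** between
groups stays within a user-chosen *accuracy-loss margin* of the full panel's
AGD, so that downstream population-genetic conclusions are preserved while
genotyping cost drops.

Panel selection is a combinatorial problem: with $k$ loci there are $2^k$
candidate panels, each represented by a binary inclusion vector
$I = [i_1, \dots, i_k]$, $i_j \in \{0, 1\}$. The package explores this
space with an ant colony optimizer whose pheromone trails can be *seeded*
from each locus's polymorphic information content (PIC), and compares that
scheme against PIC ranking alone and a random control.

## The cost function

Between two groups $a$ and $b$ with allele frequencies $p_{ajk}$ (allele
$j$, locus $k$), the genetic distance restricted to a panel is Nei's
standard distance,

$$
D_{a,b} \;=\; -\ln
\frac{\sum_k \sum_j p_{ajk}\, p_{bjk}}
{\sqrt{\sum_k \sum_j p_{ajk}^2 \;\cdot\; \sum_k \sum_j p_{bjk}^2}},
$$

with the locus sums accumulated *inside* the numerator and both denominator
sums -- it is not a per-locus average of ratios. The AGD is the mean of the
finite pairwise distances over all group pairs, and a panel's cost is its
relative AGD deviation,

$$
f(I) \;=\; 100 \cdot \frac{\lvert AGD(I) - AGD(\text{full}) \rvert}{AGD(\text{full})} \;\; [\%],
$$

so $100 - f$ is the panel's estimation accuracy. Two grouping units are
first-class: subpopulations whenever the data carry two or more population
labels, and individuals (per-individual "frequencies" of 0, 1/2, 1)
otherwise -- single-population datasets still have a well-defined AGD this
way. Pairs that share no alleles anywhere on the panel have infinite
distance; they are excluded from the AGD mean and counted, never capped,
because capping would silently distort the cost ordering.

Because the distance depends on the panel only through per-locus
cross-products $C_{ab\ell} = \sum_j p_{aj\ell} p_{bj\ell}$, the package
precomputes the $G^2 \times k$ cross-product table once and scores a whole
epoch of candidate panels with a single matrix product. This is what makes
exhaustive enumeration (the test oracle) and 6000-panel ACO runs cheap.

## Diversity statistics

Per locus the package reports the observed allele count ($N_a$), effective
allele count ($N_{ea} = 1/\sum_i p_i^2$), allele richness
($AR = N_a / n$ with $n$ the number of genotyped individuals -- a
sample-size-normalised count, not rarefaction), observed heterozygosity
($H_o$, the fraction of heterozygous genotypes), expected heterozygosity
($H_e = 1 - \sum_i p_i^2$, with an optional $2n/(2n-1)$ small-sample
correction behind a flag), and the Botstein PIC

$$
PIC = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2\, p_i^2 p_j^2 .
$$

All statistics use pooled frequencies from observed genotypes only. A
genotype is treated as missing when *either* allele is coded 0: partially
scored genotypes are ambiguous for heterozygosity, so the whole-genotype
rule keeps every statistic's numerator and denominator consistent.
Monomorphic loci are legal ($PIC = H_e = 0$); loci with no observations at
all are flagged with a warning and carried as `NA` rows rather than
dropped, so locus indices never shift silently.

## The ant colony optimizer

The search graph has $2k$ nodes -- an include and an exclude node per locus
-- each holding a strictly positive pheromone value $\tau$. One *epoch*
consists of `ants` construction-and-scoring passes followed by one
pheromone update. The tunable parameters, with defaults:

| parameter    | meaning                                     | default |
|--------------|---------------------------------------------|--------|
| `ants`       | candidate panels constructed per epoch      | 50     |
| `epochs`     | iterations                                  | 120    |
| `alpha`      | pheromone weight exponent (dimensionless)   | 0.7    |
| `decay`      | pheromone retention per epoch, in (0, 1)    | 0.9    |
| `elite_frac` | fraction of top-ranked ants that deposit    | 0.5    |

`decay` is interpreted as *retention* ($\tau \leftarrow 0.9\,\tau$ before
deposits): a small value forgets quickly and explores more. The
documentation of this parameter family is ambiguous in parts of the
optimization literature, so the semantics are stated here prominently.

**Construction.** In fixed-size mode, `n` loci are drawn sequentially
without replacement with probability proportional to
$\tau_{in}^\alpha$ among the remaining loci. In free mode each locus is
included independently with probability
$\tau_{in}^\alpha / (\tau_{in}^\alpha + \tau_{out}^\alpha)$; panels smaller
than two loci are resampled a bounded number of times, then topped up
deterministically by pheromone rank. Fixed-size mode is what scheme
comparison uses; margin mode drives it internally.

**Update.** Ants are sorted by loss; each of the top
$\lceil \texttt{elite\_frac} \cdot \texttt{ants} \rceil$ deposits
$\Delta = (100 - f)/100$ on the edges it traversed, after evaporation.
Trails are floored at $\varepsilon = 0.01$ so every path remains reachable
forever. There is no separate heuristic-desirability exponent: locus
informativeness enters only through initialisation (below), keeping the
two schemes cleanly comparable.

The `elite_frac` default deserves a note, as it was changed during
development on benchmark evidence. With accuracy-proportional deposits and
realistic losses far below 100%, every elite deposit is close to 1, so a
small elite (say the top 10 of 50) amplifies early sampling noise rather
than quality differences; on near-tie landscapes the colony then fixates
on a locally optimal panel it can no longer leave. Benchmarks against the
exhaustive oracle (60 simulated instances at each of $N=4, k=10$ and
$N=5, k=12$) showed 9-16 misses at `elite_frac = 0.2` versus 0-3 at 0.5,
with rank-weighted and winner-only deposit variants performing worse than
either. Letting the better half of the colony deposit preserves rank-based
selection pressure while keeping reinforcement broad enough to avoid
premature convergence.

**Tie-breaking.** Equal losses are resolved toward the smaller panel, then
the lexicographically earliest inclusion vector, making every run
reproducible given its seed.

**PIC seeding.** `init = "random"` draws every trail from
$\mathrm{Uniform}(\varepsilon, 1)$. `init = "pic"` (the PIC+ACO scheme)
sets $\tau_{in,j} = \varepsilon + PIC_j$ and
$\tau_{out,j} = \varepsilon + (1 - PIC_j)$, so the first epochs
concentrate on polymorphic markers. The top-PIC locus is favoured, not
force-included: redundant high-PIC markers can and do get dropped by the
search, which is the entire point of combining PIC with a distance-based
cost.

## Selection modes and schemes

Four schemes sit behind one interface (`select_panel()`): `pic_aco`,
`aco`, `pic` (rank prefix) and `random` (control). Two modes:

* **fixed-n**: best panel of exactly `n` loci.
* **margin**: panel sizes are reduced progressively from $k-1$ downward;
  the scan stops at the first size whose best-found loss exceeds the
  margin and returns the last qualifying panel (the full set if even
  $k-1$ fails). Stopping at the first failure, rather than scanning all
  the way to 2, reflects how a practitioner reduces a panel and avoids
  returning a spuriously qualifying tiny panel that sits below an
  infeasible band. The deterministic PIC-rank scheme scans upward from 2
  instead (cheapest first); both return the minimal qualifying size, so
  results are comparable.

A degenerate `margin <= 0` returns the full set with a warning. The
exhaustive oracle (`exhaustive_panel()`) enumerates all
$\binom{k}{n}$ or all sizes and refuses beyond 20 loci.

## Evaluation

`compare_schemes()` runs each scheme over a grid of panel sizes
(stochastic schemes with independently derived, individually reproducible
seeds; deterministic schemes once) and performs all pairwise contrasts per
size with Tukey's HSD on the accuracy values. Exact-tie groups are
reported with $p = 1$ rather than dropped. `panel_discrepancy()` compares
per-locus statistics between a reduced panel and the full set with a
two-sample t-test (pooled-variance Student form by default, Welch behind a
flag, since the convention differs between software ecosystems), plus
fold changes; significance tiers are `ns` ($p > 0.05$), `*`
($0.01 < p < 0.05$), `**` ($0.001 < p < 0.01$), `***` ($p < 0.001$).
Because $AR = N_a/n$ with a common $n$, the AR and $N_a$ fold changes of
any panel coincide -- a useful internal consistency check. A statistic
that is constant on both sets (e.g. $N_a$ when every allele is seen at
every locus) is reported as an exact tie ($p = 1$) instead of failing.

## The synthetic-data generator

`simulate_genotypes()` implements the Balding-Nichols construction: per
locus an ancestral frequency vector is drawn from a symmetric Dirichlet;
each population then draws its own vector from a Dirichlet centred on the
ancestral one with concentration $(1 - F_{st})/F_{st}$; genotypes follow
Hardy-Weinberg within population, and whole genotypes are masked at the
missing rate. Defaults (4 populations of 30, 10 loci with 5-20 alleles,
$F_{st} = 0.15$, 2% missing) emulate a modest structured microsatellite
survey: multi-allelic loci, moderate divergence, occasional dropouts.

What it deliberately does not emulate: mutation models (stepwise or
otherwise), linkage between loci, null alleles, allele-specific dropout or
scoring error, and inbreeding within populations. Tests passing on this
generator therefore demonstrate correctness of the estimators and the
search on clean HWE data with exchangeable loci -- not robustness to the
artefacts of real capillary data.

`make_planted_instance()` serves a different purpose: a dataset whose
optimal panel is known by construction, for oracle tests. Two populations
carry four highly polymorphic "signal" loci (12 alleles, mirrored
block profiles with unequal skews per population) and six low-polymorphism
biallelic background loci whose contributions to the Nei similarity sums
are balanced against the signal set. The skew constants were fixed by a
direct search over the design space against exact enumeration of all
$2^{10}$ panel losses, subject to: the signal quartet reproduces the
full-panel AGD within 1%, the best competing quartet misses by several
points, every 2- and 3-locus panel misses by a wide margin, and every size
from 5 to 9 retains a qualifying panel so margin-mode reduction can walk
down to the planted size. Allele counts are allocated to the design
frequencies exactly (largest-remainder rounding) and then paired randomly
into diploids: genotype-level statistics stay stochastic, while the loss
landscape the search sees is fixed by construction rather than perturbed
by multinomial sampling noise. One property worth stating honestly: under
this cost function a locus's leave-one-out influence scales with the
magnitude of its $\sum_i p_i^2$ terms, so the low-PIC background loci
individually move the AGD *more* than the weakest signal locus -- the
signal panel is optimal because its members jointly reproduce the full-set
similarity ratio, not because each is individually the most
differentiated marker. Claims of the form "the planted loci are the most
influential" are therefore not asserted anywhere; the planted-instance
guarantees are exactly the enumerated ones above.

## Numerical choices and degenerate inputs

* Frequencies are validated to sum to 1 within $10^{-12}$ per group and
  locus; ratios marginally above 1 from rounding floor the distance at 0.
* Loss ties in the optimizer are compared at $10^{-12}$ absolute.
* Missing genotypes never enter numerators or denominators; per-locus
  denominators vary accordingly.
* Allele codes are opaque integers; every statistic and distance is
  invariant under relabeling, which the tests check explicitly.
* Single-population data fall back to by-individual grouping for
  distances; requesting population grouping there is an error with that
  suggestion.

## Problem sizes used by the tests

The test-bed sizes are chosen so the oracle stays exact: scheme-versus-
oracle checks run 20 instances at the simulator defaults ($k = 10$,
$N = 4$, $\binom{10}{4} = 210$ panels enumerated); the planted-instance
checks enumerate all $2^{10}$ panels; the seeding-benefit comparison uses
30 paired seeded runs at the full default configuration (50 ants, 120
epochs). These sizes make every claim verifiable by enumeration while each
suite run completes in well under a minute.

## Known limitations

* AGD preservation is the only cost; panels optimal for AGD are not
  guaranteed optimal for individual identification or parentage exclusion.
* $AR$ is allele count per genotyped individual, not rarefied richness;
  comparisons across datasets of very different sizes should use the
  per-dataset $n$ consciously.
* The margin-mode result is the best panel found by a stochastic search at
  each size; for $k \le 20$ the exhaustive oracle is available and should
  be preferred when certainty matters more than time.
* Infinite pairwise distances (disjoint allele sets) are excluded from the
  AGD mean; datasets where many pairs are disjoint make the AGD reference
  fragile, and the count of excluded pairs should be inspected.
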