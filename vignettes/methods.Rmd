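---
title: "Models and methods behind graftmicrobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind graftmicrobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftmicrobe)
```

`graftmicrobe` analyzes sample × OTU read-count tables from replicated
grafting field experiments: 9 rootstock treatments (8 grafted varieties plus
an ungrafted control, all carrying the same scion genotype) × 15 replicate
field positions ("locations", grouped into 3 planting lines) = 135 plants,
profiled for bacteria (16S) and fungi (ITS1) separately. This vignette
documents the statistical models, the numerical conventions, and the design
decisions that were genuinely open.

## Preprocessing cascade

The cascade runs in a fixed order: **cell filter → rarefaction →
(collapsing) → occurrence filter**.

**Cell filter.** Amplicon tables carry a background of PCR chimeras, index
hopping and tag switching that manifests as isolated low-count cells. Cells
with fewer reads than a fraction (default 0.1%) of their sample's total are
zeroed. Two conventions were open: whether the comparison is strict and
whether totals are recomputed as cells are zeroed. We use a **strict,
single-pass** rule — every cell is compared against its sample's *original*
total — because a recomputed-total rule is order-dependent and can cascade:
zeroing one cell raises no threshold under the single-pass rule, so the
operation is a pure per-cell map and exactly reproducible.

**Rarefaction.** Each sample is subsampled **without replacement** to a
common depth (default 500 reads; samples below it are discarded).
Without-replacement subsampling makes each rarefied column a multivariate
hypergeometric draw, which the tests exploit: the expected rarefied count of
a taxon with $k$ of $T$ reads is $d\,k/T$ and its variance
$d\,\frac{k}{T}\frac{T-k}{T}\frac{T-d}{T-1}$. One further choice is ours:
every sample draws from **its own RNG stream**, seeded by a hash of (master
seed, sample id). With a single shared stream, dropping one sample would
silently change every downstream sample's subsample; with per-sample
streams, rarefaction commutes with subsetting, which both the tests and
incremental re-analyses rely on.

**Collapsing.** OTUs are summed into bins keyed by the *full lineage
prefix* down to the target rank, not by the rank's name alone, so two
genera with the same name under different families stay distinct. OTUs
unassigned at the target rank go to an `"unidentified <deepest assigned>"`
bin per parent lineage; a flag drops these bins for analyses that should
only see named taxa. Per-sample totals are conserved. Collapsing is only
defined from the OTU rank (the taxonomy is keyed by OTU), which also rules
out ill-posed compositions such as re-collapsing an order table to genus.

**Occurrence filter.** Group-level tests on taxa seen in a handful of
plants are underpowered and dominated by ties; taxa present in fewer than
30 of the samples (the default, on a 135-plant design) are excluded, at the
rank being analyzed.

## Raup–Crick β-diversity

Community composition is compared on presence/absence. For samples $x, y$
with richness $a, b$ and $s$ shared taxa, the dissimilarity is the
probability that a null assembly shares more than $s$:

$$d(x,y) = \frac{\#\{S_{null} > s\} + \tfrac12\,\#\{S_{null} = s\}}{n_{sim}},$$

with the half-weight on ties placing chance expectation at exactly 0.5.
The default null model fixes each sample's richness and fills it by drawing
taxa **without replacement with probability proportional to their occurrence
frequency** across samples, which holds both α-diversity and the species
abundance distribution fixed — the remaining signal is co-occurrence
structure. An `"analytic"` variant replaces simulation with the closed
hypergeometric form under an equiprobable pool
($S \sim \mathrm{Hyper}(a, P-a, b)$); on pools with equal occurrence
frequencies the two variants coincide, which is how the simulation is
validated. The pool is the set of taxa observed in at least one sample.
Richness-zero samples are rejected by name: the null model cannot assemble
them, and their dissimilarity to anything is undefined.

## PERMANOVA

Variation in the Raup–Crick matrix is partitioned over `variety` then
`location` by sequential (type-I) sums of squares of the Gower-centered
distance matrix, with pseudo-$F$ and $R^2 = SS_{term}/SS_{total}$, computed
via `vegan::adonis2(by = "terms")`. Significance is by **free permutation**
of sample labels (default 10,000): location enters as a modeled term, not a
permutation stratum, matching a design where field position is a nuisance
factor of explicit interest. On Euclidean distances of univariate data the
pseudo-$F$ reduces to the classical sequential ANOVA $F$, which the test
suite asserts to machine precision; the permutation p-value follows the
$(1 + r)/(1 + B)$ convention throughout the package (valid under the null,
never exactly zero, ties counted as exceedances).

## Per-taxon ANOVA

For each genus passing the occurrence filter, a fixed-effects two-way ANOVA
of its per-sample relative abundance on `variety + location` (no
interaction, parametric $F$). Sums of squares are sequential with variety
entered first; the 9 × 15 design is balanced before sample dropout and
near-balanced after, so entry order has little leverage, but the convention
is pinned rather than left to chance. Taxa with a constant response are
reported as `degenerate` rows with `NA` statistics instead of erroring, so
one flat taxon cannot abort a table of hundreds.

## The host-genotype preference index

For taxon $i$ and variety $j$,

$$\mathrm{Preference}(i,j) =
  \frac{N_{obs}(i,j) - \mathrm{Mean}\,N_{rand}(i,j)}
       {\mathrm{SD}\,N_{rand}(i,j)},$$

where $N_{obs}(i,j)$ is the mean (rarefied) read count of taxon $i$ over the
samples of variety $j$ and the null ensemble shuffles the variety labels of
all samples jointly — one permutation per iteration, **shared across taxa**.
Joint shuffling preserves each taxon's marginal null exactly (the tests
check this against exhaustive enumeration) while also preserving cross-taxon
dependence within a permutation, so the ensemble is usable for joint
summaries. Conventions, each pinned deliberately:

* **Decision by empirical p, not z.** The null of a group mean of sparse
  counts is skewed; the z-score is reported as a descriptive effect size and
  the upper-tail empirical p decides significance:
  $p = (1 + \#\{\bar N_{perm} \ge \bar N_{obs}\})/(1 + B)$, ties counted as
  exceedances. Default $B$ = 100,000 for reported analyses, 999 inside the
  simulation batteries.
* **One-sided, upper tail.** The statistic asks for *preference*;
  avoidance (lower tail) is available via a flag but is not the default
  question.
* **Bonferroni over varieties, per taxon** ($\alpha/9$): each taxon's
  family is its 9 variety conditions. Cross-taxon multiplicity is visible in
  the report but deliberately not corrected — the screen is per-taxon, and
  a user scanning many taxa is expected to treat the report as a ranked
  shortlist (the calibration battery quantifies the per-taxon family-wise
  rate, not a cross-taxon one).
* **Degenerate nulls** (SD exactly 0, e.g. a constant taxon) yield
  $z = 0$, $p = 1$ by convention.
* **Population SD** (divide by $B$) of the realized permutation ensemble;
  at $B \ge 999$ the distinction from $B-1$ is far below reporting
  precision, but the choice is fixed.

## Synthetic data generator

The generator emulates the statistical structure the analyses assume, not
sequencing chemistry. Per sample with variety $v$ and location $l$:

1. baseline relative abundances: $\mathrm{lognormal}(0, \sigma=1.5)$ over
   150 taxa, normalized — a few dominant taxa, a long rare tail;
2. expected composition $\propto$ baseline × planted variety fold-changes ×
   location fold-changes (multiplicative effects, renormalized — so an
   8-fold planted effect on an abundant taxon realizes as less than 8-fold
   in proportion space, and the tests use the renormalized analytic value
   as their oracle);
3. realized composition $\sim$ Dirichlet(200 × expected): concentration
   200 gives sample-to-sample compositional scatter of the magnitude seen
   in leaf amplicon data ("moderate overdispersion");
4. counts $\sim$ Multinomial(depth, realized), with depth
   $\sim$ lognormal(log 5000, 0.5) truncated at 500, except that with
   probability 0.07 a sample is forced below 500 (uniform on [1, 499]).
   On 135 samples this drops 9–10 samples in expectation, emulating the
   125–132/135 retention typical of such field datasets.

The taxonomy assigns taxa round-robin to ~50 genera in 10 orders (so
genus-level collapsing genuinely merges), with 10% of taxa unidentified at
genus to exercise the `"unidentified"` path; it is deterministic in the
config so planted effects can reference stable taxon ids across seeds.

What the generator does **not** emulate: phylogenetic correlation among
taxa, spatially autocorrelated location effects, taxon-specific PCR bias,
and chimeric/contaminant reads. Passing calibration and power checks on
this model therefore demonstrates correctness of the statistics under
overdispersed compositional sampling — not robustness to every artefact of
real amplicon data.

## Validation batteries and problem sizes

The acceptance checks compute, at sizes chosen to make Monte-Carlo error
small relative to the bands being checked:

* calibration: 200 null datasets (each 135 samples × 150 taxa, 999
  permutations); per-taxon family-wise significance rate vs the binomial
  99% band around 0.05;
* power: 100 datasets with an 8-fold single-genus enrichment; recovery
  rate required above 80%;
* enumeration: Monte-Carlo p vs exhaustive label enumeration on ≤ 8-sample
  fixtures within 3 binomial SEs;
* PERMANOVA: 50 random designs against classical sequential ANOVA at
  machine precision; 200-simulation type-I rate at $\alpha = 0.05$;
* Raup–Crick: all-ties fixture exactly 0.5; null-model vs analytic form
  within 3 Monte-Carlo SEs at 10,000 simulations.

## Known limitations

* The preference test assumes rarefied (equal-depth) counts; feeding it
  unrarefied data confounds preference with sequencing depth.
* Sequential SS makes PERMANOVA and ANOVA results depend on term order on
  unbalanced data; the order (`variety`, `location`) is part of the method
  definition here.
* The Raup–Crick null conditions on observed richness and occurrence
  frequencies; it cannot detect structure expressed purely through those
  margins.
* Empirical p-values are bounded below by $1/(1+B)$; with $B = 999$ the
  smallest achievable p (0.001) is only just below the Bonferroni threshold
  $0.05/9 \approx 0.0056$, which is why reported analyses should use
  $B = 100{,}000$.
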