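---
title: "Statistical methods for moss-associated 16S OTU tables"
author: "mossmicrobiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for moss-associated 16S OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mossmicrobiota)
```

# Scope

`mossmicrobiota` implements the downstream statistics of a comparative
peatland moss microbiome survey: two peatland systems (minerotrophic
Amblystegiaceae "brown-moss" fens, `amb`, and acidic *Sphagnum* bogs, `sph`),
several areas and subsites per system, and per moss plant a paired sequencing
design of two endophyte technical-replicate libraries (surface-sterilized
tissue) plus one epiphyte library (wash-off), alongside sediment and vascular
plant references. The package starts from an annotated OTU count table;
read processing, OTU picking and taxonomy assignment are out of scope.

# Filtering rules

`filterTaxa()` removes OTUs whose lineage matches an exclusion pattern
(default: chloroplast, which bacterial 16S primers co-amplify from the plant
host) and OTUs whose top-rank domain contradicts the library's domain.
Matching is a case-insensitive substring test on the rank-prefixed lineage,
because chloroplasts appear at class rank in Greengenes-style lineages.

`filterRare()` implements the sample-wise rare filter: a count is zeroed when
its relative abundance within its own library is *strictly* below the
threshold (default 0.01%), evaluated against the library size before any
zeroing; entries exactly at the threshold are kept. A small relative guard
(`1 - 1e-9`) protects the strict inequality from the binary representation of
`min_fraction * library_size`, so a count of 1 in a library of 10,000 is kept.
Whether such a filter should zero entries or drop whole OTUs is genuinely
ambiguous; both are exposed (`action = "zero"` is the default, `"drop"`
removes OTUs whose relative abundance is below the threshold in every
library), and the applied rule is recorded in the result's metadata.

# Diversity and group contrasts

Inverse Simpson diversity (`1 / sum(p_i^2)`, the effective number of equally
abundant OTUs) and OTU richness are computed per library. Group contrasts use
the standard pairwise machinery: `pairwiseWilcoxon()` wraps
`stats::pairwise.wilcox.test` (exact when both groups are below 50
observations without ties, normal approximation with tie correction
otherwise) and `pairwiseTTest()` wraps `stats::pairwise.t.test` with the SD
pooled across all groups by default (`pool.sd = TRUE`), Welch per-pair tests
optionally. The p-adjustment is Holm by default — the default of the wrapped
functions — with `"none"` available, and the choice is carried in the result
object because published analyses frequently leave it unstated.

`compactLetterDisplay()` converts a symmetric p-value matrix into letters by
insert-and-absorb: one letter initially covers all groups; each significant
pair splits every letter containing both members, and letters that become
subsets of others are absorbed. The output satisfies both display
invariants — groups sharing no letter differ at `p < alpha`, groups at
`p >= alpha` share a letter — but letter assignments are not unique, so the
tests validate displays against these constraints rather than against
canonical strings.

# Community dendrograms

Community profiles are compared by Spearman rank correlation of per-sample
relative abundances (`correlationMatrix()`), converted to a dissimilarity as
`d = 1 - r` — the minimal monotone transform, recorded in the output since
the convention (1 − r versus (1 − r)/2) is a genuine free choice. Clustering
delegates to `cluster::agnes` (average linkage/UPGMA by default), the
standard tool for agglomerative nesting; `agnesCluster()` returns the merge
structure plus the agglomerative coefficient, AC = mean over leaves of
1 − (first-merge height / final-merge height). AC is 0 for equidistant
data and approaches 1 when cluster structure is strong. With continuous
dissimilarities, exact merge ties have probability zero, so no extra
tie-breaking layer is imposed on `agnes`. `exportNewick()` writes the
ultrametric tree with each node at half its merge height, so two leaves
merged at height *h* become `(A:h/2,B:h/2);`.

# Ordination

Correspondence analysis and its constrained variants are implemented from
the chi-square standardized residual matrix
`Q = D_r^(-1/2) (P − r c') D_c^(-1/2)` with `P` the table over its grand
total and `r`, `c` the sample and OTU mass vectors. Total inertia is
`||Q||_F^2`, identical to the Pearson chi-square of the table divided by its
grand total. CCA projects the rows of `Q` onto the span of the row-mass
weighted, centered constraint columns (QR decomposition); the fitted part is
decomposed by SVD into constrained axes, the remainder into unconstrained
axes. Partial CCA first removes the span of the conditioning variables from
both `Q` and the constraints, reporting the removed part as conditioned
inertia. Because the three parts are orthogonal projections, the
decomposition `conditioned + constrained + residual = total` is exact; the
tests assert it to 1e-8 relative on every fit, and the constrained
eigenvalues are cross-checked against both an independent
generalized-eigenproblem formulation and `vegan::cca`.

Numerical choices: eigenvalues below `max(eig) * 1e-12` are trimmed as
numerical zeros; site scores use principal scaling, species scores standard
scaling; categorical constraints are treatment-coded with the first level as
reference, continuous constraints centered. Exactly collinear constraint
columns raise an error by default, naming the aliased columns; fits inside
`variancePartition()` instead drop them (`allow_aliased = TRUE`), because
nested survey designs produce structural aliasing — a reference-fraction
indicator is exactly implied by the plant-label indicators — and the aliased
columns contribute nothing to the projected space, so dropping is exact.

`prepareConstraints()` drops variables missing in more than 20% of samples
(the pattern that motivates removing sparse field measurements from a full
model) and then removes samples with residual missing values; the string
`"unknown"` counts as missing.

Significance uses a permutation pseudo-F,
`F = (constrained/q) / (residual/(n − q − p_cond − 1))`, with free
permutation of the rows of `Q` when there are no conditions and permutation
of the residuals of the conditioned model (reduced-model scheme) otherwise —
the standard choice for preserving exchangeability under partialling —
and `p = (1 + #(F* ≥ F)) / (n_perm + 1)`. Fewer than 19 permutations are
refused because the p-value resolution becomes meaningless.

`variancePartition()` reports marginal-partial shares: each variable's share
is the constrained inertia of the partial CCA with that variable as the sole
constraint and all other variables as conditions, in percent of total
inertia. Marginal shares of correlated variables deliberately do not sum to
the joint constrained share; a sequential (order-dependent, Type-I-style)
scheme is available behind `scheme = "sequential"` and does sum to the joint
share. Variance inflation factors (`vif()`) come from weighted regressions of
each constraint column on the others and match `vegan::vif.cca` when given
the CCA row masses.

# Core microbiome

`minPrevalenceCount(n, t) = floor(t * n)` converts a proportional prevalence
threshold into an integer sample count; floor is forced by the worked
example that a 66% threshold over 122 samples means presence in 80 samples
(ceiling would give 81). A tiny additive guard (1e-9) keeps thresholds such
as 0.66 stored in binary floating point from flooring one integer too low.
`coreSet()` takes OTUs present (count > 0, evaluated after whatever
filtering the caller applied) in at least that many scoped samples;
"present in both systems" is read as presence in at least one sample of
every group, layered on the global rule — the stricter reading (threshold
met within each system separately) is available as the per-system preset.
`coreProfiles()` wires the standard constructions: total core at 0.66 with
the both-systems constraint, per-system cores at 0.66, per-species cores at
the more restrictive 0.75 over that species' moss samples. Abundance
contributions are the per-group min–max over samples of the summed relative
abundance of core OTUs.

# Endophyte screen

For each OTU and moss plant, `buildContingency()` forms the 2×2 table
(pooled endophyte replicates vs epiphyte library) × (this OTU vs all
others), and `monteCarloChisq()` tests it with Pearson's X² (no continuity
correction) against null tables drawn with both margins fixed — Patefield
sampling, which for 2×2 tables is exactly a hypergeometric draw of one cell,
used as a fast path; general tables use `stats::r2dtable`. The p-value is
`(1 + #(X²* ≥ X²)) / (n_rep + 1)` (ties count via a 1e-9 floating guard) and
never falls below `1/(n_rep + 1)`; tables with a zero margin are flagged
untestable with p = 1 by convention.

`classifyEndophytes()` qualifies an OTU as a putative endophyte when it is
endophyte-higher (the chi-square is direction-blind, so direction is imposed
from the relative abundances) with `p < 0.001` in at least one plant unit
*and* its endophyte-mean relative abundance exceeds 0.5% in at least four
plant units. The unit of pairing is the plant (technical replicates summed);
a pooled-per-OTU mode is deliberately not the default because the paired
design compares libraries of the same plant. The number of units that must
individually reach significance is configurable (default 1). No multiple
testing correction is layered on the stringent alpha. Only OTUs passing the
abundance gate are tested by default, since no other OTU can qualify;
`test_all = TRUE` removes the shortcut. Under these settings and the default
synthetic design (36 plant units, ~50 abundant null OTUs), the expected
family-wise false-positive budget is about one OTU — consistent with the
stringent alpha but not below it; the recovery tests measure it directly.

The heatmap export maps qualifying OTUs × plant units to
`log2(endophyte-mean relative abundance × 100,000)`, flooring zeros at half
the smallest nonzero abundance before the log, and clusters both axes with
Pearson correlation, 1 − r, average linkage.

# The synthetic-study generator

`generateStudy()` draws an OTU table, metadata and planted truth from a
log-linear composition model with Dirichlet-multinomial noise. The default
design (2 systems × 2 areas × 3 subsites × 3 plants, each plant giving
2 endophyte + 1 epiphyte libraries, plus 2 references per subsite) yields
132 libraries over 2,000 OTUs. Planted structure:

* 50 shared core OTUs at mean weight 0.02 per OTU in `sph` and 0.002 in
  `amb` — an order-of-magnitude system asymmetry that makes the core
  dominant in the bog system (tens of percent of reads) and minor in the
  fen system, as observed in real fen-versus-bog surveys;
* 300 system-specific OTUs per system, structurally absent (exact zeros)
  outside their system;
* 25 endophyte-enriched OTUs whose abundance is multiplied by
  `endophyte_fold` (default 8) in endophyte libraries only, drawn disjoint
  from the core and system-specific sets so recovery metrics are
  unambiguous;
* moss-species, hydrology and covariate effects as fixed random log-scale
  loadings per OTU. Planted core OTUs are exempt from these loadings: a
  core is by definition host-generalist, and without the exemption no
  prevalence-based core construction could succeed even in principle at the
  fen-system abundances.

Covariates are generated correlated with the system — pH 3.3–5.0 in the bog
areas versus 5.8–7.0 in the fen areas, CH4 higher in bogs, temperature
area-level — so the field-realistic collinearity between moss taxon and
environment (and hence the need for partial ordination) is reproduced.

Noise model: one latent composition per plant (Dirichlet, concentration
`dispersion`, default 1000) shared by that plant's three libraries, a small
technical-replicate jitter per library (Dirichlet, concentration
`replicate_concentration`, default 1e6, roughly 1% relative noise), and
multinomial counts at a library size uniform in 5,000–50,000. The
plant-level concentration was fixed at 1000 because the fen-system core sits
near 0.06% relative abundance: at much lower concentrations even true core
OTUs drop out of most fen samples, which contradicts the near-ubiquity that
defines a core in real data; 1000 retains visible overdispersion while
keeping presence-absence behaviour realistic. Sharing the latent within a
plant is what makes the paired endophyte screen approximately calibrated:
the endophyte-versus-epiphyte contrast within a plant reflects only the
enrichment effect plus technical noise.

What the generator does not emulate: sequence-level error, chimeras or OTU
inflation; phylogenetic correlation between OTUs; unequal numbers of
libraries per plant; missing covariates (field data often lack them — the
constraint-preparation machinery handles missingness but the default
synthetic data are complete); and effects of varying total microbial load,
which relative abundances cannot see. Passing recovery tests therefore demonstrate
that the algorithms do what they claim under a realistic sampling design,
not that real moss data meet these assumptions.

# Calibration and problem sizes

The test suite checks, among others: CA/CCA eigenvalues against an
independent generalized-eigenproblem oracle and `vegan` (1e-8); AGNES
against an O(n³) UPGMA re-implementation on 8-leaf instances; the
Monte-Carlo chi-square against exact hypergeometric enumeration on all 2×2
tables with grand total ≤ 12 (within binomial sampling bands at 5,000
replicates); permutation-test type-I error on 200 structureless synthetic
studies (99 permutations each, 28 samples × 120 OTUs); and planted-truth
recovery over 20 seeds of the full default study. These sizes were chosen to
give stable Monte-Carlo estimates on a single CPU; all are stated in the
tests themselves.

Two calibration subtleties are worth recording. First, a covariate that is
constant within subsites is *confounded* with any subsite-level structure,
including the system baseline; a naive "null" that keeps the two systems'
core baselines different is not null for such a covariate, and the
permutation test rightly rejects. The calibration study therefore equalizes
baselines and removes overdispersion so rows are exchangeable. Second,
shared plant latents make libraries of one plant correlated; design
variables aligned with that clustering (pseudoreplication) will show
inflated significance in unconditioned tests — the same reason the original
analysis conditions on area and subsite in the partial CCA.

# Known limitations

* Letter displays use greedy insert-and-absorb; the number of letters is
  not guaranteed minimal.
* Marginal variance-partition shares of strongly collinear variables can be
  small even when the variables are jointly important; this is inherent to
  partialling, not a defect, but it surprises users.
* The endophyte screen's per-unit chi-square assumes multinomial counts
  within a plant; genuine within-plant biological heterogeneity beyond the
  modelled technical jitter would inflate its false positive rate on real
  data.
* The fen-system planted core is recovered only partially by the
  per-species cores at the 75% threshold (while the bog-system species
  recover nearly all of it) — a direct consequence of the tenfold abundance
  asymmetry, and a realistic behaviour rather than a target of the tests.
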