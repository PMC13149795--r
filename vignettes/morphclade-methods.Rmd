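---
title: "Methods: parsimony analysis of discrete morphological matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parsimony analysis of discrete morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphclade)
```

# Scope and model

`morphclade` implements the complete analytical chain used in
morphological cladistics of fossil material — here, anatomically
preserved Palaeozoic seeds, but nothing in the package is specific to
seeds. The data model is a taxa × characters grid of *unordered*
multistate characters in which a cell is one of

* **determinate** — a single observed state;
* **polymorphic** — a set of observed states (treated as ambiguity:
  any one member suffices; the alternative reading, requiring extra
  steps for each additional state, is deliberately not implemented);
* **unknown** (`?`) — unpreserved; stands for the character's full
  observed state set;
* **inapplicable** (`-`) — logically unscorable (e.g. cupule characters
  of acupulate seeds). Kept distinct from unknown through I/O and
  summaries, because completeness statistics report them separately,
  but treated as full ambiguity in tree scoring: unordered parsimony
  offers no principled reductive coding for inapplicables, and treating
  them as unknown is the standard practice of the field's programs.

Tree inference is equal-weights maximum parsimony only. No likelihood
or Bayesian machinery is provided: for phenotypic characters the
package takes the position that no defensible prior model of
morphological change is available, so the minimum-change criterion is
used as-is.

## Parsimony scoring

Per-character tree length is the exact minimum number of state changes
over all ancestral assignments. The scoring kernel (in C) uses the
counting form of Hartigan's generalisation of the Fitch downpass, which
is exact on *multifurcating* trees with *set-valued* tips: under unit
costs, the Sankoff cost vector of any subtree, viewed through its root
edge, takes only two values $m$ and $m+1$, so a subtree is fully
described by the pair ($m$, set of states attaining $m$). Polytomies
are therefore scored as hard polytomies with no approximation. The
kernel is validated in the test suite against brute-force enumeration
of all ancestral assignments on trees of up to 8 leaves, and against an
independent Sankoff implementation (phangorn) on ambiguity-free data.

Per-character fit is summarised by the usual indices: with $m$ the
minimum steps on any tree (one less than the smallest state set
intersecting every cell's allowed set — computed by exact set cover,
feasible because characters have few states), $s$ the observed steps
and $g$ the steps on the completely unresolved star tree,
$\mathrm{CI} = m/s$ and $\mathrm{RI} = (g-s)/(g-m)$ (defined as 1 when
$g = m$). A character is parsimony-informative iff $g > m$. Ensemble
CI/RI sum $m$, $s$, $g$ over characters. Published ensemble values in
this literature do not always state whether uninformative characters
were included; `ensemble_fit()` therefore computes both conventions
(`exclude_uninformative = FALSE` is the default and the pipeline
reports both).

## Heuristic search

`mp_search()` mirrors a classic "traditional search": seeded
random-addition starting trees (taxa added in random order, each at the
length-minimising attachment point, ties broken by the seeded RNG),
tree bisection–reconnection (TBR) branch swapping accepting
equal-or-better trees, a per-replicate hold limit, merging of replicate
results, filtering to the global minimum length, collapse of
zero-length branches, and deduplication by bipartition set. The search
is deterministic given (matrix, configuration, seed): TBR
neighbourhoods are enumerated in canonical order and all stochastic
choices come from the seeded RNG.

Two readings of a "collapse zero-length branches" rule exist, and the
resulting tree counts differ, so both are implemented:

* `max_zero` (default): collapse a branch only when **no**
  most-parsimonious reconstruction places a change on it (its maximum
  possible length is 0);
* `min_zero`: collapse whenever **some** reconstruction leaves it
  changeless.

Per-branch minimum/maximum change counts over all reconstructions come
from the up/down Sankoff pass described below; for a tree rooted on an
internal edge the two root-adjacent half-edges are treated jointly,
since a single change can sit on either half.

The default desk profile is 50 replicates holding 20 trees;
`replicates`, `hold` and `max_explore` (a cap on how many held trees
have their full TBR neighbourhood expanded) scale the effort up to a
full overnight profile or down to bootstrap-sized searches.
`exhaustive_search()` enumerates all topologies up to 9 taxa and is the
oracle the heuristic is tested against.

## Consensus and support

Bipartitions are canonicalised as the side of an internal edge not
containing the outgroup. The strict consensus contains exactly the
bipartitions present in every input tree (asserted as a set identity in
the tests); the majority-rule consensus those in a strict majority
(cutoffs below 50% are refused because compatibility is then not
guaranteed).

Bootstrap support resamples characters with replacement, runs a reduced
search per pseudoreplicate (default: 1–2 addition replicates, hold 10,
a small expansion cap — the effort knobs are explicit arguments), and
records the bipartitions of each pseudoreplicate's strict consensus.
The reduced effort is a deliberate trade-off, standard in practice;
the calibration test checks the analytic case of a single informative
character among ten, whose expected support is
$100(1-(9/10)^{10}) \approx 65\%$.

Bremer (decay) values come from a single suboptimal-retention sweep
rather than per-branch constraint searches: starting from the
(uncollapsed, binary) most-parsimonious trees, TBR accepts every
distinct tree within `max_k` steps of the minimum; a bipartition's
value is the smallest $k$ at which it vanishes from the strict
consensus of all retained trees of length $\le L + k$, censored at
`max_k`. One sweep serves every branch; the sweep is validated against
full tree-space enumeration on small matrices. A sweep can in
principle miss a near-optimal tree if the sublevel set is disconnected
under TBR; multiple starting trees and a generous hold make this
unobserved in the oracle tests.

## Character mapping and grade-segment rates

All mapping quantities derive from the uniform-cost Sankoff dynamic
programme run down (subtree cost vectors $g_v$) and up (rest-of-tree
cost vectors $R_v$) the rooted tree. For an edge $(u,v)$ on a tree of
per-character length $m$: the edge can carry 0 changes in some
most-parsimonious reconstruction iff $\min_s g_v(s)+R_v(s) = m$, and 1
change iff $\min_{s \ne t} g_v(s)+R_v(t)+1 = m$; a parallel counting
pass (normalised per node; only ratios are used, so overflow cannot
occur) yields the *fraction* of reconstructions placing a change on
each edge. Three resolution policies are exposed:

* `acctran` / `deltran`: explicit single reconstructions built
  top-down, choosing at each node a state minimising (subtree cost +
  change indicator), which keeps the joint assignment most
  parsimonious. DELTRAN breaks ties toward the parent state (delaying
  changes tipward), ACCTRAN away from it (accelerating them rootward);
  at the root, DELTRAN prefers the lowest-index optimal state and
  ACCTRAN the highest, making both fully deterministic. These are
  operational definitions; totals always equal the Fitch length.
* `mpr_average`: each branch receives the mean change count over *all*
  most-parsimonious reconstructions (possibly fractional). This is the
  least placement-biased summary and is validated against enumeration.

The grade-segment rate statistic assigns each branch to a taxon group
iff at least one group-assigned leaf descends from it and *all*
group-assigned descendants belong to that group; spine branches whose
descendants span groups, and branches leading only to unassigned taxa,
belong to no group. This is the only assignment that never
double-counts a branch and makes paraphyletic grade segments
well-defined; the alternative (assigning boundary branches to the
distal group) is not offered because it silently double-counts under
nesting. The rate for character $c$ in group $g$ is
$r(c,g) = t(c,g)/n(c,g)$: transitions on the group's branches divided
by the number of group members scorable (determinate or polymorphic)
for $c$; cells with $n = 0$ are excluded from means. Because spine
branches are excluded, group-wise transition sums may be strictly less
than a character's total steps (asserted in the tests). The default
mapping tree is the strict consensus with hard polytomies; mapping on
each MPT is available through `optimize_all()`.

Two properties of this statistic are worth knowing. First, parsimony
counts are floors: when the expected number of changes per character
is no longer small, multiple hits on a path are reconstructed as fewer
changes and the rate table *undercounts* — at study-like rates
(roughly 0.08 changes per character per scorable taxon) simulations
show an undercount of about 5–10% regardless of resolution policy.
Unbiasedness is therefore only tested, and should only be expected, in
the low-rate regime. Second, changes near grade boundaries can be
placed on either side of an ambiguity by ACCTRAN/DELTRAN; the
`mpr_average` policy spreads them and is the recommended summary when
comparing groups.

## Disparity

`gower_distance()` first re-scores polymorphic cells as unknown and
then computes, for every pair, the mismatch proportion over mutually
determinate characters (the all-categorical Gower coefficient with
pairwise deletion and equal weights). A pair sharing no scored
character aborts with a diagnostic naming the pair — imputation would
silently fabricate signal. The triangle inequality is *not* guaranteed
under pairwise deletion and is not asserted.

`pcoa()` is classical metric scaling: double-centre $-\tfrac12 D^2$,
eigendecompose, scale eigenvectors by the square roots of their
eigenvalues. Negative eigenvalues are reported but excluded from the
percent-variance denominator, and no Lingoes/Cailliez correction is
applied; because the choice of denominator is a known source of
ambiguity when comparing published variance percentages, the object
also carries the absolute-sum convention (`pct_variance_abs`). The
similarity export emits $1-d$ with taxa ordered by
`consensus_leaf_order()` — the left-to-right tip sequence of the
ladderised, outgroup-rooted strict consensus, a concrete definition of
"base-to-apex order".

## Time-scaling and record gaps

`timescale()` uses "basic" a-priori dating: terminal nodes sit at
their taxon's first appearance (FAD), internal nodes at the oldest
descendant FAD, and `epsilon_ma` (default 0.5 Myr, purely
presentational) is imposed as a minimum internal branch duration
working root-ward. No stochastic calibration is attempted.
`record_gaps()` computes the exact interval complement of the union of
[LAD, FAD] ranges within the study window, suppressing gaps shorter
than a resolution threshold; a bundled Devonian–Permian stage lookup
(`ics_stages()`) converts stage names to numeric ages.

# The synthetic-data generator

`simulate_dataset()` provides ground truth for every pipeline stage.
Its defaults emulate the structure of the study matrix the package was
built around:

| parameter | default | rationale |
|---|---|---|
| taxa | 79 | study matrix size |
| characters | 25/8/18/20/18 by category (89) | published category counts |
| states per character | 2–5, P = (.70, .18, .09, .03), mean ≈ 2.45 | ≈ 218 states over 89 characters |
| unknown cells | 13.9% | published composition |
| inapplicable cells | 10.5%, half hierarchical | published composition; hierarchy emulates controlling characters (e.g. cupule presence) switching dependents to inapplicable |
| polymorphic cells | 0.1% | published composition |
| rate | 0.045 changes/character/unit length | with the default tree depth gives a few changes per character, i.e. study-like homoplasy |
| tree | Yule topology, branch lengths `brlen_min` + Exp(`brlen_mean`) | neutral null; no rate variation across branches |

Masking places exact cell counts (hierarchical inapplicables are
truncated or topped up to the target), so realised percentages match
targets to rounding. Polymorphism is modelled as observational
ambiguity (one extra recorded state), not biological polymorphism.
Groups for rate tests slice the true tree at two internal nodes into a
terminal clade and two successively more basal paraphyletic grades of
roughly a third of the taxa each, mirroring a clade nested within
grades. Every change event is recorded per branch.

What the generator does **not** emulate: character correlation,
directional or ordered evolution, rate variation across lineages or
characters beyond the per-character rate, non-uniform taxon
completeness (real matrices have a few very incomplete taxa), and
fossilised birth–death sampling. Passing recovery tests therefore
demonstrate algorithmic correctness under the stated null, not
robustness to these violations.

## Recovery test regimes

Two regimes are fixed in the test suite, chosen by design before the
tests were frozen:

* **Topology recovery** ("strong signal"): 20 taxa, three times the
  study's per-category character counts (267 characters), state-rich
  characters (2–5 states, mean 3.5), rate 0.045, branch lengths
  1 + Exp(0.5), no missingness. This puts roughly 12 expected changes
  on even the shortest branch, so every bipartition should be
  recoverable; the acceptance test requires a fully resolved strict
  consensus identical to the truth (RF = 0) in at least 95% of 50
  seeds.
* **Rate recovery**: a fixed 20-taxon true tree, rate 0.0025, no
  missingness, 100 replicate character sets; the mean estimated
  per-group rate must sit within 2 Monte-Carlo standard errors of
  rate × (assigned branch length)/(group size). The low rate keeps
  multiple hits rare so that the parsimony floor-count bias discussed
  above is negligible relative to Monte-Carlo error.

# Numerical and degenerate-input choices

* State sets are bit masks (up to 32 states); costs are small exact
  integers carried in doubles with a large finite sentinel for
  impossible states, so all comparisons use a 1e-9 slack that cannot
  interact with true cost differences (which are ≥ 1).
* Reconstruction counts are renormalised at every node; only ratios
  enter results.
* Characters with no scored cells get one nominal state and are
  constant (zero steps, uninformative, excluded from rate means by the
  $n = 0$ rule).
* Ties everywhere (addition attachment, held-tree order, policy state
  choices) are broken by the seeded RNG or by lowest-index rules, so
  identical inputs and seeds reproduce outputs byte for byte.
* `exhaustive_search()` refuses more than 9 taxa; Gower aborts on
  pairs with no shared scored characters; majority cutoffs below 50%
  are refused.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale on one
CPU: oracle sweeps use 4–8-taxon trees (where exhaustive enumeration
is exact and fast), search validation uses 100 random 6–8-taxon
matrices, recovery uses 50 seeds at 20 taxa, and the acceptance script
analyses one 79 × 89 study-profile synthetic matrix with a reduced
search profile (2 replicates, hold 5, bounded neighbourhood
expansion) plus a 10-seed recovery block and a 300-pseudoreplicate
bootstrap calibration. The full 1000-replicate × hold-100 search
profile of a publication-grade analysis is available through
`mp_search()` arguments and is intended for unattended runs.

# Known limitations

* TBR is the only swap; no ratchet, sectorial search or tree fusing,
  so very large or very homoplastic matrices may need many replicates.
* Inapplicable cells are ambiguity, not a logical dependency model;
  characters with controlling/dependent structure are scored the way
  the field's standard programs score them, with the known artefacts.
* The Bremer sweep is exact only insofar as the suboptimality band is
  fully explored; the hold cap is a safety valve on pathological
  plateaus.
* Bootstrap support under very flat likelihood surfaces (few
  informative characters) carries a small positive bias from held-set
  correlation; the calibration test bounds it.
* Gower distances with heavy pairwise deletion can be non-Euclidean;
  negative PCoA eigenvalues are reported, not corrected.
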