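---
title: "Quantifying incomplete lineage sorting from retrotransposon presence/absence markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying incomplete lineage sorting from retrotransposon presence/absence markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroils)
```

## The problem

Rapid radiations — bursts of speciation with very short internodes — leave
ancestral polymorphisms unsorted: an allele segregating in an ancestral
species can persist through several successive speciation events and then
fix independently in each descendant lineage. This *incomplete lineage
sorting* (ILS) produces gene-tree/species-tree conflict even without any
homoplasy. Retrotransposon (RE) presence/absence markers are nearly ideal
probes of this process: a retrotransposed element inserts once, at one
genomic location, with one target-site duplication, and is essentially never
precisely excised. A conflict in an RE marker is therefore attributable to
ILS-derived *hemiplasy* rather than to parallel gain or loss, which makes
these markers usable for localising and quantifying ILS even on deep
timescales — for example across the near-simultaneous basal divergences of
Neoaves.

`retroils` provides the complete analysis chain for such data: reading and
filtering marker matrices, mapping each marker on a rooted species tree
under Felsenstein's polymorphism parsimony, measuring per-marker ILS
duration and per-branch ILS levels and insertion rates, the combinatorics of
hemiplasy probabilities, a formal test for hybridization-like asymmetries in
placement support, target-site motif statistics, and a multispecies
coalescent generator that produces matrices with known per-locus truth.

## The character model

Each marker is a column of states over the sampled species: `1` (insertion
present at the orthologous locus), `0` (absent, with an intact single target
site), `?` (not scorable). Polarity is fixed — absence is ancestral — and is
an input assumption, not something the package infers; outgroups must have
been used upstream to polarise the matrix.

Under **polymorphism parsimony** a marker's history consists of a single
origin on one branch (`0 -> 1`, or `0 -> P` when the insertion stays
polymorphic), a connected region of branches carrying the polymorphism
(`P`), and independent fixations of the presence (`P -> 1`) or absence
(`P -> 0`) allele where lineages exit that region. Losses after fixation
(`1 -> 0`) are excluded: that is the homoplasy-free premise. The optimal
mapping minimises the number of branches retaining the polymorphism.
`map_character()` solves this exactly by dynamic programming over the node
states `{0, 1, P}` with single-origin bookkeeping; `?` tips are resolved
inside the same programme, with ties broken toward absence (conservative
with respect to inferring insertions) and the origin placed as low as the
optimum permits. An exhaustive search over all origin placements and all
connected P-regions — and, for missing data, over all `?` resolutions — is
kept in the test suite as the independent oracle; the two agree on every
rooted tree shape with up to 8 leaves and every binary tip pattern.

**ILS duration.** A mapping with `f1` fixations to presence and `f0` to
absence implies at least `f1 + f0` independently sorting lineages, hence
persistence of the polymorphism across at least `f1 + f0 - 1` speciation
events. Conflict-free markers (one step) have duration 0 and are reported in
the class `"<=1"`, because a single-step pattern is parsimoniously
consistent with sorting across one or fewer events; ILS-affected markers
fall in classes `2`, `3`, `>=4`. Two step-counting conventions are
implemented and selectable throughout (`convention = "fixations"` counts
`f1 + f0`; `"retentions"` counts `1 +` the number of polymorphic branches),
because historical polymorphism-parsimony programs do not document which
definition their printed tree lengths use; the reproduction harness tries
both against a target value. `dollo_score()` (single origin plus counted
losses) is included as the classical baseline.

**Per-branch attribution.** Every informative marker is attributed to its
parsimony-inferred origin branch; `branch_summary()` tallies conflict-free
and ILS-affected insertions per branch, the branch's percentage of ILS and —
given branch lengths in million years — the insertion rate per MY
(markers/branch length). Branches on which no marker originated report an
undefined (`NA`) percentage rather than 0, to avoid fabricating signal on
empty internodes. Under equally parsimonious origins the lowest (most
recent) feasible branch is chosen, which minimises the asserted polymorphism
duration.

## Hemiplasy combinatorics

For a polymorphism persisting across `n` speciation events on a maximally
pectinate (caterpillar) tree, the `L = n + 1` descendant lineages each fix
one allele: `2^L` equiprobable fixation vectors. A vector is congruent with
the species tree exactly when its presence set is a clade of the caterpillar
(including the empty and full sets): `L` singletons, `L - 2` non-trivial
nested clades, plus the two constant vectors — `2L` in total, so

$$P(\text{hemiplasy}) = \frac{2^L - 2L}{2^L}.$$

The module exposes the number of speciation events `n` as the user-facing
index. The clade rule is provably equivalent to "the parsimony engine needs
duration at most 1", and the test suite verifies that equivalence
exhaustively for all vectors with up to 10 lineages, as well as the
agreement of enumeration and closed form. The probability is 0 at one event,
50% at three, 93.75% at seven and 99.4% at eleven — the polymorphism only
has to survive a handful of speciation events before a discordant outcome
is more likely than a concordant one. Fixation vectors are treated as
equiprobable; population-genetic weighting of fates (drift, selection) is
deliberately out of scope.

## Placement support and the hybridization check

`placement_candidates()` removes a focal clade and regrafts it on every
branch of a user-delimited region (plus a new-root placement when the region
spans the whole backbone). A marker is counted as *diagnostic* for a
candidate when it is conflict-free on that candidate **and** its origin
branch lies on the candidate's attachment path (the focal sibling's branch
or the branch above the attachment node), **and** it qualifies for no other
candidate. Mere compatibility never counts — a marker conflict-free on
every candidate says nothing about the placement — and a marker with `?` in
the taxa needed to discriminate two placements qualifies for both and is
therefore counted for neither.

Ancient hybridization between diverged lineages predicts an
over-representation of markers behind one species-tree-incongruent
alternative; symmetric ILS predicts a near-even spread. The package
formalises this verbal argument as a goodness-of-fit test of equal expected
counts across the non-best candidates: an exact multinomial p-value (sum of
the probabilities of all outcomes no more probable than the observed one)
when the outcome space is enumerable, Pearson's chi-square otherwise, with
the flag raised only when uniformity is rejected *and* the deviating cell is
an excess. The test — including the enumeration bound (about 2·10^6
compositions, which covers profiles of the size seen in real placement
analyses) and the default alpha of 0.05 — is this package's
operationalisation, not something the original analyses specified; results
label the method used.

## Target-site motifs

`motif_matrix()` summarises the 5-bp target-site duplications: per-position
nucleotide counts and frequencies, information content
`IC_j = 2 - H_j` bits (Shannon entropy, log base 2, no small-sample
correction — negligible at thousands of motifs), and per-position chi-square
statistics against the uniform 1/4 expectation, combined across positions by
Fisher's method in `preference_test()`. `N` entries are dropped from the
affected position only. A flat logo (all IC near 0, global p large) is the
signature of no insertion-site preference, which is what underwrites the
assumption that independent insertion into the same site is vanishingly
rare.

## The synthetic-data generator

`simulate_pa_matrix()` emulates the genome-screening stage that produces a
marker matrix, under the same assumptions the estimator makes, so that
deviations in recovery are attributable to the estimator and not to model
mismatch:

* one haploid lineage per species, coalescing within each species-tree
  branch at rate `k(k-1)/2` per coalescent unit (standard multispecies
  coalescent; `coalescent_units()` converts MY given `Ne` and generation
  time, and is the only place `Ne` appears);
* a single insertion per locus placed uniformly over the realised gene
  tree's total branch length (infinite sites: no parallel insertion, no
  precise excision); presence tips are the insertion edge's descendants;
* per-entry missing-data masking, then the ascertainment filters of a real
  screen (minimum scored taxa, no plesiomorphies, no autapomorphies, no
  all-absent patterns), with rejected loci redrawn so the requested number
  of retained loci is exact;
* chromosome assignments, coordinates, a genic flag and uniform random TSD
  motifs as metadata.

Defaults are fixed at screening-scale study conditions: 2,118 loci, at least
10 scored taxa, all ascertainment filters on, a 10% per-entry missing rate
(the deposited matrices do not print their missing fraction; 10% is a
realistic figure for flank-alignment dropout, and the rate is a free
parameter), and a chromosome scheme whose Z and microchromosome shares
(114/2118 and 140/2118) mirror the marker counts of the genome-wide screen
this emulates.

Each retained locus records its truth. `true_duration` is the ILS duration
of the clean, unmasked pattern on the generating tree — the quantity the
estimator targets. `segregating_events` additionally counts the speciation
events at which both alleles genuinely segregated among the sampled
ancestral lineages. The two differ whenever a deep coalescence sorts into a
species-tree-concordant pattern ("silent" ILS): parsimony cannot see those,
so genealogical agreement sits well below pattern agreement on short
internodes (at internode length 0.5 coalescent units, roughly a third of
loci carry some silently sorted history). `recover_parameters()` reports
both agreements, on the collapsed duration scale (`<=1` vs exact integers
above 1) that the duration classes use.

What passing simulation tests do **not** show: robustness to scoring error,
alignment artefacts, paralogy, insertion-rate heterogeneity across lineages,
gene flow, or diploid frequency dynamics — none of which the generator
models. The generator validates the estimator under its own assumptions;
conclusions about real matrices rest on the upstream screening having
enforced those assumptions.

## Numerical choices and degenerate inputs

* The DP cost is lexicographic `(retained P branches, number of ? resolved
  to 1)`; all tie-breaks are deterministic, so outputs are reproducible.
* All-absent patterns return an empty mapping with zero steps; their ILS
  duration is signalled as undefined rather than 0.
* Plesiomorphic patterns (all presence) map as a single origin on the root
  stem; the ascertainment filter normally removes them first.
* Unrooted trees are rejected, not silently rooted: Dollo-type polarity
  depends on the root. Coordinates in metadata are 1-based inclusive.
* `'N'`/`'-'` in input matrices are tolerated and mapped to `?` with a
  warning; any other symbol is a hard format error naming the record.
* Spearman correlations use average ranks and the two-sided t
  approximation for p (two dozen branches is comfortably in its range); an
  exact-permutation alternative was judged unnecessary at that n.
* Branch search: stepwise addition over jumbled taxon orders followed by
  rooted-NNI hill-climbing, ties kept first-found, deterministic given the
  seed (defaults: 7 jumbles, seed 11111). The neighbourhood is NNI only;
  SPR/TBR would buy little on matrices whose signal is dominated by a few
  hundred informative clades and would cost considerably more time.

## Problem sizes used in the shipped tests

The exhaustive mapper-vs-oracle check covers every rooted binary shape with
3–8 leaves and every binary tip pattern; the classifier/engine
cross-validation covers all vectors on ladders up to 10 lineages. Simulation
checks use 10,000 loci per branch-length setting for the 3-taxon closed-form
comparison and 2,000 loci per setting on 5-taxon ladders for the
monotonicity and recovery checks. These sizes make the Monte-Carlo standard
errors small relative to the tested effects while keeping the default test
run at desk scale.

## Known limitations

Polytomies are handled by the mapper but the placement enumeration requires
a binary backbone. The search is a local heuristic: it is guaranteed no
worse than its own start trees, not globally optimal. Consistency and
retention indices are reported for orientation only; their historical
printed values depend on undocumented conventions of older software and are
treated as soft checks. The hybridization flag is a screening statistic on
count profiles, not a likelihood-based hybridization test; network
inference, D-statistics and divergence-time estimation are out of scope.
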