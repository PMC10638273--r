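---
title: "Profiling multi-subunit complex evolution: models and choices"
author: "PolyProfile authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling multi-subunit complex evolution: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PolyProfile)
```

This vignette documents the models behind the package, the parameters
that matter, the numerical and design choices that were genuinely open,
and what the synthetic-data generator does and does not emulate.

## The problem

Multi-subunit complexes such as the Polycomb repressive complexes leave a
characteristic comparative-genomics signature: their subunits tend to be
lost or retained together within a complex, while different complexes can
be lost independently. Quantifying that signature needs three ingredients
per species panel: reliable per-subunit ortholog calls, a rule for when a
complex counts as present, and a co-occurrence statistic over the
resulting binary profiles. The package implements each stage behind an
explicit, configurable interface.

## Ortholog confidence from domain architectures

Raw `hmmsearch` domain hits are filtered at a per-domain independent
E-value threshold (default `1e-5`, the classical homology-search
significance convention; profile-HMM searches in this pipeline inherit
the same documented default). Overlapping envelopes on one protein are
resolved *whole-hit greedily*: hits are globally ranked by bit score
(ties by E-value, then start coordinate) and accepted only if disjoint
from previously accepted hits. No envelope trimming is attempted — the
rule is simple, order-independent and idempotent, which makes the filter
auditable; the cost is that a genuinely interleaved pair of weak/strong
hits resolves to the strong hit only.

Subunit calls are three-state. A candidate satisfying the full required
domain set of a subunit (in N→C order where the rule declares one, e.g.
zf-RING before RAWUL) makes the species **high-confidence**; satisfying
only the putative subset (e.g. zf-RING without a recognizable RAWUL)
makes it **putative**; otherwise **absent**. Order constraints are only
enforced where the domain grammar is biologically fixed — zf-RING→RAWUL
and zf-RanBP→β-hairpin — because real proteomes contain architecture
reversals elsewhere (SAM/MBT orders differ between animal proteins and
their unicellular relatives), and an over-strict order rule would turn
those into false absences. The β-hairpin carried C-terminally by both
CBX and RYBP/YAF proteins is one domain label here (`beta-HP`); profile
names `CBX7_C` and `YAF2` are normalised to it on read.

A consequence worth knowing: calls are monotone in evidence. Adding a
domain hit can only move a species upward (absent → putative →
high-confidence), never demote it; this is property-tested.

## Species-overlap orthology and LECA

Gene-tree internal nodes are labelled by the species-overlap rule. With
child-clade species sets $S_L$ and $S_R$, the overlap score is
$|S_L \cap S_R| / |S_L \cup S_R|$; a node is a duplication when the score
exceeds the threshold (default 0 — any shared species). The threshold
default is the common species-overlap convention; because "large
overlap" is a matter of degree, the score itself is stored per node so
any stricter post-hoc cut can be audited. Raising the threshold can only
convert duplications to speciations, never the reverse.

Orthologous groups are the connected components left after removing
duplication nodes from the tree graph; they provably partition the
leaves (property-tested on random trees, and against a brute-force
oracle exhaustively on all small topologies). Each group is vetted by
three criteria: (i) defining-node support strictly greater than 90
(ultrafast-bootstrap-style integer supports read from internal node
labels; a missing support fails with its own reason), (ii) at least 80%
of members sharing the modal architecture string, and (iii) at least 80%
sharing the modal function-prediction label. The 0.8 consistency
fraction makes an otherwise qualitative "consistency" requirement
explicit and configurable; members lacking a function label are excluded
from criterion (iii)'s denominator rather than counted as disagreements,
since a missing prediction is absence of evidence.

LECA presence is inferred for a group when its species cover both sides
of an assumed root of the eukaryotic species tree *and* span at least 3
distinct major groups. Requiring both sides operationalizes "the
duplication is older than the root"; the 3-group floor guards against a
two-species coincidence. Adding species can only gain, never lose, a
LECA verdict. Gene trees are used as rooted as read — no rerooting is
attempted, so an unrooted or misrooted input is the caller's
responsibility. Multifurcations are resolved before labelling into a
deterministic left-leaning caterpillar with children ordered by their
lexicographically smallest leaf, so rotated inputs yield identical
labellings.

## Complex completeness and categories

A complex is **complete** only when *all* of its core subunits are
present: RING1 and PCGF for PRC1; EZH, EED and SUZ12 for PRC2. RBBP is
carried in every matrix but never used for completeness — it is too
promiscuous across chromatin complexes to indicate PRC2. A complex with
no present subunit is **absent** (or **putative-only** when putative
calls exist); any mixture is **partial**.

Categories are then: BOTH (both complete), PRC1_ONLY / PRC2_ONLY (one
complete, the other fully absent), NEITHER (both fully absent), UNCLEAR
otherwise. The deliberate precedence choice: a species with PRC1
complete but PRC2 partial is UNCLEAR, *not* PRC1_ONLY — a partial
complex is unresolved evidence, not evidence of absence. The categories
are exhaustively cross-checked against a truth-table oracle over all
$3^5 = 243$ possible subunit state rows.

Report percentages are nearest-integer with halves rounded away from
zero. The *uncoupled fraction* is the share of single-complex species
among the resolved-complete species (BOTH + PRC1_ONLY + PRC2_ONLY): that
denominator asks "of the organisms that demonstrably kept a complete
complex, how many kept only one?", which is the meaningful measure of
uncoupling; with no resolved species it is reported as undefined, never
as 0.

## Phi co-occurrence

Profiles are binarized (1 present, 0 absent) and putative calls excluded
— they contribute neither presences nor absences. The default exclusion
is *pairwise* (a species is dropped for a pair only if either subunit is
putative there), the most direct reading of that rule; *listwise*
exclusion is available behind a flag for sensitivity analysis. Phi is
computed from the 2×2 contingency counts and equals Pearson correlation
on the same vectors (verified to 1e-12 on a thousand random pairs).
Zero-variance profiles (such as an all-present RBBP column) give an
*undefined* value, flagged and excluded from averages — never coerced to
0, which would fabricate a "no association" claim.

Intra-complex averages are means over within-set pairs (1 pair for PRC1,
3 for PRC2); the inter-complex average is over the 6 cross pairs, with
RBBP excluded throughout. Clustering is stats::hclust average linkage on
$d = 1 - \phi$; subunits are presented in lexicographic order so that
equal-distance merges resolve deterministically to the lexicographically
smallest pair, and subunits with undefined distances are minimally
excluded (greedily dropping the most-undefined subunit) rather than
aborting the clustering.

## The synthetic generator: what it emulates, what it does not

`simulateSpeciesTree()` draws a Yule tree rescaled to unit height with
leaves assigned round-robin to six synthetic major groups on two root
sides. `simulateProfiles()` implements a coupled Dollo loss model: both
complexes present at the root; each complex carries its own Poisson loss
process (rate λ per unit branch length, realised per branch as an event
probability $1 - e^{-\lambda t}$); an event spreads to the partner
complex with probability ρ; losses are irreversible; retained complexes
additionally lose individual subunits at rate δ; finally present calls
are downgraded to putative with probability π (optionally per subunit,
to mimic subunits that are hard to detect by sequence). At ρ = 0 the two
complexes are lost independently; at ρ = 1 their profiles are identical.

Defaults — λ = 0.9, ρ = 0.3, δ = 0.05, π = 0.05 on the unit-height tree
with 178 species — were fixed once to give eukaryote-panel-like
retention: roughly a fifth of species keeping both complexes, about a
third keeping neither, and a modest unresolved fraction. They are
conditions of the simulated study, not tuning knobs.

What the generator does **not** emulate: sequence evolution and
alignment/tree-inference error (fixture gene-tree supports are written
as constants, not estimated), gene gain or transfer after the root
(strict Dollo), correlated loss between subunits *within* a complex
beyond the shared complex-loss event, and the taxon-sampling biases of a
curated proteome panel. Passing simulation tests therefore demonstrates
that the statistical machinery recovers the parameters of this loss
model — not that real proteome panels satisfy it.

One stand-in deserves emphasis: `syntheticSourceMatrix()` is a
deterministic 178-species matrix matching the *marginal* structure of a
published eukaryote panel (per-subunit high-confidence and putative
counts, five-way category counts). Those marginals do not determine the
joint distribution of states across the 57 unresolved species; the
constructor fixes it by a single coherence packing chosen from the count
constraints alone. Category counts, percentages and subunit counts
computed from it are exact reproductions; phi averages computed from it
are indicative only, and the package reports them as computed rather
than adjusting the packing to land on any external value.

## Numerical choices and degenerate inputs

* Support values are integers in [0, 100] parsed from internal node
  labels; any other label is a clade name. Criterion (i) is strict
  (`> 90`), so support exactly 90 fails.
* Newick branch lengths round-trip at six decimals; fixture files are
  byte-identical under a fixed seed.
* Empty inputs fail loudly at the contract boundary (empty orthologous
  group, empty category vector, empty species map with LECA requested)
  rather than propagating empty results.
* All randomness is seeded through a single wrapper that restores the
  caller's RNG state; every stochastic function takes an explicit seed.

## Problem sizes used in the test-suite

The exhaustive event-labelling cross-check enumerates every rooted
binary topology with 2–5 leaves under every 3-species assignment
(~26,800 trees) and samples 400 seeded random 6-leaf trees; the
simulation-recovery check uses 200 replicates per coupling value at 178
species. These sizes saturate the properties being tested while keeping
the default test run fast.

## Known limitations

* Domain-only putative calls: whether a putative call should also demand
  monophyletic clustering is left to the caller (supply a gene tree and
  combine verdicts); by default putative is a pure domain statement.
* WD40-family ambiguity: EED and RBBP are both WD40 proteins, so domain
  evidence alone cannot separate them; distinguishing them requires the
  tree stage, and the fixture hit tables inherit this ambiguity.
* No reconciliation against a dated species tree and no paralog
  subfamily naming; the species-overlap rule is local and can over-call
  duplications under incomplete lineage sorting or contamination.
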