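---
title: "Contact-map scoping of membrane-protein architecture: methods"
author: "memscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-map scoping of membrane-protein architecture: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscope)
```

## Scope and data model

`memscope` analyses a single protein chain through four per-residue tracks
and one pairwise track: the sequence, a membrane-topology profile
(`i`/`o`/`M`/`S`), a three-state secondary-structure profile (`H`/`E`/`C`),
optional 3D coordinates reduced to one Cα/Cβ pair per residue, and a set of
scored residue-pair contact predictions. All indexing is 1-based with
closed intervals `[start, end]`. Contacts are canonicalised to `i < j` on
input, duplicates collapse keeping the maximum score, and "top-L" always
means the L highest-scoring pairs of a chain of length L, with ties broken
by smaller `i`, then smaller `j`, so every ranking is deterministic.

The geometric contact definition used everywhere — for truth maps of
synthetic proteins and for model validation alike — is Cβ–Cβ distance ≤ 8 Å
at sequence separation |i − j| ≥ 5, with Cα standing in where Cβ is absent
(glycine, incomplete residues). This is the convention contact predictors
are trained against; both the cut-off and the separation are exposed as
arguments (`dCut`, `sMin`) so alternative conventions can be probed.

## Domain boundaries from contact density

For the selected top-n contacts the raw spanning count is

$$S(k) = \left|\{(i,j)\ :\ i < k \le j\}\right|, \qquad k = 1 \dots L .$$

A compact domain keeps $S$ high across its interior; few contacts span the
linker between two quasi-independent domains, so boundaries appear as local
minima. The raw profile is smoothed with a discrete Gaussian kernel
(default bandwidth 3 residues, reflective edge handling) and the local
minima of the smoothed profile are reported ranked by increasing smoothed
value (deepest first). Two conventions close gaps the formulation would
otherwise leave open:

* a terminal margin (default 10 residues) is excluded at both ends, because
  the profile necessarily decays to zero at the termini and would otherwise
  always call boundaries there;
* minima within one bandwidth of each other merge, keeping the deeper one,
  to avoid duplicate calls on noisy plateaus; on an exact plateau the first
  position is reported.

The reported position `k` is the first residue of the C-terminal side of
the putative cut. Defaults (`nTop = L`, bandwidth 3, margin 10) reproduce
the qualitative behaviour expected for a ~170-residue two-domain chain
splitting near residue 60.

One property of this statistic is worth knowing before interpreting minima
on featureless maps: under a uniform null the expected spanning profile is
dome-shaped, so interior local minima are noise-driven and cannot form on
the steep monotone flanks near the termini. Calls on random maps therefore
concentrate centrally rather than uniformly; the package's null tests
assert the properties that do hold — left/right symmetry and coverage of
the allowed interval — and downstream significance is never claimed from
the density profile alone.

## Internal tandem repeats

A two-unit repeat leaves near-identical intra-unit contact patterns in the
two halves of the map. `splitMap(map, b)` cuts at residue `b` (N-half
`1..b`, C-half `b+1..L`, both re-indexed from 1; cross-half contacts are
discarded and counted). Each half is binarised to its top
`topFactor × half-length` contacts (default 1.5, deep enough to cover the
true contacts of a helical unit while keeping the permutation null
computable) and compared by the Jaccard index of the two pair sets after
shifting one by a register offset Δ, restricted to pairs valid in both
index frames — a definition symmetric under `(A, B, Δ) → (B, A, −Δ)`. The
statistic is the maximum Jaccard over candidate splits and |Δ| ≤ 10
(tolerant to indel drift between units).

Significance uses a permutation null that preserves what makes contact maps
non-exchangeable: their strong banding in sequence separation. Each
permutation replaces both halves at every candidate split with random pair
sets preserving the half's exact multiset of separations |i − j| (start
positions drawn without replacement per separation, so pairs stay unique),
then replays the identical maximisation over splits and offsets. Because
the selection is replayed inside the null, the p-value
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$ is calibrated
under the optimisation; ties count as extreme, which is conservative.
`nPerm` below 19 is rejected (the p-value grid would not reach 0.05), and
the seed is a required argument recorded in the result.

Repeats are compared in direct orientation only. A pseudo-inverted repeat —
two units related by a two-fold axis in the membrane plane — still yields
near-identical *intra*-unit maps, because a contact map is invariant to
rigid inversion of the unit in 3D. Orientation is therefore not inferred
from the map; it is read from the topology track downstream (the membrane
side each unit's elements enter from), which is also how the pipeline
summary reports inverted architecture.

## Re-entrant helix candidates

Topology predictors tend to label a membrane re-entrant hairpin as one
ordinary TM helix. The geometric rule in `findBrokenTM` looks inside every
`M` segment for exactly one maximal coil run in the secondary-structure
states with

* length within `[minBreak, maxBreak]` — default `[2, 8]`, bracketing the
  observed two- and six-residue breaks in known cases with headroom;
* helical runs of at least `minLimb` (default 4) residues on both sides;
* the run's centre inside the middle 50% of the segment ("around the
  mid-point" made precise).

The rule is deterministic: with noise-free secondary structure its
false-positive rate on hairpin-free bundles is zero, and that is asserted
in the tests. What the rule cannot do is distinguish a genuine re-entrant
hairpin from a strongly kinked TM helix on geometry alone; candidates are
therefore always reported as candidates, with a packing score attached,
never as facts.

The packing evidence: over the top contacts linking two disjoint segments,
the Spearman correlation ρ of the segment-A index against the segment-B
index is −1 for ideal antiparallel packing and +1 for parallel; it is
reported only when at least 3 supporting contacts exist. For a hairpin
whose packing partner helix *precedes* it in sequence, hairpin geometry
makes limb 1 (N-side of the break) the antiparallel limb and limb 2 the
parallel one; for a following partner the roles swap. The composite score
is

$$w_{geom} + w_{pack}\cdot\max\!\left(0, \frac{-\rho_{anti} + \rho_{para}}{2}\right),$$

defaults \(w_{geom} = 0.4\), \(w_{pack} = 0.6\): passing the deterministic
geometric rule alone scores 0.4, and perfect anti/parallel packing reaches
1.0. The partner is the flanking unbroken membrane segment with the most
supporting contacts; undefined correlations contribute 0, and a candidate
with no flanking membrane helix keeps the geometric component with a
warning.

## Amphipathic helices

The Eisenberg hydrophobic moment of a window of residues with
hydrophobicities \(H_n\) placed at δ = 100° per residue around the helical
wheel is

$$\mu_H = \frac{1}{N}\sqrt{\Big(\sum_{n=0}^{N-1} H_n \sin(\delta n)\Big)^2 +
  \Big(\sum_{n=0}^{N-1} H_n \cos(\delta n)\Big)^2},$$

normalised by window length and accompanied by the direction angle
(atan2 of the two sums, wheel frame with residue 0 at 0°). The scale is
Fauchère–Pliska (1983) side-chain hydrophobicity, defined relative to
glycine (H(G) = 0), shipped as a data file under `inst/extdata/` — the
scale used by the standard helical-wheel servers, so moments are comparable
with published values (amphipathic surface helices typically score
~0.3–0.8; membrane cores much lower). For homopolymer windows the formula
collapses to the closed form
\(\mu_H = |h|\,\lvert\sin(N\delta/2)/\sin(\delta/2)\rvert / N\), which the
tests verify to 1e-9 alongside a direct complex-sum oracle.

The default analysis window is the 15 residues immediately preceding each
re-entrant candidate's first limb — the putative surface-bound amphipathic
helix feeding the hairpin; windows that would start before residue 1 are
skipped with a warning. A sliding scan over the whole chain is also
provided.

## Model validation

`topLPrecision` reports the fraction of the top-L predicted contacts
present among the model's geometric contacts. Whether a minimum sequence
separation was applied in published values of this statistic is usually
unstated, so `sMin` (and `dCut`) are explicit arguments rather than baked
in. The per-contact match table supports the standard overlay plot classes:
matched, mismatched, and model contacts not predicted.

## Re-entrant loop libraries

From PDBTM-style region annotations, each re-entrant loop is extracted
together with its preceding 30 residues (the TM helix that packs against
it), clipped at the chain start; entries missing coordinates anywhere in
the extended interval are flagged rather than silently dropped. Redundancy
removal is greedy in input order at 40% identity, with identity defined as
matches / alignment length under global alignment (unitary match score,
gap opening 10, extension 0.5 — the threshold, not the aligner, is the
contract, so the gap constants are documented rather than tuned).
Clustering of a pairwise structural-similarity Z-score matrix is the
connected components of the graph with edges Z ≥ 4.5: a membership claim
("these entries group together") that is deterministic, unlike
force-directed layouts, and monotone — raising the cut-off can only refine
the partition, never merge components. The all-against-all structural
alignment that produces the Z matrix is upstream of this package; the
matrix arrives as a CSV/matrix input.

## The synthetic generator

`buildProtein` lays out ordered elements — TM helices, re-entrant hairpins,
amphipathic surface helices, loops — as an idealised α-helical bundle:
1.5 Å rise and 100° twist per residue, Cα at 2.3 Å and Cβ at 3.3 Å from the
helix axis, a 30 Å membrane slab, membrane elements on a line of slots
9.5 Å apart so only adjacent elements pack, hairpins descending to
mid-membrane (15 Å) and returning to their entry side, amphipathic helices
lying on the membrane surface. Sequences are assigned from hydrophobicity
classes: membrane cores cycle uniformly hydrophobic residues (low moment by
construction), amphipathic elements alternate hydrophobic and polar faces
by wheel angle (high moment), loops use small polar residues. The topology
track labels a hairpin `M` across its whole span — mimicking the
single-TM-helix misprediction the detector exploits — while the
secondary-structure track shows the coil turn. A repeat plan duplicates an
element sub-list behind a 4-residue linker with inverted membrane
orientation; the linker is a spatial gap, making the two units
quasi-independent modules with a genuine density boundary between them.
`corruptMap` then simulates a predictor: each true contact survives with
probability `pTP` (scores uniform on [0.55, 0.95]), `nFP` false pairs with
separation ≥ 5 are injected at lower scores (uniform on [0.05, 0.5]), all
deterministic per seed.

What the generator does *not* emulate: backbone continuity between
elements, side-chain packing and rotamers, irregular helices, β-structure,
score distributions of real predictors (real true/false score ranges
overlap; here they are disjoint, which makes top-L behaviour exactly
computable per seed), and the evolutionary covariance process itself.
Passing tests on these fixtures therefore demonstrate that the statistics
recover planted architecture under controlled noise — not that any real
family has a given architecture.

## Reference conditions and problem sizes

The packaged study conditions (`exampleSpec`) are: a 167-residue two-domain
chain with the boundary at residue 63 (three-TM 60-residue N-domain, as in
the archetypal case of a ~170-residue chain splitting near residue 60); a
124-residue inverted tandem repeat of 60-residue three-TM units; a
140-residue DedA-like protein (amphipathic helix, re-entrant hairpin, TM
helix — twice, inverted); and a four-TM negative control. Noise defaults to
`pTP = 0.8` with `0.2·L` false positives (0.85 where the analyses target
higher-quality maps). The test suite and the acceptance script use 100
replicates for boundary recovery, 200 null maps and 199 permutations for
the repeat test's calibration, 50 replicates for its power and for
re-entrant recovery, 50 random fixtures for the brute-force contact oracle
— sizes chosen so the whole suite runs in about a minute while keeping
Monte-Carlo error well below the asserted margins.

## Known limitations

* Exactly two repeat units are considered; higher-order repeats would need
  a different statistic.
* Re-entrant detection requires a topology prediction and helical limbs;
  β-hairpin re-entrants and kink-vs-hairpin disambiguation are out of
  scope.
* The boundary detector parses one level: no hierarchical or discontinuous
  domains.
* `nonredundant` is order-dependent by design (greedy in input order), so
  library composition depends on input ordering — deterministic for a fixed
  order.
* PDBTM XML parsing covers the region subset only; coordinates come from
  the companion PDB file, and the region code treated as re-entrant is
  configurable because XML dialects differ.
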