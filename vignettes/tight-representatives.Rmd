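---
title: "Tight representative cycles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tight representative cycles: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tightph)
```

## The problem

Persistent homology detects robust holes -- loops (H1) and voids (H2) -- in
noisy point clouds and distance data, but the matrix reduction that computes
the persistence diagram yields representatives of those holes that are
usually enormous and geometrically uninformative. `tightph` computes the
diagram *and* a tight, short representative boundary for every significant
feature, so that a chromatin loop can be localized to specific genomic bins
and a protein void to specific backbone atoms.

## Filtration and significance model

The input is either an embedded point cloud or a sparse pairwise-distance
model in which an *absent* pair means an infinite distance (the convention
for Hi-C contact matrices, where a zero or NaN balanced count means the edge
never enters the complex). The Vietoris--Rips filtration at scale tau
contains every simplex (up to tetrahedra) whose vertex set has diameter at
most tau, ordered by diameter, then dimension, then a lexicographic
tie-break on the vertex tuple. The tie-break is exposed as a parameter
because the stochastic stage permutes exactly this degree of freedom: the
relative order of equal-diameter simplices.

Two user thresholds control everything and are always specified jointly
through `ph_params(tau_u, eps)`:

* `tau_u` -- the **birth-threshold**, an upper limit on the birth scale of
  features that count; lower values produce denser representative
  boundaries. Units are those of the input distances (Angstrom for
  proteins, inverse balanced counts for Hi-C).
* `eps` -- the minimum persistence for a feature to be **significant**; it
  also fixes the computed scale range: persistence is computed up to the
  PH-threshold `tau = tau_u + eps`, never set independently. A class alive
  at tau is reported with death `+Inf` and always qualifies: if it had been
  resolved, its persistence would necessarily exceed `eps`.

The protein preset `ph_params_protein()` is `tau_u = 10` A and
`eps = 3.5` A, chosen against typical protein bond lengths (roughly 1.5 to
3 A).

## Computing the diagram and birth-cycles

The default engine reduces the *coboundary* matrix (processing each
dimension in reverse filtration order, with clearing of columns already
identified as destroyers one dimension down) and recovers persistence pairs
through the bijection between coboundary and boundary pivots; H0 is paired
internally by union--find with the elder rule and never reported. A direct
boundary reduction is implemented as a second route; both produce the same
diagram on every test instance, and the test suite additionally checks both
against a brute-force pure-R reduction oracle.

The columns of the reduced boundary matrix are representatives only of
features that die, so the package instead takes the *reduction operations*
V(sigma) of each creator simplex -- the **birth-cycles** -- which form a
comprehensive representative set. Birth-cycles are computed on the fly: the
reduced column of any needed destroyer is re-derived recursively from the
persistence pairs, and the cycle is the odd-parity set of columns in the
resulting recursion DAG. A reduced column is cached only once its
computation has been requested more than `cache_limit` times (default 2);
the operations lists themselves are always kept, since they are small, while
reduced columns are the memory-heavy part. Correctness is independent of the
caching policy, which the tests verify by comparing `cache_limit` settings
and the full stored-V route.

## Tightening stages

1. **Greedy shortening.** Starting from the birth-cycles of nontrivial
   features born up to `tau_u`, the steepest decrease
   `d* = max |Ci| - |Ci xor Cj|` over ordered pairs is applied repeatedly
   (ties resolved by ascending pair index, replacements immediately
   visible) until no pair shortens any cycle. Each replacement is an
   elementary basis operation, so the Z2 span modulo boundaries is
   preserved and the total length strictly decreases, which guarantees
   termination. Because two cycles sharing no simplex can never shorten one
   another, the optimized search enumerates only index-sharing pairs; it is
   exactly equivalent to the all-pairs scan and is the variant used for
   large H1 sets, while H2 sets are small enough for either.
2. **Connectedness.** A Z2 sum can be a disjoint union of cycles. Two
   d-simplices are taken as connected when they share a (d-1)-face, and
   each face-connected component is recorded as a separate cycle. (The
   alternative reading -- sharing a d-simplex -- would make every cycle of
   a set-disjoint union "disconnected"; face-connectivity is the
   operational choice and components are themselves cycles.)
3. **Local smoothing.** H1 representatives are reduced with triangles and
   H2 representatives with tetrahedra: the cycle is XORed with the boundary
   of a cofacet whenever that strictly shortens it, scanning only cofacets
   of the current cycle in filtration order until a fixed point. The
   difference between input and output is a sum of boundaries of individual
   trivial simplices, so the class never changes. Cycles smoothed down to
   length two (or less) are degenerate, counted, and dropped.

Strict decrease is essential: a significant feature whose death lies below
`tau` is homologically trivial in the full complex at `tau`, yet a greedy
descent cannot contract its representative through the surrounding geometry,
because doing so would require temporarily lengthening the cycle. The fixed
point therefore stays wrapped around the geometric hole.

## Covers and the stochastic stage

When an embedding is available, each surviving cycle defines a **cover**:
the smallest axis-aligned box containing the cycle's points, together with
all data points on or inside it. The diagram of each cover's sub-cloud is
computed and the cover's number of significant features counted; covers
with none are dropped, a cover contained in another with the same count
replaces it, and an intersection with the same count as a parent replaces
that parent, iterated to a fixed point in creation order with
deduplication. Tightening inside a cover runs in the complex truncated at
`tau`, exactly as in the global stage; the significance *count* at `tau`
equals the count at the maximum possible threshold (see above), so the
complete complex is only built when resolved deaths are reported.

The stochastic stage re-runs the deterministic stages for every
*permutation* of every *perturbation* of a cover:

* perturbations add i.i.d. uniform offsets in `[-delta, delta]` per
  coordinate; `delta` starts at 1 percent of the cover's box diagonal and
  is halved (at most 6 times) until the number of significant features is
  identical across all perturbations, the stability check; a cover that
  never stabilizes is an error, not a silent answer;
* permutations reshuffle only the order of equal-diameter simplices, via a
  seeded tie-break key.

The unperturbed data set and the identity permutation are always the first
run, so the minimum-length selection can never return a longer
representative than the deterministic pipeline, and a `(1, 1, delta = 0)`
plan reproduces it bit-exactly. Features are matched across runs by (birth,
death) within 1e-9 -- permutations of the same perturbation leave the
diagram unchanged -- and otherwise greedily by persistence rank; the
shortest representative per matched feature wins, earliest run on ties.
Results are reproducible given (seed, plan). The protein default is 15
perturbations with 15 permutations each.

## Persistence-diagram comparison

`l0_distance` reduces each diagram to its descending list of significant
persistences (at least `eps`), pads the shorter list with zeros and takes
the maximum absolute element-wise difference -- an L-infinity norm on
zero-padded sorted vectors, hence a pseudometric. Infinite persistences are
capped at `tau - birth` before list construction, since diagrams are
compared as truncated; padding with infinity would break the metric. Two
diagrams are *significantly different* when the distance strictly exceeds 3
(protein default), provided at least one has a significant feature.

## Hi-C layer

Distances are the multiplicative inverse of non-zero balanced contact
counts; zero and NaN counts leave the edge out at any threshold. Matrix
balancing itself is upstream (a cooler-style workflow); the package
consumes balanced counts as dense TSV or COO triples with a bin-table
sidecar. For cross-protocol comparison, estimates are standardized on the
bin-distance-1 distribution (top 0.1 percent trimmed, population standard
deviation), positivized by adding the absolute minimum, then power-scaled
and shifted (`x+^p + c`); exponents 1.18, 1.05, 0.98, 1.05 and 0.84 with
shift 0 are provided as presets for the five protocol experiments, and
percentiles of the per-bin-distance estimate distributions supply the
thresholds. After tightening, the persistence a loop can wrap is
re-estimated (birth = longest boundary edge, death = maximum pairwise
distance between its bins against the *untruncated* model, absent pair =
infinite death) and loops below `eps` are discarded. Loops are classified
cis/trans, by maximum interaction range (closed bounds: short < 100 kb,
100 kb <= mid < 1 Mb, long >= 1 Mb), and by single versus multiple
mid-range interactions; loop/peak matching uses the Hausdorff-style bin
distance with the <= 2 bin rule, and cross-experiment consensus loops are
maximal cliques with one member per experiment (representative: lowest
experiment, then first loop -- the choice is otherwise arbitrary and is
fixed for determinism). Covers are not used here: a contact matrix carries
no spatial embedding, a documented limitation of the cover construction.

## Protein layer

`extract_backbone` keeps the N, C, CA and O ATOM records of the first
model, alternate location blank or 'A' (PDB entries often carry
alternates; taking 'A' is the deterministic choice), optionally rejecting
entries with residues outside the 20 standard amino acids, and enforcing
the 10-atom floor. `find_voids` runs the full pipeline at the protein
preset with the 15 x 15 stochastic plan. Tight H2 surfaces are closed
2-cycles; the ray-parity test (`surface_encloses`) verifies that a surface
separates the cavity center from the outside.

## What the synthetic generators emulate -- and what they do not

* `fixture_noisy_circle` / `fixture_two_circles`: rings of 200 (100 per
  circle) points with near-uniform angular spacing and Gaussian coordinate
  noise of 0.03 r. Suggested parameters `ph_params(0.35 r, 0.15 r)`: the
  birth-threshold is deliberately large relative to `eps`, because points
  clipped away by a tight cycle's bounding box thin the ring inside its
  cover and raise the in-cover birth scale; a birth-threshold dominating
  the typical tight-cycle edge length keeps the feature significant inside
  its own cover. This mirrors the regime in which covers are useful: the
  feature's representative involves a large fraction of the surrounding
  points.
* `fixture_sphere_shell` / `fixture_two_spheres`: golden-angle lattices of
  48 points on spheres of radius 6 A with 0.2 A noise -- about one
  backbone atom per 3 A, a realistic density for a cage lining a small
  interior void -- analyzed at the protein preset. The 48-point size keeps
  the complete complex of a cover (about 2 x 10^5 simplices) small enough
  that the full 15 x 15 plan runs in minutes on one CPU; these are the
  problem sizes used throughout the tests and the acceptance script.
* `fixture_planted_hic`: Poisson counts with mean `scale / (1 + gap)` on
  each chromosome -- giving the expected increase of distance estimates
  with bin distance -- plus an elevated anchor block that plants a loop;
  a trans variant uses two cross-chromosome anchor blocks. Suggested
  parameters are attached. The generator emulates distance decay and
  planted loops only, not protocol-specific biases (cross-linker or
  nuclease effects), compartment structure, or balancing artifacts.
* `fixture_toy_pdb`: a minimal idealized backbone (4 atoms per residue)
  and a synthetic spherical "cage" written as PDB text -- geometry
  stand-ins for parsing and void detection, not real folds.

Passing tests on these fixtures demonstrate the algorithms' contracts --
exact diagrams, span preservation, enclosure, planted-structure recovery --
not performance on experimental data, where noise structure is richer than
anything generated here.

## Numerical choices and degenerate inputs

* Greedy sign convention: the scan maximizes the *decrease*
  `|Ci| - |Ci xor Cj|` and exits when no pair decreases; ties between pairs
  are broken by ascending index.
* Equal-diameter order: diameter, then dimension (so faces precede
  cofaces, which share their diameter with an edge), then vertex-lex;
  stochastic permutations replace only the last key.
* Cover boxes are closed; membership tolerance on subset tests is 1e-12.
* A cycle consisting of a single point yields a zero-volume box containing
  coincident points only.
* Duplicate COO entries keep the smallest distance; self-pairs are
  dropped; negative distances or counts are rejected.
* `l0_distance` takes absolute differences (symmetry requires it) and
  returns 0 for two empty lists; `significantly_different` warns and
  returns `FALSE` when neither diagram has a significant feature.
* Degenerate-cycle threshold: length <= 2.
* Point sets are limited to about 32000 points (64-bit packed simplex
  keys).

## Known limitations

* Filtrations other than Vietoris--Rips, coefficients other than Z2 and
  homology above H2 are out of scope.
* Covers require an embedding; distance-only covers and oriented bounding
  boxes are possible extensions with different cost trade-offs.
* The cover construction assumes the tight cycle's bounding box retains
  enough of the surrounding structure; for sparse, noisy rings whose
  representative uses few points this can fail, which is why the circle
  study conditions above use a dominant birth-threshold.
* Greedy shortening and smoothing find local, not global, minima;
  globally minimal homologous cycles would require integer programming.
* The percentile-matching procedure for choosing cross-protocol `(p, c)`
  is accepted from the user (with presets); the package does not search
  for them.
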