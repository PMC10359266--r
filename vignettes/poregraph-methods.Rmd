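---
title: "Comparative H-bond graph and pore analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative H-bond graph and pore analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poregraph)
```

## Scope and motivation

Two channelrhodopsin paralogs from *Hyphochytrium catenoides* — the
K⁺-selective HcKCR1 (PDB 8GI8) and the Na⁺-selective HcCCR (PDB 8GI9) —
differ in ion selectivity despite nearly identical folds. The informative
comparisons are residue-level: hydrogen-bond network graphs and their
conserved/unique partition, a handful of key side-chain distances, a
sub-Ångström global RMSD, per-residue displacements, counts of ordered
waters, ions and lipids, and the presence or absence of a continuous tunnel
along the putative ion pathway. `poregraph` implements each of these as an
independent, tested operation and one orchestrated comparison
(`run_compare()`).

## Structure model and entity classes

A structure is a flat atom table (author residue numbering kept throughout —
"Asp116" means the same residue in both paralogs) plus a chain-to-protomer
map. Parsing is delegated to bio3d; this package adds the policies:

* atoms with zero occupancy are dropped;
* for alternate locations, the conformer with the highest total occupancy
  per residue is kept, ties broken by the alphabetically first altloc.
  Keeping one conformer is the common choice for distance analysis; an
  occupancy-weighted average would create fictitious geometry.

Every residue gets exactly one entity class (`protein`, `water`,
`monatomic_ion`, `phospholipid`, `sterol`, `retinal`, `other_het`) from a
small extensible component-code table; unknown single-atom het groups are
treated as monatomic ions, everything else unknown falls to `other_het`
with a warning. With protomer scope, het residues are assigned to the
protomer of the nearest protein chain by minimum interatomic distance — the
deposited assemblies group waters and lipids per protomer but state no rule,
and nearest-chain assignment reproduces that grouping without curation.

## Residue correspondence

`align_sequences()` is Needleman–Wunsch global alignment with BLOSUM62 and
affine gaps (open 10, extend 0.5), via Biostrings. For two sequences a
pairwise global alignment is the deterministic, dependency-free equivalent
of the multiple-alignment tool used interactively for figures. Identity and
similarity are computed over aligned (both non-gap) columns; "similar" means
a positive substitution score. Both the full-construct and the
modeled-residue (17–256) windows can be reported: `align_sequences()` gives
the former, `map_residues()` restricts to residues present in both models
and recomputes the percentages. For equal-length ungapped stretches the map
reduces to same-number pairing, which the tests assert.

## Superposition and displacement

`kabsch_superpose()` is the SVD solution of the orthogonal Procrustes
problem with the determinant correction (rotations only, det = +1;
collinear point sets are rejected). Because the atom selection behind a
printed global RMSD is often unstated, `run_compare()` reports both the
Cα-only and the all-shared-heavy-atom variants.

Per-residue displacement is measured after moving structure A into B's frame
by the superposition over *all* mapped Cα atoms of the protomer — the only
frame the two structures define without manual choices. Note the
consequence: a local shift planted into only one helix leaks slightly into
the fitted frame. The synthetic generator therefore plants *balanced*
displacements (the diametrically opposite helix moves oppositely), which
keeps the optimal frame exactly at identity and makes the planted value
recoverable at face value; this is a property of the fixture design, not of
real structures.

## H-bond graphs

The criterion is purely geometric: a donor and an acceptor heteroatom from
a fixed side-chain table within 4.0 Å form a bond; pairs within 3.5 Å are
classed *strong*. The longer-than-usual cutoff deliberately includes the
weak thioether interactions of Met side chains. No angles and no hydrogens:
the models carry no hydrogens and a distance criterion is what the graph
method this emulates uses. The table covers the polar side-chain atoms of
the 20 amino acids (His ring nitrogens as both donor and acceptor, since
protonation is unknown), the water oxygen, Met SD as acceptor, and the
retinal Schiff-base nitrogen. Backbone N/O are excluded: these are
side-chain H-bond graphs; backbone-mediated contacts are out of scope.

Detection uses a cell-list neighbor grid (cells of one cutoff length;
identical output to the all-pairs scan, which stays available as an internal
cross-check). Graphs collapse atom pairs to one edge per residue pair,
keeping the minimum distance; nodes are residues (side chains, Schiff base)
and individual waters. Water–water edges are included by default —
water chains are part of the network — and a flag excludes them.

The difference graph of A and B classifies an edge of A as conserved iff its
endpoints map to residues joined by an edge in B. Waters never correspond
across structures (there is no canonical water numbering), so all
water-involving edges are structure-specific and conserved edges connect
amino-acid/Schiff-base nodes only. The partition identities
(conserved ∪ unique-A = edges(A), conserved ∪ unique-B = edges(B), sets
disjoint) are enforced by property tests on random planted pairs.

For display, `project_graph()` plots each node at (PCA-1 of its membrane
plane (x, y) position, Cα z); the input is assumed oriented with the
membrane normal on z, as deposited membrane-protein models conventionally
are. The PCA sign is fixed by making the node of largest absolute score
positive.

## Cavities and tunnels

`rasterize()` casts the structure onto a boolean grid (default spacing
0.5 Å) using a standard Bondi-type van der Waals radius table; the grid
origin snaps to the spacing lattice so that voxel centers land on round
coordinates and results are invariant under sub-voxel translations of the
input. The clearance field is computed exactly per voxel (distance to the
nearest atom surface), capped at 6 Å — only clearances up to the largest
probe of interest matter — and equals a brute-force nearest-atom scan by
construction.

`find_cavities()` separates bulk solvent from interior cavities the way
dummy-atom cavity casting tools do: erode free space to voxels with
clearance ≥ probe (default 1.4 Å), flood-fill from the box boundary, then
dilate back by the probe radius plus half a voxel diagonal (the discrete
center of a feasible probe sphere may sit anywhere inside a core voxel).
Remaining free components are cavities; components smaller than one water
volume (10 Å³) are discarded as casting noise between surface atom spheres.
Volumes are voxel counts × spacing³; on an analytic hollow shell of radius
6 Å the estimate is within 10% at 0.5 Å spacing and changes under 5% when
the spacing halves.

`tunnel_search()` finds the seed-to-bulk path maximizing the minimum
clearance (the bottleneck path). The maximal feasible clearance threshold is
located by bisection over the sorted clearance values with a flood-fill
connectivity check per candidate — equivalent to a max–min Dijkstra but
vectorizable — and the reported path is the breadth-first shortest path at
that threshold, which fixes ties deterministically. A tunnel exists for a
probe iff the bottleneck radius is at least the probe radius (0.9 Å default
for ion-pathway comparisons), which makes monotonicity in the probe radius
immediate. For the paralog comparison the seed is computed, not hand-picked:
the midpoint between the Schiff-base nitrogen (Lys233 NZ) and the centroid
of the extracellular aromatic cluster Cα atoms (residues 102, 210, 221,
222). Only the qualitative presence/absence at the same protocol in both
structures is treated as reproducible; path identity is not.

## Synthetic fixtures

`make_fixture()` builds ideal parallel α-helix bundles (rise 1.5 Å/residue,
100°/residue, Cα radius 2.3 Å, default 4 helices × 18 residues — exactly
five turns, so per-helix ring offsets cancel) with an apolar background
sequence and minimal side chains: only the atoms the donor/acceptor table
needs. Each planted bond is placed on the segment between the two Cα atoms
so its heteroatom distance is exact; planted water bonds put the water
beyond the side-chain atom on the same line. After placement the generator
verifies that *no unplanted* polar pair falls within 4.2 Å and errors
naming the offending pair otherwise, so planted counts are exact truth.
Decoy entities (waters, Na⁺ ions, sterol- and phospholipid-like groups) go
on a wide ring ≥ 10 Å outside the bundle with ≥ 6 Å mutual separation.
Placement randomness comes from a package-local linear-congruential
generator seeded in the spec — the global RNG stream is never touched, and
identical specs give byte-identical PDB output.

What the fixtures do *not* emulate: real rotamer geometry, backbone
polarity, crystallographic disorder, membrane curvature, or realistic
lipids. Passing fixture tests demonstrates the correctness of the
*operations* (detection, partition, superposition, grid analysis), not that
any particular biological conclusion transfers; the deposited-structure
checks exist separately for that and require the public models.

## Numerical choices and defaults

| parameter | default | unit | why |
|---|---|---|---|
| H-bond cutoff | 4.0 | Å | includes weak Met-S interactions |
| strong class | ≤ 3.5 | Å | conventional H-bond distance |
| grid spacing | 0.5 | Å | volume error < 10% on analytic shells |
| surface probe | 1.4 | Å | water radius; bulk/cavity separation |
| tunnel probe | 0.9 | Å | dehydrated-ion scale for pathway continuity |
| clearance cap | 6 | Å | bounds reportable bottlenecks; speeds the field |
| min cavity volume | 10 | Å³ | one water volume; drops casting noise |
| gap open/extend | 10 / 0.5 | score | standard BLOSUM62 affine penalties |
| distance report tolerance | ±0.15 | Å | printed values are one-decimal |

Problem sizes in the test-suite: bundles of 72–100 residues, grids up to
~100³ voxels (the 0.25 Å convergence check), 200 random fixtures for the
neighbor-grid equivalence property. These sizes make the full suite run in
about a minute while every property is exercised at non-trivial scale.

## Known limitations

* The H-bond criterion is distance-only; no angular term, no
  donor-capacity bookkeeping, no energy model. π-interactions and
  cation–π contacts are reported only indirectly via distances.
* Membrane orientation is taken from the input frame; models not oriented
  with the membrane normal on z need pre-alignment before projection.
* The tunnel search is grid-based: bottleneck radii carry a discretization
  error up to about half a voxel diagonal, and paths are voxel chains, not
  smooth centerlines.
* Entity classification is component-code driven; exotic lipids need a
  config entry or they land in `other_het`.
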