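---
title: "Surface roughness and contact-network topology of membrane-binding proteins: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface roughness and contact-network topology of membrane-binding proteins: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnsurf)
```

## What the package computes

`pcnsurf` analyses protein and protein--membrane structures frame by
frame, as one does when post-processing molecular-dynamics snapshots of
a peripheral membrane protein such as cytochrome c approaching a
cardiolipin-containing bilayer. Three families of observables are
produced:

1. **Surface geometry** — solvent-accessible surface area (SASA) as a
   function of probe radius, and from it the surface fractal dimension
   (FD), a single-number summary of surface roughness.
2. **Contact-network topology** — a residue-level protein contact
   network (PCN) built from C-alpha distances, its spectral
   bipartition into two structural modules, and per-residue betweenness
   centrality (BC) and participation coefficient (P).
3. **Membrane-interaction geometry** — minimal protein--membrane
   distance kinetics, inter-residue distances, buried interface area
   attributed to each module, and the orientation of a planar cofactor
   (heme) ring relative to the membrane plane.

Everything operates on standard PDB files; multi-model files are the
trajectory interchange format, one MODEL per time point.

## SASA: deterministic Shrake--Rupley sampling

For every atom $i$ with van der Waals radius $r_i$ and probe radius
$PR$, `sasa()` places $m$ quasi-uniform points on the sphere of radius
$r_i + PR$ and counts the fraction not contained in any other atom's
equally expanded sphere; the accessible area of the atom is that
fraction of $4\pi (r_i + PR)^2$.

Two numerical choices matter:

* **The point set is a fixed golden-spiral (Fibonacci) lattice, not a
  random sample.** SASA is therefore a deterministic function of the
  coordinates, radii, probe and $m$ — there is no seed anywhere in the
  surface pipeline, reruns are byte-identical, and the FD regression
  below is not polluted by sampling noise that differs between probe
  radii.
* **$m$ = 960 points per atom by default.** On the closed-form
  two-sphere overlap benchmark the relative error at 960 points is
  well under 1%; 240 points are adequate for smoke work and are used
  in some fast tests, 4000 when a tight comparison against a
  closed-form area is wanted.

Radii come from an element-keyed table (C 1.70, N 1.55, O 1.52, S
1.80, P 1.80, H 1.20, Fe 1.80 Å), overridable per call. Hydrogens are
included when present in the file; a `heavy_only` selection flag
provides the alternative convention. Both conventions are legitimate
and shift absolute FD by a few hundredths, which is why the choice is
exposed rather than hard-wired.

## Fractal dimension

The defining relation is

$$2 - FD = \frac{d\,\log SASA}{d\,\log PR},$$

estimated by unweighted ordinary least squares of $\log SASA$ on
$\log PR$ over the probe grid 1.0--2.0 Å in steps of 0.2 (six points,
the default returned by `fd_probe_grid()`). A perfectly smooth large
body has slope approaching 0 and FD approaching 2 from below; rougher
surfaces lose area faster as the probe grows and push FD above 2;
globular proteins typically measure 1.7--2.3. The natural logarithm is
used internally; the slope (hence FD) is invariant to the base and to
uniform rescaling of SASA, both of which only move the intercept —
properties the test suite asserts.

`fit_fd()` reports $R^2$ and warns (never errors) below 0.99: real
protein log--log curves are near-linear, while coarse synthetic lattice
bodies and near-flat curves (slope $\approx 0$ makes $R^2$
uninformative) legitimately fall below the threshold. A constant-SASA
input is treated as a perfect flat fit ($R^2 = 1$), not an undefined
one.

## The protein contact network

Nodes are residues, represented by their C-alpha atoms; an undirected
link joins two residues iff their C-alpha distance lies in the
**closed** interval [4, 8] Å. The 4 Å floor removes the trivial
backbone contacts of sequence neighbours (canonical spacing ~3.8 Å),
so the network encodes tertiary organisation. "Between 4 and 8" is
read as inclusive at both ends; the boundary behaviour is unit-tested
so a half-open variant is a one-line change.

**Bipartition.** The Laplacian $L = D - A$ is eigendecomposed with the
dense symmetric solver (networks here have ~100 nodes). The Fiedler
vector (eigenvector of the second-smallest eigenvalue) is thresholded
at the mean of its components: components $\le$ mean form cluster 1,
the rest cluster 2. On a connected graph the Fiedler vector is
orthogonal to the constant vector, so the mean is numerically zero and
the rule is a sign split; ties (component exactly equal to the mean)
deterministically go to cluster 1. The eigenvector's sign ambiguity is
removed by requiring that cluster 1 contain the first residue; across
trajectory frames, labels are additionally matched to the previous
frame by maximal overlap, so a sign flip or permutation between frames
cannot relabel the clusters. A gap below $10^{-9}$ between the second
and third eigenvalues sets a `degenerate` flag with a warning. Graphs
that are exactly degenerate in this sense are rare in practice — even
two merged random blobs keep a clearly simple $\lambda_2$ — so the
flag is exercised in tests with a fixture whose degeneracy is exact by
symmetry (the 4-cycle, spectrum $\{0, 2, 2, 4\}$), and merged-blob
inputs are documented as "unstructured", not "degenerate".
Disconnected networks are an error naming the component sizes, and
`pcn_series()` skips and logs such frames rather than failing the run.

**Betweenness centrality.** $BC(i) = \sum_{u \ne i \ne v}
\sigma_{uv}(i) / \sigma_{uv}$ on the unweighted graph, computed by
Brandes-style BFS dependency accumulation and verified in the tests
against an independent exhaustive shortest-path-counting oracle and
against igraph. The sum over *unordered* pairs is reported by default;
the literal double sum over ordered pairs is available
(`ordered_pairs = TRUE`) and exactly doubles every value — a uniform
rescaling that cannot affect rankings, cluster comparisons or
trajectory trends. Raw values are reported; normalisation by
$(n-1)(n-2)/2$ is a flag, since whether published per-residue BC plots
are normalised is often unstated.

**Participation coefficient.** $P_i = 1 - (k_{si}/k_i)^2$, with
$k_{si}$ the links of $i$ into its own cluster. $P_i = 0$ for purely
intra-module residues, 1 for purely bridging ones. Isolated nodes get
$P = 0$ with a warning rather than NaN. Summary tables count residues
with $P$ above a threshold (default 0.05; the notion of "significant
P" has no standard cutoff, so it is a parameter) within residue
windows defaulting to the three omega-loops of cytochrome c (20--30,
40--57, 71--85), overridable for other proteins.

## Membrane-interaction geometry

* **Minimal distance** $\xi$ is the exact minimum over protein--lipid
  atom pairs of the centre--centre distance — not a distance to a
  fitted plane. All atoms are used by default, heavy atoms only behind
  a flag, since published kinetics rarely state the convention.
* **Buried interface area** is $SASA(\text{protein alone}) -
  SASA(\text{protein with membrane atoms as occluders})$ at the same
  probe — "the protein surface in contact with lipids", an area of the
  protein, not half of a symmetric buried area. Because both
  evaluations use the same deterministic lattice, per-atom buried
  areas are non-negative by construction; they aggregate to residues
  and, through a partition, to clusters. Contact residues are those
  with a heavy atom within 4 Å (configurable) of any lipid atom.
* **Heme orientation** fits the best plane through the ring heavy
  atoms (direction of least variance, via SVD) and reports the angle
  between that plane and the membrane plane folded into [0°, 90°]
  (0° parallel, 90° orthogonal). The membrane plane defaults to the
  xy-plane; frames from arbitrary simulations should be pre-rotated.

## Synthetic data: what it emulates, and what it does not

No raw MD trajectories are shipped or downloaded; every pipeline stage
is exercised on seeded generators whose ground truth is known by
construction (`same spec + seed` is bit-identical, and no generator
touches the caller's RNG stream):

* `make_sphere_cluster()` — single spheres, disjoint pairs, closed
  cages and solid balls with analytic SASA for the oracle cases.
* `make_two_domain()` — two compact jittered-lattice C-alpha blobs
  (nearest-neighbour spacing ~6 Å, inside the contact window) joined
  only by a short linker, so the network's minimal cut is a linker
  edge and the spectral bipartition must recover the planted modules
  exactly.
* `make_membrane_slab()` / `make_approach_trajectory()` — a flat
  pseudo-lipid grid and a rigid body descending onto it with a known
  $\xi(t)$ schedule (linear descent to a contact plateau, realised
  exactly by aligning the body's lowest atom over a slab particle).
* `make_roughening_trajectory()` — a ball whose surface corrugation
  grows linearly across frames, giving a non-decreasing FD trend.
* `make_cytc_like()` — a **synthetic stand-in** for the cytochrome-c
  fold topology: 104 residues in two modules (residues 1--34 + 86--104
  with His18; residues 35--85 with Met80) connected only through the
  sequence bridges 34--35 and 85--86, eight heavy atoms per residue
  packed at protein-like density, and a planar heme-like HETATM ring
  between the modules. It reproduces the *architecture* reported for
  cytochrome c (terminal segments co-clustering, axial ligands split
  across modules) by construction, and its compact packing yields an
  FD in the globular 1.7--2.3 range (about 2.10, stable across seeds).

What the generators deliberately do **not** emulate: real side-chain
chemistry and packing heterogeneity, thermal fluctuations, lipid
conformational disorder, or equilibration-induced drift of cluster
boundaries. Passing tests therefore demonstrate that the algorithms
are correct on structures whose answer is known, not that any
particular biological system has a particular FD or partition; on real
deposited structures the cluster boundaries may shift by a residue or
two relative to idealised constructions, and such discrepancies should
be reported, not absorbed.

## Problem sizes and runtime choices

The test suite and the acceptance script run on: 104-residue (~850
atom) stand-ins for whole-pipeline checks with 960-point SASA; 240-
or 480-point SASA for invariance smoke tests; 200 random graphs of up
to 8 nodes for the exhaustive betweenness comparison; 20-node blobs
and 24-node planted graphs for partition recovery. These sizes keep a
full run in tens of seconds on one core while leaving every numerical
tolerance meaningful at the scale of a real ~100-residue protein.

## Known limitations

* SASA is sampled, not analytic; accuracy is bounded by the point
  density (benchmarked at better than 1% for 960 points on two-sphere
  fixtures).
* The spectral bipartition is only defined for connected networks, and
  k > 2 clustering is intentionally unsupported: recursive
  bipartitions of small proteins are unstable frame-to-frame, and no
  acceptance surface depends on them.
* PDB parsing rejects insertion codes rather than merging them;
  mmCIF, compressed trajectories (XTC/DCD) and topology formats are
  out of scope.
* The membrane is treated as a passive occluder; no energetics, no
  umbrella sampling, no free-energy estimates.
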