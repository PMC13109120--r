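# pcnsurf

Per-frame structural analysis of proteins and protein–membrane systems
from standard (multi-model) PDB files, for people post-processing
molecular-dynamics snapshots of peripheral membrane proteins — the
motivating case being cytochrome c binding a cardiolipin-containing
bilayer, where the interesting observables are the roughening of the
protein surface, the two-module organisation of its contact network,
and the geometry of the protein–lipid interface.

Three method families, all operating on plain PDB input:

* **Surface fractal dimension.** Solvent-accessible surface area
  (SASA) is computed by a deterministic Shrake–Rupley sampler (fixed
  golden-spiral point lattice, no RNG) at a grid of probe radii
  (default 1.0–2.0 Å, step 0.2), and the fractal dimension follows
  from the defining relation

  > 2 − FD = d log SASA / d log PR,

  estimated by ordinary least squares of log SASA on log PR.
  Globular proteins typically give FD in 1.7–2.3.

* **Protein contact network (PCN).** Residues are nodes; links join
  Cα pairs whose distance lies in the closed window [4, 8] Å. The
  Laplacian's Fiedler vector, thresholded at its mean, bipartitions
  the network into two structural modules (labels kept stable across
  frames by overlap matching); per-residue betweenness centrality
  BC(i) = Σ σ_uv(i)/σ_uv and participation coefficient
  P_i = 1 − (k_si/k_i)² quantify intra- vs inter-module communication.

* **Membrane-interaction geometry.** Minimal protein–lipid distance
  ξ per frame, mass-weighted centre-of-mass separation, inter-residue
  Cα distances, buried interface area (SASA of the protein alone minus
  its SASA with the membrane present, attributed per residue and per
  cluster), membrane-contact residues, and the angle between the heme
  plane and the membrane plane.

Seeded synthetic generators (sphere clusters with analytic SASA,
two-domain Cα bodies with planted modules, pseudo-lipid slabs, rigid
approach trajectories with a known ξ(t) schedule, and a synthetic
cytochrome-c-like stand-in) provide ground truth for every stage, so
the whole pipeline runs and is tested without any downloads.

## Worked example

Build the synthetic cytochrome-c-like structure (104 residues, planted
two-module architecture, heme-like ring), partition its contact
network and measure its surface fractal dimension:

```r
library(pcnsurf)

cc   <- make_cytc_like(seed = 1)
net  <- build_pcn(ca_trace(cc$frame))
part <- fiedler_partition(net)
net
#> contact_network: 104 residues, 198 links (window [4, 8] A)
part
#> pcn_partition: 53 | 51 nodes (lambda_2 = 0.01776)
cluster_segments(part, net, 1)
#>   from  to
#> 1    1  34
#> 2   86 104

fd <- fd_of_frame(select_atoms(cc$frame, component = "protein"))
fd
#> FD = 2.0974  (slope -0.0974, R^2 0.94925, 6 probe radii 1.0-2.0 A)

mean(betweenness(net))
#> [1] 280.625
sum(participation(net, part) > 0.05)
#> [1] 4
```

Reading of the numbers: cluster 1 is exactly the planted pair of
terminal segments (residues 1–34 and 86–104, containing His18; Met80
falls in the other module), the network's 198 links sit in the 4–8 Å
window, and the compact all-atom body has FD ≈ 2.10, inside the
globular 1.7–2.3 range. The λ₂ value is the algebraic connectivity of
the contact network; the mean betweenness and the count of
high-participation residues are the per-frame summary statistics the
pipeline tabulates along a trajectory.

The full per-frame pipeline (FD series, partition/BC/P tables, ξ
kinetics, interface report, per-frame summary) is one call:

```r
slab <- make_membrane_slab(8, 8)
traj <- make_approach_trajectory(cc$frame, slab, start_gap = 18,
                                 n_frames = 4, contact_gap = 3)
res <- run_full(run_config(traj, outdir = "run"))
```

which writes `fd.tsv`, `xi.tsv`, `partition.tsv`, `metrics.tsv`,
`interface.tsv`, `summary.tsv` and a run log into `run/`. A thin
shell wrapper with the same entry points ships in
`inst/scripts/pcnsurf`.

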