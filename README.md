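# uoxgeom

Geometry analysis of enzyme active sites in hydrogen/deuterium-resolved
crystal structures and conformational ensembles, built around the urate
oxidase (UOX) complex with 8-azaxanthine (8AZA) and its catalytic water W1.

UOX is a cofactor-independent oxidase: a single water molecule held in the
electrostatically positive "peroxo hole" above the ligand plane alternates
with O2 during catalysis, coordinated by a Thr/Lys dyad from the partner
protomer and an Asn side chain that populates two alternate conformations.
When the hydrogen (deuterium) atoms of such a site are experimentally
resolved, its chemistry becomes a set of measurable geometric quantities.
`uoxgeom` is for structural biologists and simulators who want those
quantities computed reproducibly, with every convention explicit:

* **Structure I/O** — PDB (and mmCIF) reading/writing on top of `bio3d`,
  preserving alternate locations, occupancies and deuterium (`element "D"`,
  never renamed); multi-model ensembles and a plain-text frame-table
  dialect; a small deterministic selection language.
* **Exact vector geometry** — distances, angles, IUPAC signed torsions,
  total-least-squares ring planes, Kabsch superposition (no reflections),
  main-chain RMSD with pair-then-fit semantics; all tested against
  independent oracles to 1e-9.
* **Interactions** — hydrogen-bond detection with explicit H/D criteria
  (d(H⋯A) ≤ 2.5 Å, ∠(D—H⋯A) ≥ 120°, configurable and echoed into output),
  and X—H⋯π contacts in the classical parametrization: the donor-to-ring-
  midpoint distance d(X⋯m), the angle ω(X) between the X⋯m line and the
  ring normal, and the ∠(X—H⋯m) angle at the hydrogen.
* **Ensemble statistics** — von Mises kernel densities of torsion angles
  (1D circular and 2D toroidal, plug-in bandwidth, FFT convolution),
  density-peak clustering on the torus (seedless, deterministic), water-site
  radial coordinates r = |C5—Ow| and θ = torsion(C4, C5, Ow, mid(H1,H2)),
  residence traces and cluster/residence coupling (odds ratio, Cramér's V).
* **Synthetic generators** — a toy active site whose planted internal
  geometry is realized exactly through 3D coordinates, and coupled
  ensembles (torsion mixtures + 2-state Markov chain + state-coupled
  water) with ground-truth manifests, so the entire pipeline is verifiable
  offline.

## Worked example

```r
library(uoxgeom)

toy <- build_toy_active_site(toy_site_spec())   # calibrated toy UOX site
rep <- run_structure_analysis(list(input = toy$model))
print(rep)
```

```
active-site geometry report [toy_active_site]
distances (A):
                 label altloc value
       Thr57*DG1...W1O    -/-  2.16
 Lys10*DZ1...Thr57*OG1    -/-  1.97
    Thr57*DG1...AZA N7    -/-  2.77
          AZA D9...W2O    -/-  1.84
     Asn254 DD21...W1O    A/-  2.23
     Asn254 DD21...W1O    B/-  2.25
torsions (deg):
                label  altloc  value
 Thr57* CA-CB-OG1-DG1 -/-/-/- -110.4
X-H...pi contacts:
                label altloc d_xm omega angle_xhm passes
 W1 O-D2...pyrimidine    -/- 3.64  23.8       141   TRUE
plane tilts (deg):
                label value
 W1 plane vs AZA ring    45
```

Reading the report: the catalytic water W1 donates one deuterium to an
O—D⋯π interaction with the ligand's pyrimidine ring (3.64 Å to the ring
midpoint, 23.8° off the ring normal, 141° at the deuterium — a classical
π hydrogen-bond geometry, hence `passes = TRUE`), while its oxygen accepts
a 2.16 Å bond from the Thr hydroxyl deuteron; the Lys—Thr dyad is linked at
1.97 Å; the Asn amide stays within hydrogen-bond reach of W1 in both of its
alternate conformations (2.23/2.25 Å, one value per altloc, never
averaged); and the water plane is tilted 45° against the ring.

On the ensemble side (stages `analysis/02`–`04`, n = 1e5 frames, seed 1):

```
dominant mode: -72.5 deg (planted -72)
shoulder:      -132.5 deg (planted -135)

  planted (179.0, 192.0) -> recovered (179.0, 192.0)
  planted (272.0,  81.0) -> recovered (272.1,  81.0)
label accuracy vs manifest: 100.00%

residence trace: occupancy 0.757 at r <= 4.00 A (100000 frames, ...)
residence/cluster coupling: odds ratio 43.3 (reference cluster 1), Cramer's V 0.882
```

i.e. the torsion landscape, the four side-chain rotamer clusters and the
water-displacement coupling planted by the generator are recovered by the
analysis chain running on raw coordinates.

The numbered drivers under `analysis/` run these stages end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_toy_structure_report.R
Rscript analysis/02_thr57_torsion_landscape.R 1   # trailing arg = seed
Rscript analysis/03_asn254_clusters.R 1
Rscript analysis/04_w1_residence_coupling.R 1
```

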