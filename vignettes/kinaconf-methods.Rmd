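---
title: "Methods: discriminating kinase DFG states from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminating kinase DFG states from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinaconf)
```

## The problem

Protein kinases switch between an active (DFG-in) and an inactive
(DFG-out) conformation of the conserved Asp-Phe-Gly motif at the start of
the activation loop. In the ROS1 kinase domain the DFG triad is
D2102-F2103-G2104: in the active state the F2103 side chain is buried
under the alphaC-helix, while in the inactive state it rotates into the
ATP-binding pocket, shrinking it and opening the specificity pocket that
type II inhibitors exploit. Gatekeeper-adjacent mutations such as F2004C
and F2004V shift this equilibrium and underlie clinical resistance.

`kinaconf` post-processes molecular-dynamics trajectories of kinase
domains with three coordinated analyses that together separate the two
states:

1. a **DFG rotation angle** -- the planar angle at the alphaC-helix
   residue 1997 C-alpha subtended by the beta4-strand residue 1980
   C-alpha and the DFG phenylalanine 2103 C-alpha -- with per-frame
   DFG-in/DFG-out classification;
2. a **grid-based ATP-pocket volume** sampled along the trajectory; and
3. **occupancy networks** of salt bridges, hydrogen bonds and
   hydrophobic contacts aggregated over concatenated replicas.

## The DFG rotation angle and state rule

For frames with atom positions $\mathbf{r}$, the statistic is

$$\theta = \arccos\frac{(\mathbf{r}_{1980}-\mathbf{r}_{1997})\cdot
(\mathbf{r}_{2103}-\mathbf{r}_{1997})}
{\lVert\mathbf{r}_{1980}-\mathbf{r}_{1997}\rVert\,
\lVert\mathbf{r}_{2103}-\mathbf{r}_{1997}\rVert}$$

in degrees. Active-state ensembles center near 31 degrees with SD about
6; inactive ensembles near 72 degrees with SD about 8. Design choices
that the angle definition itself leaves open:

* **Vertex.** The three residues are listed 1980-1997-2103; the middle
  residue (1997) is taken as the vertex. This is stored in the
  `kinase_motif_map()` configuration and can be overridden.
* **Threshold.** A frame is DFG-in iff $\theta < 50^\circ$, the midpoint
  separating the two population means; the comparison is strictly less,
  so a frame exactly at the threshold is DFG-out. The threshold is a
  parameter of `classify_state()`.
* **Histogram mode.** Distribution modes are reported on 2.5-degree bins
  by default (`angle_histogram()` bins are left-closed over
  [0, 180]); no canonical bin width exists for this statistic, and the
  mode moves by at most one bin width when the binning changes.
* **Degenerate frames.** A vertex coincident with an arm atom yields NaN
  for that frame (with a warning) rather than aborting; NaN frames are
  excluded from summaries and histograms but still counted in
  `n_frames`.

The angle is invariant under rigid rotation and translation of a frame;
the test suite asserts this to within 1e-6 degrees under random rigid
transforms.

## Grid-based pocket volume

A cubic box of edge 1.5 nm is centered on the hinge residue L2026
C-alpha and filled with grid points at 0.1 nm resolution; points
overlapping any protein atom are deleted and the volume is the count of
surviving points times the voxel volume, evaluated every 1 ns along the
trajectory. Numerical conventions, chosen once and fixed:

* **Voxel centers.** Points sit at voxel centers,
  `round(edge / spacing)` per axis, so the defaults give 15^3 = 3,375
  points and an empty box measures exactly 3.375 nm^3. This makes
  `volume = count * spacing^3` exact and the box edge unambiguous.
* **Overlap rule.** A point is deleted iff its distance to an atom
  center is *strictly* less than that atom's Bondi element radius
  (C 0.170, N 0.155, O 0.152, S 0.180, H 0.120 nm). Strictness matters
  only on a measure-zero set but is fixed so the implementation agrees
  bit-for-bit with the brute-force enumeration oracle. A fixed-radius
  mode (`pocket_grid_spec(fixed_radius = )`) exists for sensitivity
  checks.
* **Heavy atoms.** Hydrogens are excluded from the overlap test by
  default (`include_h = TRUE` reverses this).
* **Box orientation.** The box is axis-aligned in the laboratory frame
  and follows the center atom. Volumes are therefore
  translation-equivariant but *not* rotation-invariant; trajectories
  should be aligned before volume calculation if cross-frame rotation is
  substantial. This is the simplest defensible reading of a cubic box
  centered on one atom, and the alignment choice can shift absolute
  volumes slightly.

`pocket_volume()` prunes atoms that cannot reach the box
(half-edge plus the largest radius); the acceptance suite verifies
against an unpruned, point-by-point enumeration
(`count_free_grid_points()`) that pruning never changes the integer
free-point count.

## Interaction occupancy networks

All cutoffs are configuration keys with these defaults:

| interaction | criterion | default |
|---|---|---|
| salt bridge | any Asp/Glu side-chain carboxylate O within cutoff of any Lys/Arg side-chain N (heavy atoms) | 0.4 nm |
| hydrogen bond | donor-acceptor distance AND H-donor-acceptor angle | 0.35 nm, 30 deg |
| hydrophobic | any partner side-chain C within cutoff of any F2103 side-chain heavy atom | 0.45 nm |

Occupancy is the fraction of frames of the *concatenated* replica
trajectory in which at least one qualifying atom pair exists for a
residue pair; replicas are pooled into one frame population before
counting. Pairs are stored in canonical order (lower residue number
first) and detection is symmetric. Design decisions:

* "Within cutoff" is distance <= cutoff; the boundary case is
  measure-zero and documented for exactness of fixture tests.
* The H-bond geometric defaults (0.35 nm, 30 degrees,
  hydrogen-donor-acceptor) mirror the conventional GROMACS criteria.
  Donors are identified as N/O atoms with a bonded hydrogen inferred by
  proximity (<= 0.125 nm within the residue). On hydrogen-free
  topologies the screen degrades to distance-only with a warning; this
  is *not* equivalent to the full screen and is flagged as such.
* The H-bond screen is restricted to pairs touching the DFG or HRD
  motifs by default (the biologically informative hub); the restriction
  set is configurable, and an empty restriction is an error rather than
  a silent full scan.
* Salt-bridge eligibility is side-chain-only. Histidine is excluded by
  default because its protonation is ambiguous; `include_his = TRUE`
  admits ND1/NE2. Non-ionizable residues can never form a salt bridge
  under this definition, whatever their distance.
* The hydrophobic partner list (L1951, V1959, A1978, L2010, L2026,
  L2086) follows the network described for the inactive-state cluster;
  0.45 nm is a standard heavy-atom hydrophobic-contact criterion (no
  number is canonical for "van der Waals contact").
* The cross-variant matrix retains a pair iff occupancy **strictly
  exceeds** 0.15 in at least one variant, reporting all variants' values
  (zero where never observed) for retained pairs.

## Synthetic data: what it emulates, what it does not

The generator builds a rigid toy protein (`make_toy_kinase()`) carrying
every motif anchor at ~1.5 nm residue spacing so no interaction exists
until scheduled. Three generators animate it:

* `make_dfg_sweep_trajectory()` places the two angle-arm alpha-carbons
  on unit arms about the vertex in a fixed plane so the realized angle
  equals the schedule plus (optional) Gaussian jitter applied *to the
  angle itself*; the ground truth is exact by construction and emitted
  as a sidecar, never re-derived from generator internals.
* `make_contact_schedule_trajectory()` moves a residue rigidly so a
  designated atom pair sits at `on_distance` in scheduled frames and
  `off_distance` otherwise; when the moved atom is a donor, its bonded
  hydrogen is re-aimed along the donor-acceptor axis so scheduled
  contacts also satisfy the angle criterion. Designed occupancies are
  exact rational numbers.
* `make_cavity_frame()` builds single frames whose free grid-point count
  is computed by the brute-force oracle before the production
  implementation ever runs.

These fixtures are geometric, not energetic: they have no solvent, no
thermal ensemble, no correlated motions, and rigid side chains. Passing
tests therefore demonstrate that the *statistics are computed correctly*
(exact angles, exact occupancies, exact grid counts, determinism), not
that the package reproduces any property of real force-field
trajectories. On deposited simulation data the absolute pocket volumes
and angle summaries additionally depend on equilibration trimming (a
config key, default 0 ns) and on the box-orientation convention above.

Problem sizes in the shipped tests are desk-scale by design: sweeps of
10^2-10^3 frames, 25-30 random cavities, 6-frame pipeline fixtures --
large enough for the closed-form statistical checks (normal tail mass at
3 standard errors, law-of-large-numbers bounds) to be sharp, and small
enough to run in seconds.

## Pipeline and reproducibility

`run_analysis()` drives the full analysis from a YAML configuration
(variants with topology and replica trajectory paths, plus any parameter
override; every default above is a named key). Per-variant outputs are
CSV series and summaries; cross-variant outputs are the filtered
salt-bridge matrix, the H-bond radar table (percent occupancies), and a
variant summary. A JSON manifest records the package version, seed,
configuration hash and any failed stage; independent stages continue
past a failure. Identical configuration, inputs and seed produce
byte-identical CSVs, asserted in the test suite by rerunning the
pipeline and comparing files.

Equilibration trimming deserves emphasis: published ensemble averages
are computed on *equilibrated* portions of trajectories, and the number
of nanoseconds dropped per replica is rarely stated. The
`equilibration_trim_ns` key defaults to 0; matching printed means on
deposited data may require tuning it.

## Known limitations

* XTC/TRR trajectories are not read directly; convert to DCD or
  multi-model PDB first (no R-native reader for those formats is
  available to the package).
* No bimodality detection on angle distributions; the classifier is a
  single threshold.
* No water-mediated bridges, pi-stacking geometry, backbone salt-bridge
  variants, or pocket-shape descriptors beyond the single cubic box.
* Rotation of the protein relative to the laboratory frame changes
  pocket volumes (see box orientation above).
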