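# kinaconf

Trajectory post-processing for protein kinase domains: tell the active
(DFG-in) conformation from the inactive (DFG-out) one, and quantify what
stabilizes each.

Kinases carry a conserved Asp-Phe-Gly (DFG) motif at the start of the
activation loop — D2102-F2103-G2104 in the ROS1 kinase domain. In the
active state the F2103 side chain is buried under the alphaC-helix; in
the inactive state it rotates into the ATP-binding pocket. `kinaconf` is
for computational structural biologists who have molecular-dynamics
trajectories of kinase variants (wild type and resistance mutants, in
both conformations, usually in replicas) and want the standard
discriminating statistics computed reproducibly:

* **DFG rotation angle** — the planar angle
  theta = angle(CA_1980, CA_1997, CA_2103) at the alphaC vertex, in
  degrees. Active ensembles sit near 31° (SD ≈ 6°), inactive near 72°
  (SD ≈ 8°); frames with theta < 50° are classified DFG-in.
* **ATP-pocket volume** — a 1.5 nm cubic box centered on the hinge
  L2026 C-alpha, filled with grid points at 0.1 nm resolution (voxel
  centers, 15³ = 3,375 points); points strictly inside any heavy atom's
  Bondi radius are deleted and `volume = free points × 0.001 nm³`,
  sampled every 1 ns.
* **Interaction occupancies** — salt bridges (side-chain carboxylate O
  to side-chain N, ≤ 0.4 nm), hydrogen bonds (donor-acceptor ≤ 0.35 nm
  and H-donor-acceptor angle ≤ 30°, restricted to the DFG/HRD motifs),
  and hydrophobic contacts of the F2103 side chain (≤ 0.45 nm), each
  reported as the fraction of frames of the concatenated replicas where
  the contact exists, with a strict 15 % presence filter for the
  cross-variant matrix.

A synthetic-trajectory generator produces desk-scale fixtures with exact
ground truth for every one of these statistics, so the whole pipeline is
testable without downloading simulation data.

## Worked example

Generate a two-population angle sweep (300 frames from the active
distribution, 200 from the inactive one), classify, and measure a
scheduled salt bridge and a countable pocket:

```r
library(kinaconf)
set.seed(42)
sched <- pmin(179.9, pmax(0.1, c(rnorm(300, 31, 6), rnorm(200, 72, 8))))
traj   <- make_dfg_sweep_trajectory(sweep_spec(sched))
angles <- dfg_rotation_angle(traj)
cls    <- classify_state(angles, threshold_deg = 50)
cls$summary
#>    variant n_frames n_nan mean_deg   sd_deg mode_deg frac_dfg_in frac_dfg_out
#>  dfg-sweep      500     0 47.18577 21.07768    31.25         0.6          0.4
```

The classifier recovers the designed 60/40 mixture exactly (at these
population means, under 0.1 % of the probability mass crosses the 50°
threshold), and the histogram mode lands on the active peak.

```r
cav <- make_cavity_frame(cavity_spec(shell_xyz = matrix(0, 1, 3),
                                     shell_radii = 0.17))
pocket_volume(cav$model)        # 3.356 nm^3
cav$expected_free_points        # 3356, by brute-force enumeration
```

A single carbon at the box center occludes 19 of the 3,375 voxel
centers (the center point, 6 neighbors at 0.1 nm, 12 at 0.141 nm — the
8 corners at 0.173 nm stay free), and the grid implementation agrees
with the independent enumeration oracle point for point.

```r
base <- make_toy_kinase()
tr <- make_contact_schedule_trajectory(
  base,
  list(contact_schedule(atom_selector(1997, "OE1"),
                        atom_selector(1980, "NZ"),
                        present_frames = 1:6,
                        on_distance = 0.35, off_distance = 0.60)),
  n_frames = 10)
interaction_occupancy(tr, function(m, x) salt_bridge_contacts(m, x),
                      "wt-active")
#>              pair res_a res_b   variant occupancy n_frames
#> 1 LYS1980-GLU1997  1980  1997 wt-active       0.6       10
```

The K1980-E1997 salt bridge — the beta3/alphaC hallmark of the active
kinase — is scheduled in 6 of 10 frames and comes back at exactly 0.6
occupancy.

For full runs, write a YAML config listing variants (label, topology,
replica trajectories) and call `run_analysis("config.yaml")`, or use the
CLI wrapper (`inst/scripts/kinaconf.R`) with subcommands `run`, `angle`,
`pocket`, `contacts`, and `synth`. Every cutoff above is a config key.

## Scope

The package post-processes trajectories; it does not build homology
models, set up or run MD, or score druggability. XTC/TRR inputs must be
converted to DCD or multi-model PDB first. See
`vignettes/kinaconf-methods.Rmd` for the full account of conventions,
defaults and limitations.
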