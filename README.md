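# ectodimer

Chimeric modeling of ErbB-family ectodomain dimers and quantitative analysis
of their dimer interfaces, in R.

Receptors of the EGFR/ErbB family activate through ectodomain dimerization,
and the interface is built almost entirely by domain II: ligand binding
straightens domain II, no ligand leaves it bent, and a dimer of two bent
subunits opens a gap in its interface. Her2 — which binds no ligand and
signals by heterodimerizing with ligand-bound EGFR or Her3 — is the key case
where no experimental heterodimer structure exists, so such dimers must be
modeled from templates and compared through a few quantitative observables.
This package is for structural bioinformaticians who need to build such
models and compute those observables reproducibly.

## What it computes

* **Bend angle θ** of domain II: the interior angle at three Cα anchors
  (EGFR 194/239/296 or their equivalents via sequence mapping);
  θ = 180° is straight, ligand-free subunits sit near 150–160°.
* **Buried interface area**, domain-restricted:
  `ΔSASA = SASA(A) + SASA(B) − SASA(A∪B)` summed over atoms of domains
  I–III, with Shrake–Rupley SASA (probe 1.4 Å, 960 quadrature points,
  Chothia-style heavy-atom radii).
* **Chimeric dimer models**: anchored Kabsch superposition of a donor
  monomer into a template dimer slot (`replace_subunit`), three-segment
  placement of bent monomers (`segmented_replace`), ligand grafting/removal,
  χ-grid side-chain clash resolution — with provenance (anchor RMSDs,
  junction shifts) recorded for every step.
* **Trajectory series**: per-frame buried area with centered 200-ns boxcar
  averaging, contact distances (H-bond / salt-bridge / cation–π criteria),
  and dimerization-arm drift relative to the partner's binding pocket.
* **Sequence layer**: BLOSUM62 global alignment, percent identity, and
  residue equivalence maps that transfer EGFR-numbered definitions to
  Her2/Her3/dEGFR numbering.
* **Synthetic systems** with known ground truth (tunable bend, tunable
  interface gap, closed→open pseudo-trajectories with seeded noise) so the
  entire measurement layer is testable with no downloads.

## Worked example

```r
library(ectodimer)

# a Her2-like bent arm: the bend metric recovers the construction exactly
arm <- make_toy_arm(156, n_res = 40)
bend_angle(arm, attr(arm, "anchors"))
#> [1] 156

# closed vs open interface
dm <- toy_domain_map(40)
closed <- make_toy_dimer(toy_dimer_params(gap = 0,  n_res = 40))
open10 <- make_toy_dimer(toy_dimer_params(gap = 10, n_res = 40))
buried <- function(d) buried_interface_area(
  assign_radii(dimer_subunit(d, "A")), assign_radii(dimer_subunit(d, "B")),
  domain_map = dm)
buried(closed); buried(open10)
#> [1] 1524.253
#> [1] 0

# closed -> open pseudo-trajectory, 25 frames x 20 ns, windowed at 200 ns
traj <- make_pseudo_trajectory(pseudo_trajectory_params(
  start = toy_dimer_params(bend = 156, gap = 0),
  end   = toy_dimer_params(bend = 156, gap = 10),
  n_frames = 25, spacing_ns = 20, noise_sd = 0.3, seed = 1))
ser <- interface_series(traj, "A", "B", domain_map = dm, window = 200)
round(range(ser$windowed))
#> [1]   0 494
```

The first number says the designed 156° bend is measured back exactly at the
anchors; the buried areas say a 10 Å interface gap empties the toy interface
(1524 Å² → 0); the windowed series tracks that same opening over the
pseudo-trajectory, smoothed from noisy per-frame values to a clean 494 → 0 Å²
decay.

The `analysis/` directory holds the study as numbered drivers —
`01_simulate.R` (fixtures), `02_build_models.R` (chimera construction with
provenance), `03_bend_angles.R`, `04_interface_series.R`,
`05_contacts_drift.R`, `06_report.R` — each writing its tables under
`results/`.

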