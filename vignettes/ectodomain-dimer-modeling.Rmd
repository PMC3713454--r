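---
title: "Modeling ErbB ectodomain dimers and measuring their interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ErbB ectodomain dimers and measuring their interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectodimer)
```

## The scientific problem

Receptors of the epidermal growth factor receptor (ErbB) family signal
through ectodomain dimerization. The dimer interface is formed almost
entirely by domain II of each ~620-residue ectodomain: when a ligand wedges
between domains I and III of a subunit, its domain II straightens and can
engage the partner; without a ligand, domain II is bent and the interface
opens a gap. Her2 is the family's oddity — it binds no ligand, its domain II
appears constitutively bent, and it signals by heterodimerizing with a
ligand-bound partner (EGFR or Her3). Because no crystal structure of a
1-ligand human heterodimer exists, such dimers have to be *modeled*: a known
dimer structure serves as the geometric template, a monomer crystal
structure of the other receptor is superposed into one subunit slot, a
ligand is grafted in or removed, and the resulting models are compared
through a small set of quantitative observables.

This package implements that modeling protocol and those observables:

* **Chimera building** — anchored rigid-body subunit replacement
  (`replace_subunit()`), segment-wise placement of a bent monomer onto a
  straight template (`segmented_replace()`), ligand grafting and removal
  (`graft_ligand()`, `remove_ligand()`), and side-chain clash resolution
  (`resolve_clashes()`).
* **Geometry** — Kabsch superposition and RMSD (`kabsch_superpose()`,
  `rmsd()`), the domain-II bend angle (`bend_angle()`), clash detection, and
  chi-angle manipulation (`set_chi_angle()`).
* **Interface metrics** — Shrake–Rupley solvent-accessible surface area
  (`sasa()`), domain-restricted buried interface area
  (`buried_interface_area()`), windowed trajectory series
  (`interface_series()`, `window_average()`), contact monitoring
  (`contact_series()`), and dimerization-arm drift (`arm_drift()`).
* **Sequence transfer** — pairwise global alignment and percent identity
  (`global_align()`, `percent_identity()`), and residue equivalence maps
  (`build_equivalence()`, `map_residues()`) so definitions written in EGFR
  numbering (bend anchors 194/239/296, contact residues such as Gln194,
  Arg228, Tyr251/Arg285) transfer to Her2, Her3, or the *Drosophila*
  receptor's numbering.
* **Synthetic systems** — generators for arms, dimers, and
  pseudo-trajectories with known ground truth, so every metric is testable
  offline.

## The observables and their definitions

**Bend angle.** The bending of domain II is summarized by the interior angle
θ at three C-alpha anchors spanning the domain-II dimerization face (EGFR
residues 194, 239, 296; hinge at 239). θ = 180° is straight; ligand-free,
bent subunits sit near 150–160°. We take the plain three-point interior
angle at the hinge atom — the anchor-caption definition — rather than any
segment-midpoint variant; the two differ only in how noise is averaged, and
the three-point form is what the anchors define.

**Buried interface area.** For subunits A and B,
`SASA(A) + SASA(B) − SASA(A∪B)`, i.e. total ΔSASA, with per-atom
contributions summed only over atoms in domains I–III of either subunit.
Domain IV is excluded because it is flexible, often unresolved, and not
part of the interface being studied; ligand atoms are excluded by default
because the metric tracks the receptor–receptor interface (a flag includes
them). We interpret published interface areas as total ΔSASA (both
subunits' contributions), not per-subunit half-burial; this is the common
convention, and the two differ by a factor of two, far outside any
plausible tolerance, so a mismatch would be unmistakable.

**SASA.** Shrake–Rupley quadrature: each heavy atom's sphere is inflated by
the probe radius (1.4 Å, water), sampled at `points` near-uniform lattice
points (default 960), and a point is accessible if it lies outside every
neighbour's inflated sphere. Radii come from a Chothia-style heavy-atom set
(C 1.70, N 1.55, O 1.52, S 1.80 Å) shipped as `extdata/atom_radii.json` and
overridable. Hydrogens are excluded throughout — crystal structures
generally lack them, and the contact criteria are heavy-atom based. One
numerical subtlety: the quadrature lattice is rotated per atom by a
rotation derived from the atom's own coordinates. A shared lattice aliases
badly on regular structures, while a coordinate-derived rotation
decorrelates the error, keeps results independent of atom order, and —
because the rotation depends only on the atom's position — gives an atom
identical quadrature whether its subunit is evaluated alone or in the
complex, making the buried-area difference exactly zero for separated
subunits and exactly symmetric in A and B.

**Window averaging.** Series over trajectory frames are smoothed with a
centered boxcar of fixed width in nanoseconds (default 200 ns, the
conventional smoothing for microsecond-scale interface plots). Edge windows
are truncated, never padded: each point averages whatever samples fall
within half a window of it.

**Contacts.** Hydrogen bonds use the minimum donor/acceptor N,O heavy-atom
distance with a 3.5 Å cutoff; salt bridges the minimum charged-group N–O
distance at 4.0 Å; cation–π the cation-nitrogen-to-ring-centroid distance
at 6.0 Å. These are conventional heavy-atom criteria, configurable in
`contact_spec()`; angular hydrogen-bond terms are deliberately omitted
because the structures of interest (crystal models, homology models) lack
hydrogens.

**Arm drift.** Per-frame C-alpha RMSD of a dimerization-arm selection after
superposing each frame on the *partner* subunit's domain II, so the series
measures motion of the arm relative to the pocket it binds, and is exactly
invariant to global rigid motion of the whole dimer.

## The modeling protocol

`replace_subunit()` superposes a donor monomer onto a chosen template
subunit over the C-alpha atoms of an anchor range and swaps it in. For ErbB
work the anchor is the dimerization-critical part of domain II (EGFR
residues 240–309, transferred to the donor's numbering through an
equivalence map); at least 80% of the anchor must pair, and the anchor RMSD
is recorded in the model's provenance. Placement is provably independent of
the donor's starting pose (a property test covers this).

When the donor's conformation differs qualitatively from the template —
a bent domain II onto a straight template — one rigid fit is poor, so
`segmented_replace()` places ordered residue segments independently (the
three-segment treatment of a bent monomer's domain II). Junction residues
between consecutive segments are then set to the midpoint of their
positions under the two flanking transforms. This linear blend is
deliberately minimal: it guarantees bounded, reported junction shifts
without pretending to refine geometry the protocol cannot know. No
minimization is attempted anywhere; that is out of scope by design.

`graft_ligand()` places an incoming ligand by superposition onto a bound
template ligand over a shared anchor (for EGF-family ligands, the
structurally conserved core, e.g. EGF residues 26–46), then removes the
template ligand. `resolve_clashes()` searches a 30° grid over χ1/χ2 of any
side chain involved in an inter-subunit clash (< 2.5 Å heavy-atom by
default), choosing first by structure-wide clash count, then by smallest
rotation from the input; the backbone never moves, and irreducible clashes
(e.g. backbone–backbone) are reported rather than hidden. The 2.5 Å cutoff
is a package choice — published protocols typically say only that "minor
clashes were resolved" — and is configurable.

The template in this package is any user-supplied dimer `Structure`. The
historical protocol used a microsecond-relaxed 1-ligand dimer as its
template; producing such a template requires molecular dynamics, which is
out of scope here, so the builder accepts the crystal dimer directly, a
user-supplied relaxed template, or the synthetic surrogate.

## Sequence transfer choices

Alignment scoring is BLOSUM62 with gap open 10 / extend 0.5, end-gap-free
(Needleman–Wunsch "overlap") — standard defaults for full-length homologous
ectodomains; published identity figures for these pairs are stable to a
point or two under reasonable parameter changes, which is why the package's
checks put ±3-point bands on them. Percent identity divides identical pairs
by the aligned span excluding terminal-gap columns (internal gaps count in
the denominator); a `shorter`-sequence denominator is available. Equivalence
maps take the non-gap columns only: a residue aligned to a gap is reported
as explicitly unmapped, never silently dropped.

## The synthetic systems: what they emulate, and what they do not

`make_toy_arm()` builds a C-alpha-trace arm with a hinge: the requested bend
angle is reproduced *exactly* (at zero noise) at three designated anchor
residues (first, hinge, last). A small alternating ±0.3 Å out-of-plane
dither, zeroed at the anchors, keeps every sub-range non-collinear so rigid
fits on segments are well conditioned, as they are for real backbones.
`make_toy_dimer()` pairs two such arms (40 residues each by default) across
an interface; each residue carries one pseudo side-chain sphere (radius
1.9 Å) so the SASA and clash machinery have volume to act on. The `gap`
parameter swings one arm away from the interface in a V anchored just
beyond its C-terminus — the N-terminal portion separates first, exactly the
geometry of interface opening in a ligand-free dimer — and buried area is,
verifiably, strictly decreasing in the gap. `make_pseudo_trajectory()`
interpolates linearly between two parameter states and adds seeded Gaussian
coordinate noise (default frame spacing 20 ns, so a 200-ns window spans 10
frames).

These systems are geometric stand-ins, not physics: there is no force
field, no thermodynamics, no claim that a 10 Å gap "takes" 480 ns to open.
What passing tests on them demonstrate is that the *measurement layer* is
correct — that the bend metric recovers a constructed bend, that burial
responds monotonically to constructed separation, that windowing equals the
brute-force mean, that superposition recovers constructed transforms — not
that any biological number is reproduced. Conclusions about real receptors
require the real crystal structures, which the package reads but cannot
redistribute (see `extdata/reference/README.md`): dropped into place, they
flow through the identical code paths.

## Default study conditions

The pipeline defaults (`pipeline_config()`) fix the synthetic study: bend
156° (the bent, Her2-like regime reported for ligand-free subunits), closed
gap 0 Å vs open gap 10 Å (enough to empty the toy interface, as a wide-open
gap does), 40 residues per arm, 25 frames at 20 ns spacing (a 480 ns span,
so the 200-ns window both smooths and leaves a visible trend), coordinate
noise 0.3 Å (sub-resolution jitter), SASA probe 1.4 Å with 960 points, and
clash cutoff 2.5 Å. Problem sizes throughout the tests (arms of 12–40
residues, a few hundred atoms, ≤ 25 frames) were chosen as the smallest
systems on which every geometric regime of interest — closed, partially
open, fully open — is still distinguishable.

## Numerical choices and degenerate inputs

* Kabsch superposition uses SVD with the determinant correction, so
  reflections are never returned; under 3 points or collinear points raise
  a degenerate-input error rather than an arbitrary answer.
* Bend angles are clamped into [−1, 1] before `acos` to absorb rounding;
  the angle is reported in (0°, 180°].
* Clash detection and SASA neighbour search use a cell grid, checked
  against all-pairs enumeration in tests.
* Alternate locations reduce to one atom per name (highest occupancy by
  default, "first" available); waters are dropped on read; hydrogens are
  kept in the structure but excluded from SASA, clashes, and contacts.
* Writing enforces PDB fixed-width limits (residue numbers ≤ 9999) rather
  than silently renumbering.
* Chi rotations move exactly the atoms distal to the chi bond (by walking
  the residue's side-chain bond graph), so bond lengths and angles are
  untouched to machine precision; two 180° flips restore the input.

## Known limitations

* No molecular-dynamics relaxation, energy minimization, or loop building:
  models are rigid-body chimeras with side-chain adjustment only.
* Domain maps for Her2/Her3 default to EGFR's mature-numbering intervals —
  adequate at domain granularity for close homologs, but residue-exact work
  near domain boundaries should supply an alignment-derived map (the JSON
  config is overridable).
* The hydrogen-bond criterion is distance-only (no angles), appropriate for
  hydrogen-free models but looser than an MD-trajectory criterion.
* The mmCIF reader covers the `_atom_site` loop (coordinates, occupancy,
  altloc, models), not the full mmCIF dictionary.
* Buried-area values on toy dimers (hundreds of Å²) are smaller than real
  ectodomain interfaces (thousands of Å²) simply because toy arms are
  smaller; only trends and invariants, not magnitudes, transfer.
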