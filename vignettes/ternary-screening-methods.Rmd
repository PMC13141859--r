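---
title: "Methods: ligand-centric ternary-complex screening and SPR cooperativity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-centric ternary-complex screening and SPR cooperativity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protacscreen)
```

## The modelling problem

A PROTAC degrades its target only through a productive ternary complex:
target protein : PROTAC : E3 ligase. For flexible linkers the accessible
geometries of that complex are vast. A rigid diyne linker collapses the
problem: with both warheads bound in their known crystallographic poses
and the linker a straight four-carbon rod, the single remaining degree
of freedom is the torsion about the linker axis. `protacscreen`
exhaustively enumerates that torsion, builds the implied protein–protein
arrangements, and filters them sterically. The complementary SPR module
quantifies whether the surviving arrangements are productive in
solution, via binding kinetics and the cooperativity factor α.

## Conformer enumeration

`diyne_ligand()` partitions the PROTAC into a fixed warhead, a mobile
warhead, and the four linker sp-carbons. The rotation axis is the
total-least-squares best-fit line through the linker carbons, anchored
at their centroid: the linker is never exactly collinear in real
coordinates, and the best-fit line is the unique axis that treats the
small deviations symmetrically. Inputs whose linker bonds deviate from
that axis by more than 5° are rejected loudly rather than scanned about
an ill-defined axis — a real diyne is near-linear, so a larger deviation
indicates a mis-specified partition rather than chemistry.

`enumerate_conformers()` rotates the mobile warhead in `step_deg`
increments (default 10°, hence 36 conformers) using the Rodrigues
formula. The grid starts at the input geometry (angle 0); no reference
torsion is defined because none is needed — the screen is exhaustive
over the full turn. Which warhead is "mobile" is a labelling convention:
swapping sides produces the same conformer set up to relabelling, which
the test suite checks via rigid-motion-invariant distance signatures.
Only the single-axis scan is implemented; linkers with additional
rotatable bonds would need a multi-torsion enumeration that is out of
scope here.

## Warhead superposition

Each protein–ligand complex is posed by superimposing its bound ligand
onto the corresponding PROTAC warhead. The atom correspondence is an
explicit two-column map file, never inferred: automatic substructure
matching is a separate, error-prone concern, and an explicit map makes
the fitted subset reportable. The fit is the standard Kabsch solution
(SVD of the weighted cross-covariance) with the determinant sign fix, so
a reflection is never silently returned; weights default to uniform.
Degenerate maps (fewer than 3 atoms, or near-collinear geometry) are
rejected because the rotation would be underdetermined. The whole
complex then moves rigidly, preserving its internal geometry exactly.

## Clash screening

A clash is an unordered inter-structure heavy-atom pair strictly closer
than 2.4 Å. A pose is viable iff it has zero backbone–backbone clashes
and at most 20 heavy-atom clash pairs; both inequalities are strict in
the sense of the rule's wording ("any" backbone clash rejects; "greater
than 20" heavy clashes rejects, so exactly 20 is viable). Three choices
deserve justification:

* **Pairs, not atoms.** "20 total clashes" is read as 20 clashing atom
  pairs. The counting unit is configurable in effect because the
  threshold is a parameter, and the report carries the raw pair list on
  request.
* **Protein-vs-protein census by default.** Warhead placement
  reproduces the crystallographic binding pose, so ligand–protein
  contacts are by construction near their crystal values and would add
  noise, not signal. `include_ligand = TRUE` restores them. Accessory
  chains (e.g. a ligase's scaffolding partner) can be kept or trimmed
  with selection strings — both modes are supported because the original
  protocol does not state which was used.
* **Strict inequality at the cutoff**, so an atom pair at exactly
  2.4 Å does not count.

Two census implementations are maintained deliberately: a naive
all-pairs census and a cell-list census (grid cells of edge `cutoff`,
27-neighbourhood lookup). They must agree exactly; the test suite and
the acceptance script assert this on randomized scenes. Waters and ions
should be stripped before the census (crystallographic solvent would
dominate the counts); `read_pdb()` keeps only heavy atoms by default
and selection strings handle the rest.

## Staged relaxation and representative-frame selection

Rigid-body poses need relaxation before interpretation.
`build_restraint_schedule()` encodes the four-stage harmonic-restraint
release: (1) all protein and ligand heavy atoms restrained at
10 kcal mol⁻¹ Å⁻², (2) sidechains released, (3) backbone released,
(4) ligand released. The restrained sets are nested by construction —
a stage releases atoms and never re-restrains them. The schedule
exports as an engine-agnostic text report; production molecular
dynamics itself (solvent, thermostats, force fields) is explicitly not
implemented. To keep the release semantics *testable*, the package
ships a deliberately simple restrained minimizer: soft-sphere repulsion
`(σ/r)¹²` with σ = 2.4 Å echoing the clash cutoff, plus the harmonic
term `k·|x − x_ref|²`, minimised by steepest descent with backtracking
so the energy is non-increasing between accepted iterations. It is a
test instrument, not an MD engine.

Trajectories (from any engine, consumed as multi-model PDB with frame
times in `REMARK 250 TIME_NS` lines or a sidecar table) are filtered by
`equilibration_filter()`, which keeps frames strictly after the discard
window (default 10 ns; at the canonical 0.5 ns cadence over 50 ns this
keeps 80 of 100 frames). `select_representative()` then picks the
medoid frame: every other frame is aligned *pairwise* onto the
candidate frame on the alignment selection (E3-ligase backbone in the
intended use), RMSD is computed over the measurement selection (target
Cα), and the median over the other frames is minimised. Pairwise
alignment — rather than alignment to a global average — is used because
the selection criterion is defined per comparison. The self-pair is
excluded; an even count takes the midpoint average; a single frame has
median 0; ties break to the lowest frame index. These conventions are
stated because the verbal rule "lowest median RMSD to all other frames"
does not pin them down.

## SPR kinetics and cooperativity

Binding follows the 1:1 Langmuir model. Association:
`R(t) = R_eq (1 − e^{−(k_on C + k_off) t})` with
`R_eq = R_max C/(C + K_D)`; dissociation decays exponentially at
`k_off` from the end of contact. The closed form is verified in the
tests against an independent numerical ODE integration of
`dR/dt = k_on C (R_max − R) − k_off R`. Injection designs mirror the
two assay formats: binary (120 s contact, 180 s dissociation, 10-point
2-fold dilutions) and ternary pre-mix (400 s contact, 600 s
dissociation). The stated ternary design "4-point 2-fold serial
dilution, 1 µM to 62.5 nM" is internally inconsistent — spanning those
endpoints in 2-fold steps takes five concentrations — and the package
honours the endpoints, emitting five.

`fit_kinetics()` fits all cycles globally with shared `k_on`, `k_off`,
`R_max` by Levenberg–Marquardt on log-parameters (positivity without
constraints). Initialisation is deterministic so convergence is
reproducible: `k_off` from per-cycle log-linear regressions of the
dissociation tails (median slope), `k_on` from the slope of the
observed rate versus concentration, `R_max` back-computed from the
largest plateau. Standard errors come from the residual variance and
the Jacobian at the optimum (delta method back to the natural scale).
The fit warns when fewer than two concentrations or a ≤ 4-fold span
make the problem ill-conditioned. Mass-transport limitation, drift,
bulk refractive-index jumps, and two-state binding are not modelled;
noise is i.i.d. Gaussian. The ternary format is treated as effective
1:1 binding of the pre-formed PROTAC:target complex to the immobilised
ligase, which matches the near-saturating pre-mix design; partial
occupancy of the pre-mix is out of scope.

Derived quantities: `K_D = k_off/k_on`, `t_1/2 = ln 2 / k_off`, and
`α = K_D(binary)/K_D(ternary)` with classification positive / neutral /
negative. Computing t₁/₂ as ln 2/k_off is self-consistent for one of
the published compound rows (0.0085 s⁻¹ → 81.5 s, printed 81 s) but not
for the others (e.g. 0.0084 s⁻¹ → 82.5 s against a printed 120 s),
suggesting those half-lives came from instrument-software fits rather
than the first-order formula; only the self-consistent row is used for
verification, and the discrepancy is documented here rather than
papered over.

## Synthetic data: what it emulates and what it does not

The generators produce every input with ground truth known by
construction:

* `make_toy_ligand()` — four collinear carbons with alternating
  1.21/1.37/1.21 Å bonds (end-to-end 3.79 Å), capped by rigid planar
  6-carbon rings standing in for warheads. Six-atom planar rings are
  the smallest rigid bodies giving a well-conditioned superposition.
* `make_toy_protein()` — residues as rigid local clusters (N, CA, C, O
  plus pseudo-sidechains, 2.6 Å spacings) on a self-avoiding random
  walk, so a toy protein never self-clashes at the 2.4 Å cutoff and
  every clash in a scene is a planted one.
* `plant_ternary_scene()` — the key construction. Complex B carries a
  backbone probe atom on a circle of radius 20 Å about the linker axis;
  complex A carries static backbone blockers at every *non*-designated
  grid angle on the same circle. Aligning B onto the conformer at angle
  θ sweeps the probe to angle θ: at a non-designated angle it lands on
  a blocker (backbone clash), at a designated angle the nearest blocker
  is a full grid step — a 3.5 Å chord at the 10° grid — safely outside
  the 2.4 Å cutoff. Protein bodies sit ±60 Å along the axis, far from
  everything. Planting is geometric construction plus post-hoc
  verification, not rejection sampling: before a scene is returned its
  truth is confirmed twice, by an independent brute-force distance scan
  on directly rotated coordinates and by the real alignment + screening
  pipeline. A failed check raises an error, so downstream tests can
  never pass against an unverified truth.
* `make_sensorgram_dataset()` — one simulated cycle per concentration
  with per-cycle seeds derived from the dataset seed; the generating
  parameters travel with the data.

All generators are pure functions of their seed and parameters
(bitwise reproducibility). What the synthetic data does *not* emulate:
real protein folds and packing densities, crystallographic solvent,
partial occupancy and disorder, correlated SPR artefacts
(mass transport, drift, bulk jumps). Passing tests therefore
demonstrate the correctness of the geometry, counting, selection, and
fitting machinery under the stated model assumptions — not the
biological accuracy of any particular predicted complex.

## Numerical choices and degenerate inputs

* Tolerances: rotation orthonormality 1e-8; linker collinearity 5°;
  conformer rigidity asserted to 1e-6 Å; clash boundary strict at the
  cutoff.
* Alternate locations: highest occupancy wins, ties go to altloc 'A',
  then first encountered — the common crystallographic convention.
* Hydrogens are dropped at parse time by default (the clash rule is a
  heavy-atom rule); a flag retains them.
* Backbone is `{N, CA, C, O, OXT}` of polymer (ATOM) records; HETATM
  atoms are never backbone.
* Empty selections are valid views; an empty structure cannot be
  written; a trajectory fully consumed by the equilibration filter
  warns and returns empty, and the pipeline wrapper turns that into an
  actionable error naming the discard setting.
* Kabsch with exactly planar point sets is fine (the rotation is still
  unique for labelled points); collinear sets are rejected.

## Problem sizes

The test suite and acceptance script run at sizes chosen to exercise
every code path with comfortable margins: planted scenes with ~40-atom
protein bodies per side (the census behaviour is size-independent and
the two census paths are cross-checked on randomized scenes up to ~80
atoms/side), trajectories of 5–20 frames for the medoid oracle, and
20 replicate SPR fits at 2% of R_max noise on the 5-cycle ternary
design sampled at 2 s. These sizes are the package's own choices for
fast, deterministic verification; all operations accept arbitrarily
larger inputs.

## Reproducing the published screen on real structures

The full reproduction — the 4-of-36 and 23-of-36 viable counts —
requires the BRD4^BD1 and CRBN/DDB1 crystal structures from the PDB and
reconstruction of the PROTAC 3-D models, which this package does not
download or ship. The workflow is: `read_pdb()` both complexes;
build the PROTAC with its warhead/linker partition via `diyne_ligand()`;
write explicit warhead atom maps; then `run_scan()` with the census
toggles (`include_ligand`, `selection_a`/`selection_b` for the
accessory chain) — reporting which toggle combination reproduces the
counts. Because the accessory-chain and ligand-census questions are
genuinely open, both switches exist and are recorded in the scan
summary's provenance block.

## Known limitations

* Single-axis torsion scan only; flexible linkers are out of scope.
* No force-field energy ranking of conformers or interface scoring —
  the screen is purely steric.
* The toy minimizer is a semantics test instrument; it makes no claim
  to physical energetics.
* SPR fitting assumes the 1:1 model and i.i.d. Gaussian noise; vendor
  instrument formats are not parsed.
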