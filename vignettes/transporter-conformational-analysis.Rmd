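---
title: "Quantifying alternating-access conformations of NSS-fold transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alternating-access conformations of NSS-fold transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transportcv)
```

## The model

Neurotransmitter-sodium-symporter (NSS) fold transporters alternate between
outward- and inward-facing conformations. The mechanical picture this
package quantifies is the rocking-bundle model: a quasi-rigid four-helix
bundle (TM1, TM2, TM6, TM7) tilts against a scaffold (TM3–TM5, TM8–TM10),
and because TM1 and TM6 are unwound at their centres, their intracellular
halves — above all TM1a — can additionally hinge away from the bundle. The
package reduces a trajectory to a small set of geometric observables that
are monotone reporters of this transition, and then classifies frames in a
two-dimensional conformational plane.

### Collective variables

Each membrane face gets a scaffold anchor and a bundle anchor: the centre of
mass of the Cα atoms of the third and fourth residues from the relevant end
of each member helix. The counting convention treats the terminal residue as
the first, so a helix spanning residues 100–120 contributes residues
117/118 at its C-terminal end and 102/103 at its N-terminal end. Residues
one and two from the end are deliberately excluded because helix termini
fray; this offset is configurable (`offsets`) but the default `c(3, 4)` is
the convention the rest of the package assumes. The collective variable is
the Euclidean distance between the two anchors, computed within the frame,
so it is invariant under global rigid motion — property-tested, not assumed.
The standard group membership for the fold is exported as `nss_groups()`.

Opening of the cytoplasmic permeation route is measured independently as the
total solvent-accessible surface area of a configured set of
pathway-lining residues. Using two observables with different failure modes
(a distance between ~16 Cα atoms; an occlusion integral over side chains)
is what makes the 2D classification robust: local rearrangements can raise
SASA briefly without the faces actually separating, and the plane separates
those events from genuine opening.

### SASA engine

`shrake_rupley()` implements the classical test-point algorithm: each heavy
atom's sphere is expanded by the probe radius (default 1.4 Å, a water
molecule), `n_points` near-uniform lattice points are placed on it via the
deterministic golden-spiral construction, and a point is exposed if it lies
outside every neighbouring expanded sphere. Per-atom SASA is the exposed
fraction times the expanded-sphere area. Defaults: 960 points, Bondi radii
(C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å, 1.70 Å for anything else),
hydrogens excluded both as surfaces and as occluders so results are
identical for structures with or without explicit hydrogens.

Two numerical details are worth stating. Exactly coincident atoms are
counted once: the later atom in file order is treated as fully buried,
which keeps the degenerate case finite and deterministic. And the occluder
*context* is explicit: `"monomer"` occludes with all atoms of the chains
spanned by the measured set (protein plus that chain's HETATM ligand/ion),
so a dimer partner does not artificially bury an interface residue, while
`"full_frame"` uses every heavy atom. The engine is validated against the
isolated-sphere and two-sphere spherical-cap closed forms, a Monte-Carlo
surface-sampling oracle, lattice-refinement convergence (960 vs 3840
points within 2 %), and a monotone-occlusion property (removing an occluder
can never decrease another atom's area).

### Superposition, RMSF, kink, ion displacement

Superposition is SVD-based Kabsch with the determinant correction that
forbids reflections; collinear point sets are refused (the rotation about
the line is undetermined), with the degeneracy threshold at `1e-8` of the
leading singular value. RMSD series align on one selection and measure on
another without re-fitting — the standard recipe for ligand RMSD after Cα
alignment. RMSF aligns all frames to the first, forms the mean structure,
re-aligns once onto that mean, and reports per-atom root-mean-square
deviations; iterative re-alignment to convergence changes nothing at test
precision and a single declared pass is reproducible.

A helix axis is the principal eigenvector of its Cα covariance, oriented
N→C. The TM1a kink angle is the absolute angle between the segment axis and
a fixed reference — the scaffold principal axis of the *first* frame — on
[0°, 90°]. Other definitions exist (tip vectors, per-turn fits); this one is
declared rather than claimed identical to any particular tool, and it is
rotation-equivariant and monotone in the toy generator's hinge angle, which
is the property the tests pin down.

Ion displacement is reported along the membrane normal after superposing
each frame onto the first on protein Cα atoms, signed so that negative
always means movement towards the cytoplasm; the `membrane_normal` entry in
the topology (+1 when +z points extracellular) makes the orientation an
explicit, checkable input rather than an assumption about the file.

### State classification

Reference structures (crystal conformations, or synthetic anchors) are
placed on the (pathway SASA, intracellular distance) plane by running them
through exactly the same measurement code. A frame is assigned to its
nearest reference after dividing each axis by a scale — by default the
per-axis range of the references, which keeps the Å² axis (hundreds) from
swamping the Å axis (units). Ties break deterministically to the earliest
reference in list order, and coincident scaled references with different
labels are an error rather than a silent coin flip. Classification is
invariant under any common rescaling of both axes. Boxplot summaries use
type-7 (linear-interpolation) quantiles so the five numbers are
bit-reproducible.

## The synthetic toy transporter

`build_toy_transporter()` places twelve 20-residue ideal helices
(2.3 Å radius, 100°/residue, 1.5 Å/residue) with the fold's topology: the
scaffold on a ring of radius 10 Å, the bundle on a small ring offset 6 Å to
one side, TM11/TM12 peripheral, odd-numbered helices running
intracellular→extracellular and even ones the reverse so every group
definition in `nss_groups()` lands on the correct membrane face. Each
residue carries a Cα and one pseudo side-chain heavy atom 1.5 Å radially
inward; designated residues carry the atom names the gate presets expect.
A pseudo-ligand sits at the bundle centre and a pseudo-ion descends 0.2 Å
per degree of hinge, emulating intracellular sodium release at full opening
(−6 Å at the default 30° maximum).

Two deliberate geometric choices:

- **TM1 packs inward.** TM1 sits 2 Å from the bundle centre rather than on
  the bundle ring, so in the closed state its intracellular half lies
  against TM6b across the pathway. The hinge then rotates TM1a rigidly
  about its split-point Cα, swinging the tip outward by over 7 Å at 30°.
  This makes pathway SASA genuinely occlusion-driven: it rises
  monotonically from ~214 Å² to ~326 Å² across the schedule because
  contacts are broken, not because atoms merely drift apart.
- **The rock is a sway.** The whole bundle rocks by
  `rocking_angle × θ/θmax` about the membrane-parallel axis aligned with
  the scaffold→bundle direction. About that axis, the rock moves both
  bundle faces *perpendicular* to the separation vector, so it perturbs
  both face distances only at second order (~0.04 Å at the default 5°),
  while the TM1a hinge moves the intracellular anchor along the separation
  (~1.2 Å). That reproduces the fold's signature asymmetry — the
  intracellular face opens, the extracellular face holds — at the default
  parameter values. A rock about the perpendicular axis would move the
  extracellular anchor by ~0.9 Å and destroy the asymmetry, which is why
  the axis choice is part of the model, not a free knob.

Schedules: `linear_open` (a ramp to `hinge_angle_max`), `hold_closed`,
`hold_open`, and `two_state`. Noise is i.i.d. Gaussian per coordinate from
one seeded generator — the simplest model under which
classification-accuracy-versus-noise curves are interpretable. The default
study conditions are 50 frames, 0.1 Å noise and a 30° maximal hinge.

What the toy does *not* emulate: sterics, a force field, lipids or water,
realistic side chains, sequence, or dimer contacts. Passing tests therefore
demonstrate that the measurement pipeline recovers known geometry under
noise — not that any particular biological system behaves this way. The
quantitative magnitudes (a ~1.2 Å intracellular opening; SASA in the low
hundreds of Å²) are scaled-down analogues of the real fold's transition,
where the intracellular face separates by several Å between outward- and
inward-facing crystal forms.

```{r example}
params <- synthetic_params(n_frames = 20, noise_sigma = 0.1, seed = 7,
                           schedule = "linear_open")
gen <- generate_trajectory(params)
refs <- reference_points(toy_anchor_structures(params))
states <- classify_trajectory(gen$trajectory, gen$topology, refs)
glance(states)
```

```{r plane, fig.width = 6, fig.height = 4}
autoplot(states)
```

## Working with real structures

Real inputs are oriented, whole-molecule multi-model PDB files (the package
does no periodic-boundary imaging and parses no binary MD formats). TM
helix ranges for crystal structures are taken from their HELIX records via
`helix_records()` and mapped to TM identities with `assign_tm_ranges()` —
the mapping and the TM1/TM6 unwound-centre split points must be curated by
the analyst, because deposited annotations do not carry transmembrane
assignments. For hSERT-family homology models the package ships the
gate-distance presets (`hsert_gates()`) and the published
intracellular-pathway and aromatic-lid residue identities belong in the
user's topology file; helix ranges are user input by design, since no
deposited annotation defines them and silently guessed ranges would shift
every collective variable.

## Numerical choices and test scale

Tolerances and sizes used by the test-suite and the acceptance script,
chosen as the package's own study conditions: superposition invariance to
1e-9 Å over 100 random point sets and agreement with an
exhaustive-rotation oracle to 1e-4 Å on planar sets (where proper 3D
rotations include in-plane reflections — the oracle searches both
families); SASA closed forms to 1 %/1.5 % and the Monte-Carlo oracle (1e5
points/atom) to 3 %; ground-truth recovery over 20 seeds of 50-frame,
0.1 Å-noise trajectories (mean Spearman ≥ 0.95); the classification sweep
over noise levels 0.1/0.5/1/2 Å with 20 seeds and short held trajectories;
and byte-identical reruns for pipeline determinism. The per-frame SASA of a
~25-atom residue set against ~480 occluders costs roughly a millisecond per
atom at 960 lattice points, so all of the above completes in minutes on a
single core.

## Known limitations

- Only fixed-column PDB input; no PSF/DCD/XTC, no bond perception,
  insertion codes are passed through but not interpreted.
- Altloc handling keeps blank/'A' only.
- The kink-angle definition is one of several reasonable ones; compare
  absolute values across tools with care.
- SASA context includes at most one chain's HETATMs as occluders in
  monomer mode; lipids and waters, if present in the file, count as
  occluders only in `full_frame` context and only as generic elements.
- Classification is nearest-reference on a plane: it carries no kinetic or
  free-energy meaning, and with two anchors every frame is labelled one or
  the other.
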