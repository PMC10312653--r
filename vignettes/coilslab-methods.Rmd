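---
title: "coilslab: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coilslab: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

coilslab studies whether coiled-coil (CC) domains are sufficient to drive
liquid-liquid phase separation (LLPS) of proteins, using a coarse-grained
associative-polymer representation. A protein is an alternating sequence
of *coil segments* — helical stickers standing in for CC domains — and
*linker segments* — disordered, inert spacers. Every residue is one bead
centred at the C-alpha position, so a 3-coil-2-linker protein with the
default segment lengths (32-residue coils, 25-residue linkers) is a
146-bead chain. Two kinds of multivalency are tunable:

* **polymeric multivalency** — the number of coil segments per chain
  (`make_coil_protein(n_coils, ...)`), and
* **multimeric multivalency** — how many partners one coil can engage at
  once (`multimer_mode("dimer" | "trimer" | "tetramer")`).

Four simplifying assumptions shape the energetics: coils are held
helical regardless of binding state (no folding-upon-binding); linkers
relax into disordered spacers; protein–protein attraction exists *only*
between coil segments; and linker beads interact with everything through
excluded volume alone, i.e. they are indifferent between solvent and
protein.

### Bonded terms

Pseudo-bonds, pseudo-angles and periodic pseudo-torsions (multiplicity
1) hold the chain geometry. Their equilibrium values are the internal
coordinates of the ideal C-alpha helix used by the structure builder
(rise 0.15 nm/residue, twist 100 degrees/residue, helix radius 0.23 nm;
`helix_internal_geometry()` gives bond 0.383 nm, angle ~91.8 degrees,
torsion ~49.8 degrees). Coil force constants default to bond
8000 kJ/mol/nm^2, angle 200 kJ/mol/rad^2, torsion 30 kJ/mol — stiff
enough that an isolated coil stays helical on the 100 ns scale at 293 K.
Linker segments use the *same* equilibrium values with all force
constants divided by 100, which lets linkers leave the initial helix and
behave as flexible spacers while remaining connected chains. A bonded
term takes coil parameters only when every bead it spans lies in one
coil segment; junction-crossing terms are soft.

### Nonbonded terms

All pairs interact through a truncated-and-shifted Lennard-Jones
potential, cut off at 1.1 nm with the shift making the energy exactly
zero and continuous at the cutoff. One bead diameter (sigma = 0.47 nm)
and one mass (109 amu, the average residue mass) are used throughout.
Pairs that are not eligible for attraction use a small excluded-volume
epsilon (0.1 kJ/mol); eligible sticky pairs use the mode's coil-coil
strength: 5.5 kJ/mol for dimer-forming coils, 4.0 kJ/mol for trimer- and
tetramer-forming coils (the trimer value is not separately documented in
the source material for this model family; we use the same reduction as
the tetramer, exposed as a parameter). Nonbonded exclusions cover the
1-2, 1-3 and 1-4 pairs spanned by the bonded terms.

### The maximally specific interaction scheme

Attraction exists only between sticky beads of coils that carry the
*same* `coil_type_id` on *different* chains. In the standard
architectures every coil position gets its own type, so coil *i* of one
chain can only bind coil *i* of another chain, and no intrachain
coil-coil attraction is possible at all. In the engine this is a
structural property of the energy function (equal nonzero interaction
group *and* different chain id), not a post-hoc filter; in the exported
GROMACS topologies the same rule is carried by per-type
`nonbond_params` plus intramolecular exclusions.

### How multimer valence is enforced

The valence mechanism was genuinely open and took three design
iterations, all run through the desk-scale multimerization assay below:

1. *a/d two-column face* ({0,3} heptad positions, columns 60 degrees
   apart around the helix). Natural-looking, but a 60-degree face turned
   out wide enough for **two** partner helices to dock on its two
   columns simultaneously (their axes sit ~0.95 nm apart — exactly bead
   contact distance), so even "dimer-forming" coils behaved divalently
   and the census was dominated by trimers and open chains.
2. *Single-column faces* ({0} alone). Valence is strictly capped, but
   five contacts spread over a 4.7 nm column bind too weakly/slowly:
   at 293 K and desk-scale durations essentially everything stayed
   monomeric.
3. **Compact two-column faces** (the shipped default): one face is a
   pair of near-axial sticky columns only 40 degrees apart — {0,4} at
   0/40 degrees, plus {1,5} and {2,6} for the second and third face
   (9 sticky beads per face on a 32-residue coil). Angularly this caps
   valence: a second partner docking on the same face would have to
   put its helix axis ~0.65 nm from the first partner's, far below
   bead contact distance. Dimer-mode coils carry one face, trimer-mode
   two, tetramer-mode three.

A fourth element closes the mechanism. Full-length columns alone leave
an *axial* leak: a partner can dock in shifted register on part of a
face, leaving the rest free for a third coil, so dimer-mode systems
slowly coarsen into chained multimers. (Confinining the sticky beads to
the coil core — `sticky_core_fraction < 1`, still exposed — suppresses
the chaining but weakens docking so much that trimer- and
tetramer-mode systems stop forming their multimers at desk timescales.)
The shipped fix is **register sub-typing**: within each face, sticky
beads carry a sub-type given by the parity of their 7-residue period,
and attraction requires matching sub-types. An in-register partner
pairs like with like at full strength; a half-period register shift
faces mismatched sub-types and gains nothing, so docking is pinned to
the in-register pose and staggered chaining is suppressed without
weakening the intended interfaces. Two side effects are accepted and
documented: a full-period (two-turn) shift still matches on part of
the column, so a minority off-target multimer population survives —
consistent with the "moderate control" over multimerization this model
family itself reports — and, because an antiparallel partner reverses
the parity sequence, the scheme carries an implicit preference for
parallel docking (orientation specificity is otherwise out of scope
for the framework).

Face 1 beads are classed `coil_sticky`, additional faces
`multimer_driver`; all sticky beads of a coil share its interaction
type and strength.

## The dynamics engine

`run_langevin()` integrates Langevin dynamics with the BAOAB splitting —
the "sd" leapfrog Langevin scheme of GROMACS samples the same NVT
ensemble; we document this as an equivalence of ensembles, not an
identity of trajectories. Defaults follow the protocol's common
parameters: 25 fs step, friction 0.2 / ps, centre-of-mass translational
velocity removed every 10 steps. Gaussian noise comes from a private
seeded generator, so trajectories are bit-reproducible for a given seed
and build. With `friction = 0` the scheme reduces to velocity Verlet,
which the tests use for energy-conservation checks.

Numerical choices:

* **Neighbour list** — cell list plus Verlet buffer (default skin
  0.3 nm), rebuilt whenever any bead has moved more than half the skin
  since the last build, so no eligible pair inside the cutoff is ever
  missed (the same concern that motivates the strict
  `verlet-buffer-tolerance = 1e-7` written into the exported MDP files).
* **Force cap** — near-overlapping nonbonded pairs have their pair force
  capped (default 2000 kJ/mol/nm), so a pathological start degrades
  gracefully instead of producing NaNs. The cap engages only below
  ~0.3 nm separations that equilibrium dynamics never samples, and it
  is deliberately smaller than the force needed to stretch a bond
  appreciably — a harder cap can tear chains apart when box compression
  creates deep overlaps. Pair *energies* are never capped.
* **Minimization** — GROMACS-style steepest descent (trial step scaled
  so the largest bead moves by the current step size, step grows 1.2x on
  success, shrinks 5x on failure), default tolerance max force
  < 50 kJ/mol/nm, initial step 2 pm.
* **Degenerate inputs** — zero-bead systems are rejected at the I/O
  layer; linear angle/torsion geometries fall back to guarded
  denominators; NaN coordinates abort the run, returning the frames up
  to the last valid sample.

### The NPT-compression stand-in

The at-scale protocol compresses the packed box along z in the NPT
ensemble (Parrinello-Rahman, semi-isotropic z-only, 1 bar,
compressibility 3e-4 1/bar, 5 ps coupling, 200 ns at 150 K). A barostat
is deliberately *not* re-implemented in the desk engine: `compress_z()`
instead rescales the box z-length and the chain centres of mass in
stages (molecules move rigidly, bonds untouched), with a short Langevin
relaxation at 150 K between stages and a final minimization. This is an
explicit approximation adequate for generating a slab desk-side; the
faithful NPT run is what the exported GROMACS files encode.

## The slab protocol

`run_slab_pipeline()` chains the full procedure: single-molecule
minimize + 500 ps NVT equilibration + NVT production; random selection
of 5 conformations from the equilibrated tail (`select_configurations`);
random rigid packing to the coil budget (450 coils standard; 448 for
4-coil proteins since 112 x 4 = 448) with a 1.0 nm inter-chain
tolerance; staged z-compression to ~15% of the start length; expansion
to the final z (150 nm at scale) with whole-molecule unwrapping and the
slab recentred via a circular mean; NVT temperature equilibration; NVT
production. `prepare_slab_run()` exports the same pipeline as GROMACS
file sets (4 temperatures x 3 replicates by default, distinct seeds per
replicate, manifest in YAML) for the 20 microsecond at-scale runs that
are out of desk reach.

**Equilibration detection.** The protocol's criterion — centre and edge
densities both "stable" — is visual in the source material, so it is
operationalized: the trajectory is equilibrated from the earliest time
t\* such that over every subsequent sliding window (10 samples by
default) the fitted linear change across the window is below 2% of the
window mean, for both series. Both knobs are exposed; the detector is
monotone (appending stable data never moves t\* later) and is tested
against an exhaustive-scan oracle.

## Analyses and conventions

* **Density profiles** — number density in 2 nm slices along z,
  time-averaged; replicate aggregation is mean with *population* sd
  (n = 3 replicates). Slices conserve the mean bead count to 1e-9
  relative; a box length that is not a multiple of the slice width
  truncates (and flags) the last slice.
* **Coexistence densities** — dense = mean slice density in the 70–80 nm
  window, dilute = mean over 1–35 and 115–150 nm combined; for other box
  lengths the windows scale proportionally.
* **Binodals** — per-temperature replicate mean ± sd for both branches;
  a point is *melted*, and omitted from the binodal, when the dense and
  dilute mean ± sd intervals overlap.
* **Molecular clusters** — two molecules are linked if any
  inter-molecular bead pair is within 0.9 nm (minimum image); clusters
  are single-linkage connected components, sampled every 10 ns of
  equilibrated trajectory at scale. Probabilities are over *clusters*
  (one triple plus two singles gives P(3) = 1/3), matching the
  normalized cluster-count populations convention.
* **Multimer census** — coils on different chains are bound when at
  least `min_contacts` sticky-bead pairs are within 0.9 nm; an n-mer is
  a connected component of n coils, and fractions are coil-weighted and
  time-averaged. The underlying at-scale criterion is not public;
  reusing the 0.9 nm molecular cutoff with a small contact count is the
  package's choice, and both knobs are exposed (a sweep of the contact
  count from 3 to 10 barely moves the result, because docked coil pairs
  share well over ten contacts). Two normalizations are reported:
  `fractions` over *all* coils (monomers included, summing to 1) and
  `multimer_fractions`, the composition of the multimer species present
  (renormalized over bound coils) — the latter is what the package
  compares against reference multimer percentages, since monomers are
  not a multimer species.
* **LLPS calls** — LLPS requires *both* markers: dense/dilute ratio of
  at least 10 ("sharp density transition") and a largest cluster holding
  at least 90% of the chains ("nearly all of the proteins"); both
  thresholds are configurable since the qualitative criteria carry no
  printed numbers. A zero dilute density counts as an infinite ratio.
* **Rg / RMSD / KL** — mass-weighted radius of gyration; RMSD with
  optional Kabsch superposition; Gaussian-KDE Kullback-Leibler
  divergence in nats, Scott's-rule bandwidth
  (sigma-hat n^(-1/5)), trapezoidal quadrature on a 2048-point grid
  spanning both samples ± 3 bandwidths, q clamped at 1e-12 with a
  warning where it underflows.

## Synthetic data

The fixtures module generates data with known ground truth so every
analysis operation is testable without dynamics: slab trajectories with
prescribed dense/dilute densities (Poisson frame-count noise, straight
rod "chains"), cluster frames with exact compositions (intra-cluster
spacing below the cutoff, inter-cluster gaps above twice the cutoff),
and centre/edge density series that are stable, drifting, or stepped at
a known index. Fixtures emulate the *statistical* structure the
analyses consume — densities, connectivity, stationarity — and none of
the physics: no excluded volume, no realistic conformations, no
correlation between frames. Passing fixture tests therefore validates
the analysis operators, not the force field.

## Desk-scale study sizes

The package's own validation runs are sized for a single CPU:

* *Multimerization assay* — 10 copies of the 3-coil protein (1460
  beads) in a 14 nm cubic box at 293 K, 8 ns of production sampled every
  100 ps; the census is a composition over simulation time, averaged
  over the whole run from its monomeric start. Dimer-mode dominance is
  strongest during and shortly after association and then slowly erodes
  as register-shifted chains coarsen, so the composition-over-time
  average carries a genuinely large seed-to-seed spread at this
  miniature scale. Maturing trimers into tetramers is the slowest
  process in this model family (at scale such systems need on the order
  of 10 microseconds), so the desk-scale tetramer census
  over-represents trimers relative to tetramers.
* *Slab coexistence* — 6 copies of the 3-coil protein in an
  8 x 8 x 30 nm start box, compression to 15%, expansion to z = 45 nm,
  1 ns NVT, 4 ns production, analysis over the last half.
* *Equipartition* — 300 non-interacting beads, 1.5 ns.

These are miniatures of the at-scale protocol (450 coils, 25 x 25 x
150 nm, 20 microseconds, triplicates at four temperatures), which the
exporters emit for an external engine. Desk-scale results are
qualitative: orderings (dimer vs trimer vs tetramer dominance, cold vs
hot density ratios) are meaningful; absolute coexistence densities are
not converged at these sizes.

## Known limitations

* No residue-specific chemistry; linkers carry no attraction at all.
* Parallel vs antiparallel coil orientations are not distinguished.
* Coils cannot unfold; the free-energy cost of folding-upon-binding is
  absent, which shifts phase equilibria relative to real CC proteins.
* Valence control is geometric and imperfect by design — dimer-mode
  systems still show minority trimer populations from face-edge
  contacts, mirroring the imperfect specificity of the model family
  this framework reproduces.
* The desk engine is serial; at-scale slabs must go through the
  exported GROMACS inputs.
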