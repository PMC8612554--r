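---
title: "Methods: geometry, energetics and synthetic validation in pocketdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, energetics and synthetic validation in pocketdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketdyn)
```

`pocketdyn` analyses MD snapshots of an RNA aptamer–ligand complex: who
stacks against the ligand, which hydrogen bonds persist, how wide the
pocket doors are, where ions sit, what the binding free energy components
are, and through which door the ligand leaves. This vignette documents the
definitions, the numerical choices, and what the synthetic validation does
and does not establish. Units are fixed throughout the package: lengths in
Å, energies in kcal/mol, times in ps; residues are referred to by their
1-based author numbering (G5, C15, ...).

## Base stacking: the rectangle-projection metric

A nucleobase is classified per frame as "in" (stacked) or "out" relative to
the ligand rings:

1. A least-squares plane is fitted to the ligand ring atoms (SVD of the
   centered coordinates; an error is raised when the atoms are colinear).
2. The ring atoms are projected into the plane and expressed in the
   in-plane principal axes of the projected points. Principal axes make the
   construction invariant under global rotations and reproducible between
   frames; because a perfectly regular polygon has degenerate axes, the toy
   ligand ring is built slightly elongated.
3. The bounding box of the projected ring atoms is expanded by a margin
   (default 0.5 Å) on every side.
4. The base's ring-center projection is tested against this rectangle.
   A projection exactly on the edge counts as "in" — a measure-zero tie,
   fixed for determinism. The vertical distance is the unsigned distance of
   the base center from the ligand plane.

The per-trajectory summary reports the in-fraction and the mean vertical
distance over "in" frames only; with zero "in" frames the mean is reported
as `NA` with `n_in = 0` rather than a number. The classifier is verified
against an independent corner-based point-in-polygon oracle on 10^4 random
configurations and is tested to be invariant under rigid transforms.

Whether the original rectangle construction was axis-oriented per frame or
held fixed is not derivable from its verbal description; this implementation
recomputes the principal-axis rectangle every frame and states so here.
Which atoms constitute "the ligand rings" is configurable; head-group atoms
are excluded from the default toy selection.

## Hydrogen bonds

A bond is formed in a frame iff donor–acceptor distance < 3.5 Å and
donor–H–acceptor interior angle > 120° (both strict, both configurable).
Rows that list two alternative acceptors for one bond are expressed as
`hbond_group()`: the group is formed when any member is. Occupancy is the
fraction of frames formed. Stricter cutoffs can only lower occupancy; this
monotonicity is a tested property.

## Pocket frame, collective variables and densities

* **Pocket center**: geometric center of the heavy atoms of the six
  pocket-lining residues (the field's sources say only "center of the
  binding pocket"; heavy-atom geometric center is the stated choice here,
  and the ligand center is defined the same way).
* **Bisecting plane**: through three named atoms; the normal is the z-axis
  with its sign fixed so that the midpoint of the front-marker atoms (the
  C1' pair of the front-door residues) has z > 0. A front marker lying in
  the plane is an error demanding explicit orientation rather than a silent
  sign choice.
* **CV trace**: r = |ligand center − pocket center|, z = (ligand center −
  plane origin)·normal, recomputed per frame — the analysis lives in the
  aptamer's moving frame.
* **Θ angle**: one plane per base (ring atoms), Θ = mean over all
  cross-group pairs of the acute angle between plane normals, range 0–90°.
* **Distances**: per-frame Euclidean distances with mean, SD and a
  unit-area histogram (default bin 0.2 Å).
* **Grid densities**: counts of selected atom positions on a regular grid
  (default spacing 0.5 Å — the upstream density-tool settings are not
  published, so the default is stated here and configurable), auto-sized to
  the bounding box + 3 Å. Positions outside the grid go to an overflow
  tally so mass is conserved exactly. Optional Gaussian smoothing convolves
  with a normalized separable kernel and *expands the grid* by the kernel
  half-width, so smoothing also conserves mass (to 1e-9). Density peaks are
  26-neighbour local maxima above a configurable fraction (default 0.5) of
  the global maximum; site occupancy is the fraction of frames with any
  selected atom within a radius (default 2 Å) of a reference site.

## Unbinding and rebinding events

A two-state machine over the r trace: starting IN (bound complexes start
bound), the first frame with r ≥ 9 Å emits an unbinding event and switches
to OUT; in OUT, the first frame with r ≤ 1 Å emits a rebinding event and
switches back. Threshold crossings are inclusive (the verbal rule
"increase of r to 9 Å" does not specify strictness; ≥/≤ is the documented
choice). Because heavily biased simulations expel the ligand almost
immediately, the first unbinding event is discarded by default and counting
starts at the subsequent rebinding event. The door is front iff z ≥ 0 at
the event frame (the z = 0 tie is measure-zero and assigned to front for
determinism). No smoothing and no minimum dwell time are applied — none are
stated by the sources this rule set follows. Events therefore strictly
alternate within a trajectory; the tabulator validates this invariant on
externally supplied lists.

## MM-PBSA energetics

The binding free energy is assembled per

ΔG_bind = ΔE_ele + ΔE_vdW + ΔG_pol + ΔG_nonpol − TΔS,

with the single-trajectory protocol: complex, receptor and ligand states
share coordinates, so the gas-phase terms reduce to cross-terms.

* **ΔE_ele**: k_C Σ q_i q_j / r_ij over all RNA×ligand pairs, no cutoff.
  The Coulomb constant 332.0636 kcal·Å/(mol·e²) (AMBER convention) is not
  printed by the sources; it is exposed in the configuration.
* **ΔE_vdW**: 12-6 form in Rmin/ε parameters with Lorentz–Berthelot
  combination — the convention of the force-field ecosystem the parameters
  come from.
* **ΔG_pol**: finite-difference solution of the linear
  Poisson–Boltzmann equation at zero salt (i.e. the Poisson equation) —
  see below.
* **ΔG_nonpol**: γ·SASA + β with γ = 0.00542 kcal/mol/Å² and β = 0.92
  kcal/mol. SASA uses probe-inflated radii (probe 1.4 Å) and a
  deterministic Fibonacci sphere point set (default 960 points/atom),
  validated against the isolated-sphere closed form (4π(r+p)²) and a
  spherical-cap formula for two overlapping spheres.
* **−TΔS**: vibrational entropy as a sum of quantum-harmonic-oscillator
  mode contributions over supplied positive frequencies, plus
  Sackur–Tetrode translational and rigid-rotor rotational terms. Normal
  modes themselves (Hessian construction, vacuum minimization) are out of
  scope — frequencies are inputs.
* **Replicates**: components are averaged per replicate, then mean and SEM
  (SD/√n) are reported across replicates; dH and dG_bind satisfy the
  assembly identities to 1e-9 by construction and by test.

### The Poisson solver

A cubic grid (default spacing 0.4 Å, default 5000 SOR sweeps at relaxation
1.9) covers the molecule plus padding (30 % of the molecular extent with a
probe-dependent floor; configurable). Charges are spread trilinearly to the
eight surrounding nodes. The dielectric boundary is the molecular
(solvent-excluded) surface built on-grid: nodes within (r_i + probe) of any
atom are tentatively solute, then every node within the probe radius of
solvent-accessible space is returned to solvent. The discrete erosion is
made deliberately conservative (over-reaching by half a voxel diagonal) and
the result is unioned with the exact van der Waals region, so convex parts
of the surface sit exactly on the atom spheres while reentrant crevices
remain filled. Face dielectrics between neighbouring nodes use a harmonic
mean weighted by the sub-grid boundary position estimated from the signed
distance to the nearest atom sphere (edge midpoint where that distance does
not change sign — reentrant parts). The Dirichlet boundary holds the
solvent-screened Coulomb potential of all charges. The reaction-field
energy is ½ Σ q_i (φ − φ_hom) with the homogeneous (ε = 1 everywhere)
reference solved on the same grid with the same charge spreading, so the
grid self-energy cancels exactly.

The solver runs a fixed sweep count rather than to a residual tolerance
(the iteration budget is part of the stated protocol); the maximum-update
history is attached to the result so non-convergence is visible, and a
warning is emitted when the residual grows. On a Born ion (q = 1 e, R =
2 Å, ε 1→80) the solver is within 0.4 % of the closed form at 0.4 Å
spacing, and the error decreases monotonically under 0.8 → 0.4 → 0.2 Å
refinement (a tested property).

### Per-residue decomposition

Only the enthalpic components are decomposed. ΔE_ele and ΔE_vdW decompose
exactly: each RNA residue receives its pair sums with the ligand, so
per-residue sums reproduce the totals to machine precision (tested).
ΔG_nonpol is decomposed through per-atom SASA differences scaled by γ, with
the ligand's share and the −β constant carried by a ligand row so the table
still sums to the total. ΔG_pol is optionally decomposed by charge
annihilation — zero one residue's charges, re-solve, difference — which is
well-defined and testable but is an approximation that does not sum exactly
to the total; it is off by default and flagged as such.

ΔG_exp = RT ln K_D uses R = 1.9872×10⁻³ kcal/(mol·K). The temperature
behind published ΔG_exp values is typically not printed; 300 K reproduces
them and is the default.

## The synthetic-data module

The toy complex is a rigid geometric stand-in for a six-nucleotide pocket:
a planar (slightly elongated) ligand ring at the origin; a stacking plate
1.7 Å above the ring plane and two plates 1.7 Å below (plate gap 3.4 Å, the
aromatic stacking distance); three in-plane pseudo-bases whose acceptor
atoms sit exactly at the configured donor–acceptor distance (2.9 Å, a
typical formed bond); and marker C1' atoms placed so the front and back
door distances equal their configured widths *by construction* (defaults
12.0 Å and 7.5 Å, the regimes reported for ligand-bound pockets). All atoms
carry charges, LJ parameters and PARSE-like PB radii from a bundled toy
table.

Programmed trajectories add Gaussian positional noise (default 0.1 Å per
coordinate) and switch discrete states — plate stacked/displaced, bond
formed/broken (acceptor moved to 4.5 Å, beyond the 3.5 Å cutoff), C15
parallel/orthogonal — with two-state Markov chains whose stationary
occupancies equal the programmed probabilities. Markov switching (rather
than i.i.d. frames) gives the trajectories autocorrelation, as real MD has;
the switching scale (default 0.5, lag-1 autocorrelation 0.5) is a program
knob. Consequently the correct 99 % sampling interval for a recovered
occupancy uses the effective sample size n_eff = n(1−λ)/(1+λ) with λ the
lag-1 autocorrelation; the recovery tests use exactly this interval rather
than the i.i.d. binomial one. Ion trajectories place each ion per frame at
a reference site (noise 0.3 Å) or uniformly in a bulk box with the
programmed probabilities.

### The well-tempered metadynamics toy

A 2D overdamped Langevin particle (Euler–Maruyama; timestep 0.005 ps,
diffusion 1 Å²/ps, so the per-step displacement SD is one fifth of the hill
width — stability over sophistication) moves in a landscape with a bound
well at the origin (depth 5 kcal/mol), a barrier shell at r = 4 Å crossed
by two angular channels (front along +x, default 3 kcal/mol; back along −x,
default 5 kcal/mol; 12 kcal/mol elsewhere; half-angle 30°), and a soft
harmonic outer wall beyond 11 Å mirroring the restraint that keeps a ligand
near the RNA in biased simulations. The channel term carries a radial
window r²/(r²+a²) so its torque vanishes smoothly at the origin. kT
defaults to 0.596 kcal/mol (300 K).

The bias acts on r. Every 500 steps (the deposit interval is not stated by
the protocol this mirrors; 500 is the package's documented default) a
Gaussian hill of width 0.5 Å is deposited with height 1.2·exp(−V_b(r) /
((γ−1)kT)) kcal/mol, γ = 15 — the well-tempered rule. The bias and its
derivative are accumulated analytically on a fine r-grid (width/10
spacing) and linearly interpolated, which keeps the per-step cost constant.
A step larger than five hill widths raises an integration error advising a
smaller timestep.

The barrier shell is two hill-widths wide (SD 2 Å). This width is a
physical design requirement, not a tuning knob: door classification is only
meaningful when a crossing particle is angularly equilibrated at the shell,
i.e. when the radial traverse time exceeds the angular relaxation time
there; a thin shell makes crossings ballistic and the exit door arbitrary.
With the default geometry, a 2 kcal/mol front/back asymmetry yields a
strong (≈85 %) front-door preference over dozens of events, consistent
with a first-passage picture, and this is what the acceptance suite checks
(≥ 70 % of ≥ 50 events).

For free-energy reconstruction checks a 1D variant runs the same
well-tempered scheme on a symmetric double well V(x) = B((x/x0)²−1)²
(B = 3 kcal/mol, x0 = 1.5 Å). After 2.5×10⁵ steps the estimator
F = −(γ/(γ−1))·V_bias matches the designed potential with RMS ≈ 0.25
kcal/mol over the sampled range (threshold 0.5), and the designed landscape
itself is cross-checked against a Boltzmann histogram of a long unbiased
run at a reduced barrier.

### What the toy does and does not establish

The generator emulates the *statistical structure* the analyzers must
recover — programmed occupancies with autocorrelation, geometric states
straddling the classification cutoffs, two-channel escape statistics — on a
rigid scaffold with isotropic noise. It does not emulate force-field
physics: no solvent, no thermostat, no correlated collective motions, no
realistic energetics (the toy's stacked plates sit inside LJ contact, so
its absolute interaction energies are meaningless even though every
decomposition identity holds). Passing tests therefore establish that the
analysis stack is correct and deterministic, not that any particular
biological system behaves this way.

## Problem sizes and determinism

Default validation sizes were chosen so the whole suite exercises every
stage at statistical power without waste: 5000-frame recovery runs
(sampling error ≈ 1–2 % on occupancies), 10⁴ random cases for the geometric
oracle, 12 × 1.5×10⁵-step metadynamics trajectories (≈ 60 unbinding
events), and 2.5×10⁵-step 1D reconstructions. Every stochastic function
takes an explicit integer seed; the same seed gives bit-identical
trajectories, hill logs and pipeline outputs (tested). The pipeline writes
a JSON run manifest (configuration echo, seed, versions, timings) so any
output is regenerable from the manifest alone.

## Known limitations

* The PB solver is linear and salt-free (appropriate for the zero-salt
  protocol it implements) and its per-residue polar decomposition is a
  charge-annihilation approximation.
* SASA and PB accuracy are set by the sphere-point count and grid spacing;
  defaults are validated on closed forms, but very large molecules would
  need finer control of grid padding and memory than the toy-scale defaults
  assume.
* The PDB reader keeps the first alternate location and rejects insertion
  codes outright — toy-scale scope, failing loudly rather than guessing.
* Binary trajectory formats (DCD/XTC) and mmCIF are not supported; inputs
  are multi-model PDB, TSV parameter tables and YAML configs.
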