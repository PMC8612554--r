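# pocketdyn

Analysis of binding-pocket dynamics and energetics for RNA aptamer–ligand
complexes from molecular-dynamics trajectories.

Small structured RNAs such as riboswitch aptamers recognise their ligands
through a compact buried pocket: two nucleobase "plates" stack against the
ligand rings while in-plane partners form a network of hydrogen bonds, and
ligands enter and leave through narrow grooves ("doors") on opposite sides
of the pocket. `pocketdyn` implements, as reusable R functions, the full
analysis stack such a study needs on top of saved MD snapshots:

* **Base stacking** by the rectangle-projection metric: a rectangle is drawn
  around the projected ligand ring atoms (expanded by a 0.5 Å margin on
  every side, oriented along the in-plane principal axes) and a nucleobase
  is "in" when the projection of its ring center falls inside; the reported
  summary is the in-fraction and the mean vertical distance over "in"
  frames.
* **Hydrogen bonds** with the standard geometric criterion (donor–acceptor
  distance < 3.5 Å and donor–H–acceptor angle > 120°), including OR-groups
  of alternative acceptors counted as one bond, and occupancy tables.
* **Pocket geometry**: named atom–atom distances with histograms, the
  pocket center, the pocket-bisecting plane with a front-positive normal,
  the collective variables *r* (ligand center to pocket center) and *z*
  (signed coordinate along the plane normal), the inter-base-plane angle
  Θ, 2D CV density maps, and 3D grid densities (OpenDX output) with
  reference-site occupancies.
* **Unbinding/rebinding events**: a two-state machine over *r* (unbind at
  *r* ≥ 9 Å, rebind at *r* ≤ 1 Å, first unbind discarded so counting starts
  at the first rebind), each event classified through the front door
  (*z* > 0) or back door (*z* < 0), tabulated per ligand.
* **MM-PBSA energetics**:

  ΔG_bind = ΔE_ele + ΔE_vdW + ΔG_pol + ΔG_nonpol − TΔS

  with cutoff-free Coulomb and 12-6 Lennard-Jones cross terms (Rmin/ε,
  Lorentz–Berthelot), a finite-difference Poisson solver (0.4 Å cubic grid,
  5000 SOR iterations, dielectrics 1/80, molecular-surface dielectric map
  from a 1.4 Å probe), the nonpolar model γ·SASA + β (γ = 0.00542
  kcal/mol/Å², β = 0.92 kcal/mol, Shrake–Rupley-style SASA), quantum
  harmonic oscillator / Sackur–Tetrode / rigid-rotor entropy terms,
  replicate means with SEM, per-nucleotide decomposition of the enthalpic
  components, and ΔG_exp = RT ln K_D.
* **Synthetic data**: a rigid toy pocket whose door widths and hydrogen-bond
  geometry are set by construction, trajectories with programmed
  (Markov-switched) stacking/H-bond/ion-site occupancies and a ground-truth
  state log, and a well-tempered metadynamics toy simulator (Gaussian width
  0.5 Å, initial height 1.2 kcal/mol, bias factor 15) on a two-channel
  escape landscape, so every analyzer can be validated against known truth.

The package is aimed at computational structural biologists who want the
analysis layer of such a study as tested, scriptable functions rather than
one-off scripts.

## Worked example

```r
library(pocketdyn)

toy <- build_toy_complex()          # rigid toy pocket, doors 12.0 / 7.5 A
sel <- toy$selections

prog <- occupancy_program(
  stacking_in_fraction = c(G5 = 0.95, G11 = 0.98, C16 = 0.97),
  hbond_occupancy      = c(U6 = 0.85, C15 = 0.90, A29 = 0.88))
sim <- simulate_bound_trajectory(toy, prog, n_frames = 2000, seed = 1)

stacking_summary(sim$trajectory, sel$ligand_ring, sel$plates$G5)
#> stacking: in-fraction 0.949 (1898/2000 frames), mean vertical 1.70 A

hbond_occupancy(sim$trajectory, sel$hbonds)
#>         label occupancy n_formed n_frames
#> U6   D1-U6:O4    0.8655     1731     2000
#> C15 D2-C15:O2    0.9060     1812     2000
#> A29 D3-A29:N1    0.8750     1750     2000

pot <- toy_potential_spec(front_barrier = 3, back_barrier = 5)  # kcal/mol
runs <- lapply(1:4, function(i)
  simulate_wt_metadynamics(pot, metadynamics_params(),
                           n_steps = 150000, seed = i))
events <- lapply(runs, function(r)
  detect_events(r$trace, r_unbind = 9, r_rebind = 1))
tabulate_events(events, rep("toy", 4))
#>   ligand unbind_front unbind_back rebind_front rebind_back
#> 1    toy           14           3           14           5
```

The programmed in-fraction (0.95) and bond occupancies (0.85/0.90/0.88) are
recovered within sampling error; with the front escape channel 2 kcal/mol
lower than the back, unbinding events exit predominantly through the front
door. An end-to-end pipeline over a YAML config (with TSV outputs and a run
manifest) is available as `run_pipeline()`; see
`inst/extdata/demo_config.yaml` and the thin CLI wrapper in
`inst/scripts/pocketdyn.R`.

MM-PBSA assembly works on any component table, e.g. reproducing a published
column:

```r
s <- mmpbsa_summary(data.frame(dE_ele = -32.93, dE_vdW = -32.42,
                               dG_pol = 33.77, dG_nonpol = -3.32),
                    TdS = -16.17)
energy_term(s, "dH")       #> -34.9
energy_term(s, "dG_bind")  #> -18.73
dg_from_kd(2.05e-9, 300)   #> -11.93  (kcal/mol)
```

## Documentation

The methods vignette (`vignettes/pocketdyn-methods.Rmd`) describes the
geometric definitions, the Poisson-solver numerics, the synthetic-data
model and its limitations, and the design decisions behind every default.
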