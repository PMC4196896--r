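# microswitchr

Tidy analysis of GPCR **micro-switch** dynamics from molecular dynamics
trajectories, built around the serotonin-receptor activation problem: two
receptors crystallised with the same agonist can favour different
signalling pathways (G protein vs β-arrestin), and the difference is
carried by a handful of conserved residues — the P-I-F motif at the base
of the ligand pocket, the D(E)/RY salt bridge and R3.50–E6.30 "ionic
lock" at the intracellular face, and Y7.53 of the NPxxY motif — together
with the rotational freedom of helix 6.

The package implements the complete measurement layer for that kind of
study:

* **Ballesteros–Weinstein numbering** (`bw_table()`, `select_atom()`):
  residues addressed as `H.PP` generic indices, resolved to atoms through
  a validated lookup table (consecutive-numbering invariant enforced).
* **Micro-switch classification** (`switch_series()`,
  `engagement_summary()`): per-frame distances for each switch, engaged
  iff the distance is *at or below* its threshold (9.5 Å for the
  F6.44/F6.41 activation distances, 5 Å for the ionic lock, 4 Å
  minimum-over-pairs for the D3.49–R3.50 salt bridge), and engagement
  percentages pooled frame-weighted across replicates.
* **Helix rotation** (`fit_axis()`, `rotation_series()`): the helix axis
  from Cα coordinates (PCA-initialised cylinder fit), per-frame rotation
  about it relative to a reference structure after core pre-alignment,
  with the 6.44–6.50 and 6.44–6.60 spans as presets.
* **Solvation and contacts** (`water_occupancy()`, `waters_near()`,
  `contact_frequency()`, `ligand_rmsd()`): bulk-normalisable
  water-occupancy grids (OpenDX export), mean water counts near a
  residue, heavy-atom ligand contact frequencies at a 3 Å cutoff, and
  ligand RMSD after receptor superposition.
* **Well-tempered metadynamics** (`read_hills()`, `reconstruct_fes()`,
  `label_states()`): multi-walker HILLS logs merged and rebuilt into the
  2D free-energy surface `F(s) = −γ/(γ−1) · V(s)` over the two
  connector-region distances (d1, d2), with activation-state regions
  labelled by the 9.5 Å threshold.
* **Synthetic ground truth** (`gen_switch_trajectory()`,
  `gen_rotating_helix_traj()`, `gen_solvated_box()`,
  `run_langevin_metad()`): two-state Markov switching, rigid rotating
  helices, uniform solvent, and an overdamped Langevin walker with
  on-the-fly well-tempered hill deposition — every estimator in the
  package is validated by parameter recovery against these generators.

Results come back as tibbles (with `tidy()` / `glance()` methods) and
every result type has an `autoplot()`.

## Worked example

Simulate five replicate trajectories of a receptor-like system whose
ionic lock closes 73% of the time and whose F6.44 switch is active 54%
of the time, then recover those fractions with the classification
pipeline:

```r
library(microswitchr)
library(purrr)

reps <- map(1:5, function(r) gen_microswitch_system(
  c("F6.44 activation" = 0.54, "Ionic lock closure" = 0.73),
  n_frames = 10000, dwell = 50, seed = 100 + r, replicate = r))

defs <- builtin_switch_definitions()
ser <- map(reps, function(sys) {
  rbind(switch_series(sys$traj, sys$top, defs[["F6.44 activation"]]),
        switch_series(sys$traj, sys$top, defs[["Ionic lock closure"]]))
}) |> dplyr::bind_rows()

glance(engagement_summary(ser))
#> # A tibble: 2 × 5
#>   switch             n_replicates n_frames n_engaged pct_engaged
#>   <chr>                     <int>    <int>     <int>       <dbl>
#> 1 F6.44 activation              5    50000     26504        53.0
#> 2 Ionic lock closure            5    50000     37281        74.6
```

`pct_engaged` is the frame-weighted percentage of time each switch is
engaged (distance at or below its threshold), pooled over the
concatenated replicates: 53.0% and 74.6% against the generators' 54% and
73%. Single replicates scatter much more (`tidy()` on the same summary
shows 45–60% for F6.44), which is exactly why engagement is quoted over
total simulation time. A metadynamics surface is just as direct:

```r
met <- run_langevin_metad(potential_double_well(barrier_kcal = 2.5),
                          n_walkers = 6, n_steps = 15000, dt_ps = 2,
                          pace_steps = 2, seed = 1)
fes <- reconstruct_fes(met$hills, n_nodes = 81)
fes_minima(fes, divide_cv1 = 9.5)$barrier_kcal
#> [1] 2.63  (ground truth 2.5 kcal/mol)
autoplot(fes, threshold_A = 9.5)
```

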