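---
title: "Measuring GPCR micro-switch dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring GPCR micro-switch dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and where the genuinely open design choices
were resolved.

## The measurement problem

Class-A GPCRs carry a small set of conserved residue motifs —
micro-switches — whose local conformation tracks the receptor's
activation state: the P-I-F motif (P5.55 / I3.40 / F6.44) at the base of
the ligand pocket, the D(E)/RY motif with its D3.49–R3.50 salt bridge,
the R3.50–E6.30 ionic lock that holds the intracellular face shut, and
Y7.53 of the NPxxY motif. In an MD trajectory each switch reduces to one
interatomic distance per frame, and its "engagement" to a threshold
classification of that distance. Alongside these, the package measures
the axial rotation of helix 6 (whose freedom to rotate correlates with
G-protein-coupling capacity), water occupancy and ligand contacts, and
reconstructs free-energy surfaces from well-tempered multiple-walker
metadynamics over the two connector-region distances d1 (ring C-4 of
F6.44 to Cα 5.50) and d2 (ring C-4 of F6.41 to Cα 5.54).

Units are fixed throughout: Å for lengths, ps for times, kcal/mol for
energies, degrees for angles.

## Switch classification

Each `switch_definition()` names two atom selectors, a threshold and the
engaged side. The classification rule is *boundary-inclusive*: a
distance exactly equal to the threshold is engaged, because the
activation criteria are "equal or lower than" 9.5 Å (F6.44, F6.41
activation) and 5 Å (ionic lock closure). Defaults:

| switch | atoms | threshold |
|---|---|---|
| F6.44 activation | ring C-4 of F6.44 ↔ Cα 5.50 | ≤ 9.5 Å |
| F6.41 activation | ring C-4 of F6.41 ↔ Cα 5.54 | ≤ 9.5 Å |
| ionic lock | Cε R3.50 ↔ Cδ E6.30 | ≤ 5 Å |
| D3.49–R3.50 salt bridge | min over (OD1, OD2) × (NE, NH1, NH2) | ≤ 4 Å |
| Y7.53 reporters | OH 7.53 ↔ Cα 3.50 and ↔ Cα 2.40 | none |

Three of these required decisions the protocol leaves open:

* **"C-4" of a Phe ring** is taken as the para carbon, PDB atom name CZ.
  Ring atoms number C1–C6 from the attachment carbon (C1 = Cγ), so C4 is
  the unique para position, which is CZ in PDB v3 nomenclature. This is
  a recorded package convention.
* **The salt-bridge criterion** has no single canonical atom pair;
  the package uses the standard salt-bridge definition —
  minimum over all carboxylate-oxygen × guanidinium-nitrogen pairs at
  4 Å — and exposes the cutoff (`salt_bridge_cutoff_A`).
* **Y7.53** is reported as two raw distances and never binarised; no
  threshold exists for it, and scatter of the two distances is the
  informative picture.

Distances are plain Euclidean with no minimum-image correction:
intramolecular distances of a membrane protein never span the periodic
box in wrapped trajectories. Engagement percentages pool replicates
frame-weighted, `100 · Σ engaged / Σ frames` — a percentage "over total
simulation time", not a mean of per-replicate means, so replicates of
unequal length contribute proportionally. No equilibration discard or
stride is applied by default; both are arguments.

Because consecutive MD frames are strongly correlated, a binomial CI on
an engagement fraction would be far too tight. `engagement_ci()` uses
the lag-1 autocorrelation ρ of the state indicator and the Markov-chain
effective sample size `n_eff = n (1−ρ)/(1+ρ)`. For the two-state
generator below, ρ = 1 − 1/dwell exactly, so a 10 000-frame series with
dwell 50 carries only ≈ 100 effective observations — which is why pooled
percentages over several replicates are the quantity worth quoting.

## Helix rotation

`fit_axis()` initialises the axis as the principal (largest-variance)
singular direction of the centred Cα set, then refines it by a cylinder
fit: the direction and offset minimising the variance of the radial
distances. On an ideal helix every Cα sits at the same radius, so the
refined axis is exact for any span length; the raw principal direction
is exact only over whole turns and tilts by up to ~2° on partial turns
(a 17-residue span covers 4.7 turns). That mattered here because the
rotation tests demand 0.1° accuracy. The PCA-only estimator remains
available (`method = "pca"`). Fewer than 4 residues, or a degenerate
(collinear) point set, is an error.

`rotation_about_axis()` projects each Cα onto the plane normal to the
*reference* axis and measures the right-handed change of its angular
coordinate, averaged with a circular mean; residues with projection
radius < 0.5 Å are excluded with a warning (their angle is undefined
near the axis). `rotation_series()` removes rigid-body drift by Kabsch
superposition of a core atom set — by default every protein Cα outside
the measured span — onto the reference before measuring; invariance
under global tumbling is asserted by test, not assumed. Angles are
unwrapped assuming < 90° change between consecutive frames, which also
fixes the antipodal tie toward the previous frame's value. The rotation
is referenced to the supplied reference structure — the crystal
coordinates by convention — and the reference is always explicit, never
implicitly the first frame. Both documented helix-6 spans, 6.44–6.50 and 6.44–6.60, ship as
presets; neither is privileged.

## Solvation, contacts, ligand RMSD

`water_occupancy()` bins water *oxygens* (residue names HOH / WAT /
TIP3 / SOL, configurable) into a regular grid, default 1 Å voxels.
`bulk_relative` normalisation divides per-frame occupancy by
0.0334 waters/Å³ × voxel volume — pure water at 300 K — so 1.0 means
bulk-like hydration; the raw-count total is an exact integer identity
against the in-bounds observations. Grids export as OpenDX text.

`waters_near()` counts oxygens within a cutoff (default 2 Å) of a
selected atom, averaged over frames; a "water near G5.36" is counted by its oxygen, the unambiguous
single-site choice. `contact_frequency()` uses heavy atoms only (hydrogen
placement is model-dependent), a 3 Å cutoff, and reports the top 10
residues by default — the binding-pocket report format. `ligand_rmsd()`
superposes each frame's receptor Cα set onto the reference and then
measures ligand heavy-atom RMSD *without* re-fitting the ligand, so it
reports pose stability in the receptor frame; the superposition set is
all resolved receptor Cα.

## Metadynamics reconstruction

Hills logs are whitespace text, one file per walker, `#!` headers
ignored, columns `time cv1 cv2 sigma1 sigma2 height [biasfactor]`.
Files merge sorted by time with ties broken by walker id — a stable
multi-walker merge. Heights are taken to be the *deposited*
(already-tempered) values, the convention of standard metadynamics
engines; reconstruction therefore applies only the well-tempered
prefactor, never a second tempering decay:

F(s) = −γ/(γ−1) · V(s),  V(s) = Σᵢ wᵢ exp(−Σₖ (sₖ−sₖᵢ)²/(2σₖᵢ²))

With the standard bias factor γ = 10 the prefactor is 10/9. The sum is
evaluated exactly (no Gaussian cutoff) as a separable matrix product, so
the reconstruction matches the closed-form oracle to 1e−9 at every node.
The default grid is 120×120 over [6, 14] Å² — covering the crystal-state
and active-state distances with 0.1 Å hills well resolved — and the
surface is shifted so its minimum is zero (free energy is defined up to
a constant). No reweighting is applied: the plain well-tempered estimate is the
quantity such surfaces conventionally show. γ ≤ 1 is an error; standard (untempered)
metadynamics is out of scope.

`label_states()` partitions the (d1, d2) plane at the 9.5 Å activation
threshold into inactive (both high), intermediate (d2 engaged only) and
active (both engaged) regions, with the fourth quadrant (d1 engaged, d2
not) reported as `forbidden_path`: the activation-ordering claim is that
d1 cannot engage before d2, i.e. that quadrant holds no low-lying
minimum, and the region summary makes that directly checkable.
Boundaries are inclusive on the engaged side, matching the classifier.

`fes_minima()` reports basin positions both as grid argmins and as
Boltzmann-weighted centroids `⟨s⟩ = Σ s·e^(−F/kBT) / Σ e^(−F/kBT)`. The
centroid is the estimator the validation uses: in a soft direction with
curvature k, surface roughness of magnitude δF moves the *argmin* by
√(2δF/k) — ≈ 0.3 Å for the toy potential below at the residual
roughness of a converged run — while the centroid averages that noise
away (observed errors < 0.1 Å across seeds). The barrier is the minimum
of F along the dividing line between the basins.

## The synthetic generators: what they emulate, and what they do not

All validation is parameter recovery on synthetic inputs with known
ground truth; labels are drawn first and never re-derived from the
coordinates.

* `gen_switch_trajectory()` — a two-state Markov chain with stationary
  engaged fraction p and dwell scale D, exit rates `q_eng = (1−p)/D`,
  `q_dis = p/D` (stationarity exactly p; lag-1 autocorrelation
  1 − 1/D), carried by two marker atoms whose distance is the state mean
  (engaged 8.5 Å / disengaged 10.5 Å, σ = 0.25 Å for the 9.5 Å switches;
  3.5/7.0 Å, σ = 0.4 Å for the 5 Å lock — straddling the thresholds by
  ≥ 3σ, which the generator enforces). Dwell 50 frames mimics the
  slowly-switching character of real switch series.
* `gen_microswitch_system()` — the same dynamics wrapped in a minimal
  topology with *real* residue and atom names (PHE CZ, ARG CE/NE, GLU
  CD, ASP OD1 …) and a consistent BW table, so the built-in definitions
  resolve unchanged and the whole pipeline runs end to end.
* `gen_rotating_helix_traj()` — an ideal helix (rise 1.5 Å, twist 100°,
  radius 2.3 Å) rigidly rotated per frame by a prescribed profile, a
  static second helix as alignment core, optional random tumbling.
* `gen_solvated_box()` — iid uniform water oxygens at a prescribed
  density (count = round(ρV) per frame), optionally one water pinned
  within a cutoff of a marker atom in a prescribed fraction of frames.
  Unpinned waters still cross the cutoff sphere at the known uniform
  rate, which the tests subtract analytically.
* `run_langevin_metad()` — overdamped Euler–Maruyama dynamics of 6
  walkers on an analytic potential plus the shared bias, hills every
  4 ps with the well-tempered decay `w·exp(−V/(kB·ΔT))`, bias shared at
  a 20 ps exchange interval, γ = 10, hill 0.1 kcal/mol × 0.1 Å — the
  deposition settings standard for this class of study, reused as
  defaults. The bias lives on an
  internal grid (bilinear interpolation for forces), the grid-cache
  scheme of production engines; walkers reflect at the CV bounds.
  Overdamped dynamics suffice because only the stationary sampling
  matters at this scale, not kinetics. The Euler step carries an O(dt)
  sampling bias, so the Boltzmann validation uses dt = 0.5 ps
  (relaxation time 60 ps) and decorrelated subsamples.

A single seed fans out to named per-component RNG streams
(`component_seed()`), so adding a generator never shifts existing
streams and every bundle is bit-reproducible.

What passing these tests does *not* show: the generators have no
receptor energetics, no membrane, no force field, no correlated
switch–switch coupling, and solvent with no structure. Recovery here
validates the *estimators* — classification exactness, pooling, axis
and angle measurement, grid statistics, FES algebra — not any biological
claim. Engagement percentages, rotation spans, water counts or RMSD values
reported from microsecond production campaigns are properties of
trajectories that typically are not deposited, which is precisely why
the validation here is parameter recovery rather than value matching.

## Problem sizes and numerical tolerances

The validation suite runs on one CPU in well under a minute of
computation per component: 10 000-frame switch series (× 6 engagement
levels spanning 14–77%), 1 000-frame water boxes, and a metadynamics
validation of 6 walkers × 15 000 steps of 2 ps (30 ns-equivalent each,
≈ 45 000 hills) reconstructed on an 81-node (0.1 Å) grid — enough
deposition that the recovered barrier of the 2.5 kcal/mol double well
sits within ±17% across seeds (tolerance 20%), with basin centroids
within one grid cell. Exact identities (classification counts, grid
totals, FES vs closed form) are asserted at 1e−9 or tighter; stochastic
recoveries at 99% autocorrelation-adjusted or 3σ intervals.

Two small conventions worth noting: atom indices are 1-based row numbers
of the atom table (the R idiom; residue numbers shown to users are
always author/PDB numbering), and trajectory sources without a time axis
(multi-model PDB, DCD) get `0, dt, 2dt, …` with a user-supplied `dt`.

## Limitations

XTC input is not supported (no reader in the dependency set); DCD and
multi-model PDB are. No hidden-Markov or kinetic modelling of switch
dynamics (states are threshold classifications), no helix kink/tilt
metrics, no water-channel pathfinding, no secondary-structure analysis,
and no on-the-fly biasing of real MD — the Langevin walker is the only
dynamics engine, and it is a validation instrument, not a simulator.
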