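---
title: "Pore, cavity and ligand-exchange analysis of pentameric channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore, cavity and ligand-exchange analysis of pentameric channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`chancav` analyses topology + trajectory data of pentameric ligand-gated ion
channels (pLGICs) such as GLIC: the geometry of the ion-conduction pore, the
transmembrane binding cavities that harbour alcohols, anesthetics, water and
lipid, and the exchange kinetics of small ligands between those cavities and
the bulk.  It implements the full analysis chain — superposition and RMSD,
M2 kink angles, HOLE-style pore radius profiles, grid-based consensus cavity
detection with Monte-Carlo volumetrics, per-cavity occupancy counting,
number-density maps, occupancy autocorrelation with double-exponential
exchange fits, and occupancy-correlation statistics — together with a
synthetic channel generator that provides exact ground truth for every one
of those quantities.

This vignette documents the models and conventions, the tunable parameters
with their defaults, what the generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

# The synthetic channel generator

Because production molecular-dynamics trajectories of a solvated,
membrane-embedded pentamer are enormous and rarely deposited, every stage of
the pipeline is validated against `channel_spec()` /
`simulate_trajectory()`, which generate a C5-symmetric toy channel with
*known* ground truth:

* **Pore wall**: stacked rings of carbon pseudo-atoms at radius
  $r(z) + r_\mathrm{vdw}$, so the true pore radius profile is the declared
  piecewise-linear $r(z)$.  The default profile has its tightest
  constriction, 2.25 Å, at the 9′ level ($z = 0$) with secondary
  constrictions near 16′ ($z = +10$ Å), 2′ ($z = -10$ Å) and −2′
  ($z = -18$ Å), the classic pLGIC pattern.
* **M2-like helices**: five pore-lining rods (residues 221–245, one per
  subunit) with marker residues at the 9′/14′/16′ prime positions
  (residues 233/238/240) and an optional rigid kink at residue 238.  The
  rods are built with a 0.01 Å helical radius so that the declared kink
  angle is exact ground truth under the inertia-axis convention (see below).
* **Cavities**: five membrane-facing intra-subunit boxes (default
  5 × 5 × 7 Å = 175 Å³ at radius 18 Å, z = +7) and five interface
  inter-subunit boxes (5 × 5 × 5 Å = 125 Å³ at z = −7).  Each box is
  surrounded by planes of pseudo-atoms exactly $r_\mathrm{vdw} + 1.4$ Å
  outside its faces, so the probe-free interior *is* the declared box and
  the declared volume is exact.  The remaining interstitial space is packed
  with pseudo-atoms so that the declared cavities are the only enclosed
  voids.
* **Ligand exchange**: each ligand (a rigid 3-pseudo-atom body, ethanol
  sized) follows a two-state continuous-time Markov chain between "bulk"
  and "bound", with exponential dwell times of means $\tau_b$ (default
  50 ns) and $\tau_u$ (default 500 ns — a dilute-bulk regime in which
  rebinding is slow).  Bound ligands are placed uniformly strictly inside
  their cavity; bulk ligands in a solvent shell starting 8 Å outside the
  protein, mirroring how ethanol is introduced into simulated systems.
  The stationary bound fraction is $\tau_b / (\tau_b + \tau_u)$.
* **Water and lipid**: inter-subunit cavities hold a baseline of water
  (default 3 molecules) displaced one-for-one by resident ligands;
  intra-subunit cavities hold 8-atom lipid chains inserted per frame with
  probability $p \cdot f^{\,n_\mathrm{lig}}$ (defaults $p = 0.7$,
  $f = 0.5$), giving the anti-correlations between ligand and lipid/water
  occupancy seen in real systems.
* **Noise**: protein pseudo-atoms receive per-frame Gaussian jitter
  (default 0.05 Å).  All randomness derives from a single seed; identical
  seeds give byte-identical trajectories.

What the generator deliberately does **not** emulate: physical forces and
correlated protein dynamics, realistic lipid conformations, periodic
imaging, solvent structure, or any coupling between pore radius and cavity
occupancy.  Passing tests therefore demonstrate the *correctness of the
analysis operators* against known inputs, not the biological realism of any
particular trajectory.

# Conventions and models

## Units and frames

Ångström and nanoseconds everywhere; conversions (e.g. the nm of GRO files)
happen only at the I/O boundary.  A pentamer is aligned with
`align_to_pore_axis()`: the five-fold axis — the non-degenerate principal
axis of the protein Cα inertia tensor — is rotated onto $+z$ (the
eigenvector sign is canonicalized toward $+z$ so that consecutive frames of
an already-aligned trajectory never receive spurious 180° flips), the
extracellular side (16′ marker) points up, and the origin is fixed with the
mean 9′ Cα at $z = 0$.  The azimuth is not pinned by the axis alignment;
`run_pipeline()` therefore aligns frame 1 and superposes all later frames
onto it (Kabsch on protein Cα), which keeps cavity regions consistent in
time.

## Kink angle

Following the standard M2 convention, the kink is the angle between the
first principal inertia axes (unit masses) of the Cα sets of residues
221–238 (bottom, 7′–14′) and 238–245 (top, 14′–21′); the hinge residue 238
belongs to both segments, and the angle is folded into [0°, 90°] because
principal axes are sign-ambiguous.  A caveat worth knowing: for an ideal
*straight* α-helix (2.3 Å Cα radius) the 8-residue top segment spans 2.2
helical turns and its inertia axis is intrinsically tilted by ≈ 8.3° from
the helix axis.  Kink angles computed by this convention therefore carry a
baseline offset of several degrees for real helices — comparable to
published crystal-structure values near 8° — and are best read
comparatively (mutant vs wild type, bent vs straight).  The generator
avoids the offset entirely by using thin rods.

## Pore radius

$r(z)$ is the HOLE-style radius: the largest sphere centred in the plane at
height $z$ that touches no atom van der Waals sphere,
$r(z) = \max_{c} \min_i (\lVert c - x_i \rVert - r_{\mathrm{vdw},i})$.
Atoms within ±6 Å of the plane contribute; the centre search runs over a
5 Å disc around the pore axis using a deterministic 0.5 Å coarse grid
followed by Nelder–Mead refinement from the nine best grid points
(tolerance 10⁻³ Å).  The objective is piecewise smooth, which is why grid
preselection rather than isolated fixed starts is used; on toy systems the
result matches a 0.05 Å brute-force grid search to machine precision.
Slabs containing no atoms yield *missing* (not zero) radii.  Default grid
step 0.5 Å; heatmaps profile every frame by default (1 ns at 1 ns
spacing), and `min_radius_window()` extracts the per-frame minimum within a
5 Å z-window around a marker residue such as 9′.

Radii are computed from Bondi van der Waals radii by element (H 1.10 Å),
configurable in `vdw_radii()`.  Because reference pore/cavity software does
not document its radius set, absolute radii and volumes carry a systematic
offset against published numbers; validation is therefore against the
synthetic ground truth.

## Cavity detection and volumes

`detect_voids()` classifies voxels of a 1 Å cubic lattice over the
transmembrane region: a voxel is void when (i) its centre is at least
$r_\mathrm{vdw} + r_\mathrm{probe}$ (probe 1.4 Å) from every protein heavy
atom, (ii) it is *buried* — at least 9 of 14 scan rays (6 axial, 8 body
diagonal) meet a protein heavy atom within 8 Å — and (iii) it is not in
the pore lumen (radial distance ≤ pore radius + probe at its height).  The
burial rule and the 8-voxel minimum component size are artifact choices,
both configurable; the probe, the 1 Å lattice, the 5 ns consensus stride,
the 20% consensus frequency threshold and the 10,000 Monte-Carlo iterations
follow the reference protocol.  Consensus components are connected by
26-neighbourhood; the per-voxel frequency is exactly the mean of the
per-frame booleans.

Components are classified by their lining (protein heavy atoms within 5 Å):
intra-subunit when ≥ 80% of lining atoms belong to one chain, inter-subunit
when two chains each contribute ≥ 20%, ambiguous otherwise (reported, never
dropped).  `symmetrize_cavities()` rotates the largest component of a class
by k·72° onto the other four sites; rotated regions keep their template
lattice plus a rotation angle, so no re-snapping error is introduced.

`mc_volume()` samples uniformly in the region's bounding box; hits lie
inside the region's voxel cubes and at least vdw + probe from every protein
heavy atom; volume = box volume × hit fraction with the binomial standard
error.  For per-frame volumes inside a fixed consensus region the pipeline
dilates the region by one voxel first (`dilate = 1`): the sharp cavity
boundary is then defined by the atoms rather than by the voxel
discretization, which removes the half-voxel surface bias that otherwise
appears when a cavity is not lattice-aligned (up to ~10% for a 175 Å³
box).  For open cavity mouths this choice can add a thin rind of genuinely
open volume; the synthetic cavities are fully enclosed, so their recovery
is exact to Monte-Carlo noise.

## Occupancy

A molecule occupies a cavity when its heavy-atom geometric centre lies
within 1.0 Å of a cavity voxel centre (configurable); the rule is symmetric
between ligand and water.  Lipid occupancy counts acyl-chain heavy atoms
individually (carbons excluding the glycerol C1–C3).  Strictly interior
placements are classified with zero error because the 1 Å lattice covers
the box interior with covering radius √3/2 < 1.  Summaries default to the
trailing half of the trajectory (frames with $t \ge T/2$, inclusive).
Density maps accumulate one count per heavy atom per frame on a 1 Å grid
over the averaging window and divide by the frame count, so the voxel sum
equals the mean atom count in the mapped box exactly (number density; no
mass weighting).

## Exchange kinetics

Per-molecule binary traces $b_m(t)$ mark occupancy of any cavity of a class
(molecules never bound are excluded; re-entries count as continued
occupancy — no re-entry correction).  The occupancy autocorrelation is the
conditional-survival form
$$C(\Delta) = \frac{\sum_m \sum_t b_m(t)\, b_m(t+\Delta)}
                   {\sum_m \sum_t b_m(t)},$$
with $t$ restricted so that $t + \Delta$ is in range in both sums: the
aggregate probability that a molecule bound at $t$ is (or is again) bound
at $t+\Delta$.  $C(0) = 1$ exactly, and an all-ones trace gives $C \equiv 1$.
A classical mean-subtracted variant is available (`type = "covariance"`).
For a two-state Markov ligand this decays as
$\pi + (1-\pi)\,e^{-\Delta/\tau_r}$ with
$\tau_r^{-1} = \tau_b^{-1} + \tau_u^{-1}$ and $\pi$ the stationary bound
fraction, which the property tests verify.

`fit_double_exponential()` fits
$A_f e^{-\Delta/\tau_f} + A_s e^{-\Delta/\tau_s} + c$ by multi-start
bounded least squares ($\tau_f$ starts at {2, 10, 30} × frame spacing,
$\tau_s$ at {0.1, 0.3, 0.6} × max lag; $A_f, A_s, c \ge 0$ summing to 1;
$\tau_f < \tau_s$).  The non-negative floor $c$ absorbs the long-time
rebinding equilibrium of a finite bulk reservoir; for curves that decay
fully it converges to 0 and the model reduces to the plain
double-exponential.  The slow decaying constant $\tau_s$ is the headline
exchange time.  Fits collapse to a flagged single-exponential when the
second component is degenerate: amplitude below 2%, slow amplitude below
15% (plateau noise, not exchange), $\tau_s/\tau_f < 1.25$, no SSE
improvement, or $\tau_s$ beyond twice the observation window (unresolved,
indistinguishable from the floor).  Standard errors of $\tau$ come from a
bootstrap over molecules (200 seeded replicates by default; jackknife with
a warning below 5 molecules) — the appropriate resampling unit because
molecules, not frames, are approximately independent.

A caution established during validation: at moderate sample sizes
(~100 molecules × 1000 frames with dwells of ~150 frames) the fitted
$\tau_s$ has a strongly right-skewed distribution — individual realizations
containing a few very long bound episodes produce genuinely two-timescale
empirical curves and overshoot by up to a factor ~2.  Replicate summaries
in the package's own validation therefore use the median across generator
seeds.

## Occupancy statistics

Occupancy correlations (ligand vs lipid, ligand vs water) are computed on
time-binned per-cavity pairs (default bin 10 frames) pooled over the five
sites, because grand per-cavity means wash out the time-resolved
anti-correlation the displacement mechanism produces.  `linear_fit()` is
ordinary least squares with textbook standard errors; its $R^2$ equals the
squared Pearson correlation to 10⁻¹².  `cavity_table()` reproduces the
publication layout: rows = quantity, columns = cavities 1–5 plus an
Average column whose value is the mean of the per-cavity means and whose
SD is that of the subunit-averaged time series.

# The pipeline and its configuration

`run_pipeline()` executes input → align → RMSD/kink → pore → cavities →
occupancy → kinetics → statistics, taking every seed, window, stride and
threshold from a nested configuration (R list or YAML) merged over
`default_config()`.  Any stage failure halts with the stage name and
cause; outputs already written are retained.  Reports bundle CSV series,
OpenDX grids and a JSON summary.  The package's validation exercises the
full chain at 50–100 frames with 10,000-sample Monte-Carlo volumes —
deliberately compact problem sizes chosen so the whole suite re-runs in
minutes while still leaving every estimator's noise well inside its test
tolerance — and checks that declared cavity volumes are recovered within
max(5%, 2 voxel volumes), declared kinks within 1°, the bound fraction
within 3 SE, and that repeated runs with the same configuration are
identical.

```r
library(chancav)
report <- run_pipeline(list(
  input = list(n_frames = 100, dt = 1, seed = 1,
               spec = list(kink = rep(12.46, 5))),
  out_dir = "report"))
report$kink$per_chain_mean
report$cavities$volume_mean
report$kinetics$bound_fraction
```

# Known limitations

* Absolute pore radii and cavity volumes depend on the van der Waals radius
  set and on artifact choices (burial rule, probe, membership distance);
  agreement with published absolute values from other software is not
  claimed.  Comparative statements (mutant vs wild type, with vs without
  ligand) are robust to these offsets.
* The kink-angle convention carries an intrinsic partial-turn offset for
  real helices (see above).
* XTC/TRR trajectories are not read directly; convert to DCD or multi-model
  PDB first.
* `align_to_pore_axis()` does not pin the azimuth; per-frame independent
  alignment of a trajectory whose protein drifts azimuthally should go
  through `run_pipeline()`'s superposition-based alignment.
* The occupancy membership rule is a centre-in-region criterion; molecules
  straddling a cavity mouth count as in or out by their centre alone.
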