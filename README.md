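# chancav

Pore, cavity and ligand-exchange analysis for pentameric ligand-gated ion
channels (pLGICs).

Alcohols and anesthetics modulate pLGICs such as GLIC, GlyR and the GABA-A
receptors by occupying small transmembrane cavities: a membrane-facing
pocket inside each subunit (the inhibitory anesthetic site) and a pocket at
each subunit interface (the potentiating alcohol site). Quantifying that
picture from molecular-dynamics trajectories requires a chain of geometric
and statistical analyses that are usually scattered across separate tools.
`chancav` implements the whole chain as one tested R package, for
computational structural biologists working on channel modulation:

* **Superposition and RMSD** — Kabsch least-squares fitting, whole/domain
  RMSD time series with trailing-window statistics, per-residue mean RMSD
  averaged over the five chains.
* **M2 kink angle** — the angle between the first principal inertia axes of
  the Cα sets of the lower (7′–14′, residues 221–238) and upper (14′–21′,
  238–245) halves of the pore-lining M2 helix, folded into [0°, 90°].
* **Pore radius profiles** — HOLE-style
  r(z) = max over centres c of min over atoms i (‖c − xᵢ‖ − r_vdw,i),
  per frame and as an r(z, t) heatmap, plus the per-frame minimum radius in
  a 5 Å z-window around a marker residue such as the 9′ hydrophobic gate.
* **Consensus cavities and volumes** — grid-probe void detection on a 1 Å
  lattice (probe 1.4 Å, burial by 14 scan rays), consensus over trajectory
  frames sampled every 5 ns with a 20 % frequency threshold,
  intra/inter-subunit classification by chain composition of the lining,
  five-fold symmetrization by 72° rotations, and Monte-Carlo volume
  integration (10,000 iterations) with binomial standard errors.
* **Occupancy** — per-cavity, per-frame counts of ligand and water
  molecules (heavy-atom centre within 1 Å of a cavity voxel) and lipid
  acyl-chain atoms; 1 Å number-density maps averaged over the second half
  of the trajectory; publication-style mean ± SD cavity tables.
* **Exchange kinetics** — per-molecule binary occupancy traces, the
  conditional-survival occupancy autocorrelation
  C(Δt) = Σₘ Σₜ bₘ(t)bₘ(t+Δt) / Σₘ Σₜ bₘ(t)  (C(0) = 1),
  and bounded multi-start least-squares fits of
  A_f·exp(−Δt/τ_f) + A_s·exp(−Δt/τ_s) + c with bootstrap standard errors
  over molecules; τ_s is the headline exchange time.
* **Occupancy statistics** — time-binned ligand–lipid and ligand–water
  pairing with OLS fits and R² (equal to the squared Pearson correlation).

Everything is validated against a **synthetic pentameric-channel
generator** (`channel_spec()`, `simulate_trajectory()`) that produces toy
trajectories with exact ground truth: a prescribed pore radius profile,
declared cavity volumes, declared per-subunit kink angles, two-state
(bound/bulk) ligand exchange with exponential dwell times, water displaced
by ligands, and lipid chains whose insertion is suppressed by resident
ligands. See the vignette (`vignettes/channel-cavity-analysis.Rmd`) for the
models, conventions and their caveats.

## Worked example

```r
library(chancav)
# a 20-degree kink on subunit A of an otherwise straight pentamer
spec <- channel_spec(kink = c(20, 0, 0, 0, 0))
sim  <- simulate_trajectory(spec, nf = 20, dt = 1, seed = 42)
ka <- kink_angle(get_frame(sim$trajectory, 1), sim$trajectory$topology)
round(attr(ka, "per_chain"), 2)
#>     A     B     C     D     E
#> 19.99  0.27  0.08  0.44  0.58

# pore radius near the 2' / 9' / 16' levels (declared 2.6 / 2.25 / 2.8 A;
# the 0.05 A thermal jitter of the scaffold narrows the instantaneous pore)
al <- align_to_pore_axis(get_frame(sim$trajectory, 1), sim$trajectory$topology)
radius_profile(al$frame, sim$trajectory$topology, z = c(-10, 0, 10))
#>     z        r
#> 1 -10 2.466960
#> 2   0 2.162667
#> 3  10 2.634028

# Monte-Carlo volume of a declared 7 x 7 x 7 A cavity region
box <- chan_cavity(as.matrix(expand.grid(0:6, 0:6, 0:6)), spacing = 1)
v <- mc_volume(box, n = 10000, seed = 1)
cat(sprintf("volume = %.1f +/- %.1f A^3\n", v, attr(v, "se")))
#> volume = 343.1 +/- 2.0 A^3
```

The full chain — alignment, RMSD, kink, pore heatmap, consensus cavities,
volumes, occupancy, kinetics, statistics — runs from one configuration:

```r
report <- run_pipeline(list(
  input = list(n_frames = 100, dt = 1, seed = 1,
               spec = list(kink = rep(12.46, 5))),
  out_dir = "report"))
```

`report$kink$per_chain_mean` returns the five recovered kink angles (here
≈ 12.49° each against the declared 12.46°), `report$cavities$volume_mean`
the per-site Monte-Carlo volumes inside the symmetrized consensus regions
(≈ 176 Å³ intra, ≈ 126 Å³ inter against declared 175/125), and
`report$kinetics` the bound fraction and exchange-time fits per cavity
class. A thin command-line wrapper for `simulate`/`run`/`info` is installed
at `inst/scripts/chancav`.

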