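# mdscope

Multi-scale analysis of protein molecular-dynamics trajectories in R.

Multi-domain enzymes move on many timescales at once: loops breathe over
nanoseconds while whole domains swing, twist and bend over hundreds of
nanoseconds, often about a small set of hinge residues. No single observable
captures this hierarchy. `mdscope` bundles the complementary analyses a
structural-bioinformatics practitioner chains together to dissect it — from
raw per-residue fluctuations to collective modes, time-frequency maps and
free-energy landscapes — behind one consistent set of containers, and ships
synthetic-trajectory generators with planted ground truth so every stage can
be validated end to end without any external data.

## What it computes

- **Superposition / RMSD** — weighted Kabsch least-squares fitting,
  per-frame RMSD series (with exclusion selections), and per-residue
  RMSD-through-time maps.
- **Fluctuations** — RMSF_i = sqrt((1/n) Σ_t ‖r_i(t) − ⟨r_i⟩‖²) and
  B_i = (8π²/3)·RMSF_i², with Pearson comparison against crystallographic
  B-factors.
- **Essential dynamics** — coordinate covariance C = ⟨r rᵀ⟩ − ⟨r⟩⟨r⟩ᵀ at a
  configurable frame stride, eigendecomposition with normalised eigenvalue
  fractions, mode projections, and half-vs-half Kullback–Leibler divergence
  of projection histograms as a convergence diagnostic.
- **Elastic-network normal modes** — anisotropic network model on Cα atoms
  (uniform springs within a distance cutoff), exact removal of the six
  rigid-body modes, thermal amplitudes ∝ k_B·T/λ.
- **Dynamical cross-correlation maps** — C_ij = ⟨Δr_i·Δr_j⟩ /
  √(⟨Δr_i²⟩⟨Δr_j²⟩) from trajectories, mode sets, or multi-model structure
  ensembles, with map-vs-map Pearson comparison and per-domain block
  statistics.
- **Morlet wavelet maps** — continuous wavelet transform (ω₀ = 6) of
  per-atom displacement series over a geometric scale grid (default 0.2–25
  ns, step 1.01), with red-noise χ² significance testing in the style of
  Torrence & Compo.
- **Free-energy landscapes** — G = −k_B·T·ln(P/P_max) from 2-D kernel
  density estimates over principal-component pairs (k_B·T ≈ 2519 J/mol at
  303 K), connected-component basin extraction and basin-shift measurement
  between conditions.
- **Hinge detection** — average unsigned deviation of backbone φ/ψ angles
  along low-frequency modes; inter-domain bending-angle series.
- **Hydrogen bonds** — donor–acceptor occurrence maps over frame clusters
  (distance + optional D–H···A angle criterion), plus a separate
  minimum-distance contact listing.

Structures are read and written as PDB (via `bio3d`), trajectories as
binary DCD; all coordinates are Å, times are ps internally and ns at
reporting boundaries.

## Worked example: detecting a domain hinge

A synthetic two-domain protein whose distal domain swings by ±20° about a
planted pivot residue (residue 30 of 60):

```r
library(mdscope)

h <- gen_two_domain_hinge(n_res = 60, n_frames = 2000, seed = 42, theta0 = 20)
h$trajectory
#> md_trajectory: 2000 frames x 180 atoms, dt = 10 ps (20 ns total)

# anti-correlated domain motion after least-squares fitting
map <- dccm_map(h$trajectory, "name CA", fit = TRUE, fit_selection = "all")
block_statistics(map, list(core = 1:30, domainV = 31:60))
#>   block_i block_j  mean   min max   n
#> 1    core    core  0.39 -0.76   1 435
#> 2 domainV    core -0.39 -1.00   1 900
#> 3 domainV domainV  0.41 -0.72   1 435

# backbone-dihedral deviation pinpoints the pivot
aud <- dihedral_aud(h$trajectory, h$structure)
attr(aud, "hinges")
#> [1]  9 28 30 35 56

# the bending angle across the hinge oscillates with the planted amplitude
ang <- bend_angle_series(h$trajectory, c(2, 30, 59))
sprintf("mean %.1f deg, amplitude %.1f deg", mean(ang), sd(ang) * sqrt(2))
#> [1] "mean 134.2 deg, amplitude 20.0 deg"
```

The two domains move against each other (mean inter-block correlation
−0.39), the strongest dihedral deviation sits at the planted pivot
(residue 30), and the bending-angle amplitude recovers the planted 20°.

A ten-stage pipeline (`simulate-fixture`, `align`, `rmsf`, `pca`, `enm`,
`dccm`, `wavelet`, `fel`, `hbond`, `report`) is exposed as
`run_pipeline()`, writing TSV/JSON artifacts plus a manifest with output
checksums; `inst/cli/mdscope.R` wraps it for shell use:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mdscope.R", package = "mdscope"))')" \
    simulate-fixture,pca,fel --out run1 --seed 4
```

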