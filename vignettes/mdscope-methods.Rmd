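---
title: "Methods: models, parameters and design choices in mdscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mdscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscope)
```

`mdscope` dissects the hierarchy of motions in molecular-dynamics
trajectories of multi-domain proteins. This vignette documents the models
behind each stage, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic validation
fixtures do and do not establish about real data.

## Containers and conventions

Coordinates are Å throughout; time is ps internally and ns at reporting
boundaries. Trajectories are stored as frames × 3N matrices (row layout
`x1 y1 z1 x2 …`), structures as an atom table plus an n × 3 coordinate
matrix. Residue identifiers are the author numbering of the source PDB and
are never renumbered; selections accept a numbering-scheme `offset` so that
ranges written in an alternative scheme can be applied without touching the
structure. Gaps in author numbering (unresolved loops) are preserved and
reported by `structure_gaps()`.

Supported formats are PDB (read/write, multi-model files becoming structure
ensembles) and binary DCD (read/write; the frame spacing is stored in the
header and round-trips). XTC is not supported: no R-side reader exists in
this package's dependency set and the format's coordinate compression is a
substantial codec in its own right; `.xtc` inputs fail with a clear message
rather than silently converting.

## Superposition and deviation measures

Global rotation and translation are removed by weighted Kabsch fitting
(SVD of the 3 × 3 cross-covariance; the reflection case is corrected so the
rotation determinant is +1). Configurations whose cross-covariance has rank
< 2 (collinear or coincident points) make the rotation ill-defined and are
rejected rather than silently resolved. Fitting weights default to uniform;
mass weighting is available where several atoms collapse to one residue
value.

`align_trajectory()` fits either to a fixed reference or to the iteratively
refined average structure: fit all frames to the running mean, recompute the
mean, stop when the mean moves < 1e-6 Å or after 10 passes. Both constants
are convergence safeguards, not physical parameters; in practice the fixed
point is reached in 2–3 passes.

The per-residue RMSD map tracks each residue's deviation from a reference
position through time, averaged over non-overlapping windows (`window = 1`,
i.e. no smoothing, by default). The reference is the residue's time-average
position by default — deviation *about the mean* is the quantity that pairs
naturally with RMSF — with the crystallographic structure available as an
alternative reference. The conventional 2/4/6 Å display bin edges ship as an
attribute; they are presentation, not analysis.

## Fluctuations and B-factors

RMSF is the root of the mean squared displacement about the time-average
position. The companion relation B = (8π²/3)·RMSF² converts to
crystallographic B-factors (RMSF of 1 Å ↔ 26.3189 Å²). "Mass-weighted" is
interpreted as mass-weighted *averaging* when collapsing several atoms to
one residue value — the fluctuation formula itself contains no mass term,
so for Cα-only selections the flag is a no-op. Comparison against
experimental values uses per-residue Cα B-factors over the intersection of
residue ids, reporting the n used and the residues dropped.

## Essential dynamics and convergence

The coordinate covariance is accumulated over frames sampled at a stride
(`offset`, default 10 frames) — the stride decorrelates successive snapshots
and bounds memory, and with 10 ps snapshots it corresponds to one sample
per 100 ps. Eigendecomposition returns modes in descending variance order
together with normalised eigenvalue fractions and their cumulative sums.
Eigenvector sign is fixed by making each vector's largest-magnitude
component positive; this removes the inherent sign ambiguity so that
projections, basin shifts and mode comparisons are reproducible.

Convergence is probed by the Kullback–Leibler divergence between projection
histograms of the first and second halves of the trajectory. The estimator
is deliberately simple and fully specified: 100 bins spanning the union of
both ranges, a pseudo-count of ½ per bin, natural logarithm, asymmetric
KLD(p‖q) with p the first half (a symmetrised variant is available behind a
flag). The pseudo-count bounds the divergence of identical samples near
zero and keeps empty bins finite. `kld_profile()` evaluates the same
diagnostic on growing prefixes of the series, giving the familiar
KLD-versus-time decay curve.

## Elastic-network normal modes

Low-frequency collective modes come from a Cα anisotropic network model:
uniform springs of constant γ between atoms within a cutoff (default 12 Å,
a common choice giving well-connected Cα networks), Hessian assembled from
the standard −γ(d̂⊗d̂) blocks, full eigendecomposition. Exactly six
eigenvalues must fall below 1e-8 × the largest — the rigid-body null space —
and are removed; any other count is a geometry error and is reported as
such, not repaired. Notably, *planar* or collinear networks legitimately
fail here: displacements perpendicular to a plane change no pairwise
distance to first order, so a planar ANM has a whole extra band of zero
modes. This is a property of the model, and the error message is the right
answer for such inputs.

An all-atom force-field normal-mode analysis would serve the same role at
vastly higher cost; the network model reproduces the low-frequency
collective geometry (counter-rotating blocks, hinge bending) that the
downstream analyses consume, which is what the package needs modes *for*.
The retained-mode count (default 26) is the exposed knob; a frequency
cutoff in cm⁻¹ is not meaningful for a dimensionless network. Thermal mode
amplitudes are k_B·T/λ with T = 303 K by default; γ is arbitrary, so ENM
B-factors are meaningful up to scale while correlation maps are
scale-free.

## Cross-correlation maps

c_ij is the scalar product convention ⟨Δr_i·Δr_j⟩, normalised to
C_ij = c_ij/√(c_ii·c_jj) ∈ [−1, 1]. The scalar convention is the one whose
output range statement (+1 fully correlated, −1 fully anti-correlated)
holds for vector displacements. A consequence worth knowing: a *single*
mode yields C_ij = cos(angle between the atomic direction vectors), not
±1 — |C| = 1 for every pair is a property of per-component correlations,
not of the scalar convention. Atoms with zero variance get masked (NA)
rows/columns rather than numeric sentinels. Maps can be computed from
trajectories, from mode sets (amplitude-weighted outer products; with all
PCA modes this reproduces the trajectory map by construction), or from
multi-model PDB ensembles. `compare_dccm()` reports the Pearson correlation
over unique off-diagonal pairs; `block_statistics()` summarises named
(possibly discontiguous) residue partitions such as structural domains.

## Morlet wavelet maps

Each selected atom's displacement about its mean position is transformed
with the complex Morlet wavelet (ω₀ = 6, the standard
admissibility-compliant choice) by FFT convolution over a geometric scale
grid, default 0.2–25 ns with multiplicative step 1.01. Scales are reported
as Fourier periods via the Morlet factor 4π/(ω₀+√(2+ω₀²)).

The transformed series is the **per-axis displacement**, with power summed
over x, y, z. The obvious alternative — the scalar displacement magnitude
‖r(t) − ⟨r⟩‖ — rectifies any centred oscillation (|sin| has fundamental
period T/2), which systematically halves the period attributed to a planted
sinusoid; the per-axis transform preserves it. The magnitude convention
remains available (`component = "magnitude"`) for comparability with tools
that use it, with that caveat documented.

Per-residue power is the mean over the residue's atoms; at every (residue,
frame) cell the scale of maximum power defines the dominant period. A cell
is significant when its power exceeds the background spectrum — lag-1
autoregressive red noise estimated per residue, or white noise — times the
χ² quantile at the requested confidence (ν = 2) times a threshold constant
`chi2_critical` (default 1.6094). That constant is treated as an opaque,
user-visible multiplier: it tightens the test beyond the plain χ² quantile,
which compensates for the fact that selecting the *maximum* over many
correlated scales inflates the plain per-scale false-positive rate. The
calibration is verified empirically in the test suite: on pure white noise
at the 99 % level, the fraction of significant non-edge cells stays within
the nominal few-percent budget. Cells inside the cone of influence
(√2 × scale from either edge, evaluated at the cell's dominant scale) are
flagged and excluded from significance by default.

## Free-energy landscapes and basins

The joint density of two projection coordinates is estimated with a 2-D
Gaussian kernel on a regular grid (default 100 × 100 cells spanning the
data range ± 3 bandwidths). The bandwidth follows Scott's rule per axis,
σ̂·n^(−1/6), user-overridable. Free energy is G = −k_B·T·ln(P/P_max) in
J/mol with T = 303 K by default (k_B·T ≈ 2519 J/mol), so the most populated
cell sits at exactly 0 and the normalisation constant cancels. Cells whose
density underflows are flagged infinite and excluded from basin
connectivity.

Basins are 4-connected components of cells below a free-energy threshold,
ordered by minimum energy; each reports member frames, occupancy and an
occupancy-weighted centroid in PC space. The threshold is a resolution
dial, not a constant of nature: to resolve a minority state of relative
population q against a majority p the cutoff must exceed k_B·T·ln(p/q)
(e.g. ≈ 1.39 k_B·T ≈ 3493 J/mol for an 80/20 split), while staying below
the inter-well saddle. The 100 J/mol default mirrors the tight
cluster-extraction use (frames within ~4 % of peak density, a natural
choice for pulling representative conformers); basin-topology analyses
should pass a threshold of order k_B·T. `basin_shift()` compares
deepest-basin centroids between two landscapes; this is only meaningful in
a common eigenbasis, so the recommended workflow projects both conditions
onto one reference mode set.

The bending-angle series (vertex angle at the Cα of a middle residue) is a
deliberately simple 1-D monitor of a bending mode; angles are invariant to
rigid transforms, so it needs no alignment.

## Hydrogen bonds

Candidate pairs are N/O heavy atoms on either side. A pair is bonded in a
frame when the donor–acceptor distance is ≤ 3.5 Å and, when the topology
carries hydrogens (detected by a ≤ 1.25 Å attachment in the first frame),
some donor hydrogen makes a D–H···A angle ≥ 135°. Hydrogen-free topologies
use the distance criterion alone. These are the conventional geometric
cutoffs; both are parameters. Occurrence is the percentage of frames in
which a pair is bonded — typically computed over the members of a
free-energy basin cluster. Nonpolar stacking contacts are reported
separately by `contact_occurrence()` (any heavy-atom pair ≤ 4.5 Å), labelled
`contact`, never `hbond`.

## Synthetic study conditions

The generators produce the five planted situations the pipeline is
validated against, each a pure function of its seed, each returning the
ground truth needed to predict downstream results:

- `gen_gaussian_traj()` — Gaussian fluctuations along planted orthonormal
  internal modes (defaults: 200 residues, amplitudes 3/2/1.4 Å, 0.2 Å
  isotropic noise floor, 10 ps frames). Planted modes are constructed
  orthogonal to the six rigid-body directions so that least-squares fitting
  leaves them intact — the analogue of internal motion in a fitted
  trajectory.
- `gen_two_domain_hinge()` — a backbone chain with a static 45° kink whose
  distal block rotates rigidly about the pivot's Cα by θ₀·sin(2πt/T)
  (default θ₀ = 20°, T = 4 ns). After fitting, the two blocks move in
  anti-correlated directions; dihedrals deviate only at the pivot; the
  Cα bending angle oscillates with amplitude θ₀ exactly. Its noise floor
  (0.02 Å) is deliberately below the general default because dihedral
  angles amplify coordinate noise over ~1.4 Å bond lengths.
- `gen_oscillatory()` — groups of residues oscillating along fixed random
  directions at planted periods, optionally time-localised bursts, over a
  0.2 Å white-noise floor.
- `gen_double_well()` — a two-component Gaussian mixture along two planted
  internal modes (centres ±separation/2, default 6 in-well σ apart),
  independent draws per frame.
- `gen_hbond_fixture()` — a rigid 10-residue pocket and a 23-atom
  disaccharide-like ligand with three donor–acceptor pairs on a
  deterministic schedule (always / every second frame / never bonded).

What passing on these fixtures shows: the estimators are correct — planted
quantities are recovered at their closed-form values, oracles agree to
machine precision, significance tests are calibrated under their null.
What it does not show: behaviour under force-field physics. The fixtures
have no solvent, no anharmonic coupling between modes, no kinetics (the
double well draws i.i.d. states, so populations are exact but transition
paths are meaningless), and Gaussian noise in place of vibrational
structure. Conclusions about a real trajectory still require the usual
care — convergence checks (the KLD diagnostic exists for exactly this) and
sensitivity of results to the fitting selection.

## Problem sizes and reproducibility

The validation suite exercises parameter recovery at 200 residues × 50 000
frames (PCA/DCCM), 10 000-frame null calibrations over 20 seeds (wavelet),
and 15 000-frame double wells — sizes chosen so planted-versus-recovered
comparisons have comfortable statistical margins while a full run stays in
the minutes range on one CPU. All randomness flows through explicit seeds;
generators save and restore the session RNG state, and the pipeline's
manifest records output checksums so that reruns under one seed can be
verified bit-for-bit.

## Known limitations

- No XTC or mmCIF I/O; no topology formats (PSF/prmtop); no trajectory
  imaging/wrapping.
- The ENM is Cα-based with uniform springs: mode *energies* are in
  arbitrary units, and planar/collinear inputs are rejected by design.
- DCCM is the equal-time scalar convention: no time-lagged correlation, no
  mutual-information generalisations.
- Landscapes are limited to two coordinates, and basin extraction is
  geometric — no kinetics, no Markov-state modelling.
- Hydrogen-bond detection is geometric only; no energy scoring, no
  water-mediated bridges.
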