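---
title: "Methods: conformational analysis of saposin-fold hinge proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational analysis of saposin-fold hinge proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapflex)
```

## The scientific problem

Saposin-fold proteins — among them surfactant protein B (SP-B), a
79-residue hydrophobic protein of pulmonary surfactant — form a U-shaped
four-helix bundle whose N- and C-terminal helices are tied together by
three conserved disulfide bonds (in mature SP-B numbering: 8–77, 11–71,
35–46). The two halves of the molecule act as flaps joined by flexible
hinge regions: an *open* conformation exposes the hydrophobic interior for
lipid interaction, a *closed* conformation buries it for stability in
water. sapflex implements the complete trajectory-analysis pipeline used
to characterize this open/closed dynamics from molecular-dynamics output:
superposition statistics (RMSD, RMSF), diagnostic inter-flap separations
with state classification, Boltzmann-inversion free-energy landscapes,
k-means clustering, DSSP secondary structure with helicity occupancy
maps, and radial solvent distribution functions. A synthetic hinge-protein
generator provides exact ground truth for every stage.

## Diagnostic separations and classification

Flap geometry is monitored by two residue separations spanning the flaps:
d1 between residues 7 (helix 1) and 34 (helix 2), and d2 between residues
45 (helix 3) and 70 (helix 4); the conserved cysteine separation 8–35 is
recorded alongside. Separations default to mass-weighted residue centers
of mass (the convention of the common trajectory tools, which measure mask
distances as centers of mass); a CA-only mode is provided for sensitivity
analysis, and the two differ by fractions of an Angstrom for compact
residues.

Frames classify as **open** when both separations lie in 20–40 Å,
**closed** when both lie in 12–17 Å, **partially open** when d1 is in the
closed range while d2 exceeds it (the C-terminal flap separates first),
and **other** otherwise. Boundary values are resolved closed-first with
inclusive bounds; the ranges themselves are configurable. "Other" is kept
as an explicit label rather than snapping to the nearest class so that
reported state fractions stay honest.

## Superposition, RMSD and RMSF

Rigid-body fits use the Kabsch algorithm (SVD of the weighted covariance,
determinant forced to +1 so reflections are excluded). The test suite
cross-checks it against an independent quaternion-eigenvalue
implementation to 1e-8 Å on random instances. The backbone selection
defaults to N, CA, C.

Per-residue RMSF follows the two-pass scheme: compute the iterative
average structure (align all frames to the current average, recompute,
default tolerance 1e-4 Å, at most 10 iterations — convergence is
essentially immediate), align every frame to it, then take mass-weighted
RMS deviations from the per-atom means, aggregated within residues.
High-flexibility regions are maximal runs of residues whose RMSF strictly
exceeds the profile mean plus one standard deviation, with no gap
tolerance. With alignment disabled, i.i.d. Gaussian coordinate noise of
s.d. σ gives the closed form RMSF = σ√3, which the suite verifies.

## Free-energy landscapes

The two separations are histogrammed on half-open bins of width 0.1 Å
whose edges are anchored at integer multiples of the width, so bin
identity is data-independent and count grids from different replicates
pool by exact summation. By default only the final 500 ns of each
trajectory enter the landscape, discarding residual equilibration.
Probabilities P_i = count_i / total convert to relative free energies by
Boltzmann inversion,

  ΔG_i = −RT ln P_i,

with R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹ and T = 310 K, shifted so the
occupied minimum is exactly zero. Unoccupied bins are reported as
undefined (`NA`) rather than infinite, keeping exports finite; renderers
paint them at the top of the color scale.

Two minimum reports are provided. `find_minima()` is the literal
definition — occupied bins strictly below all occupied neighbors — which
is the right tool on constructed or densely sampled grids but is
hypersensitive to Poisson noise: sampled basins fragment into several
strict minima and isolated single-frame bins are vacuous minima.
`basin_minima()` therefore applies topological persistence: bins are
flooded in order of increasing ΔG, basins merge at their connecting
saddle, and a basin's persistence is the barrier height above its own
minimum. Basins still separate after flooding connect through unobserved
territory at the sampling ceiling RT ln(N P_max), the ΔG a single-frame
bin would have. Noise minima sit behind barriers of order
RT ln(count ratio) ≲ 0.7 kcal/mol, while genuine conformational basins in
these landscapes are either disconnected or separated by much larger
barriers, so the default persistence threshold of 1.0 kcal/mol (≈1.6 kT
at 310 K) separates the two regimes with margin on both sides. The
threshold is an analysis parameter of this package, chosen on that
physical argument.

## Clustering

True k-means under a pairwise-RMSD metric is ill-posed — RMSD is not a
Euclidean metric and has no well-defined centroids — so the standard
surrogate is used: all frames are superposed onto the iterative trajectory
average on the backbone selection and their flattened coordinates are
clustered. Lloyd iteration runs with 10 random restarts (best inertia
kept) under a caller-supplied seed; the global RNG state is left
untouched. Clusters are reported in descending size order ("the k largest
clusters"), and each cluster's representative is the member frame closest
to its centroid, which the pipeline projects onto the (d1, d2) landscape.
stats::kmeans supplies the Lloyd iteration; restarts stand in for
k-means++ seeding.

## Secondary structure (DSSP)

Assignment follows the Kabsch–Sander hydrogen-bond formalism. The
electrostatic bond energy is

  E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol,

with a bond declared below −0.5 kcal/mol and energies clamped at −9.9
when atoms overlap (r < 0.5 Å). Amide hydrogens absent from the file are
reconstructed 1.0 Å from N along the preceding residue's O→C bond
direction — the convention of reference DSSP implementations, adopted
here because it reproduces them exactly on ideal geometries (a bisector
placement was evaluated and produces boundary flips at helix caps).
Proline and chain-start residues donate no bond; chains split where
consecutive CA atoms exceed 4.5 Å. n-turns (n = 3, 4, 5) with two
consecutive turn starts produce 3₁₀/α/π helices (G/H/I), Kabsch–Sander
bridge patterns produce strand/bridge (E/B), remaining turns produce T,
and CA pseudo-angles above 70° produce bends (S); per-residue priority on
overlap is H, E, B, G, I, T, S. Agreement with the mdtraj reference
implementation is exact on ideal α- and 3₁₀-helices and on the synthetic
reference models, and the suite enforces ≥95%.

Helicity maps binarize classes to helical = {H, G, I} (π, α, 3₁₀).
Replicates of unequal length are averaged on a common
fraction-of-trajectory axis with 100 time bins by default; occupancy 1
renders white, 0 black, intermediate gray.

## Radial solvent distribution

For each frame the distance from a region's center of mass to every
solvent molecule's reference site (O for water, C for chloroform,
configurable) is histogrammed into 0.5-Å spherical shells to 25 Å by
default, under the minimum-image convention on an orthorhombic box; r_max
may not exceed half the shortest box edge. Shell densities are normalized
by the bulk density N_solvent/V_box averaged over frames, the concrete
reading of "normalized according to the volume of the simulation box":
uniform solvent reads g = 1, making profiles comparable across solvents
of different molecular density. Poisson standard errors are reported per
shell, floored at one count so empty shells carry an honest error bar;
differences between distributions propagate them in quadrature.

## The synthetic generator: what it emulates, and what not

`build_hinge_protein()` constructs a backbone-only (N, CA, C, O) chain
from ideal internal coordinates: four helical segments (φ = −57°,
ψ = −47°) at the conserved regions 9–19, 27–33, 46–61 and 69–72 joined by
extended linkers, arranged as two flaps — helices 1+4 carrying the
disulfide-tied termini, helices 2+3 as the mobile flap. The mobile flap
is placed by numerically solving a rigid transform so the measured
(d1, d2) hit the basin targets, (15, 14) Å closed and (25, 27) Å open by
default, within 0.5 Å; unreachable targets raise an error. Cysteines of
the default (mature SP-B) sequence carry SG pseudo-atoms, placed 2.05 Å
apart across each of the three disulfide pairs, so disulfide detection
has a ground truth. Because no experimental coordinates ship with the
package, these models are explicitly *synthetic stand-ins* whose sequence
facts (79 residues, 9 positive / 2 negative, net +7, 7 cysteines) and
fold topology are real, but whose coordinates are constructed.

`simulate_hinge_trajectory()` drives a two-state Markov chain between the
basins (default switch probability 0.02 per frame in each direction,
giving mean dwells of ~12 ns at the default cadence) and adds isotropic
i.i.d. Gaussian noise of 0.5 Å per coordinate — the simplest model with
closed-form expectations for RMSF (σ√3) and stationary occupancy
(π_open = r_co/(r_co + r_oc)). Defaults emulate a 1000-ns production run
sampled every 0.25 ns (4000 frames). All randomness derives from one
seed, and the global RNG state is restored afterwards.

Deliberate idealizations, hence what passing tests do *not* show about
real data: thermal motion is uncorrelated between atoms, so backbone
geometry degrades faster with σ than physically plausible — i.i.d. noise
beyond ~0.2 Å already disrupts the sharply distance-dependent DSSP
H-bond energies, which is why helicity-focused checks run at σ = 0.1 Å
while separation/landscape checks use the default 0.5 Å; solvent is an
ideal gas with no first-shell structure; boxes are cubic (truncated
octahedra are out of scope); transitions are instantaneous jumps with no
intermediate states; and linker torsions are fixed, so the hinge protein
has no internal flexibility beyond noise.

## Numerical choices and degenerate inputs

* Disulfide detection: greedy nearest-first matching of SG pairs under a
  2.5 Å cutoff (typical S–S bond 2.05 Å); each sulfur pairs at most once;
  cysteines without SG warn and are skipped.
* Charge census at pH 7.4: Arg/Lys positive, Asp/Glu negative, His
  neutral — the only assignment consistent with the mature chain's
  printed 9/2/+7 census; free termini contribute +1/−1 and cancel.
* Superposition requires ≥3 non-collinear atoms; degenerate geometry is
  an error, not a silent fallback.
* k-means with fewer distinct frames than k reduces k with a warning;
  k exceeding the frame count is an error naming the stage.
* Landscape windows longer than a replicate fall back to the full series
  with a message in the pipeline, and are an error when windowing is
  called directly.
* Masses come from a built-in standard table keyed by element, with
  elements inferred from PDB atom names (ions disambiguated by residue
  name); unknown residue codes warn and keep their atoms.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on synthetic data
at sizes chosen to make the statistical assertions sharp at interactive
cost: 10,000 frames for stationary-occupancy recovery (3 binomial
standard errors ≈ 1.5%), the default 4000-frame run for the end-to-end
pipeline, 300–400 frames for RMSF closed forms, and 100 random instances
for the quaternion cross-check. These sizes are package choices; all of
them scale linearly if larger runs are wanted.

## Known limitations

Only orthorhombic/cubic periodic boxes are supported in the solvation
module; mmCIF/DCD/XTC readers, bond-order perception and protonation
prediction are out of scope; no β-bulge handling or polyproline-II class
in DSSP; no KDE or reweighting estimators for the landscapes — the method
is deliberately the plain histogram inversion; and printed RMSF
magnitudes from long heterogeneous MD runs depend on alignment
conventions that cannot always be reconstructed, so the package commits
to the literal two-pass scheme described above.
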