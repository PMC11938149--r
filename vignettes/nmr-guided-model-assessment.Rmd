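---
title: "Assessing protein-protein complex models against NMR titration data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing protein-protein complex models against NMR titration data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdock)
```

## The problem

Weak, transient protein-protein complexes (dissociation constants in
the micromolar range, as for the bacterial division inhibitor MinC
binding the tubulin homolog FtsZ) often cannot be crystallized or
frozen for cryo-EM. Solution NMR titrations still carry structural
information: amide peaks of residues at or near the binding surface
move (chemical shift perturbations) or vanish (broadening beyond
detectability, the signature of intermediate-exchange binding). That
information is residue-level, not atomic, so it cannot produce a
structure by itself — but it is an excellent *judge* of candidate
structures produced by docking, AlphaFold-Multimer or molecular
dynamics. `nmrdock` implements that judging pipeline end to end, with
synthetic ground-truth generators so every stage is testable offline.

## The model

### Chemical shift perturbation

For a residue assigned in both the apo and the titrated spectrum,

$$\Delta\delta = \sqrt{(\Delta\delta_H)^2 +
  \left(\frac{\Delta\delta_N}{\alpha}\right)^2} \quad \text{[ppm]},$$

with the ¹⁵N change down-weighted by $\alpha = 10$ (configurable),
reflecting the roughly ten-fold wider ¹⁵N shift dispersion. The
statistic is non-negative, zero iff both changes are zero, monotone in
each axis, and symmetric under sign flips — properties the test suite
asserts. A residue assigned in the apo state but absent from the bound
state is classed `broadened`; when peak intensities are available, a
bound/apo intensity ratio below 0.15 (configurable) also counts as
broadening. Prolines have no amide and are classed `no_amide`.

### Significance threshold

Published work typically quotes a single cutoff σ (e.g. 0.021 ppm for
one partner, 0.012 ppm for the other in the MinC/FtsZ study) without
stating its derivation. The package default is the field-standard
iterative trimmed SD: compute the sample SD of all defined Δδ, discard
values above 3×SD, repeat. Two numerical choices deserve note:

* **Collapse guard.** The uncentered trim rule can cascade: when the
  surviving values cluster tightly around a nonzero mean, every value
  exceeds 3×SD and the iteration would discard everything. The
  implementation stops as soon as fewer than two values would survive
  and returns the last SD computed on at least two values. This also
  reproduces the intended behavior on the canonical example (95
  baseline values plus 5 large outliers: the result is the SD of the
  95).
* **Broadened residues never enter the statistic** — they carry no
  Δδ. Whether the published σ values included them is unknowable from
  the paper; excluding them is the only self-consistent choice.

A `fixed` method accepts a literature value directly; σ is always
recorded in the perturbed-set output.

### Perturbed set and model scoring

$I_{NMR}$ = residues with $\Delta\delta \ge \sigma$, plus (by default)
broadened residues — peak disappearance is positive evidence of
binding, so excluding it would bias coverage downward. $I_{pred}$ =
residues of one partner with any atom, hydrogens included, within 5 Å
of the other partner. If a model carries no hydrogens the computation
falls back to heavy atoms at the same cutoff, with a prominent
warning, rather than silently rescaling — the cutoff is part of the
published protocol.

Coverage and error share one denominator:

$$C\% = 100\,\frac{|I_{pred} \cap I_{NMR}|}{|I_{pred}|}, \qquad
E\% = 100\,\frac{|I_{pred} \setminus I_{NMR}|}{|I_{pred}|}.$$

`error_pct()` is computed as `100 - coverage()` so the invariant
$C + E = 100$ holds exactly in floating point; the integer counts are
kept on the score card. Models are ranked by the ratio $C/E$. The
ratio is undefined at $E = 0$; such models are by construction the
best possible and are ranked above every finite ratio, ordered among
themselves by $C$, with remaining ties broken lexicographically on the
model id so the order is total and reproducible. When models with
different constructs are compared, an optional common-residue
restriction intersects $I_{pred}$ before scoring; it applies to both
numerator and denominator (same-denominator convention), which the
score card records.

### Interface features

Buried surface area is SASA(A) + SASA(B) − SASA(AB), each term from a
Shrake–Rupley calculation: probe 1.4 Å, 960 deterministic
golden-spiral points per atom, Bondi-style radii (1.8 Å for unknown
elements), heavy atoms only, hetero atoms excluded — all
configurable. The published buried-area figure for the FtsZ:MinC
complex (2353 Å²) does not state the tool or probe used, so the
benchmark tolerance is deliberately loose (±7%). Contact polarity uses
a simple rule the paper leaves unstated: an atom is polar if its
element is N, O or S, hydrogens inherit the class of their bonded
heavy atom, and a residue pair is polar if any in-cutoff atom pair is
polar on both sides.

### Trajectory analysis

Contact frequency is the percentage of window frames in which a
residue pair has any-atom distance ≤ 5 Å; 100% means present in every
analyzed frame; unordered pairs are counted once. Hydrogen bonds
require donor–acceptor distance ≤ 3 Å *and* deviation of the D–H···A
angle from linearity ≤ 20° in the same frame; "angle cutoff"
conventions differ between tools, and the deviation-from-linearity
reading is used here, documented and configurable. Donors are N/O
with a covalently bonded hydrogen, inferred distance-wise (H within
1.2 Å) when connectivity records are absent. The ligand RMSD series
superposes each frame's receptor selection onto the reference frame
(frame 1, the initial configuration) by a Kabsch fit and measures the
ligand selection without further fitting; disordered tails are
excluded by residue ranges supplied by the user. There is no
automatic convergence detection: the analysis window is a user
parameter, defaulting to all frames (published practice was the
converged last half of the simulation).

Clustering builds a pairwise RMSD matrix on a selection (after
optional receptor alignment), applies agglomerative clustering
(average linkage by default, threshold in Å), and reports as
representative the frame with minimum RMSD to the coordinate-wise
mean of the most populated cluster. Ties — equal cluster sizes, or
equal RMSD to the mean — resolve to the lowest frame index, making
the result deterministic and permutation-stable as a partition.

### Restraint bookkeeping and relaxation

NOE distance restraints are classed purely by sequence separation
|i−j|: 0 intraresidue, 1 sequential, 2–4 medium range, ≥5 long range.
Relaxation decays are fit to $I(t) = I_0 e^{-Rt}$ by least squares
(log-linear start, Gauss–Newton refinement); the uncertainty on $R$
is the standard error from the fit covariance, into which replicate
delays feed naturally, so duplicated delays with differing
intensities always produce a nonzero uncertainty. Noiseless data are
detected (residual of the log-linear fit below 1e-10) and returned
exactly without iterative refinement. Non-decaying input yields a
result flagged invalid rather than an error. The heteronuclear NOE is
the per-residue saturated/reference intensity ratio.

## The synthetic world

The generators state a simplified but fully controlled world:

* `make_complex()` builds two chains of internally ideal alanine-like
  residues (N, H, CA, C, O, CB) on a coarse two-row grid (12 Å
  spacing, 14 Å row offset). Exactly `n_contacts` residue pairs sit
  within 4.5 Å — each as a geometrically perfect, linear N–H···O
  hydrogen bond at 2.9 Å donor–acceptor distance — and every other
  inter-chain residue pair is farther than 6 Å. The generator
  verifies these margins after construction. Consecutive residues are
  *not* covalently connected: a connected chain cannot satisfy the
  contact/separation contract, and a quasi-1D chain makes rigid-body
  alignment ill-conditioned (rotation about the chain axis is
  unconstrained), which would corrupt the closed-form RMSD
  expectation used as an oracle. The two-row layout gives the chains
  genuine 3D extent.
* `make_titration()` draws baseline shifts per residue (¹H ~ N(8.3,
  0.4), ¹⁵N ~ N(119, 3.5) ppm, typical amide ranges), adds to
  interface residues a perturbation of exact combined magnitude
  `effect` split at a random phase between the ¹H and (×10) ¹⁵N axes,
  adds per-axis Gaussian noise everywhere (¹⁵N noise 10× the ¹H
  noise, honoring the weighting), and deletes a chosen fraction of
  interface residues from the bound table to emulate broadening. The
  stated acceptance world is effect = 3σ and noise = σ/3 with σ =
  0.02 ppm, between the two published thresholds.
* `make_trajectory()` keeps frame 1 as the exact complex (the RMSD
  reference) and jitters later frames i.i.d. per coordinate;
  optionally chain B is rigidly displaced from a chosen frame onward,
  destroying contacts, hydrogen bonds and pose membership at a known
  frame count. With reference jitter zero the expected ligand RMSD is
  $\sqrt{3}\,\sigma_{xyz}$, the closed form used in testing.
* `make_decay()` produces $I_0 e^{-Rt}(1+\epsilon)$ with
  multiplicative Gaussian noise.

All generators consume an integer seed, restore the caller's RNG
state, and are bit-reproducible; structures round-trip through the
package's own PDB reader.

What a green test does **not** establish: the generators contain no
real protein geometry (side chains, secondary structure, physical
contact densities), no chemical-shift physics (ring currents,
exchange broadening lineshapes), no correlated MD motion, and no
titration-series Kd behavior. Green means the *algorithms* implement
their definitions correctly at controlled effect sizes — not that the
thresholds will perform identically on experimental spectra.

## Numerical and design choices

* Backbone atom set for RMSD: N, CA, C, O (configurable through
  selections); "backbone" in published methods rarely states whether
  O is included.
* Ensemble structures default to conformer 1; any conformer is
  selectable, since published comparisons usually do not state which
  ensemble member was used.
* Altloc handling on reading: highest occupancy wins; dropped records
  are logged.
* Residue renumbering is per-chain integer offsets (e.g. mapping
  author numbering to UniProt); original numbers are retained, and a
  shift that would collide with insertion-coded identifiers is an
  error.
* Kabsch superposition excludes reflections (det = +1) and refuses
  fewer than three non-collinear atoms.
* The interface cutoff comparison is inclusive (≤ 5 Å), as are the
  hydrogen-bond cutoffs (≤ 3 Å, ≤ 20°); boundary tests pin this.
* Percentages are reported to one decimal in CLI output; comparisons
  and ranking use full precision with integer counts.

## Limitations

* PDB and mmCIF only; no DCD/XTC binary trajectories — multi-model
  PDB or frame directories stand in.
* No Kd fitting from titration series, no peak picking, no model-free
  dynamics analysis, no docking or structure prediction, no
  electrostatics or ΔG estimation.
* The mmCIF and NMR-STAR readers cover the single-block coordinate
  and chemical-shift-loop subsets the pipeline needs, not the full
  formats.
* Benchmarks against deposited ensembles (backbone RMSD between
  solution and crystal structures; buried area of the published
  complex model) require the user to supply the coordinate files;
  they are not redistributable with the package.
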