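---
title: "Methods: gas-phase compaction and rehydration recovery analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gas-phase compaction and rehydration recovery analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacuform)
```

## The problem

When a protein is electrosprayed into a mass spectrometer it exchanges its
aqueous environment for vacuum. Two things happen that this package
quantifies. First, the charge state changes: in solution the side chains
are ionized according to their pKa at the working pH, while in the gas
phase the ion carries a fixed net charge set by the ESI process, so
specific residues must be assigned additional protons. Second, the
conformation responds: without water the structure compacts by several
percent in collision cross-section, and if the ion is returned to solvent
one can ask how completely the solution conformation is recovered.

`vacuform` implements the analysis layer for this cycle on ensembles of a
two-chain homodimer: protonation-site assignment, geometric observables
(CCS, SASA, volume), trajectory statistics (RMSD, RMSF, contact maps,
hydrogen bonds), and the compaction/recovery bookkeeping, plus a synthetic
generator that produces three-phase ensembles with analytically known
answers. Running molecular dynamics itself is out of scope: the package
consumes structures and multi-model PDB trajectories, it does not produce
them.

## Data model

An atom table (tibble) carries one row per atom: serial, name, element,
chain, 1-based residue number, residue name, coordinates in Å, van der
Waals radius and formal charge. Residue numbers are 1-based everywhere —
internally and in all I/O — because that is both the PDB convention and
the R convention; maintaining a 0-based internal index would invite
off-by-one errors for no benefit. Radii come from a Bondi-style element
table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å, configurable);
unknown elements get a default radius with a warning.

A trajectory ensemble couples one topology with a list of frame coordinate
matrices and strictly increasing frame times in ns; a replica set groups
trajectories sharing a topology and a phase label (`bulk`, `vacuum`,
`rehydration`). All analyses except hydrogen-bond counting are defined on
heavy atoms, so hydrogen-free structures are first-class inputs.

## Vacuum protonation protocol

The assignment pipeline mirrors the workflow used for charge-state
preparation of gas-phase simulations:

1. **Solution charges.** At pH 7, Asp/Glu are −1, Lys/Arg +1, His 0, and
   each chain gets +1/−1 termini. The rule table is replaceable for other
   conditions.
2. **Per-residue SASA** over the supplied solution frames (mean ± sd
   across frames), restricted to the six candidate types Lys, Arg, His,
   Gln, Asp, Glu.
3. **Threshold**: residues with mean SASA below 50 Å² are disregarded
   (strictly smaller areas are dropped; 50.0 survives).
4. **Ranking** by gas-phase basicity, descending; ties break by larger
   SASA, then lower residue number. The default GPB table
   (Arg 1007 > His 958 > Lys 951 > Gln 937 > Glu 910 > Asp 885 kJ/mol)
   encodes the literature ordering of side-chain proton affinities; only
   the ranks matter and the table is user-overridable.
5. **Neighbor exclusion**: a candidate beside a +1 residue is skipped.
   "Beside" defaults to sequence-adjacent (±1 in the same chain), the only
   parameter-free reading; a spatial mode (charged-group centroid within a
   cutoff) is available when a distance scale is preferred. Chain termini
   are also excluded as sites: their exposure and charge are dominated by
   the terminal amine/carboxylate, and their residue-level charge
   bookkeeping conflates side chain and terminus.
6. **Greedy assignment** walks the ranked list until the target charge is
   reached exactly. Each protonation adds +1 e: acidic sites are
   neutralized (−1 → 0), His/Gln gain a charge (0 → +1), and Lys/Arg —
   already protonated at pH 7 — are visited but skipped. In symmetric mode
   (the default for homodimers) an accepted position is applied to every
   chain simultaneously, consuming `n_chains` charge units per step, and
   must be eligible in all chains; a charge deficit not divisible by the
   chain count is a parity error, and exhausting the candidates reports
   the shortfall.

The plan records every visited site with its outcome (selected, excluded
and why, skipped, not needed), so the output doubles as an audit table.

## Geometry kernels

**SASA** uses the Shrake–Rupley construction: each atom's sphere is
expanded by the probe radius (default 1.4 Å, water) and covered with a
deterministic Fibonacci lattice (default 960 points); the accessible area
is `4π(r+p)²` times the fraction of points outside all neighbouring
expanded spheres. Determinism makes the per-residue tables reproducible;
the point count trades accuracy for time (closed-form sphere tests pass at
~0.2 % with 960 points).

**Volume** counts voxel centres (default 0.3–0.4 Å spacing) inside at
least one atomic sphere over a padded bounding box.

**Collision cross-section** uses the plain projection approximation: the
union area of probe-expanded discs (default probe 1.0 Å, helium-like)
projected along random orientations, averaged. Orientations are uniform
random rotations from seeded quaternions; each projection's area is
measured by deterministic rasterization (0.5 Å pixels), so the only
randomness is the orientation sample and the Monte-Carlo standard error is
reported (and halves when the orientation count quadruples). No
trajectory-method calibration is applied; an optional multiplicative
calibration constant defaults to 1.0, because the analyses here compare
CCS values relatively. Absolute experimental CCS agreement is explicitly
not a goal. A deterministic fine-grid oracle over a fixed quasi-uniform
direction set (`ccs_grid_oracle()`, ≤100 atoms) cross-validates the PA
kernel to within 1 %.

## Trajectory metrics

RMSD uses Kabsch superposition (SVD, proper rotation enforced) on a
configurable selection (default Cα). The ensemble-average structure is
computed iteratively — superpose all pooled frames on the running mean,
recompute, repeat until the mean moves < 1e-6 Å — and RMSF is the
root-mean-square displacement from that average after per-frame
superposition, reported per residue. Pooling frames across replicas makes
RMSF of a replica set identical to RMSF of the concatenated trajectory.
Averages across replicas at fixed time points report sd; time-window
aggregates report sem over the pooled values.

Contacts are defined by minimum heavy-atom distance ≤ 3.5 Å between two
residues; occupancy is the fraction of (replica, frame) pairs in a window
showing the contact, so 0 means "never, in any replica". The matrix keeps
the diagonal and sequence neighbours (maskable in plots). Hydrogen bonds
use the GROMACS-like geometric criterion (donor–acceptor ≤ 3.5 Å, H–D–A
angle ≤ 30°); without hydrogens a distance-only donor-heavy/acceptor proxy
is used and flagged in the result.

## Compaction and recovery

Phase-level estimates average the final fraction of each trajectory
(default 0.1 — the last 50 ns of a 500 ns run — chosen because the tails
are approximately stationary). Then, per metric:

- compaction % = 100 (bulk − vacuum_tail)/bulk,
- recovery % = 100 (1 − |bulk − rehydration_tail|/bulk); the absolute gap
  means overshooting the solution reference is penalized like
  undershooting, although compacted ions in practice undershoot.

Contact recovery binarizes the three occupancy matrices at 0.5 (explicit
config; the raw matrices are always emitted) and compares unordered
off-diagonal pairs: the restored fraction of bulk contacts, and the
persistent fraction of vacuum-only contacts that survive rehydration.

## The synthetic generator, and what it does not emulate

`build_toy_dimer()` constructs two sequence-identical 24-residue chains of
four heavy backbone atoms per residue on a compact spherical-spiral body
with one protruding hairpin-like loop per chain (a stand-in for a mobile
FG-type hairpin). The residue census is fixed so the dimer sits at +2 e at
pH 7 and the protonation protocol is fully exercisable: eligible acidic
and amide sites, a Lys-adjacent excluded site, and surplus candidates all
occur by construction.

`generate_phase_ensemble()` produces frames as
`scale(t) · (X₀ − centroid) + centroid + jitter`, with per-coordinate
Gaussian jitter (default σ = 0.3 Å; ×3 on loop residues) and designated
residue pairs stochastically toggled into contact. The default scenario
uses a vacuum scale decaying from 1.0 to 0.96 and a rehydration scale
relaxing to 0.9875, i.e. a small residual offset so recovery is high but
below 100 %. Affine scaling plus heteroscedastic jitter is the minimal
generative model reproducing every statistic the pipeline measures with
evaluable expectations; it makes no attempt at physical realism. Note that
with finite atomic radii a centre-contraction to 0.96 yields a PA-CCS
compaction of roughly 4 % on this toy (the radii do not shrink), not the
(1 − 0.96²) ≈ 8 % a point-cloud argument would give; the ground truth is
therefore always evaluated geometrically rather than by the s² shortcut.

`ground_truth()` evaluates the expected per-phase CCS/SASA/volume directly
on the deterministically scaled reference — no ensemble sampling — and
adds, for each toggle pair, the probability-weighted metric and
contact-map difference of the deterministically toggled configuration.
This linearization is exact when toggles act independently, which the pair
picker guarantees by enforcing spatial clearance between all vacated and
occupied sites (`pick_toggle_pairs()`); expected RMSF is σ√3 × boost
(flagged invalid for toggled residues); expected occupancies mix the
untoggled and toggled contact maps by the toggle probability.

What passing the end-to-end tests shows — and what it does not: the
pipeline recovers programmed compaction, recovery, fluctuation contrasts
and contact statistics from sampled ensembles within stated tolerances.
It does not show that a real force field produces such ensembles, nor
that absolute CCS/SASA values match experiment; real MD output has
anharmonic, correlated fluctuations the generator deliberately lacks.

## Numerical choices and degenerate inputs

- Superposition requires ≥3 non-collinear selected atoms; collinear or
  coincident selections raise a degeneracy error rather than returning an
  ill-conditioned rotation.
- Jitter inflates projected areas slightly relative to the jitter-free
  ground truth; the bias is shared across phases and largely cancels in
  the compaction/recovery ratios (observed residuals are a few tenths of a
  percentage point, within the 1 % acceptance band).
- Contacts whose distance lands within the jitter band of the 3.5 Å cutoff
  flicker; their binarized status is seed-dependent. This is a property of
  the measurement, so contact-persistence comparisons use a binomial CI on
  the number of vacuum-only contacts rather than exact equality.
- Coincident atoms in SASA are both retained (a warning is logged); empty
  candidate lists, empty contact windows, charge-parity violations and
  exhausted candidate walks raise informative errors.
- GPB values and the 0.5 contact binarization threshold are configuration,
  not constants; every default lives in `pipeline_config()`.

## Problem sizes

The shipped defaults — 2 × 24 residues (192 atoms), 6 replicas × 30 frames
per phase, 32 CCS orientations per frame, 240 SASA points in series
evaluations — run the full pipeline in about four minutes on one CPU and
were chosen as desk-scale stand-ins for production ensembles (hundreds of
replicas of 500 ns). All sizes are parameters of `phase_spec()` /
`pipeline_config()`; the statistical tolerances in the test suite are set
for these defaults.

## Known limitations

- Proton placement is static: no proton mobility or migration between
  sites, no pKa prediction — the protocol reproduces a defensible initial
  charge configuration, not charge dynamics.
- PA-CCS underestimates drift-tube CCS for concave shapes; only relative
  comparisons are meaningful at calibration 1.0.
- The H-bond proxy mode (no hydrogens) overcounts relative to the angle-
  gated criterion and is only suitable for phase-to-phase comparisons, for
  which it is flagged.
- The generator's affine compaction cannot produce genuinely new folds;
  contact rearrangements are injected, not emergent.
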