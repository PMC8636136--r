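---
title: "A coarse-grained model of promoter DNA opening in the Pol II pre-initiation complex"
author: "cgpic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of promoter DNA opening in the Pol II pre-initiation complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpic)
```

## The problem

Transcription initiation by RNA polymerase II requires opening the promoter
duplex inside the pre-initiation complex (PIC). Cryo-EM has produced static
snapshots of three states along this path — the closed complex (CC, intact
duplex outside the cleft), the open complex (OC, a small DNA bubble with the
template strand near the active site), and the initially transcribing complex
(ITC, a ~13-bp bubble with the template strand engaged) — but the dynamics
connecting them are not directly observable. `cgpic` implements a
structure-based (Go-type) coarse-grained simulation and analysis pipeline for
studying this transition: the energy model, Langevin dynamics with the
mismatch-melt / sequence-revert / annealing protocols, and the trajectory
statistics used to characterize the states (DNA bubble size, state-specific
contact fractions, fork-loop gate distances).

## Representation and energy model

Each amino acid is one bead at its C-alpha position; each nucleotide is three
beads at the phosphate-group, sugar-ring and base-ring centroids (the
5'-terminal phosphate is absent). The energy function has eight terms, each
independently testable against numerical gradients:

* **Protein local terms**: harmonic virtual bonds and angles plus
  native-biased periodic dihedrals, with native values taken from the
  reference structure. This is a simplified fixed-constant parameterization of
  the flexible local potentials used by atomistic-informed CG protein models;
  the simplification is a design choice to keep every constant transparent.
* **Intra-protein native contacts**: 12-10 wells
  \(\epsilon[5(r_0/r)^{12} - 6(r_0/r)^{10}]\) between residue pairs within
  8 Å in the reference structure (sequence separation ≥ 4), depth
  0.6 kcal/mol.
* **DNA model**: a simplified three-site-per-nucleotide parameterization in
  the spirit of 3SPN-class models — harmonic backbone bonds/angles, periodic
  backbone dihedrals, nearest-neighbour intra-strand stacking wells
  (1.2 kcal/mol), and orientation-dependent Watson-Crick pairing wells. The
  pairing well multiplies a 12-10 radial well by a Gaussian factor in the two
  sugar-base-base flanking angles (width 0.35 rad), penalizing non-facing
  geometries. A:T wells are 2/3 the depth of G:C wells (two versus three
  hydrogen bonds). The pairing core is flattened below ~0.89 r0 so that
  re-enabling pairing on a distorted geometry (the sequence-revert protocol)
  produces a bounded force; true overlap is handled by excluded volume.
* **Protein-DNA native contacts**: 12-10 wells on the union of the contacts
  detected in the three reference states, \(\epsilon_{go}\) = 1.2 kcal/mol.
  Contact wells are truncated and shifted at \(2 r_0\): a contact broken far
  beyond its native distance exerts no force, which keeps the three state
  basins local in configuration space.
* **Excluded volume**: purely repulsive \(r^{-12}\) with per-kind radii
  (CA/P/S 2.0 Å, B 1.5 Å), truncated-shifted, linearly capped at small
  separations so the energy is finite at r = 0.
* **Electrostatics**: Debye-Hückel screened Coulomb at 200 mM monovalent
  salt and 300 K (Debye length ≈ 6.8 Å), cutoff at 3.5 Debye lengths with a
  shift to continuity. Charges are fixed: −0.6 e per phosphate
  (counterion-condensation convention), +1 e on Lys/Arg, −1 e on Asp/Glu.
  This is a deliberate simplification relative to surface-charge-optimized
  protein models; the package documents it as its own convention.

Forces are exact analytic gradients; the test suite checks every term against
central differences at 10^-4 relative accuracy, and checks invariance under
rigid motion. Near-collinear angles and dihedrals use a clamped (bounded)
gradient so rare degenerate geometries cannot kick the integrator; the clamp
engages only where the exact gradient would diverge.

## Dynamics

Propagation is BAOAB-splitting Langevin dynamics. Units are Å, kcal/mol and
amu-scale masses (CA 110, P 95, S 83, B 110), giving a reduced time unit of
~50 fs; defaults are a 0.2 time-unit step and friction 0.25 per time unit,
common CG practice. Temperature protocols (piecewise-linear annealing
schedules, e.g. a 300 K → 1 K quench before structure export) are supported.
Runs are bit-reproducible for a given seed via a self-contained xoshiro256++
generator; zero friction reduces the integrator to velocity Verlet, which the
suite uses to verify energy conservation, and equipartition is verified at
150/300/600 K.

Step counts quoted in protocols are integrator steps. Published protocols of
this kind use 5×10^6–2×10^7 steps per run on cluster hardware; the package's
defaults are ~100× smaller so that full protocol ensembles complete on one
CPU in minutes. All step counts are arguments, so the full-scale protocol is
one argument away.

## Calibrations — part of the method, not post-hoc tuning

Two quantities are calibrated, and both calibration procedures ship in the
package:

* **Pairing depth** (`eps_bp`). `calibrate_pairing_strength()` scans the G:C
  well depth so that a free 20-bp duplex at 300 K / 200 mM shows a 0.3%
  per-(frame,pair) probability of a base-base distance beyond 6.2 Å — the
  same statistic used to define a broken pair in the analysis. The shipped
  default, 9.25 kcal/mol, was fixed by this procedure (10 seeds × 10^6
  steps; the per-seed spread of the rare-event rate is roughly ±50%, so the
  default targets the pooled mean). `calibrate_break_threshold()` inverts the
  relationship: on the calibrated model it recovers ~6.2 Å from the 0.3%
  target.
* **Contact strength** (`eps_go`). `calibrate_epsilon()` implements the
  four-condition protocol for the protein-DNA well depth: (1) CC keeps the
  DNA/E-wing contact; (2) OC keeps template-strand contacts near the active
  site; (3) OC and ITC keep the upstream-DNA/TFIIE contacts; (4) the
  N50E/K51E/T52E charge-flip triple mutant loses them. Probes run short
  equilibrium simulations and score mean contact survival over the
  equilibrated half of each run against a 0.5 criterion; the scan returns the
  smallest depth satisfying all probes. At the CG resolution the mutation is
  modeled as a +1 → −1 charge flip plus deletion of the residues' Go
  contacts, since beads carry no side-chain geometry.

## The synthetic three-state testbed

Reproducing the cryo-EM systems requires downloading the deposited structures
and cluster-scale runs, so the package ships a generator
(`build_toy_pic()`) for a desk-scale stand-in with the same *statistical*
structure:

* a solenoidal clamp protein (default 110 residues) whose serpentine arcs
  enclose a channel, with a flexible gate loop arcing across the channel
  mouth. The gate loop carries local terms only (no intra-protein contacts),
  so it fluctuates open — the analog of fork loop 1. Its shut conformation is
  the native; `restrain_group()` pins it shut.
* an ideal B-form duplex (fiber values: rise 3.38 Å, twist 34.3°/bp) posed
  in three reference states: CC-like (outside the mouth, displaced along the
  channel axis), OC-like (at the mouth, its 15-position mismatch window
  pre-melted), ITC-like (threaded on the axis past the gate loop). Poses are
  displaced both laterally and axially so that contacts are bead-specific:
  sliding the duplex changes the register and breaks one state's contacts in
  the others.
* contact sets of exactly the prescribed sizes 92 (CC) / 22 (OC) / 118 (ITC)
  with 19 of the 22 OC contacts shared with ITC — the subset structure the
  analysis assumes (CC contacts specific; OC mostly contained in ITC;
  99 ITC-unique). Selection filters guarantee that a state's contacts are
  beyond their wells' truncation range in the other poses, with one
  deliberate exception: a tranche of ITC-unique contacts (default 70) is
  drawn from the "approach band", where the well already reaches toward the
  OC pose. These wells are the driving force of the OC → ITC transition once
  the E-wing-analog hold is released — mirroring the proposed mechanism, in
  which E-wing detachment gates the template strand's descent.

What the toy does *not* emulate: sequence-realistic DNA geometry and
elasticity, the real subunit architecture, RESPAC-optimized electrostatics,
and the absolute time scales of the transition. Tests passing on the toy
demonstrate that the pipeline's statistics, protocols and gating logic behave
as specified on a system with known ground truth; they do not by themselves
validate predictions on the cryo-EM systems, for which
`scripts/reference_structures.R` documents the accession-dependent workflow
(contact counts 92/22/118, the 19/22 overlap, protein CC-vs-OC RMSD
~0.85 Å).

## Trajectory statistics

* **Bubble size**: count of Watson-Crick pairs with base-bead distance above
  6.2 Å, optionally restricted to a TSS-relative window. TSS numbering skips
  zero; intervals are half-open.
* **Contact fractions**: fraction of a state-characterizing subset formed,
  with formation defined as \(r \le 1.2\, r_0\) (standard Go convention).
* **State labels**: deterministic cutoffs on (f_CC, f_OC, f_ITC) with E-wing
  and gate flags separating the I1/I2 intermediates. The defaults (CC ≥ 0.6;
  pre-OC at f_CC ≤ 0.3 with f_OC in [0.25, 0.7); OC at f_OC ≥ 0.7 with
  f_ITC < 0.25; I1/I2 at f_ITC in [0.25, 0.7); ITC ≥ 0.7) anchor the
  qualitative fractions reported for these states (~80% CC loss and ~40% OC
  formation at pre-OC; ~35% ITC formation at I1) and are all configurable.
* **Gate distance**: distance between the centers of mass of the gate-loop
  analog and an anchor group (in the real system: fork loop 1 of Rpb2,
  residues 468–476, versus the TFIIB B-linker, residues 99–102). The
  gate-open threshold defaults to the closed-state mean + 2 SD estimated from
  the first decile of the trajectory, since no absolute value is published.
* **Moving average**: centered, 11 points by default, truncated at the edges.
* **RMSD**: Kabsch superposition; for multi-state reference sets the RMSD is
  computed over protein beads only, as DNA differs qualitatively between
  states.

## Protocols

`protocol_cc_to_oc()` runs the mismatch route: introduce a 15-base mismatch
(each non-template base replaced by the opposing template base, guaranteeing
non-complementarity — the deposited mismatch sequence is not printed in the
source structures, so an explicit string can be supplied), simulate, detect
the pre-OC/OC pause (label stable over the trailing 10% of the segment),
revert to the native sequence, and continue. Melting and re-pairing happen
dynamically; revert touches only the topology. `protocol_oc_to_itc()` runs
the second leg with optional E-wing weakening (`weaken_contacts()`, the
intentional-weakening variant) and optional gate restraint. Ensembles report
terminal labels, transition counts, per-state bubble statistics, I2 dwell
frames and gate-opening events; each run is seeded, divergent runs are
flagged and excluded with a log line, and full reruns are bit-reproducible.

## Numerical choices and degenerate inputs

* Timestep 0.2 reduced units with bond constants of 100 kcal/mol/Å^2;
  the stiffest oscillation is resolved by ~15 steps per period.
* The 12-10 well is linearly continued below 0.3 r0 (finite at r = 0); the
  excluded volume is capped below 0.55 σ; the divergence guard aborts a run
  when |E| exceeds 10^7 kcal/mol and reports the step.
* Pairing for non-complementary bases is refused at topology construction;
  mismatch windows instead *disable* the pairing term, and disabled pairs
  regain excluded volume so melted strands cannot interpenetrate.
* Ties in Watson-Crick pair detection (real structures) resolve to the
  mutually nearest complementary pair; r0 conflicts for a contact present in
  several states resolve by CC > OC > ITC priority with a warning beyond 2 Å.
* `build_reference_set()` requires identical protein composition and
  ordering; it does not attempt to reconcile differently-modeled residues
  (missing residues are reported at read time and excluded, never rebuilt).

## Problem sizes used by the shipped tests

The test-suite and acceptance runs use a 20-bp duplex (10^6 steps × 3 seeds
for the break-rate check), the 110-residue toy PIC with 10-run ensembles of
1–1.5×10^5 steps per protocol arm, and 12-bead chains for integrator checks.
These sizes were chosen so the entire suite runs on a single CPU in well
under half an hour while leaving each stochastic criterion enough sampling
for its stated tolerance.

## Known limitations

* The DNA model is a deliberately simplified two-class (A:T/G:C)
  parameterization: no sequence-dependent elasticity beyond the two pairing
  depths, no single-strand stacking thermodynamics, no major/minor groove
  asymmetry.
* Fixed unit charges instead of surface-charge optimization shift the
  electrostatic balance; conclusions that depend on fine electrostatics
  should be re-checked with a better charge model.
* The calibrated 0.3% break rate is a rare-event statistic with large
  seed-to-seed variance (~±50% per 10^6-step run); comparisons should pool
  several seeds, as `duplex_break_rate()` does.
* The toy PIC's transition rates are engineered to be observable at desk
  scale; they carry no physical time-scale information.
* In the toy, nothing stabilizes an open bubble once the native sequence is
  restored, so the window re-anneals during the second protocol leg; the
  sustained 8.2 ± 1.7 bp (OC) and 13.4 ± 1.1 bp (ITC) bubbles of the real
  systems are only reachable with the cryo-EM structures at full protocol
  scale (see `scripts/reference_structures.R`).
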