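---
title: "Coarse-grained event-driven DMD of cadherin dimer disruption: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained event-driven DMD of cadherin dimer disruption: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgdmd)
```

## What this package models

Vascular endothelial (VE-)cadherin holds the endothelial barrier together
through a strand-swapped *trans* dimer of its outermost EC1 domains.
Anionic amyloid species — monomers, oligomers and fibril seeds — can bind
this dimer and weaken it, which is one proposed molecular route to
amyloid-induced endothelial leakiness.  `cgdmd` implements, at one bead
per residue and desk scale, the in-silico pipeline used to probe that
mechanism: replica binding simulations of a dimer with each amyloid
species, constant-force steered simulations over a 0–60 pN grid, and the
derived readouts (per-residue binding-frequency maps, censored first
dissociation times, flexible-domain RMSF, and a hydropathy-class
breakdown of intermolecular contacts).

The engine is event-driven discrete molecular dynamics (DMD): all
interactions are piecewise-constant in distance, so particles move
ballistically between instantaneous events — shell crossings, bond-wall
reflections, thermostat velocity reassignments, wall bounces and
force-plane crossings — and each event is resolved exactly, conserving
energy to arithmetic precision.  Working in reduced units (Å, kcal/mol,
Da) the natural time unit is $\sqrt{\mathrm{Da}\,\text{Å}^2 /
(\mathrm{kcal/mol})} \approx 48.9$ fs.

## The Hamiltonian

A `dmd_topology` holds four interaction classes:

* **Chain bonds** between consecutive backbone beads, and next-nearest
  pseudo-bonds as an angle surrogate: infinite square wells at the
  reference distance ±2% and ±5% respectively.  These widths are not
  prescribed by any experiment; they are standard Gō-DMD practice and
  configurable.
* **Native (Gō) contacts**: single square wells of depth $\varepsilon$
  at the reference distance ±15%.  The canonical well depth is
  0.4 kcal/mol ($\approx 0.67\,k_BT$ at 300 K), the weak contact energy
  assigned to the strand-swapped dimer interface.
* **Calcium-site cross-links**: residues annotated as calcium sites are
  rigidly cross-linked (±1% wells) *within* each chain.  Whether such
  constraints should tether residues to an explicit ion or to each other
  is ambiguous; we chose intra-chain inter-residue cross-links because
  they reproduce the physiological effect of calcium — rigidifying the
  domain — without introducing ion particles, and because cross-chain
  links would make dimer dissociation impossible by construction.
* **Non-bonded step potentials** resolved by hydropathy class: a 4 Å
  hard core for all pairs; a single attractive well
  (depth `hydrophobic_depth`, width 2 Å) between hydrophobic beads; and
  screened-Coulomb shells (Debye–Hückel with solvent dielectric 80,
  screening length 10 Å, four shells to 12 Å, discretized as exact shell
  averages) between charged beads.  Counter ions are not explicit; all
  screening is carried by the electrostatic term.

Constant-force steering discretizes the linear potential $-F x$ into
planes spaced $\delta = 0.5$ Å apart along the pulling direction
($\Delta U = F\delta \times 0.0143933$ kcal/mol per pN·Å, split equally
over the pulled domain).  At this spacing even 60 pN changes the energy
by less than $k_BT$ per plane, so steering stays smooth.  Temperature is
maintained by an Anderson thermostat: a Poisson stream (default 0.1
events per mobile bead per time unit — weak enough not to distort escape
kinetics, and treated as a free parameter) of Maxwell–Boltzmann velocity
reassignments.

### Engine design notes

Events live in a priority queue keyed by time, with per-bead validity
counters to discard stale entries; ties are broken deterministically by
bead index.  After any velocity change the affected bead's pair events
are recomputed against all other beads.  At the system sizes this
package targets (≤ a few hundred beads) this exact $O(n)$ rescheduling
is faster and simpler than maintaining a cell list with cell-crossing
events, so no cell list is used; the engine is not intended for
thousands of beads.  Immobilized beads are infinite-mass collision
partners: they never move but keep their excluded volume.  The box has
reflecting walls — the natural choice for a non-periodic binding
problem.  All randomness (velocities, thermostat, placements) derives
from integer seeds; rerunning any campaign with the same master seed
reproduces every table bit for bit.

## The synthetic systems

Real structures can be coarse-grained from PDB text
(`read_pdb_coarse()`, CA or CA+CB schemes), but the pipeline is designed
to run end-to-end on generated systems, which is what every test uses.

**Dimer.**  `generate_toy_dimer()` builds two β-hairpins stacked face to
face, joined by an annotated set of interface bead pairs of which a
chosen fraction lies in both chains' N-terminal strands (the
domain-swap mimic).  The default campaign dimer uses 30 residues per
chain, 16 interface contacts and calcium staples at residues
{5, 11, 20, 26} — the two strand-1 sites pair with the two strand-2
sites, rigidifying each hairpin the way calcium rigidifies cadherin
ectodomains.  Each chain's sequence places cationic lysines at the
hairpin turn (the region an anionic species is expected to target),
leucines along the strands and glutamates near the C-terminus.

**Ligands.**  Three classes differ in conformational rigidity at equal
per-bead chemistry: the *monomer* is a single near-straight chain with
no intra-chain native contacts; the *oligomer* is a single chain
collapsed into a compact slab whose realized intra-contact count is
tuned (by the length of the collapsed segment) to within ±20% of a
target density; the *seed* is four extended chains stacked at the
cross-β spacing with annotated inter-peptide Gō contacts at the same
0.4 kcal/mol as the dimer interface.  Net charge is negative by default
(amyloid-β-like, pI below physiological pH); the generator balances
E/K counts to realize the requested sign exactly.  The published
oligomer geometry is not retrievable, so the compact-globule stand-in is
an emulation, not a reproduction.

**Placement.**  The species is rotated uniformly at random and placed at
least 12 Å from the dimer.  At desk scale the initial separation is also
bounded above (20 Å by default): a free 25-mer diffuses only ~10 Å per
ns in this model, so an unbounded uniform placement in a 70 Å box would
rarely produce an encounter within a 1 ns run.  The printed simulation
box ("150 nm³") is dimensionally ambiguous; the box edge is therefore a
parameter, defaulting to 4× the combined system diameter when not set.

## Desk-scale study conditions

The published campaigns (40 × 50 ns binding; 7 forces × 70 × 100 ns
steered, i.e. 2.0 and 49 μs aggregate) are encoded as the `"paper"`
preset and used for configuration checks and time bookkeeping only.
The `"desk"` preset — 10 replicas × 1 ns, forces {0, 10, 20, 40} pN,
60–130 beads — runs the full pipeline in minutes on one CPU.

Three desk-scale Hamiltonian choices deserve justification.  They were
fixed once, before the acceptance analyses, on physical grounds:

* `intra_epsilon = 1.5` kcal/mol: the fold of each domain is held, in
  the all-atom original, by a full force field, not by the weak
  interface Gō energy.  Folding wells at ~2.5 $k_BT$ keep the hairpins
  folded on the ns scale while the *interface* wells stay at the
  canonical 0.4 kcal/mol.
* `interface_well_width = 0.3`: at ±15% a 0.67 $k_BT$ well is open most
  of the time for entropic reasons alone, and a 16-contact interface
  ruptures within ~0.3 ns even without force.  Wider interface wells
  (±30%) restore marginal ns-scale stability — the regime in which both
  force and ligand effects are measurable in 1 ns runs.
* `hydrophobic_depth = 0.8` kcal/mol (~1.3 $k_BT$): with the 0.3
  kcal/mol default, amyloid-dimer encounters happen but never persist;
  per-contact attractions near 1 $k_BT$ are the scale used by one-bead
  implicit-solvent contact potentials and give multivalent species
  ns-scale residence.

RMSF is computed from the zero-force replicas, over the associated
segment of each run only (a dissociation event would otherwise dominate
the fluctuation signal); the analysis window is the trailing 40% of
frames, matching the last-20-ns-of-50 convention (the figure-caption
variant, the last 10 ns, is available via `window_fraction = 0.2`).
Interface survival is judged against each contact's own well outer
radius, so "dissociated" is defined by the Hamiltonian; the 6.5 Å map
cutoff is used only for binding-frequency maps, as in the original
analysis.  Censored replicas enter mean dissociation times at the run
duration; a Kaplan–Meier restricted mean is reported alongside.

## What the toy systems do and do not show

The generator reproduces the *architecture* of the study — a marginally
stable multivalent strand-swap interface, species differing in rigidity
and charge, constant-force unbinding with censoring — but none of the
atomistic specifics: no sequence-accurate energetics, no hydrogen-bond
directionality, no solvation structure, and ~30× less simulated time.
Tests that pass on these systems demonstrate that the pipeline computes
its readouts correctly and that the engine realizes the intended
physics (exact energy conservation, Maxwell–Boltzmann statistics,
Bell-like force-accelerated bond rupture, charge-selective binding).
Directional, distribution-level comparisons between ligand classes at
desk scale are stochastic and summarized by the acceptance analysis;
they should be read as qualitative tendencies of the toy model, not as
quantitative statements about amyloid-cadherin energetics.  In our
desk-scale runs the rigid multivalent species bind persistently near
the interface but act as often as cross-bridges (stabilizing) as wedges
(destabilizing); the clean oligomer-led destabilization seen at full
scale is not reliably reproduced at 1 ns with 60–130 beads.

## Numerical choices

* Event times come from the quadratic $|r + vt| = R$; pairs numerically
  past a shell are treated as just-crossed (scheduled at zero delay with
  the approach-direction guard), and band indices — not floating-point
  comparisons — decide which side of a shell a pair occupies.
* Crossings rescale only the radial velocity component:
  $v_r' = \pm\sqrt{v_r^2 - 2\Delta U/\mu}$ on crossing, $v_r' = -v_r$ on
  reflection; total energy is conserved to $10^{-10}$ kcal/mol per
  event and verified globally per run.
* An event-time underflow guard (10⁶ consecutive events within
  $10^{-12}$ time units) aborts with the offending bead pair named.
* Degenerate inputs fail loudly: beads starting inside a hard core or
  outside a bond well, annotations referencing missing beads, unreachable
  oligomer contact densities, and placements that cannot satisfy the
  separation bounds all raise errors naming the constraint.

## Problem sizes used by tests and the acceptance analysis

Unit and property tests run seconds-long simulations (10⁵–10⁶ events) on
systems of 2–60 beads.  The acceptance analysis runs the NVE and
thermostat checks on the 60-bead dimer, the Bell check on a two-bead
bond (20 replicas × 4 forces × 1 ns), and the directional campaign at
4 conditions × 2 forces × 20 replicas × 1 ns (~90–130 beads); these
sizes keep the complete analysis within a desk-scale compute budget
while leaving every statistical criterion at 20 or more replicas.
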