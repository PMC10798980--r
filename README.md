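# cgdmd — coarse-grained event-driven DMD of cadherin dimer disruption

Vascular endothelial (VE-)cadherin seals the endothelial barrier through a
strand-swapped *trans* dimer of its outermost EC1 domains.  Anionic amyloid
species — monomers, oligomers and fibril seeds — can bind this dimer and
weaken it, one proposed molecular route to amyloid-induced endothelial
leakiness.  `cgdmd` is an R package for studying that mechanism *in silico*
at one bead per residue: it generates synthetic dimer/ligand systems, builds
Gō-model step-potential Hamiltonians, runs exact event-driven discrete
molecular dynamics (DMD) with an Anderson thermostat and constant-force
steering, and computes the field's standard readouts.

**Who it is for.**  Structural/computational biophysicists who want a small,
fully reproducible, scriptable DMD pipeline for binding and forced-unbinding
experiments on coarse-grained protein assemblies — and a reference
implementation of the event-driven algorithm with an independent brute-force
oracle in its test suite.

## The model

All interactions are piecewise constant in pair distance, so dynamics is a
sequence of exactly-resolved events.  A topology combines:

* chain bonds (reference ±2%) and next-nearest pseudo-bonds (±5%) as
  infinite square wells;
* Gō native contacts as square wells of depth ε = 0.4 kcal/mol
  (≈ 0.67 kBT at 300 K) at the reference distance ±15%;
* rigid intra-chain calcium-site cross-links (±1%);
* class-resolved non-bonded shells: 4 Å hard core, a hydrophobic well, and
  Debye–Hückel electrostatics (ε_r = 80, λ = 10 Å) discretized as exact
  shell averages.

At a shell of height ΔU a pair with reduced mass μ and radial speed v_r
crosses iff ½μv_r² > ΔU, rescaling v_r' = ±√(v_r² − 2ΔU/μ), else reflects —
energy is conserved to arithmetic precision.  A constant pulling force F is
a plane-discretized linear potential (ΔU = Fδ·0.0143933 kcal/mol per pN·Å).
First dissociation time is the first frame with zero surviving interface
contacts; runs that never dissociate are censored at the run duration.
Binding frequency is the fraction of analysis-window frames with any bead
within 6.5 Å of the partner.  Units: Å, kcal/mol, Da; the derived time unit
is ≈ 48.89 fs.

## Worked example

Build the toy strand-swapped dimer, run 0.2 ns at 300 K, and compute the
standard readouts:

```r
library(cgdmd)

dimer <- generate_toy_dimer(n_per_chain = 30, n_interface_contacts = 16,
                            swap_fraction = 0.5,
                            calcium_site_indices = c(5, 11, 20, 26), seed = 1)
topo <- build_topology(dimer, options = list(intra_epsilon = 1.5,
                                             interface_well_width = 0.3))
topo
#> <dmd_topology> 60 beads, 126 bonds, 96 contacts (16 interface), 30 immobilized, 30 pulled

traj <- run_dmd(topo, sim_config(duration_ns = 0.2, sampling_ns = 0.002,
                                 seed = 1, box_edge = 70))
traj
#> <dmd_trajectory> 100 frames x 60 beads, 0.198 ns, 105126 events (pair=92650, thermostat=12476, wall=0, plane=0)

first_dissociation_time(contact_count_series(traj), duration = 0.2)
#> # A tibble: 1 × 2
#>   dissociation_time censored
#>               <dbl> <lgl>
#> 1               0.2 TRUE

rp <- rmsf_profile(traj, "flexible_domain", window_fraction = 0.4)
mean(rp$rmsf)
#> [1] 2.29
```

The dimer stayed associated for the whole run (censored at 0.2 ns — the
convention under which a dissociation time equal to the run length means
"still bound"), and the mobile domain fluctuates by ≈ 2.3 Å about its mean
position.  Utility conversions recover the printed reference numbers:

```r
energy_in_kT(0.4)                                  # 0.671  (Gō well in kT)
peptide_average_mass(amyloid_sequence("abeta42"))  # 4514.1 Da
campaign_total_time(campaign_config("paper"), "binding")  # 2 (μs)
```

Full campaigns — replica binding runs with per-residue binding-frequency
maps, and a steered force grid with violin-ready dissociation records — are
one call each (`run_binding_campaign()`, `run_steered_campaign()`) from a
single `campaign_config()`; results are tidy tibbles with `tidy()`,
`glance()` and `autoplot()` methods.

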