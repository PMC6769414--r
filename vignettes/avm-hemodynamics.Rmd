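---
title: "Modeling intranidal hemodynamic compartments in a brain AVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling intranidal hemodynamic compartments in a brain AVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nidusflow)
```

## The model and its assumptions

`nidusflow` treats the cerebral circulation around an arteriovenous
malformation (AVM) as a resistive electrical network. Blood in and around
an AVM flows through thin vessels downstream of high-capacitance arteries,
so turbulence, pulsatility, wall compliance and shear-dependent viscosity
are neglected, and each vessel reduces to a Hagen–Poiseuille resistor
$R_v = 8 L \eta / (\pi r^4)$ (CGS units; $\eta$ = 3.5 cP). Pressure losses
at vessel junctions are ignored: junction regions are short compared with
vessel lengths at this caliber. Under these assumptions the steady state is
the solution of a linear Kirchhoff system. The solver performs sparse
nodal analysis: node pressures are the unknowns, flow conservation is
imposed at every free node, and the pressure (loop) law holds by
construction because branch drops are differences of nodal pressures.
Occluded vessels are removed from the system — an exact infinite
resistance — rather than given a large finite resistance, which avoids
conditioning artifacts; the loop-law and conservation properties are then
verified post hoc in the test suite rather than used for assembly.

Internally everything is CGS (dyn, cm, s); the interfaces report mm Hg
(1 mm Hg = 1333.22 dyn/cm²) and mL/min (1 cm³/s = 60 mL/min).

## Boundary conditions and calibration

The physiological anchors are pressures, not resistances: mean systemic
pressure 74 mm Hg at the source, 47 mm Hg at the two major arterial
feeders (AF1, AF2), 50 mm Hg at the two minor feeders (AF3, AF4),
17 mm Hg at the three draining veins, and a 5 mm Hg central venous sink.
`calibrate_extranidal()` adjusts the terminal extranidal artery and vein
segments by fixed-point iteration (`R <- (P_parent - P_target)/Q`) until a
baseline solve reproduces every target within 0.05 mm Hg (the exposed
tolerance is ±2 mm Hg; the iteration normally converges far tighter in
under ten iterations). A realization whose arterial tree cannot reach a
target (the parent pressure falls below it at the required flow) raises an
error carrying the last residuals.

## The canonical nidus and its generator

The nidus is a seeded random realization with fixed vessel classes and
geometry: 93 plexiform vessels (r = 0.05 cm, effective length 5.0 cm —
tortuosity is folded into the length, i.e. the default tortuosity factor
is 1) and a 4-segment fistula (r = 0.10 cm, 4.0 cm segments) running as a
simple path from AF2's nidus entry to DV2's exit. The generator:

* scatters interior nodes in a unit cube with a Gaussian density peaked at
  the core, so near-neighbour wiring makes the core the most tightly
  meshed region;
* gives every feeder a *supply ball* — the `m_i` interior nodes nearest
  its territory anchor, each connected to the feeder's entry hub by one
  plexiform "spoke". Ball sizes come from `feeder_supply_fractions`; the
  anchors place AF1–AF3 near-concentrically at the core (so territories
  nest and overlap) and AF4 at a peripheral corner;
* attaches plexiform branch vessels to the fistula path nodes ("a direct
  connection with branching plexiform vessels"); because the fistula is a
  low-resistance channel into DV2, this zone is clamped near venous
  pressure and forms the low mode of most injection responses;
* drains the interior through a bridge-edge budget into the three exit
  nodes, sampled with a tight proximity weight so drainage concentrates on
  collector nodes near the venous face;
* spends the remaining budget on near-neighbour "ring" edges with a
  fraction `long_range_frac` of uniformly random 3-D shortcut edges.

The canonical defaults (`nidus_config()`: seed 1661, supply fractions
(7, 9, 24, 5)/45, 24 interior nodes, 45 spokes, 29 bridges, 9 fistula
branches, feeder radius 0.162 cm) are *calibration constants* of the
model, chosen once so that the baseline solve reproduces the published
hemodynamics of a large cerebral AVM — 678 mL/min total nidus flow — and
the reference SSA condition (AF1 + 20 mm Hg, others occluded) yields a
bimodal ΔP% distribution with 38% of nidus vessels in the upper class.
They are not meant to be re-tuned per analysis; build variability studies
use `perturb_geometry()` and `rewire_nidus()` instead.

What the generator emulates: vessel counts and calibers, the fistula's
dominance, feeder-territory structure with overlap, a 3-D morphology with
long-range connections, and published boundary pressures. What it does not:
anatomically faithful cerebral artery geometry, patient-specific
angioarchitecture, vessel taper, or any non-Newtonian/pulsatile physics.
Passing tests therefore support conclusions about this model class, not
about any individual patient's AVM.

## Simulating superselective angiography

A microcatheter injection raises the intravascular pressure within the
injected feeder by the injection pressure (10, 20 or 30 mm Hg in the study
grid). `simulate_ssa()` therefore holds the feeder inlet, as a boundary
condition, at its uninjected pressure plus the delta. An alternative
mechanics (`method = "emf"`) places an ideal series pressure source in the
feeder branch; we do not use it as the default because the systemic tree
impedance absorbs most of such a source, so the realised pressure rise at
the feeder falls well short of the nominal injection pressure — not what a
pressure-monitored injection does.

The comparison baseline is the uninjected network *in the same occlusion
state* (`baseline = "matched"`). This isolates the injection response and
guarantees a non-negative pressure change at every nidus and venous node
(maximum principle); comparing an occluded, injected state against the
fully patent baseline (`baseline = "patent"`) mixes in the occlusion
effect, which collapses pressures in the other feeders' territories and
makes most deltas negative. Upstream arterial nodes may dip slightly even
under matched baselines, because the injection draws extra flow through
the feeding artery; the maximum principle is therefore stated over the
nidus and venous sides.

Per vessel we report the percent change of the mean intravascular
pressure (the average of the endpoint node pressures) — the ΔP% map that
compartment detection thresholds — along with the absolute change and the
percent changes of pressure drop and flow. Percent maps are guarded: when
the baseline magnitude is below `eps = 1e-6` the denominator is clamped
and the vessel flagged, since baseline drops below 1 mm Hg are common and
relative changes there are numerically explosive; the absolute map is
authoritative for flagged vessels.

## Compartment detection

`otsu_threshold()` is exact-value Otsu: every midpoint between consecutive
sorted unique values is a candidate split and the between-class variance
$w_0 w_1 (m_0 - m_1)^2$ is maximised, ties broken toward the lowest
qualifying threshold. With only 97 values this avoids the bin-count free
parameter of image-histogram Otsu (provided as
`otsu_threshold_binned()` for comparison). Membership is strictly above
the threshold; compartment size is members as a percent of all nidus
vessels. Distributions whose spread is below numerical noise (e.g. a
zero-strength injection) are reported as degenerate rather than split.

Bimodality is scored by a two-sided Welch t test between the two Otsu
classes ("mean separation"). This is the simplest test literally matching
that notion, but it is important to know its calibration: because the Otsu
split itself maximises class separation, the test rejects on essentially
*any* continuous sample — in a 1000-replicate simulation of 97 unimodal
normal draws, 100% of replicates gave p < 0.05 (median p ≈ 1e-22). The
test suite freezes this measured behavior. A "not significant" outcome
therefore only arises from degenerate distributions or an Otsu class with
fewer than 2 members, and the ensemble's fraction of significantly bimodal
geometries runs near 100%. Mixture-model likelihood ratios or dip tests
would be better-calibrated alternatives; they are noted but not the
default.

## The three experiments

* `run_ssa_grid()`: 4 feeders × {10, 20, 30} mm Hg × occlusion on/off =
  24 conditions, each with compartment detection.
* `run_sensitivity()`: n independent draws perturbing every vessel's
  radius and length uniformly within ±10% of its canonical value
  (topology fixed), re-solving, and summarising min/max/mean of the nidus
  statistics. The reference analysis uses 1000 draws, which takes a few
  seconds here.
* `run_rewiring_ensemble()`: n variants with one endpoint of 50% of the
  97 nidus vessels reassigned to a uniformly chosen different nidus node
  (no self-loops or duplicate edges; source-to-sink connectivity enforced
  by bounded resampling; an unrepairable draw is replaced by a fresh seed
  and counted). Endpoint reassignment was chosen as the minimal
  interpretation of "varying the connections"; edge swapping is the main
  alternative. Each variant gets a baseline solve plus one SSA condition
  (default: AF1 + 20 mm Hg, others occluded) with compartment detection.

Per-draw seeds derive from the experiment seed through a single
`sample.int` stream, so results are reproducible bit for bit, independent
draws can be replayed individually from their recorded seeds, and a
parallel evaluation under the same derived seeds would give identical
results.

## Numerical choices

* Conservation residual threshold: 1e-6 relative to throughput (the solver
  typically achieves ~1e-12).
* Solver agreement with an independently assembled dense nodal solve is
  tested to 1e-9 relative on 100 random small networks.
* Calibration: tolerance 0.05 mm Hg, at most 60 fixed-point iterations.
* Otsu ties: lowest qualifying threshold; degenerate spread: < 1e-9.
* Welch test with both classes at zero variance but distinct means
  reports p = 0 (perfect separation); a class with < 2 members reports NA
  with a reason attribute.
* Test-suite problem sizes: structural invariants are checked across 60
  generator seeds, solver equivalence on 100 random networks (≤ 20
  nodes), Otsu against brute force on 60–80 random inputs (≤ 50 values),
  the sensitivity acceptance run uses the full 1000 draws and the
  ensemble acceptance run the full 100 networks.

## Known limitations

* With all feeders patent, an injection field decays away from the
  injected feeder against source impedances that are pinned by the
  published boundary pressures (roughly (74 − 47 mm Hg)/Q per feeder). The
  patent-feeder compartments of this model are therefore confined to each
  feeder's supplied neighbourhood (about 8/29/32/6% of nidus vessels for
  AF1–AF4 at 10 mm Hg, in the published size order AF3 > AF2 > AF1 > AF4),
  substantially smaller than published compartment sizes whose sum
  approaches twice the vessel count; those sizes would require the
  non-injected feeders to float almost freely, i.e. source impedances far
  below what the published pressures imply. With the other feeders
  occluded — the condition under which the reference compartment figure is
  printed — the clamps are gone and the model reproduces the 38% figure
  exactly.
* Boundary pressures cap every intranidal quantity: with a 74 mm Hg source
  and 5 mm Hg sink no vessel can drop more than 69 mm Hg, so published
  per-vessel figures above that (e.g. plexiform values above 100 mm Hg)
  are unreachable under any reading of this model class.
* The Welch-on-Otsu bimodality test is anti-conservative by construction
  (see above); its near-100% ensemble significance rate is a property of
  the statistic, not evidence of strong bimodality in every geometry.
* Compartments are a two-class split; multi-compartment (k > 2)
  decomposition and spatial contiguity constraints are out of scope.
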