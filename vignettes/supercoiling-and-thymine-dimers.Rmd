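---
title: "Mesoscale supercoiling with thymine-dimer defects: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale supercoiling with thymine-dimer defects: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plectodimer)
```

## The problem

Underwound DNA relieves torsional stress in two ways: it buckles into
plectonemes (interwound superhelices with an apical end loop, the "tip"),
or it denatures locally into bubbles, which have a much lower twist modulus
and therefore absorb twist cheaply. Which channel wins depends on the
pulling force and the superhelical density `sigma = (Lk - Lk0)/Lk0`. A
thymine dimer (cyclobutane pyrimidine dimer, CPD) perturbs this competition
locally: it bends the duplex (an increased roll at the lesion), weakens the
base pairing of the two dimer base pairs, and keeps the two thymines
covalently stacked. The package simulates a single DNA molecule in a
magnetic-tweezer geometry - one end held at a surface, the other pulled
with a force `F` and rotated by a set number of turns - and provides the
analysis machinery for the resulting trajectories: twist-writhe-linking
number decomposition, plectoneme and bubble detection, tip-bubble
classification, force-torsion state diagrams, plectoneme-pinning statistics
and denaturation probabilities.

## The chain model

The simulator is a Metropolis Monte Carlo sampler of a discrete
twist-storing chain with one rigid site per base pair:

* per-site midpoint positions (nm) and per-step orthonormal material frames
  (tangent, major-groove normal, binormal);
* a binary pairing state per site (intact or denatured);
* harmonic bond stretching about the rise `h = 0.34` nm (stiffness
  800 kBT/nm^2, i.e. effectively rigid bonds);
* harmonic bending per joint with stiffness `p/h` in kBT per rad^2
  (`p = 45` nm for intact steps, 3 nm for denatured steps);
* twist per joint, measured between consecutive material frames after
  parallel-transport removal, with stiffness `C/h` (`C = 95` nm intact,
  3 nm denatured), preferred twist 360/10.55 degrees per intact step and 0
  for denatured steps - an open region therefore absorbs about 0.6 rad of
  undertwist per base pair at low cost;
* opening free energies per base pair plus a domain-wall cost per
  intact-denatured boundary (see Calibration below);
* a hard core of 2.5 nm between sites at sequence separation of at least 8
  (1.0 nm when either site is denatured, since single strands are thinner);
* the tweezer boundary conditions: a frozen 12-bp surface handle, a pulled
  12-bp handle confined to the axis but free along it, a constant force on
  the pulled end, repulsion planes at both handles so the chain cannot wrap
  around the ends, and imposed turns applied by rotating the pulled-handle
  frames quasi-statically (2000 sweeps per turn by default).

Because the core of `n` base pairs sits between handle sites, it spans
exactly `n` twist steps; the twist of an ideal relaxed 600-bp helix is
600/10.55 = 56.87 turns, its relaxed linking number.

### Topology bookkeeping

Twist is treated as a continuous ribbon variable: each joint carries a
winding number so a soft denatured joint can wind past 180 degrees without
the principal value slipping a full turn. With the hard core preventing
segment crossings (large moves are additionally checked at swept
intermediate configurations), the discrete Calugareanu-White-Fuller
identity makes `Tw + Wr` exactly conserved up to the applied turns;
trajectories record the residual, and the test suite requires it to stay
below 0.05 turns over a 10^4-sweep wound run (in practice it stays at the
1e-9 level). Writhe is computed with the exact per-segment-pair
solid-angle closed form; open chains are closed virtually through distant
axial extensions, the natural convention for the tweezer geometry.

### Monte Carlo moves

Crankshaft rotations of internal arcs; single-frame and block twirls
(a contiguous run of frames rotated about their own tangents, which
transports twist over long distances in one move - single-site twirls alone
would equilibrate twist only diffusively, in O(n^2) sweeps); smooth
transverse "wave" displacements of an arc (a sine bump vanishing at the arc
ends) that equilibrate long-wavelength bending modes; ramped axial shifts
that transport contour slack to and from the pulled handle (the
displacement is spread over up to 30 bonds so no single bond absorbs it);
per-site pairing flips; and, for torsionally unconstrained chains, tail
pivots. The pairing flip co-rotates a ramp of ~40 frames so the flipped
joint lands at the new preferred twist while the released intrinsic twist
spreads over the neighbourhood; the transformation is an involution, so
plain Metropolis acceptance applies, and without it bubble nucleation would
face an artificial kinetic barrier (the elastic mismatch of an unrelaxed
flip) even where bubbles are thermodynamically favourable.

### The defect model

A defect parametrization (`defect_model_spec()`, presets TD0/TD1/TD2)
carries a roll angle `phi`, the number of modified steps (1 or 2), a
hydrogen-bond weakening fraction and a stacking multiplier. In the chain
these become:

* a directional bend preference at the modified joint(s): the rotation
  vector between successive tangents prefers `phi` times the local roll
  axis (the material normal), so a single modified step relaxes to a duplex
  bend of `phi` and two adjacent modified steps bend further - the
  minimized bend angle is linear in `phi` across the validated range
  (`predict_bend_angle()`);
* opening free energies of the two dimer base pairs scaled by
  `1 - weakening`;
* for a stacking multiplier `m > 1`, an alignment restraint of stiffness
  `m - 1` (kBT/rad^2) that keeps the two dimer frames in their rolled
  mutual orientation even when the base pairs are denatured, mimicking the
  covalent cyclobutane link that holds the thymines stacked in an
  extrahelical arrangement.

At the mesoscale the minimized bend angle per modified step equals `phi`
itself; the nucleotide-level model this parametrization descends from bends
about half as much per unit roll, which is why the loop-energy presets use
the stored reference bend angles (the "thermal"/MD row of the published
parametrization) rather than angles recomputed from `phi`.

### Loop-formation energy estimate

`loop_energy_reduction()` evaluates `theta0 * sqrt(2 kBT p F zbar) / kBT`,
the estimated reduction of the plectoneme end-loop nucleation free energy
at a defect bent by `theta0`, with `p = 45` nm, `zbar = 0.88` (a writhe-
fluctuation correction at 1.5 pN) and physical `kB T` (4.142 pN nm at
300 K). With the presets' thermal bend angles this gives 1.06 kBT (TD0),
2.87 kBT (TD1) and 1.29 kBT (TD2); the literature rounds the first to
1.1 and prints 3.1 and 1.4 for the other two - faithful evaluation lands
7-8% below those two printed values, and the package reports the computed
numbers.

## Calibration

The opening energetics are the model's calibration knobs. `dG_open_AT` and
`dG_open_GC` are *effective* opening free energies: the engine adds the
joint-softening entropy released when a step switches from duplex to
single-stranded stiffness (`ln(p_ds/p_ss) + ln(C_ds/C_ss)/2`, about 4.4 kBT
at the defaults; less at a stacking-restrained dimer joint) to obtain the
bare flip energy. The defaults (AT 5.5 kBT, GC 7.0 kBT, wall cost 2.5 kBT)
were calibrated on the undamaged 600-bp chain so that the melting torque
(where denaturation starts absorbing twist, about 4.2 kBT/rad here) sits
just above the plectonemic coexistence torque at 1.5-2 pN (measured at
4.0-4.6 kBT/rad in winding runs with pairing suppressed). That ordering
produces the structure of the published force-torsion diagrams: buckling
pre-empts melting on winding, bubbles appear preferentially co-localized
with the highly bent plectoneme tip (tip-bubbles) and at the weakened
defect, and raising the force pushes the system toward denaturation. Two
caveats are documented deliberately: the effective opening costs are higher
than calorimetric base-pair stabilities (they bundle everything the
two-state site omits), and a regime where *bulk* bubbles dominate whole
frames was not reached at 2 pN within this parametrization - denaturation
here stays tip- and defect-associated, so state-diagram comparisons with
nucleotide-level models are structural (the ordering of regimes), not
boundary-exact.

## Analysis conventions

* Base-pair indices in all inputs and outputs are 0-based core coordinates
  (handles excluded from every per-bp statistic).
* A base pair is denatured on the energy route iff its hydrogen-bond
  binding energy is strictly below 10% of its maximum possible value; a
  bubble is at least two consecutive denatured base pairs.
* Plectonemes: midpoint contact pairs at sequence separation >= 40 bp and
  distance <= 7 nm, single-linkage clustered with a 20-bp gap; calls below
  40 bp are discarded. Extent and tip come from the contacts within 1 nm of
  the cluster's closest approach (the interwound body), the tip being the
  mean contact midpoint of their shortest-separation half - grazes at the
  cutoff distance (for example the flanking duplex passing the branch)
  cannot masquerade as the tip.
* A frame is a tip-bubble plectoneme iff some bubble centre lies strictly
  within 20 bp of some plectoneme tip; otherwise plectoneme beats bubble
  when both are present (writhe is the dominant structural response); the
  dominant state of a `(sigma, F)` cell needs >= 50% occupancy, a maximum
  in [0.4, 0.5) is "mixed", below 0.4 "none".
* Equilibration: `tau_eq` is twice the integrated autocorrelation time of
  the end-to-end distance (Sokal window, c = 5); the first `2 tau_eq`
  samples are discarded and a trajectory counts as converged iff at least
  `6 tau_eq` samples remain. White noise gives `tau_eq ~ 1` sample; an
  AR(1) series with coefficient rho gives `(1+rho)/(1-rho)`.
* Denaturation probabilities: the site-pair route reports the fraction of
  retained frames with both target base pairs open; the `at_mean` route
  averages the both-open fraction over all adjacent A/T pairs (per pair,
  then over pairs); `at_any` asks for at least one fully open adjacent A/T
  pair per frame and always dominates `at_mean`. Confidence intervals are
  95% Wilson intervals on pooled counts, with per-replica fractions
  retained.
* Bend angles are measured by total-least-squares lines fitted through the
  midpoints on either side of a boundary, excluding 2 bp around it so the
  kink does not contaminate either line.

## Synthetic fixtures

Every analysis operation is testable without external data through
deterministic generators: random sequences, ideal helices, planted
plectonemes (two interwound arms of radius 2.2 nm and axial period 6 nm
around a horizontal axis, an end-loop arc whose apex is the tip, flanking
stems receding at a gentle angle; ground truth records the realized extent,
tip and chirality), planted bubbles (with a length-1 negative control the
bubble definition must reject), planted kinks, and planted tip random
walks for pinning statistics. Fixture geometry respects a 1.9 nm hard core
(the apical loop approaches closer than mid-chain duplex spacing, as real
sharply bent tips do); fixtures are geometric, not Boltzmann-distributed -
they validate detectors, not thermodynamics. The 200-fixture randomized
corpus used for detector validation is fully specified by the manifest
shipped in `inst/extdata/plectoneme_corpus.tsv`.

## Interoperability

Readers and writers for the classic oxDNA topology and configuration
dialects (`read_topology()`, `read_oxdna_trajectory()`,
`duplex_from_oxdna()`, `export_to_oxdna()`) let the analysis layer run on
external coarse-grained trajectories; lengths convert at 0.8518 nm per
model unit. Per-base-pair hydrogen-bond energy tables (whitespace columns
`frame i j E_HB`) drive the 10% binding-energy criterion, with reference
maxima taken per pair type across the table unless supplied; a geometric
pairing fallback (base-base proximity plus versor anti-alignment) is
available behind an explicit flag as an approximation of the energy
criterion. Internally trajectories are in-memory R objects; the command
line front end (`inst/cli/plectodimer.R`) serializes them with `saveRDS`
and can export any frame to the oxDNA text dialect.

## Problem sizes used by the test suite

The packaged tests run the full study geometry (600 bp plus 12-bp handles,
defect 110 bp from the centre, F = 1.5 pN, sigma = -0.073, three replicas
per condition) with 4000 production sweeps per replica after the winding
ramp; topology conservation is checked over a 10^4-sweep wound run;
force-extension uses a 400-bp torsionally unconstrained chain at 1, 2 and
4 pN; equipartition uses a 200-bp chain. These lengths are enough for the
orderings under test (defect versus undamaged tip-bubble occupancy,
position-distribution sharpness, denaturation probabilities) but individual
occupancy percentages carry sizeable replica-to-replica spread; longer runs
sharpen them.

## Known limitations

* One rigid site per base pair: no nucleotide-level detail, no sequence-
  dependent stacking beyond the A/T-G/C opening contrast, no melting
  thermodynamics or absolute energies of any nucleotide-level force field.
* Monte Carlo kinetics: plectoneme mobility is reported in sweeps and
  compared only qualitatively; no real-time claims.
* The transition forces between regimes differ from experiment (as they do
  in the model class this descends from); comparisons across state
  diagrams are structural.
* The torsionally constrained ensemble is sampled with a fixed move set;
  extremely compact states (|sigma| >> 0.1) slow the sampler down and are
  outside the validated range.
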