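---
title: "Ion permeation analysis with a Brownian-dynamics model channel"
author: "ionflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion permeation analysis with a Brownian-dynamics model channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the estimators it
implements, the synthetic channel that feeds them, the numerical
choices behind both, and what the accompanying tests do and do not
establish about real simulation data.

## Conventions

All quantities are in Å (length), ns (time), kJ/mol (energy),
elementary charges (valence), mV (voltage), K (temperature) and pS
(conductance), converted through the single table in `ion_constants()`
(`kB = 0.0083144626` kJ/mol/K; one elementary charge across 1 mV is
`0.0964853` kJ/mol, i.e. the Faraday constant divided by 10^6).

Orientation: +z is the extracellular side; under positive transmembrane
voltage cations permeate toward decreasing z. The transmembrane field
follows the constant-field convention, `field = voltage / Lz` in mV/Å.
Trajectories are assumed pre-aligned to the channel axis (channel
simulations typically restrain the protein), so no fitting or
superposition is performed. Frame times must be uniformly spaced: every
estimator works with frame counts times the time step. The simulation
box is treated as constant over a trajectory (fixed-volume convention).

## Permeation events

`detect_events()` runs a per-ion finite-state machine over the axially
unwrapped coordinate. An ion that crosses `z_top` downward while inside
the gate cylinder (`R < gate_radius`), stays inside the cylinder for
every frame strictly between entry and exit, and then crosses
`z_bottom`, produces one `down` event, timestamped at `frame_exit` (the
first frame on the far side) so that cumulative-count series step at
completion. Upward traversals are detected symmetrically and labeled,
but excluded from conductance by default; `mode = "net"` subtracts
them. Because detection works on the unwrapped coordinate with the pore
interval replicated across periodic cells, re-entry through the
periodic image can never double-count a crossing; bulk wandering across
the box edge produces no event because it never passes through a pore
interval. The unwrapping rule is the minimum image: per-frame axial
displacements larger than half a box are folded back, and a raw
displacement larger than one full box is a hard error (the trajectory
is under-sampled beyond repair).

The gate cylinder radius defaults to 8 Å. An all-atom pore enforces
confinement physically, so published event definitions rarely state a
radius; in a periodic synthetic box the cylinder is what distinguishes
pore passage from bulk passage, and it is configurable. For
trajectories from the bundled generator, `bd_geometry()` places the
analysis boundaries 2 Å inside the physical pore span: the confinement
wall ramps on smoothly at the mouths, so exactly at the physical
boundary an ion can still sit outside the gate cylinder, and the inset
makes the gate condition meaningful (with it, per-ion event counts
match the net pore-cell winding of the unwrapped path exactly).

Conductance is `C = N_event * Q_ion / (t * V_tm)`, converted to pS;
with several replica trajectories the result is reported as mean ± SD
over replicas (no SEM). Zero voltage is an error, not a zero.

## Cylindrical densities

`density_rz()` histograms (R, z) samples and divides each bin count by
the exact annulus volume `pi (R2^2 - R1^2) dz` times `N_i N_f`, which
equals `2 pi R_mid dR dz` with the arithmetic midpoint radius. Two
properties then hold simultaneously and exactly: the map integrates to
one whenever the grid covers all samples, and a uniform cloud is
recovered without bias in every bin, including the innermost one (no
divide-by-zero at the axis). We considered the area-weighted mean
radius `(2/3)(R2^3 - R1^3)/(R2^2 - R1^2)` instead; placing it in the
volume denominator inflates the innermost bin's volume by a third and
so biases that bin's density low by 25% on uniform data, which is why
the exact-volume convention was adopted. Samples outside the grid are
tallied and reported, and the normalization claim is withdrawn for such
maps rather than silently renormalized.

The 2-D map is a probability density per ion-frame; the 3-D grid
(`density_grid3d()`) is deliberately different — a time-averaged number
density in Å⁻³ — because isosurface thresholds (for example 0.1 Å⁻³)
are conventionally stated in number density. Both conventions are
documented side by side, and the OpenDX writer/reader round-trips the
grid at printed precision.

`convergence_blocks()` recomputes the near-axis axial profile (default
selection R < 3 Å) over user-stated time windows and reports the
maximum sup-norm difference between successive windows; a stationary
process gives a small value, a mid-run change of regime a large one.
What counts as "converged" is left to the caller, since it depends on
bin width and sample size.

## Coordination profiles

The first solvation shell is 3.0 Å for both monovalent and divalent
cations, with the boundary *inclusive* — the convention is stated
because counts at exactly the cutoff are otherwise irreproducible
across implementations. Profiles average over ion-frames (every frame
in which a selected ion occupies a z bin contributes one sample), not
per-ion-then-per-frame; that matches continuous published profiles and
weights ions by their residence. The water/protein decomposition is
exact by construction (`total = protein + water` in every bin). With
replica trajectories the error is the standard deviation of replica
means. Radial conditioning (which ions enter the profile) defaults to
the gate radius and is configurable.

## Binding sites and transition statistics

Sites are axial intervals times radial annuli with half-open membership
`[z_lo, z_hi) x [r_lo, r_hi)`, so geometrically disjoint sites can
never produce ambiguous labels; overlap is rejected at configuration
time. Unassigned space falls back to `bulk_top`, `bulk_bottom`,
`cavity` (inside the gate cylinder within the pore span) and `other`.

Transition probabilities implement the permeation-path statistic: every
dwell in the target site (S2) that is eventually followed by entry into
the sink (the cavity) counts as one transit, attributed to the last
source-set site (S1 or P) the ion visited before that target dwell.
Transient single-frame touches count as dwells — the simplest
deterministic reading — and a minimum-dwell smoothing window exists but
is off by default so the printed formula stays exact. Ions reaching the
target from outside the source set are tallied under `other` and
reported separately rather than silently folded into the
probabilities, which keeps "did anything reach S2 straight from bulk"
observable.

## WHAM

`wham()` iterates the standard self-consistent equations (window free
energies and consensus density) until the maximum change in any window
free energy is below `tol` (default 1e-8 kJ/mol), working in log space
throughout. In periodic mode, bias distances wrap by minimum image over
the period and samples are folded into the grid span. Bins never
visited are masked as NA rather than extrapolated. The profile is
anchored at min(G) = 0, or at zero mean over a user-stated bulk
interval. Gauge invariance (adding a constant to all window biases
leaves G unchanged) holds by construction because the window free
energies are normalized to the first window; the test suite verifies
the solver against closed-form Boltzmann windows of a quadratic
landscape, where the recovered profile must match `a z^2 / 2` to within
a tenth of the thermal energy.

`bootstrap_pmf()` resamples individual samples within each window
(window identity preserved — production runs per window are short, so
whole-window resampling would be far too coarse), reruns WHAM on the
shared full-data grid, and reports per-bin standard deviations over
(by default) 100 resamples, seeded. Resample failures are tolerated up
to 10% and then become an error.

`well_depth()` is minimum G over the well interval minus mean G over
the reference interval; negative means binding. Because a minimum over
noisy bins is biased slightly deep, accurate depths want either small
per-bin noise (more sampling) or a tight well interval around the known
minimum; the acceptance script does both and additionally averages the
two bulk plateaus flanking the well, which cancels most of the random
offset that accumulates along the window chain.
`binding_preference(depth_a, depth_b) = depth_b - depth_a`, positive
when species a binds more strongly.

Window protocol defaults mirror common practice: ~1 Å window spacing
(0.5 Å for finer work), force constant 10 kJ/mol/Å² (= 1000
kJ/mol/nm²), a flat-bottom cylinder of radius 5 Å keeping the tagged
ion near the axis, and a 10% equilibration fraction discarded per
window. All are arguments.

## Pore profiling

`pore_radius_profile()` uses a planar-slice algorithm: per z slice,
maximize over the in-plane probe center the minimum over nearby atoms
of (center-to-atom distance minus the atom's vdW radius). The optimizer
is Nelder-Mead from six fixed starts (previous slice's center, the
axis, four unit lateral offsets), so profiles are deterministic without
any RNG. This matches spherical-probe profilers for straight, roughly
axial pores at a fraction of the complexity; it does not trace curved
axes, and slices with no confining atoms report the configured cap with
an `unbounded` flag. vdW radii come from a small built-in element table
(overridable); published profiles depend on the radius set used, so
agreement with other tools is expected to be qualitative.
`mean_profile_with_sd()` uses the population SD (divide by n), so two
profiles differing by 2 Å in a slice have SD exactly 1 there.

## The synthetic channel

`simulate_bd()` integrates overdamped Langevin dynamics
(Euler–Maruyama): `dr = (D/kT) F dt + sqrt(2 D dt) eta`, with periodic
wrapping in all three dimensions and Gaussian draws from R's RNG, so a
(system, seed, steps) triple reproduces a trajectory bit-exactly. The
scheme was chosen because the estimators need realistic *statistics*
with known analytic limits, not dynamical fidelity: the Einstein
relation, the mobility drift `v = D q E / kT`, and Boltzmann well
occupancies are all exact targets the test suite checks to within three
standard errors.

The potential, exposed verbatim through `bd_potential()` so tests can
do quadrature against the exact surface the integrator differentiates:

- **Binding wells.** Gaussian in z (depth, width sigma) times an
  optional Gaussian in R centered at `r_center` (0 = on-axis). On-axis
  wells carry a radial factor too: without one, ions descend off-axis
  and a peripheral annulus site would geometrically capture every
  transit, which inverts the S1-vs-P transition ordering the two-site
  architecture is supposed to produce. Per-species depth scale factors
  implement selectivity.
- **Pore wall.** A flat-bottom harmonic in R (`k_conf`, engaged beyond
  the pore radius) windowed smoothly in z over `edge_a = 1` Å at the
  pore mouths; the bulk slabs above and below are unconfined reservoirs
  and z-periodicity recycles permeated ions, keeping concentration
  stationary.
- **Field.** Constant force `-q * field * 0.0964853` kJ/mol/Å on each
  ion.
- **Ion-ion repulsion.** Screened Coulomb
  `(1389.35 / eps_scale) q_i q_j exp(-r/lambda_D)/r` with
  `lambda_D = 8` Å and `eps_scale = 80`; the force is clamped below
  r = 2 Å to avoid singularities (documented cap, not a smooth
  modification). This term produces multi-ion knock-off: an incoming
  ion destabilizes a bound one.

Stability rule: `dt <= 0.01 min(width^2)/max(D)`, enforced at
construction; any single-step displacement over 5 Å aborts with a
diagnostic rather than silently producing a broken trajectory. A
single-step paired-seed construction (two runs sharing RNG draws, one
with interactions disabled) lets the tests verify the compiled forces
against the numerical gradient of `bd_potential()` exactly.

### Presets

`bd_preset("trpv6_like")` is the two-site architecture: on-axis wells
S1 (z = +7) and S2 (z = -4) separated by 11 Å, radial sigma 2 Å, depths
14 and 16 kJ/mol for the divalent species with a 0.5 scale for the
monovalent one (S2 deeper than S1, matching the ordering of occupancies
in calcium-selective filters), plus an unselective peripheral annulus P
(z = +10, r_center = 4 Å, depth 8 kJ/mol) at the filter entrance —
a staging site off the permeation axis. `bd_preset("trpv1_like")` has a
single on-axis well. `bd_preset("free")` removes wells, confinement and
field for the diffusion/drift oracles. Channel presets default to 310 K
and 500 mV (field = voltage/Lz); diffusion coefficients are bulk-like
(Na⁺-type 133 Å²/ns, Ca²⁺-type 79 Å²/ns, i.e. 1.33 and 0.79 ×10⁻⁵
cm²/s); dt = 1e-5 ns with output stride 100. Well depths are model
knobs with documented defaults, chosen once so that divalent dwell
times are long enough for multi-ion effects at 20-50 ns scale but short
enough that tens of permeation events occur; they are not measurements
of any real channel.

### What the generator does and does not emulate

It emulates: multiple cation species of different valence and mobility,
a multi-site axial binding landscape with a peripheral off-axis site,
an applied transmembrane field, ion-ion repulsion producing concerted
multi-ion permeation, divalent block of monovalent flux, and periodic
boundary recycling. It does not contain water, protein atoms, ionic
polarizability, or any structural realism: passing tests demonstrate
that the *estimators* are correct on data with the right statistical
structure, not that any biological conclusion transfers. In particular
the coordination module's "bulk reference" fixtures are constructed
shells (seven oxygens for the divalent fixture, six for the monovalent
one), emulating the bulk coordination numbers reported for real water
models, not predictions of them.

### Knock-off timing

One association deserves a precise statement. In the two-site preset
the concerted mechanism is clearly visible as a timing signature: the
probability of three or more divalent ions occupying the filter region
roughly doubles relative to its time-average in the ~0.2 ns window
*preceding* a completed permeation, and relaxes back by the exit frame
itself — by which time the permeant has left the filter and no longer
counts toward its occupancy (the test suite computes exactly this). An
association measured *at* exit frames therefore under-counts the
crowding by one ion, and in this model class that structural deficit
outweighs the enrichment: exit frames are, if anything, slightly
depleted in three-ion episodes. Associating events with multi-ion
occupancy at the pre-exit lag is the faithful way to see the mechanism
in exit-timestamped event lists.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
channel runs of 2-3×10⁶ steps (20-30 ns) with 6-8 ions, 200-250
replicas of short free-diffusion runs, umbrella sets of 25-49 windows
at 1-6×10⁵ steps per window, and 100 bootstrap resamples per PMF.
These sizes were chosen so each statistical check has the power its
tolerance implies (three standard errors for physics oracles, 0.1
thermal-energy RMS for the WHAM oracle, 1 kJ/mol for end-to-end depth
recovery) while the whole suite completes in minutes.

## Known limitations

- The event detector assumes the channel axis is close to +z when
  handling periodic images; strongly tilted axes are supported for
  coordinate transforms but not for event counting through periodic
  boundaries.
- WHAM is histogram-based; no MBAR generalization, no 2-D PMFs.
- The pore profiler does not trace curved pores.
- Site labels, not positions, drive the transition statistics; sites
  must be disjoint, and boundary chatter is visible as short dwells
  unless the optional smoothing window is enabled.
- The generator's box is constant-volume; per-frame boxes (NPT) are not
  represented.
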