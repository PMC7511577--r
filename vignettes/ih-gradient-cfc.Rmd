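---
title: "Ih conductance gradients and theta-gamma coupling in a reduced pyramidal neuron: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ih conductance gradients and theta-gamma coupling in a reduced pyramidal neuron: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Large cortical and hippocampal pyramidal neurons couple slow (theta, ~4 Hz)
and fast (low-gamma, ~40 Hz) membrane-potential oscillations: the theta
phase modulates the gamma amplitude (phase--amplitude cross-frequency
coupling, PAC).  One candidate cellular mechanism is the
hyperpolarization-activated mixed cation current Ih (HCN), which in layer-5
and CA1 pyramidal cells is distributed as an exponentially increasing
density gradient along the soma--apical axis.  Because the Ih gate is slow
(hundreds of milliseconds) it can follow a 4 Hz modulation but not a 40 Hz
signal, so theta-driven Ih gating rhythmically changes the membrane
conductance seen by the gamma signal — a within-neuron PAC generator.

`ihcfc` implements the full computational study of this mechanism: three
conductance-based multicompartment models that differ *only* in the spatial
configuration of Ih (exponential gradient / uniform / absent), the
dual-sinusoid current-injection protocols that induce coupling, and the PAC
quantification pipeline (Tort modulation index, height ratio, amplitude
ratio, theta phase of the gamma-envelope extrema).

## The model neurons

### Morphology

The cell is a 22-compartment equivalent-cylinder reduction: soma, a
13-compartment apical shaft (`apdend1..apdend13`, 75 µm each, spanning
0--975 µm from the soma), a 3-compartment apical tuft (975--1,200 µm),
three basal compartments and a two-compartment axonal stub.  The 40 Hz
injection sites used by the experiment drivers are the base of the apical
dendrite (`apdend1`, centred 37.5 µm from the soma), the middle apical
shaft (`apdend7`), and the distal shaft (`apdend12`, which begins 825 µm
from the soma); the 4 Hz modulation is injected either distally
(`apdend13`) or at the soma.

The conductance-density table is indexed by *level* (0--20).  The
level-to-compartment assignment is a modelling choice of this package
(`default_level_map()`): levels 0--1 axon, 2 soma, 3--5 basal, 6--18 the
thirteen shaft compartments (one level each — the count match between 13
shaft compartments and 13 shaft levels motivates this), 19--20 the tuft.
It is overridable wherever a `level_map` argument appears.

### Conductances and units

The density table (`conductance_table()`) carries nine shared channel
columns — persistent Na, delayed-rectifier K, Ca- and voltage-dependent K
(K(C), K2), A-type K, M-type K, and high/low-threshold Ca — plus the three
alternative Ih columns.  Fast Na is zero at every level: the models are
deliberately subthreshold, which isolates the oscillatory interaction from
spiking.

Density magnitudes of this table (hundreds for K channels) are
conventional for mS/cm² in regular-spiking pyramidal-cell models, but the
effective scale also depends on the reduced geometry.  The package
therefore treats the table as *relative* densities multiplied by one global
`density_scale` (a passive parameter), and calibrates that scale — together
with the leak density, leak reversal, axial resistivity and the
equivalent-cylinder soma/apical/tuft diameters, all inside physiological
box bounds — against six reference input resistances (soma and `apdend13`
in each Ih configuration) and the subthreshold resting range (−85 to
−56 mV).  Input resistance is probed as the impedance magnitude at the
4 Hz modulation frequency (`input_resistance()`, default
`method = "impedance_4hz"`): at 4 Hz the slow Ih gate cannot follow the
probe, so the probe sees the chord conductance.  A DC step
(`method = "dc"`) instead equilibrates Ih fully and adds its
phenomenological slope conductance; under the package kinetics no
parameterization can jointly fit all six references with a DC probe
(the residual structure concentrates on the soma pair at ~±15%), while
the 4 Hz probe fits all six within ±2% and both resting endpoints within
0.02 mV — which is why the impedance probe is the default and the
calibration measurement.  `calibrate_passive()` re-runs this
box-constrained least-squares fit; the fitted values are frozen as the
package defaults (`passive_defaults()`, `geometry_defaults()`) and every
model object records them.

### Channel kinetics

No rate equations are inherited verbatim: every gate is a standard
Hodgkin--Huxley first-order process with a Boltzmann steady state and a
constant or bell-shaped time constant, collected in one swappable
configuration (`kinetics_defaults()`, versioned so outputs can cite the
kinetics set).  The defaults were chosen once, before any coupling
experiment, to satisfy the qualitative constraints that matter for the
mechanism:

* **Ih (anomalous rectifier)** — steady state `1/(1+exp((V+75)/5.5))`
  (monotonically decreasing, half-activation −75 mV, slope 5.5 mV), time
  constant bell-shaped with a ~210 ms peak near −70 mV and >100 ms across
  the resting range.  Consequences, which the tests verify: the gate's
  single-pole gain at 40 Hz is below 0.1 (the gamma signal cannot gate
  Ih), while a 4 Hz voltage drive produces a clear 4 Hz gating oscillation
  lagging its quasi-steady drive by `atan(2*pi*4*tau)` — the lag that
  structures the coupling phase.
* Reversals: E_K = −95, E_Na = +50, E_Ca = +125, E_h = −40 mV
  (E_h well above rest, so Ih depolarizes the resting potential and its
  removal hyperpolarizes every compartment).
* K(C) and K2 are gated by a per-compartment first-order calcium pool
  (influx proportional to inward Ca current, exponential decay, Michaelis
  factor `chi/(chi+kd)`); with no Ca influx these currents vanish.
* No Q10/temperature scaling: one implicit temperature.

### Numerical integration

The cable equations are integrated in compiled code with the scheme used
by mainstream neural simulators: staggered exact-exponential
(Rush--Larsen) gate updates followed by a backward-Euler implicit voltage
solve, using the Hines parent-ordering so the tree solve is O(n) per step.
Default `dt` = 0.025 ms (the integrator refuses dt > 0.05 ms); the
steady state of the scheme is the exact fixed point of the continuous
system, so resting measurements are insensitive to dt, and the test suite
checks that halving dt changes resting potentials by far less than 0.1 mV.
Resting states are obtained by relaxation until |dV/dt| < 1e-6 mV/ms in
every compartment.  Input resistance is, by default, the impedance
magnitude of a small 4 Hz probe from rest (fundamental amplitude per nA
after a two-period transient); the DC variant relaxes both the
unperturbed and the stepped state fully, so slow conductances are
equilibrated.

## The coupling pipeline

* **Bands and filtering.**  Theta band 2--6 Hz, gamma band 30--50 Hz
  (the fast injection is 40 Hz, "low gamma").  Filtering is zero-phase by
  construction: an FFT-domain mask with raised-cosine transitions (1 Hz
  for theta, 2 Hz for gamma).  A time-domain FIR with comparable theta
  selectivity over a 2 s window would be nearly as long as the window, and
  very-low-normalized-frequency IIR designs are numerically fragile, so
  the spectral mask is the realization of choice here.  250 ms at each end
  of the window — where circular filtering wraps — are discarded.
* **Phase and envelope.**  Instantaneous theta phase and gamma envelope
  come from the analytic signal of each component.  The default phase
  origin is the *ascending zero-crossing* of the theta component (the
  phase of theta written as a sine: peak at 90°, trough at 270°, first
  half-cycle depolarizing around the peak); `phase_zero = "trough"` or
  `"peak"` shift all reported phases by a quarter or half cycle.  The
  convention matters because absolute phase windows are only comparable
  between analyses that share it; under the ascending convention the
  Ih-present simulations place the envelope minimum at ~70--100° (late
  depolarizing half, Ih deactivating) and the maximum at ~190--330°
  (hyperpolarizing half, Ih activating).  The synthetic generator uses
  the same convention, so its ground-truth coupling phase is directly
  comparable.
* **Binning (the normalized amplitude distribution).**  Phase bin j covers
  [(j−1)·360/N, j·360/N); N = 72 by default (5° bins).  The mean envelope
  per bin, normalized by its sum, gives P(j).  An unpopulated bin is an
  error (use a longer window or fewer bins) — never silently imputed.
* **Metrics.**  Modulation index `MI = (log N + Σ P log P)/log N`
  (Kullback--Leibler distance from uniform, normalized; base-free), height
  ratio `(h_max − h_min)/h_max`, amplitude ratio `sqrt(2)·RMS(theta
  component) / sqrt(2)·RMS(gamma component)` (equals the peak-amplitude
  ratio for pure sinusoids), and the bin-centre phases of the envelope
  extrema with ties broken toward the earlier phase.
* **Analysis window.**  Experiment drivers discard a 1,000 ms transient
  and analyze 8 complete theta cycles (2,000 ms) plus the 250 ms filter
  margins; the phase-folded binning makes any integer cycle count ≥ 2
  valid, and the packaged test suite runs the full 18-run grid at 4 cycles
  to keep it fast.

## The synthetic generator

`generate_coupled()` produces the controlled ground-truth input for
validating the pipeline without the simulator:
`x = A_th sin(2πf_th t) + A_ga [1 − χ + χ(1+cos(θ−φ_c))/2] sin(2πf_ga t)
+ ε`, with coupling depth χ in [0, 1] and coupling phase φ_c.  The
envelope parameterization makes χ = 1 full modulation (envelope touching
zero), aligning the height ratio's range with the coupling depth; χ = 0
gives a constant envelope and a modulation index at numerical zero.  Noise
is additive white Gaussian — a deliberate simplification: the study's own
traces are noiseless deterministic simulations, and the generator exists
to probe metric behaviour (monotonicity in χ, phase recovery to within one
bin under moderate noise), not to mimic in-vivo spectra (no 1/f
background, no multi-band structure).  `generate_passive_fixture()`
provides exact RC closed forms (step and impedance responses) as the
independent oracle for the cable integrator.

## Experiment drivers

`run_scenario()` simulates one (modulation site × gamma site × Ih mode)
cell and quantifies every compartment along the soma--apical axis;
`run_grid()` covers the full 2 × 3 × 3 grid at 1.5 nA / 1.5 nA;
`bin_sensitivity()` sweeps N over {10, 12, 18, 20, 36, 72};
`amplitude_sensitivity()` sweeps one injection amplitude over
{0.5, 1.0, 1.5} nA holding the other at 1.5 nA; `model_comparison()`
summarizes maximum coupling strength per Ih configuration, the
uniform-to-gradient reduction percentage (computed on the per-scenario
maximum height ratio across compartments and gamma sites), and the
fraction of compartments with an inverted extrema-phase relationship in
the no-Ih model.  The "middle apical" gamma site is `apdend7` (shaft
midpoint) — a documented, overridable choice.

## Design decisions in brief

* Equivalent-cylinder geometry and the level map are package choices (the
  reduction's true geometry is not part of the density table); both live
  in single config blocks and are calibration targets, not constants.
* The global density scale resolves the unit ambiguity of the density
  table; its calibrated value is recorded in every model object.
* DC-step input resistance is the default probe (a 4 Hz impedance variant
  can be obtained by driving `simulate_model()` with a small sinusoid).
* Natural logarithms in the modulation index; the uniform→0 and one-hot→1
  unit tests pin the base consistency.
* Tie-breaks, degenerate inputs (empty bins, all-zero envelopes, missing
  theta drive) are hard errors with actionable messages.

## What passing the tests does and does not show

The test suite validates the metric layer against closed-form and
quadrature oracles to machine precision, the integrator against RC and
linear-cable closed forms, and the full 18-run grid against the
structure expected of the mechanism: tuft-dominant coupling under distal
modulation, stronger coupling with uniform than with exponential-gradient
Ih, the input-resistance ordering none > uniform > gradient, monotone
decrease of the modulation index with bin count alongside a stable height
ratio, the dominance of the 4 Hz amplitude in the sensitivity sweep, and
the Ih-present envelope-extrema phase windows.  Every structural claim is
encoded as an assertion over the grid output, and the suite reports the
measured value when an assertion fails, so the test log is the factual
record of which features of the reference behaviour this kinetics set
reproduces.

It does not certify quantitative agreement with any particular biological
neuron: the channel kinetics are documented defaults satisfying the
qualitative constraints above, not fits to voltage-clamp data, and the
geometry is a calibrated reduction.  Absolute coupling magnitudes, the
cross-model reduction percentages, the near-source coupling floors and
the no-Ih phase structure are all sensitive to the exact gating curves,
which is why the package pins the kinetics in a versioned configuration
object and reports it alongside results.

## Known limitations

* **The 4/40 Hz harmonic confound.**  40 Hz is exactly the tenth harmonic
  of the 4 Hz modulation, so any nonlinear distortion of the (large)
  theta swing leaks into the gamma band and cannot be separated
  spectrally from the genuine 40 Hz response.  At sites remote from the
  gamma injection — where the true 40 Hz signal is strongly attenuated —
  the leaked harmonic can reach a substantial fraction of the gamma-band
  power, and it is theta-locked by construction, so it inflates distal
  coupling estimates and colours their phase.  This is intrinsic to the
  injection design, not to the implementation; interpret tuft-level
  coupling values with this in mind.
* **Large subthreshold swings.**  The calibrated input resistances at the
  distal 4 Hz injection site (30--76 MΩ) with 1.5 nA drive imply local
  theta swings approaching ±100 mV in the weakly conductive (no-Ih)
  configuration.  At such excursions the near-threshold channels gate
  transiently around the theta peak and contribute coupling of their own;
  in this kinetics set that transient mechanism, together with the
  harmonic confound, dominates the no-Ih model's coupling and keeps it
  from falling below the uniform model's, and it sets the no-Ih phase
  structure (no inversion of the extrema relationship).
* Subthreshold only: no fast Na current, no spike generation.
* Current injections only: no synaptic conductances, no network feedback,
  and no field-potential (LFP/EEG) forward model.
* One implicit temperature; no stochastic gating; scalar Ca pool rather
  than diffusion.
* The calcium-dependent channels are nearly silent at rest; they engage
  only during the largest depolarizing excursions of the strongest
  protocols.
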