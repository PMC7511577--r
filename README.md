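# ihcfc

Theta–gamma phase–amplitude coupling (PAC) in multicompartment
conductance-based models of a large pyramidal neuron, as a function of the
spatial distribution of the hyperpolarization-activated mixed cation
conductance (Ih / HCN).

## What this package is for

Cortical layer-5 and hippocampal CA1 pyramidal neurons carry an
exponentially increasing Ih density gradient along the soma–apical axis.
Because the Ih gate is slow (hundreds of ms), a 4 Hz (theta) membrane
modulation rhythmically gates Ih while a 40 Hz (low-gamma) signal cannot —
so the theta phase modulates the membrane conductance, and with it the
local amplitude of the gamma oscillation.  `ihcfc` lets computational
neuroscientists simulate and quantify this single-neuron PAC mechanism:

* three 22-compartment model neurons sharing one morphology and one
  conductance table, differing **only** in the Ih column — exponential
  somato-apical gradient, uniform, or none (`build_model()`);
* a compiled cable-equation integrator for dual sinusoidal current
  injections — 4 Hz modulation (distal `apdend13` or somatic) plus 40 Hz
  injection (basal/middle/distal apical) — and steady-state measurements
  (`simulate_model()`, `resting_state()`, `input_resistance()`);
* the PAC pipeline: zero-phase band decomposition, analytic-signal theta
  phase and gamma envelope, the phase-binned normalized amplitude
  distribution `P(j)`, the Tort modulation index
  `MI = (log N + Σ P log P) / log N`, the height ratio
  `(h_max − h_min)/h_max`, the theta/gamma amplitude ratio, and the theta
  phase of envelope extrema (`compute_cfc()` and friends);
* synthetic coupled-signal generators with ground-truth coupling depth and
  phase for validating the metrics (`generate_coupled()`), plus exact RC
  fixtures for validating the integrator;
* experiment drivers for the full 2 × 3 × 3 scenario grid, bin-count and
  amplitude sensitivity analyses, and cross-model comparison
  (`run_scenario()`, `run_grid()`, `bin_sensitivity()`,
  `amplitude_sensitivity()`, `model_comparison()`).

See the methods vignette (`vignettes/ih-gradient-cfc.Rmd`) for the model,
the kinetics, all tunable parameters and the design decisions.

## Worked example

Quantify coupling in the exponential-gradient model under the canonical
scenario — 1.5 nA 4 Hz into the most distal apical shaft compartment and
1.5 nA 40 Hz into the base of the apical dendrite — at the 11th apical
compartment with 72 phase bins (5° resolution):

```r
library(ihcfc)
model <- build_model("exp_gradient")
trace <- simulate_model(model, study_protocol("distal", "base"),
                        duration_ms = 3500)
compute_cfc(trace, compartment = "apdend11", transient_ms = 1000)
#>   compartment          mi height_ratio      h_max      h_min amplitude_ratio
#> 1    apdend11 0.001571651    0.2725188 0.01688714 0.01228508        2.001434
#>   phase_max_deg phase_min_deg n_bins
#> 1         192.5          62.5     72
```

Reading the output: `mi` is the normalized entropy deficit of the
phase-binned gamma envelope (0 = no coupling; values of ~1e-3 are far
above the ~4e-5 significance threshold reported for this index at
N = 18), and `height_ratio` says the weakest phase bin of the gamma
envelope is ~27% below the strongest.  `amplitude_ratio` ≈ 2.0 means
theta-band membrane fluctuations at `apdend11` are about twice the
gamma-band fluctuations (the cable filters the 40 Hz signal traveling up
from the base far more than the 4 Hz signal arriving from the adjacent
distal site).  The envelope maximum sits at 192.5° of the theta cycle
(hyperpolarizing half under the default ascending-zero phase convention,
while Ih is activating) and the minimum at 62.5° (depolarizing half, Ih
deactivating) — the phase signature of the Ih mechanism.

A profile along the whole soma–apical axis for the same scenario:

```r
prof <- run_scenario("exp_gradient", "distal", "base")
prof[c("compartment", "start_distance", "height_ratio", "mi")]
#>   compartment start_distance height_ratio           mi
#> 1        soma              0   0.06871215 7.500503e-05
#> 2     apdend1              0   0.06923111 7.575679e-05
#> ...
#> 16       tuft2           1050   0.53857013 9.498774e-03
#> 17       tuft3           1125   0.55961055 1.053111e-02
```

shows coupling growing from the soma toward the apical tuft (975–1,200
µm), where it is strongest.

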