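# dscircuit

Compartmental modelling and analysis of retinal direction selectivity.

Direction-selective ganglion cells (DSGCs) fire preferentially for one
direction of image motion. Two mechanisms, both arising from the starburst
amacrine cell network, can each generate this selectivity at the ganglion
cell: a **direction-tuned amplitude** of GABAergic inhibition (strong for
null-direction motion, nearly absent for preferred), and a
**direction-tuned timing difference** between cholinergic excitation and
GABAergic inhibition, produced by spatially offset receptive fields.
`dscircuit` builds a conductance-based multi-compartment DSGC whose
moving-bar-activated synapses carry both mechanisms, and implements the
statistics used to quantify them.

The core quantities:

* **Release probability and spatial offset** of each transmitter follow
  sigmoids of the angular distance *a* from the preferred axis
  (0° preferred, 180° null):

  Pr(a) = pPr + (nPr − pPr)·(1 − 0.98 / (1 + e^((a − 91)/25)))

  off(a) = pOff − (pOff − nOff)·(1 − 0.98 / (1 + e^((a − 74.69)/24.36)))

  A synapse's activation is advanced by off(a)/velocity relative to the
  bar's leading-edge crossing; one Bernoulli(Pr) draw per pass decides
  release.
* **DSI** (direction selectivity index) = |Σᵢ rᵢ·vᵢ| / Σᵢ rᵢ over stimulus
  directions, where vᵢ is the unit vector of direction i and rᵢ the
  response (spike count, peak rate, or clamped E/I offset); 0 is a
  symmetric response, 1 a single-direction response. The preferred angle
  is the resultant's direction.
* **E/I temporal offset** = inhibitory onset − excitatory onset, each
  onset estimated by fitting a line through the 20–80% rise of the
  synaptic current and extrapolating to the baseline; positive offsets
  mean excitation leads. Negative offsets are clamped to 0 for DSI use.
* **Firing rates** are spike trains convolved with a σ = 25 ms Gaussian.

## Worked example

Build the default model cell, clamp it at the two reversal potentials
while a preferred-direction bar sweeps at 1 mm/s, and measure the E/I
temporal offset:

```r
library(dscircuit)

morph <- generate_arbor(seed = 1)       # planar arbor, 150 um radius
sites <- place_synapses(morph)          # tri-receptor sites on terminals
cell  <- build_cell(morph, sites)       # printed channel densities

est <- measure_ei_offset(cell, sites, n_trials = 24, seed = 1)
est
#> <offset_estimate> E onset 305.84 ms, I onset 356.52 ms, offset +50.68 ms (clamped 50.68)

temporal_to_spatial_offset(est$offset_ms, 1000)
#> [1] 50.7
```

Excitation leads inhibition by ~50 ms for preferred motion at 1 mm/s —
the temporal signature of the ~50 µm cholinergic receptive-field advance
(inhibition's preferred-direction offset residual makes the ideal value
46.8 ms; trial averaging of the sparse preferred-direction IPSC scatters
estimates by a few ms). A current-clamp trial of the same stimulus:

```r
sch <- activation_schedule(bar_stimulus(0, velocity_um_s = 1000), sites, seed = 1)
cc <- run_current_clamp(cell, sch, noise_seed = 1)
cc$spikes
#> <recording spike_times> 16 spikes
max(smooth_firing_rate(cc$spikes$values)$rate_hz)
#> [1] 53.9
```

The experiment drivers reproduce the study designs:
`experiment_mechanism_dissection()` runs the battery with both mechanisms,
timing offsets alone (non-directional starburst release), and amplitude
tuning alone; `experiment_velocity_sweep()` runs the offsets-only circuit
across velocities, exposing the slow-velocity leak-through of
null-direction spikes. A thin command-line wrapper is installed at
`inst/cli/dscircuit` (subcommands `synth`, `analyze`, `simulate`,
`experiment`).

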