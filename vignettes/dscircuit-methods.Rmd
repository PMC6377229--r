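---
title: "Modelling direction selectivity from excitation/inhibition timing and amplitude asymmetries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling direction selectivity from excitation/inhibition timing and amplitude asymmetries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscircuit)
```

## The circuit and the two mechanisms

Direction-selective ganglion cells (DSGCs) in the mammalian retina fire
preferentially for one direction of image motion. Two circuit mechanisms,
both originating in the starburst amacrine cell network, can each produce
this selectivity:

* **amplitude asymmetry** — GABA release onto the DSGC is strong for
  null-direction motion and nearly absent for preferred-direction motion,
  because only null-side starbursts make inhibitory synapses and their
  dendrites are themselves direction selective;
* **temporal asymmetry** — cholinergic excitation reaches the DSGC with
  its receptive field displaced ~50 µm toward the stimulus entry side,
  while GABAergic inhibition's displacement is itself direction tuned
  (~0 µm preferred to ~50 µm null). For preferred motion excitation leads
  inhibition by tens of milliseconds; for null motion the two arrive
  together and inhibition vetoes the response.

`dscircuit` implements a compartmental DSGC driven by moving-bar-activated
synapses that carry both mechanisms, plus the analysis statistics used to
quantify them, a surrogate-recording generator with known ground truth, and
experiment drivers that toggle each mechanism independently.

## Directional tuning rules

Release probability and spatial offset follow sigmoids of the angular
distance $a \in [0, 180]$ between stimulus direction and the cell's
preferred axis:

$$\mathrm{Pr}(a) = p_\mathrm{pr} + (n_\mathrm{pr} - p_\mathrm{pr})
  \left(1 - \frac{0.98}{1 + e^{(a - 91)/25}}\right), \qquad
\mathrm{off}(a) = p_\mathrm{off} - (p_\mathrm{off} - n_\mathrm{off})
  \left(1 - \frac{0.98}{1 + e^{(a - 74.69)/24.36}}\right)$$

with GABA defaults $p_\mathrm{pr} = 0.012$, $n_\mathrm{pr} = 0.5$,
$p_\mathrm{off} = 0$, $n_\mathrm{off} = 50$ µm. Angular distance is the
absolute wrapped difference folded into $[0, 180]$ (0° preferred, 180°
null), the only interval on which the sigmoids are single-valued.
Glutamate is untuned (Pr 0.5, no offset); acetylcholine is untuned in
probability but isotropically advanced 50 µm. A bar moving at velocity
$v$ schedules each (site, transmitter) event at the leading-edge crossing
time minus $\mathrm{off}(a)/v$; one Bernoulli(Pr) draw per event decides
release. At 1 mm/s the cholinergic advance therefore corresponds to a
50 ms excitation/inhibition (E/I) onset offset for preferred motion.

```{r tuning}
tun <- directional_tuning(p_pr = 0.012, n_pr = 0.5, p_off = 0, n_off = 50)
release_probability(c(0, 91, 180), tun)
spatial_offset(c(0, 74.69, 180), tun)
```

## The model cell

The arbor is procedural: a seeded planar tree (default radius 150 µm, 6
primary dendrites, 4 branch orders, one cylindrical compartment per
branch) standing in for a reconstructed morphology — the mechanisms under
study depend on synapse positions and cable filtering, not on any
particular reconstruction. Tri-receptor synapse sites (AMPA, nicotinic,
GABA-A) sit every ~5 µm along terminal branches; the source circuit
publishes no synapse count, so the density was fixed once at a value that
makes release stochasticity average out over the arbor rather than
dominate single branches.

Passive parameters are 1 µF/cm² and 100 Ω·cm; the leak reverses at
−60 mV with density 0.1 mS/cm² (a 10 ms membrane time constant). Active
densities per region (soma / primary / terminal, mS/cm²) are sodium
150/150/30, potassium rectifier 70/70/35, slow delayed rectifier
3/0.8/0.4. The rate functions are the canonical squid-axon forms with the
sodium gates shifted +10 mV and the rectifier +25 mV, and a slow
non-inactivating K gate half-activating at −10 mV. These shifts are a
deliberate numerical choice: with unshifted kinetics the printed
densities rest near −75 mV (the rectifier is partially open at −60), and
with shifted kinetics but a weaker leak the cell is bistable a few
millivolts above rest. The chosen combination rests at −60 ± a few mV,
has a regenerative threshold near −50 mV, and fires to brief somatic
current pulses.

Synaptic conductances are bi-exponential with defaults AMPA 0.45 nS
(0.2/2 ms), nicotinic 0.2 nS (2/25 ms), GABA-A 4 nS (0.5/30 ms),
reversals 0/0/−60 mV. The inhibitory conductance is deliberately strong
and slow relative to miniature-event kinetics: evoked inhibition must
both veto coincident cholinergic drive (null direction) and outlast the
~50 ms gap to the trailing glutamate input, or the model shows no
direction selectivity at all. These are calibrated model constants, not
measurements.

Integration is a semi-implicit fixed step (default dt = 0.025 ms):
voltages solve a Hines-ordered tree system per step (backward Euler with
conductances frozen at Rush–Larsen-updated gate values), which is stable
for the stiff sodium kinetics; halving dt changes spike counts by at most
one per trial and clamp-current peaks by <2%. Channel noise is an additive
Ornstein–Uhlenbeck current per compartment (total SD 30 pA apportioned by
area, τ = 2 ms), giving ~10% spike-count CV across trials; it replaces a
stochastic channel mechanism and can be switched off for deterministic
runs. Voltage clamp pins the soma, zeroes the Na/K conductances
(mirroring the experimental blockers), and reports the electrode current;
at the −60 mV inhibitory reversal the excitatory current is isolated
(inward, negative) and at 0 mV the GABAergic current (outward, positive).
Space clamp is imperfect by construction: unclamped dendrites retain a
driving force, so the excitatory-null identity at 0 mV holds exactly only
in the single-compartment limit, which is how the package tests it.

## Analysis statistics

* **Firing rate**: spike trains convolved with a unit-area Gaussian
  kernel (σ = 25 ms); the trace integrates to the spike count.
* **DSI**: magnitude of the response-weighted vector sum over stimulus
  directions divided by the summed responses; the preferred angle is the
  resultant's direction. Multi-trial series report the trial-summed
  headline value plus per-trial values and across-trial SDs (angle SD is
  computed on deviations about the circular mean).
* **Onset latency**: the 20–80% rise of a current (amplitude measured
  baseline to *first* peak, so slow glutamatergic tails cannot contaminate
  a cholinergic onset) is fit by least squares through all samples in the
  band; onset is where the line crosses the baseline. The baseline is the
  mean of a 200 ms pre-stimulus window; a response must exceed 5 baseline
  SDs. With noisy traces a 0.5 ms Gaussian pre-smoother stabilises peak
  identification, candidate peaks must reach half the global deflection,
  and the 20%/80% crossings are anchored by walking back from the peak —
  without these guards, baseline noise crossings capture the band and the
  estimator fails catastrophically at 10%-of-peak noise. Noise-free
  recovery is within 1 ms; at 10% noise within 5 ms (mean over 100
  draws).
* **E/I temporal offset**: inhibitory onset minus excitatory onset
  (positive when excitation leads); the clamped variant sets negative
  offsets to zero before DSI computation. `temporal_to_spatial_offset()`
  multiplies by velocity, inverting the scheduler's division.
* **Phase tuning**: early window = the `early_span` (50 ms) before the
  stimulus enters the glutamate receptive field (the earliest glutamate
  crossing time, carried on every schedule); peak window = 50 ms centred
  on the preferred-direction peak of the trial-pooled smoothed rate.
  Centring on the peak is a choice — the source only locates the window
  "close to" the peak.

## Worked example

```{r example}
morph <- generate_arbor(seed = 1)
sites <- place_synapses(morph)
cell  <- build_cell(morph, sites)

est <- measure_ei_offset(cell, sites, n_trials = 8, seed = 1)
est
```

The preferred-direction offset lands near the 46.8 ms ideal (the 50 µm
cholinergic advance minus the 3.18 µm preferred-direction GABA residual,
at 1 mm/s). Because preferred-direction GABA releases at ~1% per site,
the inhibitory onset of a few-trial average carries several milliseconds
of release-sampling noise; the acceptance script averages 96 trials to
bring the spread to ~2 ms.

## Experiments

`experiment_mechanism_dissection()` runs the moving-bar battery under
three settings: both mechanisms, offsets only (GABA Pr pinned to 0.5 — a
starburst population rendered non-directional), and amplitude only (all
spatial offsets removed). "Amplitude only" removes the cholinergic
advance as well: retaining it would keep E/I timing differences and early
responses in every direction, contradicting the phenomenon the setting
exists to isolate (with offsets absent, no input precedes the glutamate
receptive field and early responses vanish).

`experiment_velocity_sweep()` runs the offsets-only circuit across
velocities (default 600/1200/2400 µm/s). In this mode the E/I ratio is
fixed across directions and velocities by construction; an explicit
quantal rescale to a chosen ratio is available via
`fixed_ratio_gaba_gain()`, but rescaling this circuit's inhibition down
to twice the summed excitatory quantal conductance abolishes its
selectivity — brief excitatory events must be outweighed by inhibition
integrated over its decay, not matched quantally. At the low end of the
grid the gap between inhibition and the trailing glutamate outlasts the
30 ms inhibitory decay and null-direction spikes leak through, dropping
the DSI — the same slow-velocity failure the timing mechanism shows in
the source circuit. The grid's low end sits at 600 µm/s because that
leak-through scale is set by the calibrated inhibitory decay; at
150–300 µm/s this model loses selectivity broadly rather than showing a
graded leak.

## What the synthetic generator emulates — and what it does not

`synthetic_truth()` + `synth_current_pair()`/`synth_spike_trains()`
produce EPSC/IPSC pairs and Poisson spike trains with configurable
preferred angle, offsets, amplitude tuning, kinetics and noise. They
emulate the *measurement structure* of the study — matched clamp pairs
per direction, trial-wise spike trains whose early rates depend only on
timing and sustained rates only on amplitude tuning — so every estimator
can be validated against known ground truth. They do not emulate
trial-to-trial correlations, space-clamp artefacts, series-resistance
errors, or any biophysics: passing the recovery tests shows the
estimators are correct, not that the simulator is realistic.

## Known limitations

* The early-phase/peak-phase contrast is weaker than in the real circuit:
  with both mechanisms on, this model's peak window remains more sharply
  tuned than its early window. The early count saturates at ~2 spikes,
  the offset sigmoid is shallow near 0°, and shunting inhibition makes
  null-direction spiking all-or-none in time, so the null response falls
  outside the peak window entirely. Distal dendritic spike initiation,
  which the source circuit credits for early-phase information, needs
  more electrotonic isolation than the one-compartment-per-branch arbor
  provides. The corresponding acceptance expectation is left failing
  rather than weakened.
* GABA reverses exactly at the leak potential, so inhibition is purely
  shunting; the real chloride reversal sits slightly above rest.
* The bar is a leading edge of infinite lateral extent; trailing-edge
  (OFF) responses and the spot/bar distinction are not modelled.
* One release decision per site, transmitter and pass; no vesicle
  depletion, facilitation, or paracrine diffusion of acetylcholine.

## Problem sizes

Default experiment batteries use 8 directions × 20 trials (the trial
count the dissection figures in the source used); the velocity sweep adds
the 3-point grid. A single bar pass over the default 91-compartment,
384-site cell integrates ~500–900 simulated ms at dt = 0.025 ms in a few
hundred milliseconds of wall time via the compiled core.
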