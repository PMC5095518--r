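---
title: "Joint development of attractor dynamics and receptive fields in a spiking V1 model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint development of attractor dynamics and receptive fields in a spiking V1 model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(v1net)
```

## The model

`v1net` simulates a small patch of developing primary visual cortex: 100
excitatory (E) principal neurons and 20 inhibitory (I) interneurons, all-to-all
connected (no autapses), with 17 x 17 x 2 feedforward inputs per E cell
representing ON-centre and OFF-centre retinal ganglion cells. Feedforward and
lateral E-E synapses are plastic; E-I, I-E and I-I weights are drawn once from
uniform distributions (inhibitory weights negated, per Dale's law) and stay
fixed. Conduction delays between cells are drawn once from an exponential
distribution with median 4 ms, floored at 1 ms, and rounded up to the 1-ms
integration grid.

### Membrane dynamics

Every cell is an adaptive exponential integrate-and-fire neuron integrated by
forward Euler at dt = 1 ms:

$$C\,\dot u = -g_L (u - E_L) + g_L \Delta_T e^{(u - V_T)/\Delta_T}
  - w_{ad} + z + I_{FF} + I_{lat} + I_{inh} + I_{noise}$$

with an adaptive threshold $V_T$ decaying to $V_{T,rest}$ (time constant
$\tau_{VT}$), a hyperpolarizing adaptation current $w_{ad}$ incremented by $b$
per spike and decaying with $\tau_{w}$, and a depolarizing spike afterpotential
$z$ set to $I_{sp}$ per spike and decaying with $\tau_z$. A spike is registered
when $u$ reaches $V_{PEAK}$; the voltage is clipped to $V_{PEAK}$ at detection,
held there for one further 1-ms step (the stereotyped spike crest), and then
reset to $E_L$, while $V_T$ jumps to $V_{TMAX}$. The stereotyped crest keeps
the plasticity rule insensitive to the variable Euler overshoot of the
exponential runaway; the exponential argument is additionally capped
(`exp_cap`) so the term saturates instead of overflowing. The adaptation
current here decays purely exponentially between spikes (no subthreshold
$a(u-E_L)$ coupling); this is the simplest reading of an adaptation current
that "increases on each spike and decays exponentially otherwise", and it
removes one free parameter.

Membrane parameters default to the standard adaptive-exponential
parameterisation ($C = 281$ pF, $g_L = 30$ nS, $E_L = -70.6$ mV,
$\Delta_T = 2$ mV, $V_{T,rest} = -50.4$ mV, $V_{TMAX} = -30.4$ mV,
$\tau_{VT} = 50$ ms, $b = 80.5$ pA, $\tau_w = 144$ ms, $I_{sp} = 400$ pA,
$\tau_z = 40$ ms, $V_{PEAK} = 20$ mV). At dt = 1 ms the membrane time constant
($C/g_L \approx 9.4$ ms) is resolved by fewer than ten steps, so a passive
10-mV excursion tracks its exponential closed form with a mean deviation of
about 1% and a worst instantaneous deviation slightly above 2% of the
excursion; this is the accuracy regime all results below live in.

### Plasticity

Feedforward and lateral E-E synapses share one voltage-dependent STDP rule
with no distinction between the two pathways. Three exponential traces of the
postsynaptic voltage are kept per cell — $u_+$ ($\tau_+ = 7$ ms), $u_-$
($\tau_- = 10$ ms) and a slow homeostatic trace $\bar u$ ($\tau_{long} = 20$ s)
of the half-rectified excess of $u$ over the LTP threshold
$\theta_+ = (V_{TMAX} + V_{T,rest})/2$ — plus, per synapse, an exponential
trace $\bar x$ ($\tau_x = 15$ ms) of presynaptic spike arrivals (arrival time
includes the conduction delay).

Depression fires on each presynaptic arrival $X(t)$:

$$\Delta w_{LTD} = -A_{LTD}\,\big(\bar u / u_{ref}\big)^2\,
  X(t)\,\max(u_- - \theta_-, 0),$$

with $\theta_- = E_L$: depression is proportional to recent depolarization and
to the *square* of long-term above-threshold activity, which makes it a
superlinear, homeostatic function of sustained firing. Potentiation fires
whenever the membrane exceeds $\theta_+$ (in practice, during the stereotyped
spike crest) while the cell was recently depolarized and a presynaptic spike
arrived recently:

$$\Delta w_{LTP} = \frac{A_{LTP}}{\gamma\,(w + w_\epsilon)}\,
  \bar x\,\max(u - \theta_+, 0)\,\max(u_+ - \theta_-, 0).$$

The $1/(\gamma w)$ attenuation makes large weights harder to increase and
replaces any hard weight ceiling; weights remain hard-floored at zero. The
regulariser $w_\epsilon$ keeps the factor finite at $w = 0$, which matters
because all lateral E-E weights start at exactly zero and must be able to
grow; $w_\epsilon$ also sets how strongly silent synapses are pulled back from
the floor, and therefore how cleanly the lateral weight distribution develops
its peak at zero (see the calibration notes below).

Updates are applied every 1-ms step (event terms gated by the spike
indicators), depression before potentiation within a step, with the traces
updated from the current step's post-clipping voltage first.

### Stimuli

Input patches emulate retinal pre-processing: grayscale images are filtered
with a difference of Gaussians (s.d. 1 and 2 px, each Gaussian unit-sum,
truncated at 4 surround s.d., border-renormalized so a uniform field maps to
exactly zero), then 17 x 17 windows are cut at uniformly random positions
under a uniformly random rotation (bilinear interpolation), mean-subtracted
and scaled to peak amplitude 1, and finally split into non-negative ON and OFF
channels (positive and negated-negative parts; the split is lossless). The 578
channels drive independent Poisson spike trains at
`rate = rate_scale * intensity`, refreshed every millisecond; each presentation
is 300 ms of stimulus followed by 50 ms of null input. Every cell additionally
receives an excitatory Poisson noise barrage (1800 Hz) at a fixed weight
`w_noise`, which is what sustains spontaneous activity.

Because the original natural-image corpus is not part of the artifact, the
package generates synthetic naturalistic images: Gaussian white noise shaped
in the Fourier domain to a 1/f amplitude spectrum, the canonical second-order
statistic of natural scenes. These reproduce the spatially correlated,
scale-free structure that drives receptive-field formation, but not the
higher-order structure of real scenes (edges, contours, occlusions), so
learned receptive fields are expected to be oriented and biphasic yet somewhat
less cleanly Gabor-like than with a real image corpus. The pixel-shuffled
control (`shuffle = TRUE`) destroys all spatial correlation while keeping each
patch's intensity histogram, and is the package's negative control for
structure-dependent group formation.

## Calibration of the free scale factors

The architecture and rule above leave a small set of scale factors that the
model's sources do not pin down numerically: the intensity-to-rate conversion
`rate_scale`, the noise weight `w_noise`, the inhibitory-path maxima
(`Wmax_EI`, `Wmax_IE`, `Wmax_II`), the feedforward initialisation range, and
the plasticity scales (`A_LTP`, `A_LTD`, `gamma`, `w_eps`, `u_ref`). These
were calibrated once, in a fixed order, against the model's published
operating regime — sparse spontaneous activity (well under 1 Hz per cell),
stimulus-dominated evoked responses with a long right tail of firing rates,
inhibition strong enough to act as real competition, and stable long-run
weight dynamics — and then frozen:

1. `w_noise` is set so that the noise barrage alone depolarizes cells to a
   fluctuation-driven regime a few mV below threshold, yielding spontaneous
   rates of order 0.5 Hz.
2. `rate_scale` and the feedforward initialisation are set so stimulus-driven
   input dominates the noise current severalfold at onset, making evoked
   responses stimulus-selective rather than noise-selective.
3. The inhibitory maxima are set so that the inhibitory current recruited at
   population activity of a few spikes per millisecond is comparable to the
   recurrent excitatory current (the inhibition-stabilized regime); too-weak
   inhibition demonstrably leaves the population responding as one undifferentiated
   group.
4. The plasticity scales are set for stabilisation within the desk-scale
   training horizon (tens of thousands of presentations rather than the
   million-scale horizon of a full run), with `u_ref` fixing the homeostatic
   set point of time-averaged suprathreshold activity.

The resulting default operating point is: `rate_scale = 800` Hz per unit
intensity, `w_ff_init_max = 30`, `w_noise = 260` pA,
`Wmax_EI = Wmax_IE = Wmax_II = 100`, `A_LTP = 0.01`, `A_LTD = 0.008`,
`gamma = 15`, `w_eps = 5`, `u_ref = 1.3` mV. At this point the frozen trained
network shows a median evoked rate of a few Hz with maximal responses of
50–80 Hz, spontaneous activity near 2 Hz, selective and spatially coherent
receptive fields, a zero-peaked lateral weight distribution, and positive
coupling between lateral weight strength, response correlation and
receptive-field similarity.

The training horizon default (50,000 presentations) and the desk-scale
learning rates are a deliberate compression, and it has a known cost: the
identity of the strongest lateral pairs is still turning over at the end of
the default horizon. The statistical bias toward co-tuned pairs is present
(transpose symmetry and correlated-pair weight share well above chance and
growing with the horizon), but the fully consolidated regime — near-perfect
bidirectionality, nearly all lateral weight in a stable top decile, and the
runaway that follows inhibition silencing — develops on the million-
presentation timescale of a full run. Statistics that mature slowly are
therefore reproduced in direction and regime rather than to the digit, which
is also how the package's acceptance checks treat them; several are expected
to sit below their full-scale values at the default horizon.

## Protocols and analyses

`train_network()` runs the plastic protocol; `test_responses()` freezes all
weights and records spike counts (and optionally mean subthreshold potential,
spike-crest samples excluded) per cell and presentation;
`record_spontaneous()` runs the frozen network with zero stimulus rates. The
analyses mirror the experiments the model is known by:

* **Response clustering** — hierarchical clustering of population response
  vectors with correlation distance (1 − Pearson) and average linkage, leaf
  order from the dendrogram. The metric and linkage are free choices
  (`cluster_and_sort(method = )`); correlation distance matches the
  correlation-matrix displays, and average linkage is the least
  shape-committal of the standard linkages. Zero-variance response columns
  are given correlation 0 and sort last, deterministically.
* **Connectivity statistics** — transpose symmetry of the lateral matrix
  (off-diagonal Pearson), weight concentration (share of total weight in the
  strongest fraction of connections), weight share of the most
  response-correlated cell pairs, and receptive-field similarity of strongly
  connected pairs.
* **Spontaneous patterns** — 50-ms binning of principal-cell spikes, keeping
  the 30% most populated bins (ties resolved toward earlier bins so the
  selection is deterministic), matched against evoked clusters by centroid
  correlation.
* **Mixture morphing** — 30 linear blends between the two stimuli preferred
  by the two largest response clusters, blended at the signed-patch stage so
  the endpoints are exactly the pure stimuli; responses are decomposed as
  $r_n = \beta_1 r_1 + \beta_2 r_2$ on unit-normalized vectors, and the
  abruptness of the crossover is summarised as the maximum consecutive jump
  of the $\beta$ series (1 for a step, $1/(n-1)$ for a linear ramp).
* **Manipulations** — silencing inhibition (I cells cannot spike), removing
  lateral connections (all, or E-E only), and spike blocking (removing the
  exponential term), the latter probing whether competition survives in
  subthreshold potentials.

## Numerical choices and degenerate inputs

* Fixed 1-ms Euler grid everywhere; sub-millisecond integration appears only
  inside test oracles.
* Spike detection at $u \ge V_{PEAK}$, not at $V_T$ crossing; the crest
  convention above makes every spike contribute identically to the traces.
* A constant patch (possible after DoG filtering of a uniform region)
  normalizes to all zeros — null input — rather than dividing by zero.
* Delays are rounded up, so the ring buffer needs max-delay + 1 slots; a
  delay of 0 never occurs.
* The engine validates every membrane update and aborts with the neuron and
  step index on non-finite values; the only regime that approaches this is
  inhibition silencing, which instead saturates at the spike-crest ceiling.
* Mean-potential recording excludes clipped samples so subthreshold analyses
  are not dominated by $V_{PEAK}$.
* All randomness flows through R's RNG: a run is bit-reproducible from
  (seed, config, stimulus stream), and `seed_streams()` fans one experiment
  seed into independent stimulus/construction/simulation streams so ablations
  do not shift unrelated draws.

## Scale of the shipped experiments

The package defaults run the desk-scale protocol: 50,000 training
presentations (about 5 simulated hours), 1,000 test presentations, 100 s of
spontaneous recording. The full-scale protocol of the original study
(1,000,000 presentations) is a flag away (`n_train`), with identical code
paths. The robustness preset re-runs training with the seven free parameters
(`A_lat`, the three inhibitory maxima, `gamma`, `A_LTP`, `A_LTD`) all scaled
by 0.8 or 1.2; the size preset quadruples the network (400 E / 80 I) while
dividing `A_lat` by 4.

## Known limitations

* Synthetic 1/f images lack the higher-order structure of natural scenes;
  receptive fields and cluster counts should be compared in regime, not
  pixel-for-pixel.
* The desk-scale learning rates trade asymptotic crispness for tractable
  runtimes; the slow tails of the weight distribution keep maturing past the
  default horizon.
* Current-based synapses and a single interneuron class; no conductances,
  no short-term plasticity, no inhibitory plasticity, no topography.
* The intensity-to-rate conversion is a calibrated constant, not a retinal
  model; absolute firing rates inherit its uncertainty, which is why the
  package treats the headline rate statistics as factor-of-two quantities.
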