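# v1net

Spiking-network model of a developing patch of primary visual cortex, for
computational neuroscientists studying how attractor dynamics and stimulus
selectivity can emerge jointly from synaptic plasticity.

The model is a fully connected network of 100 excitatory and 20 inhibitory
adaptive exponential integrate-and-fire neurons. Each excitatory cell receives
17 x 17 x 2 feedforward inputs — ON- and OFF-centre channels of
difference-of-Gaussians-filtered image patches — as independent Poisson spike
trains, plus a fixed-rate excitatory noise barrage. Feedforward and lateral
E-E synapses follow a voltage-dependent STDP rule: depression is gated by
presynaptic spike arrival, scaled by recent postsynaptic depolarization and by
the square of a slow (20 s) trace of suprathreshold activity (a homeostatic
term), while potentiation is gated by the membrane voltage exceeding a high
threshold θ₊ = (V_TMAX + V_Trest)/2 together with a presynaptic spike trace,
and is attenuated by the factor 1/(γ(w + w_ε)) so that large weights are hard
to increase (no hard weight ceiling; weights are floored at zero). Inhibitory
connections (E-I, I-E, I-I) are fixed, uniform-random, and negative from I
cells; all cell-to-cell conduction delays are exponential (median 4 ms,
minimum 1 ms). The simulation is plain forward Euler at dt = 1 ms.

Driven by naturalistic (1/f-spectrum) image patches, excitatory cells develop
selective receptive fields (reconstructed as ON-weights minus OFF-weights)
while the lateral weight matrix becomes sparse, with most weight concentrated
in a small fraction of connections; a pixel-shuffled stimulus control removes
this structure. The package ships the full experiment suite: training /
frozen-network testing / spontaneous-recording protocols, response clustering,
connectivity statistics, stimulus-mixture morphing with regression
decomposition, and the network manipulations (inhibition silencing, lateral
ablation, spike blocking).

## Worked example

Train a small network briefly, freeze it, and look at the response and
connectivity summaries (a full-scale run uses `n_presentations = 50000`
or more; this short run just illustrates the interfaces):

```r
library(v1net)

cfg  <- default_config()
stim <- make_stimuli(2000, cfg, seed = 101)       # synthetic 1/f patches
net  <- build_network(cfg, seed = 202)
net  <- train_network(net, stim, n_presentations = 2000, seed = 303)

test <- make_stimuli(200, cfg, seed = 505)
resp <- test_responses(net, test, seed = 606)

glance(resp)
glance(net)
```

```
#> # A tibble: 1 x 5
#>   n_cells n_presentations median_rate max_rate median_max_rate
#>     <int>           <int>       <dbl>    <dbl>           <dbl>
#> 1     100             200        3.33       70              50
#> # A tibble: 1 x 8
#>     n_E   n_I n_trained w_ff_sum w_lat_sum symmetry top10_share top5_share
#>   <int> <int>     <int>    <dbl>     <dbl>    <dbl>       <dbl>      <dbl>
#> 1   100    20      2000   95459.    14672.    0.257       0.527      0.306
```

`median_rate`, `max_rate` and `median_max_rate` are firing rates in Hz over
the 300-ms stimulus window: the median over all (cell, presentation) pairs,
the absolute maximum, and the median over presentations of each
presentation's most active cell. `symmetry` is the Pearson correlation of the
off-diagonal lateral weights with their transposed counterparts
(bidirectionality), and `top10_share`/`top5_share` are the fractions of total
lateral weight carried by the strongest 10% / 5% of connections; all three
grow substantially over a full-length training run.

Useful follow-ups: `plot_rf_mosaic(net)` for the learned receptive fields,
`autoplot(resp)` for the similarity-sorted response matrix,
`record_spontaneous(net)` for noise-driven activity,
`mixture_experiment(...)` for the stimulus-morphing competition test, and
`run_preset("fig2_clustering", seed = 1)` for an end-to-end pipeline. A thin
command-line front end with `train` / `test` / `spontaneous` / `manipulate` /
`mixture` / `preset` subcommands is installed at
`system.file("cli", "v1net.R", package = "v1net")`.

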