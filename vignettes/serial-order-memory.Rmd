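---
title: "Methods: a spiking serial-order sequence memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spiking serial-order sequence memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 7, fig.height = 4.5)
set.seed(1)
```

This vignette documents the model, the architecture and the stimulation
protocols implemented by **serialmem**, and walks through the three core
behaviors: learning a sequence, replaying it, and overwriting it.

```{r load}
library(serialmem)
```

## 1. Neuron and synapse model

Neurons are adaptive (exponential) integrate-and-fire units. With the
exponential spike-initiation term disabled (the default), the membrane
follows a leaky integrator with exact exponential-Euler updates, a hard
threshold, a reset potential and an absolute refractory period. Each neuron
carries a calcium trace — a low-pass filter of its own spikes — used by the
plasticity rule. Per-neuron device mismatch is emulated as multiplicative
jitter on time constants and the rest-to-threshold distance
(`mismatch_sigma`, default 0.1 in the protocol runners); it decorrelates
otherwise identical neurons and prevents artificial spike synchronization.

The integrator is validated against the closed-form firing rate of a leaky
integrate-and-fire neuron under constant current:

```{r lif}
np <- neuron_params()
lif_rate_closed_form(np, input_current = 1.6)
```

Synapses deliver currents with one simulation step of delay; each delivered
spike adds its weight to the target's synaptic current, which decays with a
single shared time constant (20 ms by default). Static weights are
restricted to a small table of levels, as on hardware with a fixed number of
programmable weights:

```{r table}
static_weight_table()
```

## 2. Plasticity: gated updates plus bistable drift

Plastic synapses hold an analog weight in [0, 1] that becomes binary in the
long term. On each presynaptic spike the weight is potentiated if the
postsynaptic membrane potential is high and the postsynaptic calcium trace
lies inside a window, and depressed if the membrane potential is low and the
calcium trace is below the upper bound; otherwise nothing happens.
Independently, the weight drifts at a constant rate toward the nearest rail,
with the drift direction decided by a threshold `theta_w`:

```{r plasticity}
pp <- plasticity_params()
plastic_update_on_pre(0.4, v_post = 0.8, ca_post = 1.0, params = pp)  # LTP
plastic_update_on_pre(0.4, v_post = 0.1, ca_post = 1.0, params = pp)  # LTD
drift_step(c(0.4, 0.6), dt = 1e5, params = pp)                        # rails
```

The depression gate's lower calcium bound defaults to 0, so presynaptic
activity slowly erases associations onto *silent* postsynaptic neurons —
this is what makes overwriting (Section 6) work.

Weights are read out non-destructively: each synapse is driven with a fixed
burst of input events while the network is otherwise silent, and an entry is
scored 1 exactly when the postsynaptic neuron fires
(`probe_plastic_weights()`). The burst intensity is chosen so the spiking
threshold falls at `theta_w`: the probe reports which side of the bistability
each weight is on.

## 3. Architecture

`build_serial_order()` assembles, within a 256-neuron budget:

- **K ordinal groups** with strong recurrent excitation and mutual
  inhibition: a winner-take-all in which only one group — the current
  sequence position — can be active.
- **K memory groups**, self-sustaining, each ignited by its ordinal group.
  Memory group *k* weakly inhibits ordinal group *k* and excites ordinal
  group *k+1*: the stored progress biases the competition toward the next
  position.
- A **content field**, a soft-WTA array over which items are Gaussian
  activity bumps; item regions partition the field (nearest-center
  assignment).
- A **condition-of-satisfaction (CoS)** group inhibiting all ordinal groups:
  a CoS pulse terminates the active position, after which the memory groups
  decide the successor.
- A **reset** group inhibiting all memory groups.
- A **plastic ordinal-to-content block**, initialized fully depressed. A
  fraction of frozen potentiated entries inside the recurrent ordinal and
  memory blocks strengthens self-excitation without taking part in learning.

```{r build}
cfg <- serial_order_config(n_items = 3)
net <- build_serial_order(cfg, seed = 1)
net
```

## 4. Teaching

The teaching protocol presents each item for 6 s as Poisson input with a
Gaussian spatial profile (peak 900 Hz, σ = 5 neurons) on the content field,
launched by a 3 s go signal to ordinal group 1 and separated by 500 ms CoS
pulses; all content neurons also receive weak background noise (≤ 10 Hz).
While ordinal group *k* and the item bump are coactive, the synapses between
them are potentiated. A final reset (overlapping the last CoS pulse) wipes
the memory groups:

```{r teach, cache = FALSE}
teach <- run_teaching(net, c("C", "A", "B"), seed = 1)
plot(teach$raster)
```

The probe readout shows one potentiated block per position:

```{r probe}
probe <- probe_plastic_weights(set_plasticity(teach$network, FALSE))
score_probe(probe, net$layout, item_regions(net))
```

## 5. Replay

During replay the content field receives no external input: the go signal
ignites ordinal group 1, whose potentiated synapses recreate the first
item's bump. CoS pulses — at arbitrary, not necessarily regular times —
advance the sequence:

```{r replay}
rep <- run_replay(teach$network, cos_onsets = c(4200, 7600, 12500), seed = 2)
rep
plot(rep$raster)
```

Decoding assigns each detected content bump to the item region containing
its center, with the fraction of its spike mass inside that region as
confidence; ambiguous bumps are flagged unassigned rather than guessed:

```{r decoded}
rep$decoded
```

## 6. Overwriting a stored sequence

Re-teaching a different sequence on the same network works because the
external item input is configured stronger than the potentiated plastic
drive: the externally imposed bump wins the content competition and
silences the old recalled bump, whose synapses are then depressed
(presynaptic activity onto silent postsynaptic neurons). Typically a single
re-teaching trial suffices:

```{r unlearn}
unl <- run_unlearning(teach$network, c("B", "A", "C"), n_trials = 2, seed = 1)
unl
unl$trials[[1]]$sequence
```

## 7. Event-camera configuration

In the robot-style configuration (`cos_mode = "dvs"`), content input comes
from a synthetic address-event stream of a blinking laser pointer, and
transitions are autonomous: an activity population driven by the events
holds the CoS down while the laser is visible; in the off-gaps the recalled
content bump excites the CoS, terminating the current position:

```{r dvs}
dnet <- build_serial_order(serial_order_config(n_items = 3,
                                               cos_mode = "dvs"), seed = 1)
script <- laser_script(x = c(107, 22, 64))  # sensor columns of items C, A, B
dteach <- run_dvs_teaching(dnet, script, seed = 1)
run_dvs_replay(dteach$network, seed = 2)
```

## 8. Reproducibility and artifacts

Every run is bit-deterministic given its seed. Rasters, weight matrices and
configurations round-trip through plain-text formats, and a manifest records
the configuration hash and seed of a run:

```{r io}
td <- tempfile(); dir.create(td)
write_raster(rep$raster, file.path(td, "replay.tsv"))
write_config(list(serial = cfg, protocol = teaching_protocol()),
             file.path(td, "config.yaml"))
m <- write_manifest(file.path(td, "manifest.json"),
                    list(serial = cfg), seed = 1)
m$config_hash
```
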