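# serialmem

Clock-driven simulator of a neuromorphic serial-order sequence memory:
soft winner-take-all (dynamic neural field) populations of adaptive
exponential integrate-and-fire neurons, calcium- and voltage-gated bistable
synaptic plasticity, and an ordinal / memory / content /
condition-of-satisfaction architecture that learns, replays and overwrites
sequences of items within a 256-neuron budget.

## What it does

- **Core dynamics** — adaptive (exponential) integrate-and-fire neurons with
  a per-neuron calcium trace, exponential postsynaptic currents, one-step
  spike transmission delay, Poisson stimulus generators, and emulated
  per-neuron device mismatch. The compiled core (`run_simulation()`) is
  bit-deterministic given a seed and is validated against a closed-form
  leaky-integrate-and-fire rate oracle and an R reference integrator
  (`integrate_step()`).
- **Synapses & plasticity** — non-plastic synapses draw from a table of four
  excitatory and a few inhibitory weight levels
  (`static_weight_table()`); plastic synapses follow a calcium- and
  voltage-gated update on presynaptic spikes (`plastic_update_on_pre()`)
  plus a constant bistable drift (`drift_step()`) that makes every weight
  binary in the long term. Stored weights are read out non-destructively by
  stimulating synapses row by row and observing postsynaptic spikes
  (`probe_plastic_weights()`).
- **Network builder** — lateral and inhibitory-pool soft-WTA patterns
  (`build_wta_lateral()`, `build_wta_pool()`) and the full serial-order
  architecture (`build_serial_order()`): K ordinal groups in mutual
  exclusion, self-sustaining memory groups, an asymmetric
  ordinal→memory→next-ordinal chain, a content field with item regions, a
  condition-of-satisfaction (CoS) group that terminates the active ordinal
  group, and a reset group that wipes the memory groups.
- **Protocols** — teaching (`run_teaching()`): a go signal, per-item
  Gaussian Poisson input, CoS transition triggers and a final reset;
  replay (`run_replay()`) recalls the sequence with flexible CoS timing and
  no content input; overwriting (`run_unlearning()`) re-teaches a new
  sequence on top of an old one; a synthetic event-camera front end
  (`laser_script()`, `synth_dvs_stream()`, `run_dvs_teaching()`,
  `run_dvs_replay()`) drives the content field from address events with
  autonomous transitions.
- **Analysis & I/O** — bump detection (`detect_bumps()`), sequence decoding
  with explicit unassigned flags (`decode_sequence()`), block-level probe
  scoring (`score_probe()`), raster plots (`plot()` on a raster), and
  plain-text/binary round-trips for rasters, matrices, YAML configurations
  and run manifests.

## Quick start

```r
library(serialmem)

net   <- build_serial_order(serial_order_config(n_items = 3), seed = 1)
teach <- run_teaching(net, c("C", "A", "B"), seed = 1)

probe <- probe_plastic_weights(set_plasticity(teach$network, FALSE))
score_probe(probe, net$layout, item_regions(net))
#> winners: ordinal_1->C, ordinal_2->A, ordinal_3->B

run_replay(teach$network, seed = 2)
#> <replay_result> decoded sequence: C-A-B

plot(teach$raster)
```

Overwrite the stored sequence without resetting the weights:

```r
unl <- run_unlearning(teach$network, c("B", "A", "C"), n_trials = 4, seed = 1)
unl$first_success   # trial at which replay flips to B-A-C
```

## Command line

A small CLI covering teaching, replay, overwriting and the event-camera demo
is installed under `inst/scripts/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/serialmem-cli.R", package = "serialmem"))')" \
  teach --items C,A,B --seed 1 --outdir out/
```

## Acceptance targets

`scripts/acceptance.R` recomputes the two quantitative behavioral targets
from scratch and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
# {"t3": <modal re-teaching trials to overwrite C-A-B with B-A-C>,
#  "t4": <modal number of correctly replayed positions of A-A-C>}
```

## Tests

```r
testthat::test_dir("tests/testthat", package = "serialmem",
                   load_package = "installed")
```

The suite contains per-module oracle tests (closed-form rates, three-branch
plasticity oracle, WTA row counts, block-structure and file round-trips) and
an end-to-end acceptance file running the full teach/replay/unlearn
behaviors over many seeds; the acceptance file takes several minutes.

## Notes on scale and units

Voltages and currents are in arbitrary-but-consistent units (the
rest-to-threshold distance is 1); time is in milliseconds. Default
architectures use 170 neurons (K = 3) or 210 neurons (K = 5) of the
256-neuron budget, simulated at dt = 0.1 ms.
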