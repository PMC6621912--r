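# deeplsm

Deep liquid state machines with neural plasticity, in R.

A liquid state machine (LSM) is a reservoir computer made of spiking
neurons: a fixed, randomly connected recurrent population transforms an
input stream into a high-dimensional transient state, and only a readout is
trained. A single reservoir limits the time-scales the state can represent.
`deeplsm` implements a *deep* LSM — a stack of leaky integrate-and-fire
reservoirs joined by small spiking winner-take-all (WTA) layers that learn,
with purely local unsupervised plasticity, a low-dimensional spike code for
the reservoir beneath them — together with the attention-modulated readout
that classifies the stack's state, and an analytic model of the synapse,
operation, memory and energy budgets of deep-LSM, flat-LSM and LSTM
architectures. It is aimed at researchers in reservoir computing and
neuromorphic systems who need a reproducible, testable reference
implementation of these mechanisms without GPU or external-dataset
dependencies.

## The model in brief

* **Neurons**: leaky integrate-and-fire, `τ_m dV/dt = −V + I·R`, forward
  Euler at 1 ms, threshold 16.5 mV, 4 ms refractory period; presynaptic
  spikes inject 3 ms square current pulses scaled by the sender's
  short-term efficacy.
* **Short-term plasticity**: `S(n) = S(n−1) − α(x(n) − β)`, clamped to
  [0, 1] — a linearized, constant-step depression/recovery rule.
* **Synaptic trace**: `X' = X·e^(−dt/τ) + x(n)`, τ = 300 ms; the
  concatenated traces `X_deep = [X_1, …, X_L]` are the classification
  state.
* **Reservoirs**: 3-D lattices, 4:1 excitatory:inhibitory, connection
  probability `C·exp(−D/λ)²` per ordered type pair, type-fixed weights,
  incoming sums normalized to 40 (E) / 36 (I).
* **WTA layers**: at most one spike per millisecond; the winner is trained
  by pre-trace STDP `ΔW = η(X_pre − X_tar)`, synaptic scaling to a fixed
  incoming sum of 15, and intrinsic threshold plasticity (+1.5 mV per win,
  τ = 500 ms).
* **Readout**: deep attention `A = softmax(W X_deep)` collapses layers,
  sigmoid spatial attention gates neurons, and a logistic layer scores
  classes; trained by full-batch gradient descent with no gradient into
  the spiking stack.
* **Resource model**: closed-form multiplication/synapse/memory/energy
  accounting (0.9 pJ add, 3.7 pJ multiply, 360 pJ DRAM access, 32-bit
  weights) for all three architectures.

## Worked example

Train a 3-layer deep-LSM on the built-in synthetic sequence task (100-dim
feature sequences of 30–650 frames, three latent-motif classes) and read
out the class from the final trace state:

```r
library(deeplsm)

spec <- synth_task_spec(seed = 11)        # 60 train / 30 test sequences
ds   <- generate_sequences(spec)

net <- deep_lsm(deep_lsm_preset("benchmark", seed = 5,   # 3 x 500 + 2 x 50
                                frame_duration_ms = 3))
net <- fit_encoder(net, ds$train$sequences)
net <- train_wta_layers(net, ds$train$sequences, epochs_per_layer = 1)

snap_tr <- collect_snapshots(net, ds$train$sequences)
snap_te <- collect_snapshots(net, ds$test$sequences)
fit <- train_readout(snap_tr, ds$train$labels, n_layers = 3, n_hidden = 500,
                     lr = 0.5, epochs = 300, seed = 5,
                     standardize = TRUE, l2 = 1e-3)
evaluate_readout(fit$params, snap_te, ds$test$labels)$accuracy
#> [1] 0.8666667
linear_baseline(ds)      # LDA on time-averaged features
#> [1] 1
```

The trained network reaches 86.7% test accuracy against a 33.3% chance
level. On the standard task a memoryless linear baseline is also strong
(the class means are linearly separable by construction); the deep network
earns its keep on the `temporal_order = TRUE` variant, where all classes
share the same motif segments in different orders — there the time-average
carries no class signal, the baseline drops to near chance (~17–30%), and
the deep-LSM still classifies well above it (~53–77% across seeds) because
trace decay weights recent segments differently.

The analytic resource table for the benchmark comparison (3×500 deep-LSM
vs. 1500-neuron LSM and LSTM, 100 inputs, 10 classes):

```r
resource_table()[, c("model", "total_synapses", "memory_gb", "fp_mults",
                     "total_uJ")]
#>                 model total_synapses memory_gb fp_mults  total_uJ
#> 1            deep-lsm         103200    0.0033   103200   39.5439
#> 2  deep-lsm+attention         847700    0.0271   845200  314.4869
#> 3                 lsm         135000    0.0043   135000   50.7358
#> 4       lsm+attention        2385000    0.0763  2385000  881.3806
#> 5                lstm        9615000    0.3077  9619500 3550.1547
```

(`*_ref` columns in the full table carry published benchmark counts where
those differ from the closed-form formulas; the energy columns are computed
from the reference counts, so architectures whose published counts are
self-consistent reproduce their published energy rows.)

A thin command-line wrapper for the pipeline stages lives in
`inst/cli/deeplsm.R`:

```sh
Rscript inst/cli/deeplsm.R synth --out runs/demo
Rscript inst/cli/deeplsm.R train-wta --out runs/demo
Rscript inst/cli/deeplsm.R simulate --out runs/demo
Rscript inst/cli/deeplsm.R train-readout --out runs/demo
Rscript inst/cli/deeplsm.R evaluate --out runs/demo
```

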