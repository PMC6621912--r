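---
title: "Deep liquid state machines: model, plasticity and resource accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep liquid state machines: model, plasticity and resource accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deeplsm)
```

## The model

A liquid state machine (LSM) is a reservoir computer built from spiking
neurons: a recurrently connected population with *fixed random* weights is
driven by an input stream, and only a readout trained on the reservoir's
state performs the task. A single reservoir captures input history on
essentially one time-scale and its performance is hostage to the random
initialization. The deep LSM implemented here stacks several reservoirs and
inserts a small competitive *winner-take-all* (WTA) layer between each pair:
the WTA layer learns, with purely local unsupervised plasticity, a
low-dimensional spike code for the reservoir below it, and that code drives
the next reservoir. Deeper reservoirs therefore see increasingly abstract,
increasingly slow descriptions of the input. Classification is performed on
the concatenated *synaptic traces* of all reservoirs through a two-stage
attention network and a logistic readout, none of which ever backpropagates
into the spiking stack.

### Neuron and synapse dynamics

Membrane potentials follow leaky integrate-and-fire dynamics
$\tau_m \dot V = -V + I R$, integrated by forward Euler at a fixed 1 ms
timestep (`lif_params()`, `lif_step()`). A neuron crossing the 16.5 mV
threshold spikes, resets to the 0 mV rest and is clamped there for a 4 ms
refractory period. A presynaptic spike injects a square current pulse into
its targets for the 3 ms following the spike, with amplitude
`weight × S × κ` where `S` is the presynaptic short-term efficacy and κ a
global current-to-potential scale (`psc_drive()`).

Short-term plasticity is the linearized rule
$S(n) = S(n-1) - \alpha\,(x(n) - \beta)$ clamped to $[0,1]$: a spiking
neuron's outgoing efficacy drops by a constant step and recovers while
silent. The update is state-independent in magnitude, which is what makes it
cheap on neuromorphic hardware. Each neuron also carries a synaptic trace —
a leaky spike count $X' = X e^{-\Delta t/\tau_{trace}} + x(n)$ with
$\tau_{trace} = 300$ ms. The decay is applied in exact closed form rather
than by Euler: the trace equation is linear, the exact form removes all
step-size error, and it lets tests pin trace trajectories against
closed-form values at $10^{-12}$ tolerance.

### Reservoir construction

Each reservoir is a 3-D integer lattice of neurons, four excitatory to one
inhibitory (exactly, which is why layer sizes must be divisible by five).
When only a neuron count is configured the lattice shape is its most-cubic
factorization (1000 → 10×10×10). A directed connection $i \to j$ forms with
probability $C\,(e^{-D(i,j)/\lambda})^2$, with $C$ and $\lambda$ per ordered
type pair (EE 0.6, EI 1, IE 1, II 0.2; $\lambda = 3$ throughout), $D$ the
Euclidean lattice distance without wraparound, and the square applied to the
exponential factor only. Self-connections are excluded; the two directions
of a pair are sampled independently. Weights are fixed by type (EE 3, EI 3,
IE 4, II 1), then each neuron's incoming excitatory weights are rescaled to
sum to 40 and its inhibitory ones to 36, so all neurons share a homogeneous
excitability. Normalization happens once at construction; reservoir weights
never change afterwards.

The input projection is Bernoulli-sparse (default connection probability
0.05): neurons with at least one input synapse are "primary", the rest
"auxiliary" and purely recurrent. Primary status thus emerges from the
sampled connectivity rather than being designated up front.

### Winner-take-all encoding layers

A WTA layer is fully connected to its reservoir. Each step it integrates
the current reservoir spike vector; among supra-threshold neurons the one
with the highest membrane potential wins (ties to the lowest index, for
reproducibility), emits the layer's only spike, and every other membrane
potential is reset — global inhibition realized as a same-timestep reset
rather than through explicit inhibitory synapses, which matches the
all-or-nothing competition at 1 ms resolution. Three homeostatic/plastic
mechanisms act on a win during training:

* **Trace-based STDP** (`stdp_update()`): every incoming weight of the
  winner moves by $\eta\,(X^{trace}_{pre} - X^{tar})$ — potentiation for
  presynaptic neurons whose trace exceeds the target $X^{tar} = 25$,
  depression otherwise. Depression uses the same rule below target rather
  than a separate post-before-pre term; the rule is a pre-trace-only
  simplification in which a single trace per neuron replaces per-synapse
  timing windows.
* **Synaptic scaling** (`synaptic_scale()`): the winner's incoming sum is
  immediately renormalized to 15, keeping the competition fair at every
  step. Scaling after each update (rather than per epoch) was chosen
  because nothing else bounds the weights between wins.
* **Intrinsic plasticity** (`intrinsic_update()`): the winner's threshold
  offset jumps by 1.5 mV and decays with $\tau = 500$ ms, preventing one
  neuron from monopolizing wins; the winner histogram over long random
  input is measurably more uniform with it on (a property test asserts a
  lower coefficient of variation).

WTA training is greedy and layer-wise: layer $k$ trains while layers
$< k$ are frozen, because the input statistics of a deeper layer only
stabilize once the layers feeding it stop changing. Intrinsic plasticity
and STDP are confined to WTA layers; reservoir neurons keep fixed
thresholds, and short-term plasticity is confined to reservoirs.

### Attention readout

After a sequence has been run, the concatenated trace vector
$X_{deep} = [X_1, \dots, X_L]$ is the classification state. A deep
attention network scores each layer
($A^{deep} = \mathrm{softmax}(W^{deep} X_{deep})$), the layers are
collapsed to $X^S = \sum_l A^{deep}_l X_l$, a spatial attention network
gates each neuron independently
($A^{spatial}_n = \sigma(W^{spatial}_n X_{deep})$, no normalization across
neurons), and the readout scores classes as
$y = \sigma(W^{out} (X^S \odot A^{spatial}))$. The predicted label is the
argmax of $y$. σ is read as the logistic function per class; training adds
a softmax-cross-entropy head over $y$, since the forward contract specifies
per-class sigmoids but no loss. The readout sees only the gated state, not
the raw traces.

Training is full-batch gradient descent through these three weight blocks
only — snapshots are constants, so no gradient ever reaches the spiking
network and no backpropagation through time occurs. Analytic gradients are
verified against central finite differences at $10^{-5}$ relative
tolerance. Optional conveniences (both off by default and not part of the
forward contract): per-column standardization of snapshots, stored in the
trained parameters and replayed at prediction, and a small ridge penalty.
Both noticeably improve conditioning when snapshots span orders of
magnitude.

## Amplitude scales: the open constants

The published dynamics fix weights (3/3/4/1), normalization targets
(40/36) and thresholds (16.5 mV) but never state the factor converting a
weighted spike pulse into millivolts of drive. These conversion constants
are genuinely open design choices in this implementation, chosen once from
an activity scan targeting 2–10% of neurons firing per millisecond (the
regime in which traces at $\tau_{trace} = 300$ ms land near the STDP target
$X^{tar} = 25$), and then frozen:

* `kappa = 2` — mV of drive per unit recurrent weight;
* `input_gain = 25` — mV per unit normalized feature through the input
  projection (features are min-max normalized per dimension, fitted on
  training data);
* `wta_gain = 60` — gain of the WTA drive. The incoming sum is pinned at
  15 by scaling, so with a fraction $f$ of reservoir neurons spiking the
  expected drive is $60 \cdot 15 f \approx 60$ mV at $f = 0.07$, enough to
  win every few milliseconds against the leak;
* `wta_in_weight = 100` and `inter_sparsity = 0.4` — the WTA→reservoir
  coupling. This is the one place this implementation departs from the
  symmetric "reuse the input sparsity" convention: a WTA layer emits at
  most one spike per millisecond across 50 channels, and at 95% sparsity
  such a code cannot keep a 500-neuron reservoir active at all (measured
  layer-2 rates below 1%, layer 3 silent). Denser, stronger inter-layer
  connections restore healthy deep-layer activity (≈5% and ≈2% per ms in
  layers 2 and 3) while the input projection keeps its 95% sparsity.

The STDP learning rate is similarly unstated in the source material. It is
set to $5 \times 10^{-4}$: with incoming sums scaled to 15 over 500 inputs
the mean weight is 0.03, and the largest possible depression step
$\eta X^{tar}$ must stay below that or a single update zeroes a neuron's
weight vector (the run-away case is additionally guarded: a row driven to
zero keeps its previous weights and the event is counted on the layer).

## The synthetic task

Real use targets CNN-extracted, PCA-reduced video-frame features; the
package instead generates sequences with the same shape so the whole
pipeline is testable offline: 100 dimensions, lengths from a log-normal
clipped to [30, 650] with its mean-log solved numerically so the clipped
mean is 157 frames. Each class is a latent motif — a class-specific
constant offset (standing in for class-conditional object features), class-
specific sinusoids, a shared random walk — projected through a fixed random
matrix with Gaussian observation noise. The `temporal_order` variant plays
the *same* three motif segments in class-specific orders, so time-averaged
features are class-uninformative by construction and a memoryless linear
baseline (LDA on time-averaged features, `linear_baseline()`) falls to
chance; the deep LSM separates it through the decay asymmetry of its
traces. What the generator does **not** emulate: the heavy-tailed,
correlated statistics of real CNN features, within-class temporal warping,
or label noise — so passing tests demonstrate mechanism recovery, not
benchmark-level vision performance.

Each frame is presented for a configurable number of 1 ms timesteps
(default 1). The synthetic study itself presents each frame for 3 ms: the
frame-to-timestep mapping is an open modelling choice, and at 1 ms/frame a
mean-length sequence (157 frames) spans only half of
$\tau_{trace} = 300$ ms, so the end-of-sequence trace barely distinguishes
*when* within the sequence a segment occurred; at 3 ms/frame a mean
sequence spans about $1.6\,\tau_{trace}$, giving the trace decay enough
contrast to separate segment orders. State is fully reset between
sequences, which are independent samples.

## Resource model

`count_fp_mults()`, `count_bp_mults()`, `count_synapses()`,
`memory_gigabits()` and `energy_estimate()` implement closed-form
accounting of multiplications, synapse counts by learning rule, 32-bit
weight memory and energy (0.9 pJ per addition, 3.7 pJ per multiplication,
360 pJ per DRAM weight access, 45 nm constants) for deep-LSM, flat-LSM and
LSTM architectures. `arch_preset("benchmark")` encodes the reference
comparison (100 inputs, 3×500 deep-LSM with 50-neuron WTA layers and a
500-unit spatial attention vs. a 1500-neuron LSM and LSTM, 10 classes).
Two accounting subtleties are surfaced rather than hidden:

* STDP-trained reservoir→WTA projections are *fully connected* in the
  simulator (50,000 weights in the preset) but the published benchmark
  counts them density-discounted (2,500); `count_synapses()` reports both
  (`wta_counting = "full"` / `"sparse"`).
* A few published benchmark counts do not follow from their own printed
  formulas (the deep-LSM forward count among them). The preset therefore
  carries the published counts as `ref_counts`, and `resource_report()`
  exposes formula-derived and reference-derived values side by side
  (`fp_mults` vs `fp_mults_ref`, etc.); tests pin only cells that are
  self-consistent.

## Numerical and degenerate-case choices

* Exact exponential decay for traces and intrinsic thresholds; Euler only
  for the membrane equation (where the 1 ms step is part of the model).
* WTA ties break to the lowest index; readout argmax likewise.
* Reservoir neurons with no incoming weight of a class are left alone by
  normalization; all-zero rows are an error for `synaptic_scale()`.
* σ = 0 in the weight-noise model short-circuits before any RNG draw, so
  the noise-free path is bit-identical to not using the model at all.
* All randomness derives from one master seed through a label hash
  (`derive_seed()`), so topology, initialization and input encoding can be
  varied independently while any experiment stays a pure function of its
  configuration.

## Problem sizes used in the test-suite

Unit tests run on 50-neuron reservoirs and 8–12 sequence datasets. The
functional-recovery check uses the benchmark geometry (3 reservoirs × 500
neurons, 50-neuron WTA layers) on 60 training and 30 test sequences of
mean length 157 — the smallest configuration at which all three reservoirs
are active and the deep state is informative; one greedy epoch per WTA
layer and 300 readout epochs suffice there. Connectivity statistics are
verified on 250-neuron grids aggregated over 25 seeds (>10,000 Bernoulli
draws per distance bin).

## Known limitations

* Current-based square pulses only; no conductance synapses, no
  sub-millisecond events, no exponential PSC kernels.
* The WTA spike budget (≤1/ms) bounds the information rate between layers;
  very deep stacks would starve without revisiting the inter-layer coupling.
* The readout trains on end-of-sequence snapshots; there is no mid-sequence
  streaming classification.
* The LSTM appears only as analytic cost formulas, not as a functional
  baseline.
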