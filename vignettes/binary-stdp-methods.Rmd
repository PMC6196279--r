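---
title: "Stochastic STDP with 1-bit synapses: models, parameters and design choices"
author: "bitsnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic STDP with 1-bit synapses: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitsnn)
```

## The problem

Dedicated neuromorphic hardware pays for every bit of synaptic precision in
memory, computation and communication. `bitsnn` simulates the limiting case:
spiking networks whose synapses hold a single bit, trained on-line by a
stochastic, order-based form of spike-timing-dependent plasticity (STDP).
A plain stochastic bit-flip rule on its own does not learn; the package
implements the set of stabilization mechanisms that make it work, and the
surrounding experimental loop (event streams, encoders, classifiers, and a
behavioral cost model of the hardware STDP unit).

## Neuron model

Neurons are linear-leak integrate-and-fire units with instantaneous synapses
and non-negative state. An input event through an active (bit = 1) synapse
increments the state by one; the state is compared against a threshold
$x_{th}$, firing resets it to zero, and there is no refractory period.

The exponential leak $x_0 e^{-t/\tau}$ is approximated the way the hardware
does it: a fixed decrement per tick whose magnitude is halved (a bit shift)
at fixed elapsed-time breakpoints. `fitLeakSchedule(tauUs)` places the
halvings one half-life ($\tau\ln 2$) apart and chooses the initial decrement
to minimize the worst-case deviation from the exponential for a reference
state of 100 units; the achieved error is stored in the schedule
(`fitError`, about 5 units per 100 for the default three segments, i.e. a
~5% envelope). Leak is evaluated lazily, only when an event touches a
neuron. Because the linear decay reaches zero in finite time, an
inter-symbol gap of `leakRestTime(schedule)` guarantees a full reset
between samples.

## The stochastic 1-bit STDP rule

The rule is of the "undiscriminating depressing", order-based family: only
a bounded pre-synaptic list is kept (`PreBuffer`, the population's last
`bufferSize` input addresses, no timestamps). Whenever a neuron produces an
STDP trigger:

1. **LTP.** Each of the up to `numberOfPotentiation` most recent buffered
   addresses is set to 1 with probability $P_{LTP}$. Potentiation is
   idempotent; duplicate addresses cost extra draws but cannot corrupt the
   state.
2. **LTD.** All remaining active synapses of that neuron are depressed so
   that the active count returns toward the budget $W_{sum}$:
   *deterministically* (exactly $\Delta W = \mathrm{popcount} - W_{sum}$
   victims cleared, chosen uniformly at random) or *stochastically* (every
   active bit cleared with probability
   $\lfloor 1024\,\Delta W/\mathrm{popcount}\rfloor / 1024$, the 10-bit
   integer scale the hardware divider produces). The stochastic variant
   removes $\Delta W$ synapses in expectation, so the popcount wanders
   around the budget instead of sitting on it.
3. **Flushing.** The pre-buffer is emptied (configurable), so the history
   that caused this trigger does not also drive the next one.

The stabilization mechanisms, all per-neuron and all configurable:
homeostatic threshold growth on every spike (`thIncrement`, default 1),
a threshold ceiling `xThMax`, weight normalization to `wSumTarget`,
optional separate learning/inference counters and thresholds
(`dualThreshold`, the on-line hardware mode; software experiments train
layers sequentially with a single threshold), winner-take-all lateral
inhibition (one spike per input event, all other population members reset),
and list flushing.

A generic event-list engine (`StdpEngine`, `kernelEval`) covers the wider
kernel family — classic, rectangular, narrow-potentiation and the two
symmetric shapes, in both time-based and order-based modes — mainly for
study and comparison; the 1-bit rule above is the narrow-potentiation
order-based kernel with $N_{min}=0$, $N_{max}=\infty$ and probabilities on
the vertical axis.

### Numerical and tie-break choices

* Deterministic-LTD victims are drawn uniformly among active synapses not
  named in the buffer; when fewer such synapses exist than $\Delta W$
  (routine when the active input region exceeds $W_{sum}$), buffered
  synapses are depressed too and a classed condition
  (`bitsnnLtdFallback`) is signaled; `runNetwork()` muffles it by default.
* WTA ties break to the lowest index by default (deterministic,
  reproducible); a seeded random policy is available.
* Probabilities live on $[0,1]$ floats by default; the hardware-emulation
  path (`probabilityScale = "int1024"`, `applyBinaryStdpHw`) works on the
  10-bit integer grid and draws from a 16-bit maximal LFSR
  (taps 16, 15, 13, 4 — verified maximal by full enumeration), accepting
  when the low 10 bits are strictly below the probability value. In that
  mode LTD rescans all weights without buffer protection, as the hardware
  does.
* The whole per-event integration loop is compiled (Rcpp); STDP updates
  are rare and are dispatched back to the single R implementation, so the
  tested rule and the rule the simulator runs are the same code.

## Classifiers

Two output layers are provided:

* **Simple teacher-driven STDP classifier.** Integer weights; the
  post-synaptic spike is replaced by a teacher naming the correct class;
  the buffered feature-layer spikes potentiate that class's column by
  `learnRate`, after which the column is renormalized to its budget by
  integer largest-remainder scaling. Readout is the spike-count-weighted
  argmax.
* **Histogram/softmax classifier.** Per-sample L1-normalized spike-count
  histograms of the feature layer train a bias-free softmax by mini-batch
  SGD; the frame-domain classifier is converted to spiking neurons by
  scaling the weights by $k$ and setting every output threshold to $k$.
  Negative weights are removed by a single *global* offset before scaling
  (a per-class offset would shift class scores unequally and change the
  argmax; a global one adds the same amount to every class per input
  event). Output neurons reset by threshold subtraction rather than to
  zero: trained softmax weights routinely exceed 1 in raw scale, so with
  reset-to-zero one input event could cross several thresholds and the
  spike count would no longer track the frame-domain score; subtraction is
  the rate-preserving conversion. Reset-to-zero remains available
  (`resetMode = "zero"`).

## Synthetic data: what it emulates and what it does not

* `orientedBarImage` draws the 32×32 oriented-bar stimulus: an 8×24-pixel
  bar with i.i.d. intensities in $U[0.8, 1.0]$; 90° is the exact transpose
  of the 0° image and diagonal angles are nearest-neighbor rotations
  (pixel count then deviates slightly from 192).
* `poissonEncode` implements constant-population-rate coding: pixel rates
  proportional to intensity, total rate fixed. With a fixed per-sample
  spike count the generator samples the population process conditioned on
  its total: i.i.d. addresses with probability proportional to intensity
  and sorted uniform times.
* `movingSymbolStream` is a *statistical stand-in* for event-camera
  recordings of hand-moved printed symbols: events come from glyph edge
  pixels and their density is proportional to instantaneous speed, so a
  stationary symbol emits nothing. It does not model sensor noise,
  per-pixel latency or polarity statistics, so passing tests show the
  pipeline works on edge-driven, motion-dependent event streams — not that
  it would reach any particular accuracy on real recordings.

## Experiment conditions

The orientation-selectivity run uses 4 neurons on 1024 inputs, initial
threshold 10, ceiling 100, buffer 250, $P_{LTP}=80\%$, $W_{sum}=180$,
deterministic normalization, 400 epochs of the four orientations in random
order. Where the reference conditions leave the encoding open, the package
fixes: 200 spikes per sample at a 100 kev/s population rate, leak
$\tau = 12$ ms, inter-symbol time equal to the full leak-to-rest time.
The rate was chosen so that per-event integration dominates the leak
between events even for unspecialized neurons (at 100 kev/s the leak costs
≈0.06 state units per inter-event gap against increments of 1); at a 20
kev/s rate the leak suppresses all but the first-winning neuron and the
population cannot diversify.

The 4-class moving-symbol pipeline uses a 32-px glyph in a 64×64 field
subsampled to 32×32 inputs, with the glyph center wandering ±2 px around
the field center. The wander amplitude is the lever that sets task
difficulty: at ±2 px raw input histograms are ~95% separable (the task
probes feature quality, not position invariance, which a fully connected
layer does not possess), while at ±5 px and beyond position variance
swamps shape and no feature layer can recover it. Training is one
unsupervised pass; weights, thresholds and inhibition are then frozen for
classifier training and evaluation. The shipped problem sizes (200
training / 50 test samples, 32 neurons, ~1500 events per sample) keep a
full STDP-vs-random comparison over five seeds within a few minutes.

Test-error confidence intervals use the binomial expression
$\hat\mu \pm z^* \sqrt{\hat\mu(1-\hat\mu)/N_T}$ with $z^* = 2.578$ at the
0.99 level.

## Hardware cost model

`CycleCostModel` reproduces the steady-state clock-cycle accounting of the
shared STDP unit: LTP takes `7 + numberOfPotentiation` cycles (3-cycle
buffer read + 3-cycle weight read + 1 pipeline pad), LTD takes
`synapseCount + 3 + 25 + synapseCount + 7` cycles (read-all, serial
divide, depress-all), so a full update costs `2090 + numberOfPotentiation`
cycles at the 1024-synapse defaults and the unit saturates at
`clockHz / totalCycles` triggers per second. Events arriving while an
update runs are ignored (modeled as a lockout, not queued). The
resource-scaling relations $R_{syn}=\alpha_{syn}N_iN_hn_b$,
$R_h=\alpha_hN_hn_b$, $R_{ov}=\alpha_{ov}n_b$ express the
neurons-for-bits trade: with overhead negligible, constant $N_h \times
n_b$ means constant hardware.

## Known limitations

* Weight matrices are dense integer matrices; at $10^4$+ neurons a packed
  bit representation would be needed.
* The simulator models one population per run; multi-layer on-line
  (dual-threshold) training is supported mechanically but the shipped
  experiments train layers sequentially.
* The moving-symbol surrogate's accuracy numbers are not comparable to
  any real event-camera dataset; only the *direction* of the
  STDP-vs-random contrast is meaningful.
* `readIdx` loads full datasets into memory; it is meant for small
  subsets and fixtures.
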