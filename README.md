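# bitsnn — event-driven spiking networks with 1-bit stochastic STDP

Synaptic plasticity rules are usually studied at full floating-point
precision, but neuromorphic hardware pays for every weight bit in memory,
computation and energy. `bitsnn` is for researchers and hardware designers
who want to study the limiting case: spiking networks whose synapses hold a
**single bit**, trained on-line by **stochastic order-based STDP**, plus the
behavioral cost model of the digital STDP unit that would run the rule.

The core rule is of the *undiscriminating depressing* family. The
population keeps a bounded pre-synaptic address list (no timestamps);
whenever neuron $j$ triggers an STDP update:

* **LTP** — each of the most recent buffered addresses $i$ is potentiated,
  $w_{ij} \leftarrow 1$, with probability $P_{LTP}$;
* **LTD** — the active-synapse count is pushed back to the budget
  $W_{sum} = \sum_i w_{ij}$: either exactly
  ($\Delta W = \mathrm{popcount} - W_{sum}$ random victims cleared) or
  stochastically, each active bit cleared with probability
  $\lfloor 1024\,\Delta W / \mathrm{popcount}\rfloor / 1024$ — the 10-bit
  integer probability the hardware compares against a 16-bit LFSR.

Learning is stabilized by per-neuron homeostatic threshold growth with a
ceiling $x_{th} \le x_{th_{max}}$, winner-take-all lateral inhibition,
optional separate learning/inference thresholds, and pre-list flushing.
Neurons are linear-leak integrate-and-fire with a bit-shift (piece-wise
linear) leak approximating $e^{-t/\tau}$.

The package also provides AER event-stream I/O and slicing, Poisson
rate-coding with constant population rate, synthetic oriented-bar and
DVS-like moving-symbol generators, a teacher-driven STDP classifier and a
histogram/softmax classifier convertible to spiking neurons, and clock-cycle
/ resource / saturation analytics of the hardware STDP unit.

## Worked example: development of orientation selectivity

Four neurons with 1024 binary inputs watch Poisson-encoded oriented bars
(0°, 45°, 90°, 135°; 8×24 px, intensities U[0.8, 1.0]) for 400 epochs with
buffer 250, $P_{LTP} = 80\%$, $W_{sum} = 180$, thresholds growing from 10
to a ceiling of 100 under deterministic weight normalization:

```r
library(bitsnn)
net <- runOrientationTraining(orientationConfig(), seed = 1)
net
#> FeNetwork: 1024 inputs -> 4 neurons
#>   firing thresholds: 100 100 100 100
#>   W_sum target: 180 , normalization: deterministic

tc <- measureTuning(net)    # plasticity, threshold dynamics, WTA disabled
tc
#> TuningCurve: 4 neurons x 19 angles
#>   preferred angles: 40 0 90 130 deg
```

Every neuron ends with exactly 180 active synapses (the budget), every
threshold has saturated at 100, and the four tuning-curve peaks sit on (or
one 10°-probe step away from) the four trained orientations — each neuron
has developed a receptive field selective for a distinct orientation.
`writeReceptiveFieldPgm()` dumps the 1-bit receptive fields as PGM images.

The hardware-unit analytics are closed-form:

```r
hwCostTable(c(90, 1024))
#>   numPotentiation ltpCycles ltdCycles totalCycles saturationEps
#> 1              90        97      2083        2180      45871.56
#> 2            1024      1031      2083        3114      32113.04

confidenceInterval(0.5, 100)   # binomial 0.99 CI, z* = 2.578
#> low      high      halfWidth
#> 0.3711   0.6289    0.1289
```

A thin command-line front end lives in `inst/scripts/bitsnn-cli.R`
(`orientation train|tune`, `pipeline run`, `hwcost`).

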