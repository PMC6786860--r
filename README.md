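# eqspike

An equation-oriented simulator for spiking neural networks in R. Models
are written as plain-text differential equations annotated with physical
units — defining a new neuron, synapse, muscle or stimulus model should
be no harder than writing down its equations — and the simulator
validates them dimensionally, compiles them to vectorized kernels, and
advances them through a fixed per-timestep schedule of graded synaptic
coupling, numerical integration, thresholding, delayed spike delivery,
and reset.

It is aimed at computational neuroscientists who need *non-standard*
models: graded (continuous) synapses, homeostatically regulated
conductances, closed sensorimotor loops, stimulus-dependent protocols —
things that fixed model libraries cannot express. The complete
computational experiment, including control flow such as parameter
sweeps or bisection searches, is ordinary R code around `run_network()`,
with `store_network()`/`restore_network()` snapshots for rewind-and-branch
protocols.

## The core machinery

* **Quantities and dimensions** — every value carries a 7-exponent SI
  dimension; `1*volt + 1*amp` is an error, `second**-0.5` (the dimension
  of the white-noise symbol `xi`) is representable. Both sides of every
  equation are checked symbolically before anything runs.
* **Equation DSL** — `dX/dt = rhs : unit (flags)` for dynamics,
  `X = rhs : unit` for subexpressions, `X : unit (flags)` for parameters;
  flags include `constant`, `linked`, `summed`, `unless_refractory`.
* **Integrators** — linear constant-coefficient systems are detected
  symbolically and advanced **exactly** via the matrix exponential of the
  augmented system, x(t+dt) = e^(A·dt) x(t) + k (per-instance matrices for
  heterogeneous coefficients); nonlinear deterministic systems default to
  exponential Euler; `dX/dt = f + g*xi` uses Euler–Maruyama. Explicit
  `euler` and `rk4` are available.
* **Synapses** — connectivity from boolean expressions over `i`, `j` and
  `_pre`/`_post` variables (`'label_pre != label_post and not (...)'`),
  per-synapse state and differential equations, per-pathway transmission
  delays through exact ring-buffer queues, and continuous graded coupling
  via `(summed)` variables.
* **Protocols** — seeded determinism, bit-exact snapshots, and
  `find_threshold()`, a parallel bisection search for per-instance voltage
  thresholds.

Five runnable fixtures ship with the package: a homeostatically
regulated pyloric circuit (`build_pyloric`), a closed-loop ocular
pursuit model (`build_ocular`), voltage-threshold finding across a
sodium-density sweep (`threshold_sweep`), a delay-line pitch detector
with a stored audio waveform (`build_pitch`), and the CUBA
random-network benchmark (`build_cuba`).

## A worked example

Three leaky integrate-and-fire neurons with different drives; only a
neuron whose asymptotic potential exceeds the −50 mV threshold can fire:

```r
library(eqspike)

g <- create_group(3, "
  dv/dt = (v0 - v)/tau : volt
  v0 : volt (constant)",
  threshold = "v > -50*mV", reset = "v = -60*mV",
  refractory = parse_unit_expression("5*ms"),
  namespace = list(tau = parse_unit_expression("10*ms")))
set_state(g, "v", "-60*mV")
set_state(g, "v0", "(-45 - 5*i)*mV")   # -45, -50, -55 mV across instances

spikes <- spike_monitor(g)
net <- create_network(g, spikes)       # dt = 0.1 ms
run_network(net, parse_unit_expression("100*ms"))

spikes$spike_counts()
#> [1] 9 0 0
round(head(spikes$times()) * 1e3, 1)
#> [1] 10.9 21.9 32.9 43.9 54.9 65.9
```

Neuron 0 (drive −45 mV) fires regularly: it charges from −60 mV toward
−45 mV and crosses −50 mV after τ·ln(15/5) ≈ 11 ms, then a 5 ms
refractory period plus the recharge sets the ~11 ms interval. Neurons 1
and 2 relax toward −50 mV and −55 mV and never cross the strict
threshold, so they stay silent. The same machinery scales to the full
benchmark: `build_cuba(N = 4000)` wires ~320,000 synapses
(`cuba_mean_in_degree()` ≈ 80) and runs with the exact integrator.

A command-line front end over the fixtures is installed at
`inst/cli/eqspike`, e.g.

```sh
Rscript inst/cli/eqspike run pyloric --duration 10s --out out/
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the equation
grammar, the execution schedule, each integration method and its
selection policy, the five fixtures with the rationale for every
calibrated constant, and known limitations.
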